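test_that("material presets carry the published plaque constants", {
  tbl <- fxPresets()
  m <- materialOf(tbl, "MATX"); c_ <- materialOf(tbl, "CALC")
  l <- materialOf(tbl, "LRNC")
  expect_equal(m@c1, 2.35e4); expect_equal(m@c2, 1.26e5); expect_equal(m@c3, 1.12e5)
  expect_equal(c_@c1, 3.02e5); expect_equal(c_@c2, -2.28e5); expect_equal(c_@c3, 2.61e5)
  expect_equal(l@c1, 2.96e4); expect_equal(l@c2, -3.32e4); expect_equal(l@c3, 1.29e5)
  # default volumetric penalty and small-strain stiffness ordering
  for (lab in c("MATX", "CALC", "LRNC"))
    expect_equal(materialOf(tbl, lab)@kappa, 1000 * 2 * materialOf(tbl, lab)@c1)
  mu <- vapply(c("MATX", "CALC", "LRNC"),
               function(lab) initialShearModulus(materialOf(tbl, lab)),
               numeric(1))
  expect_equal(unname(mu), c(4.70e4, 6.04e5, 5.92e4))
  expect_true(mu["CALC"] > mu["LRNC"] && mu["LRNC"] > mu["MATX"])
})

test_that("energy and stress vanish at the reference state for all presets", {
  tbl <- fxPresets()
  for (lab in c("MATX", "CALC", "LRNC")) {
    m <- materialOf(tbl, lab)
    expect_identical(strainEnergy(m, diag(3)), 0)
    expect_identical(strainEnergy(m, diag(2)), 0)
    expect_equal(max(abs(cauchyStress(m, diag(3)))), 0)
  }
})

test_that("incompressible uniaxial stretch reproduces the hand-computed energy", {
  m <- materialOf(fxPresets(), "MATX")
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  # cubic in (I1 - 3) = lam^2 + 2/lam - 3 = 0.10666...7 with the MATX constants
  expect_equal(strainEnergy(m, F), 4076.193, tolerance = 1e-6)
})

test_that("energy is frame-indifferent and isotropic under random rotations", {
  set.seed(7)
  tbl <- fxPresets()
  for (rep in 1:10) {
    F <- randomStates(1, amp = 0.1, seed = 100 + rep)[[1]]
    Q <- randomRotation3()
    for (lab in c("MATX", "CALC", "LRNC")) {
      m <- materialOf(tbl, lab)
      W <- strainEnergy(m, F)
      expect_equal(strainEnergy(m, Q %*% F), W, tolerance = 1e-12)
      expect_equal(strainEnergy(m, F %*% Q), W, tolerance = 1e-12)
    }
  }
})

test_that("small simple shear recovers mu0 = 2*c1 within 0.1%", {
  g <- 1e-4
  F <- diag(2); F[1, 2] <- g
  for (lab in c("MATX", "CALC", "LRNC")) {
    m <- materialOf(fxPresets(), lab)
    sig <- cauchyStress(m, F)
    expect_equal(sig[1, 2] / g, 2 * m@c1, tolerance = 1e-3)
  }
})

test_that("Cauchy stress matches the finite-difference energy oracle", {
  m <- materialOf(fxPresets(), "MATX")
  for (F in randomStates(10, d = 3, seed = 11)) {
    sig <- cauchyStress(m, F)
    expect_lt(maxRel(sig, fdCauchy(m, F)), 1e-4)
  }
  # plane-strain block agrees too
  for (F in randomStates(5, d = 2, seed = 12)) {
    sig <- cauchyStress(m, F)
    expect_lt(maxRel(sig, fdCauchy(m, F)), 1e-4)
  }
})

test_that("material tangent matches finite differences and has major symmetry", {
  tbl <- fxPresets()
  for (lab in c("MATX", "CALC")) {
    m <- materialOf(tbl, lab)
    for (F in randomStates(5, d = 3, seed = 20 + nchar(lab))) {
      A <- materialTangent(m, F)
      expect_lt(maxRel(A, fdTangent(m, F)), 1e-3)
      expect_lt(max(abs(A - aperm(A, c(3, 4, 1, 2)))), 1e-6 * max(abs(A)))
    }
  }
})

test_that("tangent at the reference state is isotropic elasticity with mu0 and kappa", {
  m <- materialOf(fxPresets(), "MATX")
  A <- materialTangent(m, diag(3))
  mu <- 2 * m@c1
  # pure shear increment
  eps <- matrix(0, 3, 3); eps[1, 2] <- eps[2, 1] <- 1e-3
  dsig <- array(0, c(3, 3))
  for (i in 1:3) for (j in 1:3)
    dsig[i, j] <- sum(A[i, j, , ] * eps)
  expect_equal(dsig[1, 2] / (2 * eps[1, 2]), mu, tolerance = 1e-3)
  # pure dilatation increment: mean stress response = bulk modulus
  epsV <- diag(3) * 1e-4
  for (i in 1:3) for (j in 1:3)
    dsig[i, j] <- sum(A[i, j, , ] * epsV)
  expect_equal(mean(diag(dsig)) / (3 * 1e-4), m@kappa, tolerance = 1e-3)
})

test_that("energy is non-negative along incompressible paths for all presets", {
  for (lab in c("MATX", "CALC", "LRNC"))
    expect_gte(energyPathMinimum(materialOf(fxPresets(), lab)), 0)
})

test_that("inverted states are rejected", {
  m <- materialOf(fxPresets(), "MATX")
  expect_error(strainEnergy(m, diag(c(-1, 1))), "inverted")
  expect_error(cauchyStress(m, diag(c(1, -2, 1))), "inverted")
})

test_that("material constructor enforces the near-incompressible kappa floor", {
  expect_error(yeohMaterial(1e4, 0, 0, kappa = 1e4), "kappa")
  expect_s4_class(yeohMaterial(1e4, 0, 0), "YeohMaterial")
})
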