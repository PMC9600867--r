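test_that("zero pressure returns the zero displacement field immediately", {
  mesh <- fxAnnulusMesh(0.4)
  sol <- solveQuasistatic(mesh, fxPresets(), loadCase(0))
  expect_true(isConverged(sol))
  expect_equal(max(abs(displacements(sol))), 0)
})

test_that("inflation oracle has the closed-form limits and monotonicities", {
  m <- materialOf(fxPresets(), "MATX")
  expect_identical(cylinderInflationOracle(m, 3, 4, 0), 1)
  lam <- vapply(c(20, 40, 80, 120), function(p)
    cylinderInflationOracle(m, 3, 4, p), numeric(1))
  expect_true(all(diff(lam) > 0))       # increasing in pressure
  lamThick <- vapply(c(4, 4.5, 5), function(Ro)
    cylinderInflationOracle(m, 3, Ro, 80), numeric(1))
  expect_true(all(diff(lamThick) < 0))  # decreasing in wall thickness
})

test_that("inflation oracle reproduces the frozen independent brute-force value", {
  # reference computed once with an independent high-resolution
  # quadrature + bisection implementation (adaptive quad to 1e-13, Brent
  # to machine tolerance) before the FE solver existed
  m <- materialOf(fxPresets(), "MATX")
  expect_equal(cylinderInflationOracle(m, 3, 4, 80), 1.185707499226,
               tolerance = 1e-8)
})

test_that("oracle rejects pressures beyond the supported stretch range", {
  soft <- yeohMaterial(100, 0, 0, name = "soft")
  expect_error(cylinderInflationOracle(soft, 3, 4, 200), "no inflation solution")
})

test_that("homogeneous annulus inflation matches the semi-analytic oracle", {
  mesh <- fxAnnulusMesh(0.3)
  m <- materialOf(fxPresets(), "MATX")
  sol <- fxMemo("sol_ann03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  lam <- innerWallStretch(mesh, sol)
  lamStar <- cylinderInflationOracle(m, 3, 4, 80)
  expect_equal(lam, lamStar, tolerance = 0.01)
})

test_that("stiffer tissue deforms less under the same pressure", {
  mesh <- fxAnnulusMesh(0.4)
  solM <- solveQuasistatic(mesh, fxPresets(), loadCase(80))
  calc <- materialOf(fxPresets(), "CALC")
  allCalc <- materialTable(calc, calc, calc)
  solC <- solveQuasistatic(mesh, allCalc, loadCase(80))
  expect_lt(max(abs(displacements(solC))),
            max(abs(displacements(solM))))
})

test_that("the solve is deterministic: identical inputs give identical fields", {
  mesh <- fxAnnulusMesh(0.4)
  s1 <- solveQuasistatic(mesh, fxPresets(), loadCase(80))
  s2 <- solveQuasistatic(mesh, fxPresets(), loadCase(80))
  expect_identical(displacements(s1), displacements(s2))
})

test_that("converged solutions are near-incompressible and self-equilibrated", {
  mesh <- fxAnnulusMesh(0.3)
  sol <- fxMemo("sol_ann03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  js <- jacobianStats(mesh, sol)
  expect_lte(js$p99, 1e-3)
  rb <- reactionBalance(mesh, fxPresets(), sol)
  expect_lte(rb$relativeImbalance, 0.005)
})

test_that("the solver is equivariant under mirror reflection", {
  # mirror-symmetric physics: reflecting mesh and constraints must reflect
  # the displacement field
  spec <- crossSectionSpec(2.5, 4.5, eccentricity = 0.3,
    calcArcs = data.frame(start_deg = 130, span_deg = 100,
                          inner_frac = 0.3, thickness_frac = 0.35))
  mesh <- meshGeometry(generateCrossSection(spec), 0.4)
  mmesh <- mirrorMesh(mesh)
  cons <- defaultConstraints(mesh)
  settings <- solverSettings()
  sol <- solveQuasistatic(mesh, fxPresets(), loadCase(80), settings,
                          constraints = cons)
  msol <- solveQuasistatic(mmesh, fxPresets(), loadCase(80), settings,
                           constraints = cons)
  u <- displacements(sol)
  um <- displacements(msol)
  expect_lt(max(abs(um[, 1] - u[, 1])) / max(abs(u)), 1e-8)
  expect_lt(max(abs(um[, 2] + u[, 2])) / max(abs(u)), 1e-8)
})

test_that("Newton divergence reports the failing pressure and residuals", {
  mesh <- fxAnnulusMesh(0.4)
  soft <- yeohMaterial(100, 0, 0, name = "soft")  # collapses under 80 mmHg
  tbl <- materialTable(soft, soft, soft)
  expect_error(
    solveQuasistatic(mesh, tbl, loadCase(80),
                     solverSettings(loadSteps = 2, newtonMaxIter = 8,
                                    maxHalvings = 1)),
    "Newton divergence")
})

test_that("mesh convergence toward the oracle is monotone at second order", {
  m <- materialOf(fxPresets(), "MATX")
  cs <- fxMemo("conv_study",
               convergenceStudy(m, hs = c(0.4, 0.2, 0.1)))
  expect_true(all(diff(cs$rel_error) < 0))
  expect_gte(attr(cs, "order"), 1.7)
  expect_lt(cs$rel_error[nrow(cs)], 0.01)
})
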