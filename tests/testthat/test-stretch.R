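test_that("zero displacement gives unit principal stretch everywhere", {
  mesh <- fxAnnulusMesh(0.4)
  sol <- solveQuasistatic(mesh, fxPresets(), loadCase(0))
  st <- principalStretch(sol, mesh)
  expect_equal(max(abs(st@lambda1 - 1)), 0)
  expect_equal(max(abs(stretchPct(st))), 0)
})

test_that("affine displacement fields reproduce their imposed stretch exactly", {
  mesh <- patchMesh(2L)
  F <- diag(c(1.2, 1 / 1.2))
  st <- principalStretch(affineSolution(mesh, F), mesh)
  expect_equal(st@lambda1, rep(1.2, length(st@lambda1)), tolerance = 1e-12)
  # pure in-plane compression is reported below 1 (plane strain keeps the
  # out-of-plane direction out of the principal-stretch readout)
  stc <- principalStretch(affineSolution(mesh, diag(c(0.9, 0.95))), mesh)
  expect_equal(unique(round(stc@lambda1, 12)), 0.95)
})

test_that("random affine stretches match a dense eigensolver oracle", {
  mesh <- patchMesh(2L)
  set.seed(5)
  for (rep in 1:8) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.15), 2, 2)
    if (det(F) <= 0.3) next
    st <- principalStretch(affineSolution(mesh, F), mesh)
    lamRef <- sqrt(max(eigen(t(F) %*% F, symmetric = TRUE)$values))
    expect_equal(st@lambda1, rep(lamRef, length(st@lambda1)),
                 tolerance = 1e-10)
  }
})

test_that("non-converged solutions are refused by the post-processor", {
  mesh <- patchMesh(2L)
  bad <- affineSolution(mesh, diag(2))
  bad@converged <- FALSE
  expect_error(principalStretch(bad, mesh), "non-converged")
})

test_that("diametral profiles of a homogeneous annulus are symmetric", {
  mesh <- fxAnnulusMesh(0.3)
  sol <- fxMemo("sol_ann03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  st <- principalStretch(sol, mesh)
  pr <- profileAlongLine(st, mesh, angleDeg = 0)
  expect_identical(names(pr), c("position_mm", "label", "stretch_pct"))
  expect_true(all(pr$label[abs(pr$position_mm) < 2.9] == "LUMEN"))
  expect_true(all(is.na(pr$stretch_pct[pr$label == "LUMEN"])))
  wall <- pr[pr$label != "LUMEN", ]
  left <- wall$stretch_pct[wall$position_mm < 0]
  right <- wall$stretch_pct[wall$position_mm > 0]
  # element-piecewise-constant sampling quantizes the steep radial stretch
  # gradient at the element scale; 5% covers that sampling noise at h = 0.3
  expect_equal(mean(left), mean(right), tolerance = 0.05)
  # wall samples span both sides at wall radii
  expect_true(all(abs(wall$position_mm) >= 3 - 0.3 &
                    abs(wall$position_mm) <= 4 + 0.3))
})

test_that("halving the sampling step preserves tissue-boundary crossings", {
  mesh <- fxStenoticMesh(0.3)
  sol <- fxMemo("sol_sten03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  st <- principalStretch(sol, mesh)
  crossingAt <- function(step) {
    pr <- profileAlongLine(st, mesh, angleDeg = 0, step = step)
    pr$position_mm[match("CALC", pr$label)]
  }
  c1 <- crossingAt(0.2)
  c2 <- crossingAt(0.1)
  expect_lte(abs(c1 - c2), 0.2)
})

test_that("profile through the calcification shows CALC below MATX stretch", {
  mesh <- fxStenoticMesh(0.3)
  sol <- fxMemo("sol_sten03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  st <- principalStretch(sol, mesh)
  pr <- profileAlongLine(st, mesh, angleDeg = 0)
  calcSide <- pr[pr$position_mm < 0, ]  # thick wall with the CALC arc
  expect_true(any(calcSide$label == "CALC"))
  expect_lt(mean(calcSide$stretch_pct[calcSide$label == "CALC"]),
            mean(calcSide$stretch_pct[calcSide$label == "MATX"]))
})

test_that("a line missing the wall yields an empty profile with a warning", {
  mesh <- fxAnnulusMesh(0.4)
  st <- principalStretch(solveQuasistatic(mesh, fxPresets(), loadCase(0)), mesh)
  fake <- mesh
  fake@lumenCenter <- c(50, 50)  # push the sampling line off the section
  expect_warning(pr <- profileAlongLine(st, fake, angleDeg = 0), "misses")
})

test_that("zone statistics partition the soft matrix and flag degenerate cases", {
  mesh <- fxStenoticMesh(0.3)
  dist <- distanceToCalc(mesh)
  sol <- fxMemo("sol_sten03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  st <- principalStretch(sol, mesh)
  z <- zoneStatistics(st, dist, mesh)
  expect_equal(sum(z$n), sum(elementLabels(mesh) == "MATX"))
  expect_false(attr(z, "single_zone"))
  expect_equal(attr(z, "ratio"), z$mean_pct[2] / z$mean_pct[1])

  # no CALC: everything is distant, near zone absent
  ann <- fxAnnulusMesh(0.4)
  stA <- principalStretch(solveQuasistatic(ann, fxPresets(), loadCase(0)), ann)
  zA <- zoneStatistics(stA, distanceToCalc(ann), ann)
  expect_true(attr(zA, "single_zone"))
  expect_identical(zA$n[zA$zone == "near"], 0L)
  expect_true(is.na(zA$mean_pct[zA$zone == "near"]))

  # degenerate all-CALC wall: near zone only
  allc <- fxAnnulusMesh(0.4)
  elementLabels(allc) <- rep("CALC", nrow(elementConnectivity(allc)))
  stC <- principalStretch(solveQuasistatic(allc, fxPresets(), loadCase(0)), allc)
  zC <- zoneStatistics(stC, distanceToCalc(allc), allc)
  expect_identical(sum(zC$n), 0L)
  expect_true(attr(zC, "single_zone"))
})

test_that("per-tissue summary covers present tissues with coherent quantiles", {
  mesh <- fxStenoticMesh(0.3)
  sol <- fxMemo("sol_sten03_80",
                solveQuasistatic(mesh, fxPresets(), loadCase(80)))
  st <- principalStretch(sol, mesh)
  ts <- tissueStretchSummary(st, mesh)
  expect_setequal(ts$tissue, c("MATX", "CALC", "LRNC"))
  expect_equal(sum(ts$n), nrow(elementConnectivity(mesh)))
  expect_true(all(ts$p5_pct <= ts$median_pct & ts$median_pct <= ts$p95_pct))
  # calcification stretches least
  expect_lt(ts$mean_pct[ts$tissue == "CALC"],
            ts$mean_pct[ts$tissue == "MATX"])
})
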