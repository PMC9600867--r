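test_that("empty inclusion lists give a single all-MATX annulus", {
  geo <- generateCrossSection(annulusSpec(3, 4))
  labs <- vapply(geo@regions, `[[`, character(1), "label")
  expect_identical(labs, "MATX")
  expect_equal(regionArea(geo, "MATX"), pi * (16 - 9), tolerance = 1e-3)
})

test_that("geometry generation is deterministic", {
  spec <- referenceStenoticSpec(seed = 3L)
  g1 <- generateCrossSection(spec)
  g2 <- generateCrossSection(spec)
  expect_identical(lapply(g1@regions, `[[`, "polygon"),
                   lapply(g2@regions, `[[`, "polygon"))
})

test_that("a calcification arc's area matches the annular-sector closed form", {
  # concentric wall 3..5 mm; 90 deg arc occupying radial fractions 0.25..0.75
  spec <- crossSectionSpec(3, 5, calcArcs = data.frame(
    start_deg = 10, span_deg = 90, inner_frac = 0.25, thickness_frac = 0.5))
  geo <- generateCrossSection(spec)
  r1 <- 3 + 0.25 * 2; r2 <- 3 + 0.75 * 2
  analytic <- (90 / 360) * pi * (r2^2 - r1^2)
  expect_equal(regionArea(geo, "CALC"), analytic, tolerance = 0.02)
})

test_that("overlapping regions are rejected with a diagnostic naming them", {
  expect_error(
    crossSectionSpec(3, 5,
      calcArcs = data.frame(start_deg = 0, span_deg = 90,
                            inner_frac = 0.3, thickness_frac = 0.4),
      lrncPools = data.frame(center_deg = 45, span_deg = 40,
                             center_frac = 0.5, thickness_frac = 0.2)),
    "calc_arc\\[1\\].*lrnc_pool\\[1\\]")
})

test_that("spec invariants are enforced", {
  expect_error(crossSectionSpec(3, 3.2), "minimum wall thickness")
  expect_error(crossSectionSpec(-1, 4), "lumenRadius")
  expect_error(crossSectionSpec(3, 5, calcArcs = data.frame(
    start_deg = 0, span_deg = 90, inner_frac = 0.8, thickness_frac = 0.4)),
    "inside the wall")
  expect_error(crossSectionSpec(3, 6, eccentricity = 1.5), "wall thickness")
})

test_that("meshing a pure annulus labels everything MATX with closed boundary loops", {
  mesh <- fxAnnulusMesh(0.4)
  expect_true(all(elementLabels(mesh) == "MATX"))
  for (side in c("LUMEN", "OUTER")) {
    ed <- boundaryEdges(mesh, side)
    # consecutive edges chain into a single closed loop
    expect_identical(ed[, 2], c(ed[-1, 1], ed[1, 1]))
  }
  expect_length(intersect(as.integer(boundaryEdges(mesh, "LUMEN")[, 1:2]),
                          as.integer(boundaryEdges(mesh, "OUTER")[, 1:2])), 0)
})

test_that("halving the target size refines element count by a 2D factor", {
  n1 <- nrow(elementConnectivity(fxAnnulusMesh(0.4)))
  n2 <- nrow(elementConnectivity(fxAnnulusMesh(0.2)))
  expect_gte(n2 / n1, 3)
  expect_lte(n2 / n1, 5)
})

test_that("meshing conserves region and total areas", {
  spec <- referenceStenoticSpec()
  geo <- generateCrossSection(spec)
  mesh <- meshGeometry(geo, 0.3)
  areas <- elementAreas(mesh)
  expect_gt(min(areas), 0)
  # total wall area: pi (Ro^2 - Ri^2) regardless of lumen offset
  expect_equal(sum(areas), pi * (5.5^2 - 2.5^2), tolerance = 0.01)
  calcMesh <- sum(areas[elementLabels(mesh) == "CALC"])
  expect_equal(calcMesh, regionArea(geo, "CALC"), tolerance = 0.05)
  lrncMesh <- sum(areas[elementLabels(mesh) == "LRNC"])
  expect_equal(lrncMesh, regionArea(geo, "LRNC"), tolerance = 0.05)
  # label partition
  expect_equal(sum(table(elementLabels(mesh))), nrow(elementConnectivity(mesh)))
})

test_that("meshing is bit-exact reproducible", {
  spec <- referenceStenoticSpec(jitterDeg = 0.5, seed = 9L)
  m1 <- meshGeometry(generateCrossSection(spec), 0.4)
  m2 <- meshGeometry(generateCrossSection(spec), 0.4)
  expect_identical(nodeCoords(m1), nodeCoords(m2))
  expect_identical(elementConnectivity(m1), elementConnectivity(m2))
  expect_identical(elementLabels(m1), elementLabels(m2))
})

test_that("distance field handles the no-CALC and CALC-element cases", {
  mesh <- fxAnnulusMesh(0.4)
  expect_true(all(is.infinite(distanceToCalc(mesh))))
  sten <- fxStenoticMesh(0.3)
  d <- distanceToCalc(sten)
  expect_true(all(d[elementLabels(sten) == "CALC"] == 0))
  expect_true(all(d >= 0))
})

test_that("distance to a circular inclusion matches point-to-circle geometry", {
  mesh <- fxAnnulusMesh(0.25, Ri = 2, Ro = 5)
  ctr <- elementCentroids(mesh)
  P <- c(3.5, 0)
  rad <- 1
  labs <- ifelse(sqrt((ctr[, 1] - P[1])^2 + (ctr[, 2] - P[2])^2) <= rad,
                 "CALC", "MATX")
  elementLabels(mesh) <- labs
  d <- distanceToCalc(mesh)
  q <- which.min((ctr[, 1] - 3.5)^2 + (ctr[, 2] - 2.5)^2)  # ~2.5 mm from P
  expected <- sqrt(sum((ctr[q, ] - P)^2)) - rad
  expect_equal(d[q], expected, tolerance = 2 * 0.25 / expected)
})

test_that("distance respects centroid-distance bounds on a small mesh", {
  mesh <- fxAnnulusMesh(0.4)
  ctr <- elementCentroids(mesh)
  labs <- rep("MATX", nrow(ctr))
  labs[ctr[, 2] > 3.6] <- "CALC"  # a cap of elements
  elementLabels(mesh) <- labs
  d <- distanceToCalc(mesh)
  calcIdx <- which(labs == "CALC")
  diam <- 2 * sqrt(max(elementAreas(mesh)))
  for (i in which(labs != "CALC")) {
    dc <- min(sqrt((ctr[calcIdx, 1] - ctr[i, 1])^2 +
                     (ctr[calcIdx, 2] - ctr[i, 2])^2))
    expect_lte(d[i], dc)
    expect_gte(d[i], dc - diam)
  }
})
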