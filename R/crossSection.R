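#' Construct a cross-section specification
#'
#' Builds a validated [CrossSectionSpec-class]. The wall is the region between
#' an outer circle of radius `outerRadius` centered at the origin and a lumen
#' circle of radius `lumenRadius` centered at `lumenCenter`. Tissue regions
#' are placed in a polar chart anchored at the lumen center: angles in degrees
#' (counterclockwise from the positive x axis) and radial position as a
#' fraction of the local wall thickness.
#'
#' @param lumenRadius lumen radius, mm.
#' @param outerRadius outer wall radius, mm.
#' @param calcArcs data.frame (or NULL) with columns `start_deg`, `span_deg`,
#'   `inner_frac`, `thickness_frac` describing macro-calcification arcs.
#' @param lrncPools data.frame (or NULL) with columns `center_deg`,
#'   `span_deg`, `center_frac`, `thickness_frac` describing lipid-core pools.
#' @param eccentricity unitless in \[0, 1\]: lumen-center offset as a fraction
#'   of the largest offset compatible with `minWallThickness`. The offset is
#'   applied along +x, so the wall is thinnest near 0 degrees and thickest
#'   near 180 degrees.
#' @param lumenCenter optional explicit lumen center (mm); overrides
#'   `eccentricity`.
#' @param minWallThickness minimum admissible wall thickness, mm.
#' @param jitterDeg amplitude of seeded angular jitter applied to the uniform
#'   mesh grid lines; 0 (default) keeps the generator fully deterministic.
#' @param seed integer seed for the jitter stream.
#' @return a [CrossSectionSpec-class].
#' @export
#' @examples
#' spec <- crossSectionSpec(2.5, 5.5,
#'   calcArcs = data.frame(start_deg = 120, span_deg = 120,
#'                         inner_frac = 0.35, thickness_frac = 0.3))
crossSectionSpec <- function(lumenRadius, outerRadius,
                             calcArcs = NULL, lrncPools = NULL,
                             eccentricity = 0, lumenCenter = NULL,
                             minWallThickness = 0.5, jitterDeg = 0,
                             seed = 1L) {
  emptyArcs <- data.frame(start_deg = numeric(), span_deg = numeric(),
                          inner_frac = numeric(), thickness_frac = numeric())
  emptyPools <- data.frame(center_deg = numeric(), span_deg = numeric(),
                           center_frac = numeric(), thickness_frac = numeric())
  calcArcs <- if (is.null(calcArcs) || !nrow(as.data.frame(calcArcs)))
    emptyArcs else as.data.frame(calcArcs)[names(emptyArcs)]
  lrncPools <- if (is.null(lrncPools) || !nrow(as.data.frame(lrncPools)))
    emptyPools else as.data.frame(lrncPools)[names(emptyPools)]
  if (is.null(lumenCenter)) {
    dmax <- outerRadius - lumenRadius - minWallThickness
    lumenCenter <- c(eccentricity * dmax, 0)
  }
  spec <- new("CrossSectionSpec", lumenCenter = as.numeric(lumenCenter),
              lumenRadius = as.numeric(lumenRadius),
              outerRadius = as.numeric(outerRadius),
              calcArcs = calcArcs, lrncPools = lrncPools,
              eccentricity = as.numeric(eccentricity),
              minWallThickness = as.numeric(minWallThickness),
              jitterDeg = as.numeric(jitterDeg), seed = as.integer(seed))
  .checkRegionOverlap(spec)
  spec
}

#' Reference stenotic plaque geometry
#'
#' The package's default synthetic plaque: lumen radius 2.5 mm, outer radius
#' 5.5 mm, eccentricity 0.4 (1 mm lumen offset; 2 mm thin wall at 0 degrees,
#' 4 mm thick wall at 180 degrees), one 120-degree macro-calcification arc of
#' 1.2 mm thickness centered mid-wall on the thick side, and one 60-degree
#' lipid-core pool opposite. Chosen so that the soft matrix contains both
#' near-CALC (< 1 mm) and distant (> 1 mm) zones.
#'
#' @param jitterDeg,seed passed to [crossSectionSpec()].
#' @return a [CrossSectionSpec-class].
#' @export
referenceStenoticSpec <- function(jitterDeg = 0, seed = 1L) {
  crossSectionSpec(
    lumenRadius = 2.5, outerRadius = 5.5, eccentricity = 0.4,
    calcArcs = data.frame(start_deg = 120, span_deg = 120,
                          inner_frac = 0.35, thickness_frac = 0.30),
    lrncPools = data.frame(center_deg = 0, span_deg = 60,
                           center_frac = 0.5, thickness_frac = 0.25),
    jitterDeg = jitterDeg, seed = seed)
}

#' Concentric homogeneous annulus
#'
#' Convenience spec for solver verification against the thick-walled-cylinder
#' inflation solution: concentric wall, no inclusions.
#'
#' @param Ri,Ro inner and outer radii, mm.
#' @return a [CrossSectionSpec-class].
#' @export
annulusSpec <- function(Ri = 3, Ro = 4) {
  crossSectionSpec(lumenRadius = Ri, outerRadius = Ro)
}

# Region table in the parametric chart: label, theta0 (rad, in [0,2pi)),
# span (rad), s0, s1, and a human-readable id.
.specRegions <- function(spec) {
  rows <- list()
  ca <- spec@calcArcs
  for (i in seq_len(nrow(ca)))
    rows[[length(rows) + 1]] <- data.frame(
      label = "CALC", theta0 = (ca$start_deg[i] %% 360) * pi / 180,
      span = ca$span_deg[i] * pi / 180,
      s0 = ca$inner_frac[i], s1 = ca$inner_frac[i] + ca$thickness_frac[i],
      id = sprintf("calc_arc[%d]", i))
  lp <- spec@lrncPools
  for (i in seq_len(nrow(lp)))
    rows[[length(rows) + 1]] <- data.frame(
      label = "LRNC",
      theta0 = ((lp$center_deg[i] - lp$span_deg[i] / 2) %% 360) * pi / 180,
      span = lp$span_deg[i] * pi / 180,
      s0 = lp$center_frac[i] - lp$thickness_frac[i] / 2,
      s1 = lp$center_frac[i] + lp$thickness_frac[i] / 2,
      id = sprintf("lrnc_pool[%d]", i))
  if (!length(rows))
    return(data.frame(label = character(), theta0 = numeric(),
                      span = numeric(), s0 = numeric(), s1 = numeric(),
                      id = character()))
  do.call(rbind, rows)
}

# Angular intervals (a, a+la) and (b, b+lb) mod 2pi overlap with positive
# measure? Touching boundaries do not count.
.arcOverlap <- function(a, la, b, lb, tol = 1e-9) {
  d1 <- (b - a) %% (2 * pi)
  d2 <- (a - b) %% (2 * pi)
  (d1 < la - tol) || (d2 < lb - tol)
}

.checkRegionOverlap <- function(spec) {
  reg <- .specRegions(spec)
  n <- nrow(reg)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ang <- .arcOverlap(reg$theta0[i], reg$span[i], reg$theta0[j], reg$span[j])
    rad <- (min(reg$s1[i], reg$s1[j]) - max(reg$s0[i], reg$s0[j])) > 1e-9
    if (ang && rad)
      stop(sprintf("tissue regions overlap: %s collides with %s",
                   reg$id[i], reg$id[j]), call. = FALSE)
  }
  invisible(TRUE)
}

# Ray length from the lumen center to the outer circle along direction theta.
.outerRay <- function(spec, theta) {
  u <- cbind(cos(theta), sin(theta))
  cu <- u[, 1] * spec@lumenCenter[1] + u[, 2] * spec@lumenCenter[2]
  -cu + sqrt(cu^2 + spec@outerRadius^2 - sum(spec@lumenCenter^2))
}

# Map parametric (theta, s) to physical mm coordinates.
.chartMap <- function(spec, theta, s) {
  t <- .outerRay(spec, theta)
  r <- spec@lumenRadius + s * (t - spec@lumenRadius)
  cbind(spec@lumenCenter[1] + r * cos(theta),
        spec@lumenCenter[2] + r * sin(theta))
}

# Label of the region containing parametric point (theta, s); precedence
# CALC > LRNC > MATX breaks exact-boundary ties (stiffest wins).
.labelAt <- function(reg, theta, s, tol = 1e-9) {
  pick <- function(lab) {
    rr <- reg[reg$label == lab, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      dth <- (theta - rr$theta0[i]) %% (2 * pi)
      if (dth <= rr$span[i] + tol && s >= rr$s0[i] - tol && s <= rr$s1[i] + tol)
        return(TRUE)
    }
    FALSE
  }
  if (pick("CALC")) "CALC" else if (pick("LRNC")) "LRNC" else "MATX"
}

#' Generate the labeled planar geometry of a cross-section
#'
#' Decomposes the wall annulus into closed, non-overlapping labeled patches.
#' The patch boundaries are the lumen/outer circles plus the angular and
#' radial-fraction boundaries of every CALC arc and LRNC pool, so the patches
#' tile the wall exactly and each carries a single tissue label. Overlapping
#' CALC/LRNC regions are rejected with a diagnostic naming the colliding
#' regions. The generator is deterministic for a fixed spec and seed.
#'
#' @param spec a [CrossSectionSpec-class].
#' @param arcResolutionDeg discretization step for the polygonal region
#'   boundaries, degrees.
#' @return a [PlaqueGeometry-class]; each region has `label`, `theta`
#'   (angular window, rad), `s` (radial-fraction window), `polygon` (outer
#'   ring vertices, mm) and, for full-annulus regions, `hole` (inner ring).
#' @export
generateCrossSection <- function(spec, arcResolutionDeg = 1) {
  validObject(spec)
  .checkRegionOverlap(spec)
  reg <- .specRegions(spec)
  thetaCuts <- sort(unique(round(c(reg$theta0, (reg$theta0 + reg$span)) %% (2 * pi), 12)))
  sCuts <- sort(unique(round(c(0, 1, reg$s0, reg$s1), 12)))
  sCuts <- sCuts[sCuts >= 0 & sCuts <= 1]
  regions <- list()
  if (!length(thetaCuts)) {
    # no angular cuts: full-annulus bands between consecutive s cuts
    for (k in seq_len(length(sCuts) - 1)) {
      s0 <- sCuts[k]; s1 <- sCuts[k + 1]
      th <- seq(0, 2 * pi, by = arcResolutionDeg * pi / 180)
      regions[[length(regions) + 1]] <- list(
        label = .labelAt(reg, pi, (s0 + s1) / 2),
        theta = c(0, 2 * pi), s = c(s0, s1),
        polygon = .chartMap(spec, th, s1),
        hole = .chartMap(spec, rev(th), s0))
    }
  } else {
    starts <- thetaCuts
    ends <- c(thetaCuts[-1], thetaCuts[1] + 2 * pi)
    for (j in seq_along(starts)) for (k in seq_len(length(sCuts) - 1)) {
      th0 <- starts[j]; th1 <- ends[j]
      s0 <- sCuts[k]; s1 <- sCuts[k + 1]
      nseg <- max(2, ceiling((th1 - th0) / (arcResolutionDeg * pi / 180)))
      th <- seq(th0, th1, length.out = nseg + 1)
      poly <- rbind(.chartMap(spec, th, s0), .chartMap(spec, rev(th), s1))
      regions[[length(regions) + 1]] <- list(
        label = .labelAt(reg, ((th0 + th1) / 2) %% (2 * pi), (s0 + s1) / 2),
        theta = c(th0, th1), s = c(s0, s1), polygon = poly, hole = NULL)
    }
  }
  new("PlaqueGeometry", regions = regions, spec = spec)
}

#' Area of a labeled geometry region (shoelace on the discretized boundary)
#'
#' @param geometry a [PlaqueGeometry-class].
#' @param label optional tissue label; when given, sums areas of all regions
#'   with this label.
#' @return area(s) in mm^2.
#' @export
regionArea <- function(geometry, label = NULL) {
  shoelace <- function(p) {
    n <- nrow(p)
    if (n < 3) return(0)
    i2 <- c(2:n, 1)
    abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
  }
  areas <- vapply(geometry@regions, function(r) {
    a <- shoelace(r$polygon)
    if (!is.null(r$hole)) a <- a - shoelace(r$hole)
    a
  }, numeric(1))
  if (is.null(label)) return(areas)
  labs <- vapply(geometry@regions, `[[`, character(1), "label")
  sum(areas[labs == label])
}
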