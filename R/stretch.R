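#' Principal tissue stretch of a converged solution
#'
#' Per-element maximum in-plane principal stretch
#' `lambda1 = sqrt(max eig t(F) %*% F)` evaluated at the element's
#' quadrature-point-averaged deformation gradient, reported also as percent
#' elongation `(lambda1 - 1) * 100`. Quadrature-point averaging (rather than
#' nodal extrapolation) avoids superconvergent-point artifacts on quadratic
#' triangles. Refuses non-converged solutions.
#'
#' @param solution a [SolutionField-class].
#' @param mesh the [LabeledMesh-class] the solution lives on.
#' @return a [StretchField-class].
#' @export
principalStretch <- function(solution, mesh) {
  if (!isTRUE(solution@converged))
    stop("refusing to post-process a non-converged solution (case '",
         solution@caseName, "')")
  d <- fem_defgrad_cpp(mesh@nodes, mesh@elements, .flattenU(solution@displacement))
  Fb <- d$F  # columns F11 F12 F21 F22
  # eigenvalues of C = t(F)F in closed form for 2x2
  C11 <- Fb[, 1]^2 + Fb[, 3]^2
  C22 <- Fb[, 2]^2 + Fb[, 4]^2
  C12 <- Fb[, 1] * Fb[, 2] + Fb[, 3] * Fb[, 4]
  tr <- C11 + C22
  disc <- sqrt(pmax(0, (C11 - C22)^2 / 4 + C12^2))
  lam1 <- sqrt(tr / 2 + disc)
  new("StretchField", lambda1 = lam1, pct = (lam1 - 1) * 100,
      caseName = solution@caseName, pressureMmHg = solution@pressureMmHg)
}

#' Stretch profile along a line through the lumen
#'
#' Samples tissue label and principal stretch along a diametral line through
#' the lumen center, emulating a cross-sectional centerline readout: ordered
#' samples of (signed position along the line, tissue label or LUMEN,
#' stretch percent). Lumen samples carry `NA` stretch; samples outside the
#' section are dropped.
#'
#' @param stretch a [StretchField-class].
#' @param mesh the [LabeledMesh-class].
#' @param angleDeg line direction, degrees; the line passes through the lumen
#'   center.
#' @param step sampling step, mm; default half the mesh target size.
#' @return data.frame with columns `position_mm` (signed, from the lumen
#'   center), `label`, `stretch_pct`.
#' @export
profileAlongLine <- function(stretch, mesh, angleDeg = 0, step = mesh@h / 2) {
  u <- c(cos(angleDeg * pi / 180), sin(angleDeg * pi / 180))
  ctr <- mesh@lumenCenter
  span <- max(sqrt(rowSums(sweep(mesh@nodes, 2, ctr)^2)))
  pos <- seq(-span - step, span + step, by = step)
  pts <- cbind(ctr[1] + pos * u[1], ctr[2] + pos * u[2])
  loc <- locateElements(mesh, pts)
  keep <- !is.na(loc)
  if (!any(keep))
    warning("profile line misses the wall entirely")
  loc <- loc[keep]; pos <- pos[keep]
  lab <- ifelse(loc == 0L, "LUMEN", as.character(mesh@labels[pmax(loc, 1L)]))
  pct <- ifelse(loc == 0L, NA_real_, stretch@pct[pmax(loc, 1L)])
  data.frame(position_mm = pos, label = lab, stretch_pct = pct)
}

#' Per-tissue stretch summary
#'
#' @param stretch a [StretchField-class].
#' @param mesh the [LabeledMesh-class].
#' @return data.frame: per tissue label, element count and mean, median, 5th
#'   and 95th percentile of stretch percent.
#' @export
tissueStretchSummary <- function(stretch, mesh) {
  labs <- as.character(mesh@labels)
  present <- TISSUE_LEVELS[TISSUE_LEVELS %in% labs]
  do.call(rbind, lapply(present, function(l) {
    v <- stretch@pct[labs == l]
    data.frame(case = stretch@caseName, pressure_mmHg = stretch@pressureMmHg,
               tissue = l, n = length(v), mean_pct = mean(v),
               median_pct = median(v),
               p5_pct = as.numeric(quantile(v, 0.05)),
               p95_pct = as.numeric(quantile(v, 0.95)))
  }))
}

#' Near-versus-distant zone statistics of soft-matrix stretch
#'
#' Splits the MATX elements at a distance threshold from the nearest
#' macro-calcification (default 1 mm) and summarizes principal stretch in
#' the near-CALC and distant zones: means, the fraction of elements whose
#' stretch exceeds a reference line (default 12.5 percent), and the
#' distant/near mean-stretch ratio. With no CALC in the mesh all MATX is
#' distant and the near-zone statistics are absent.
#'
#' @param stretch a [StretchField-class].
#' @param distance distance field from [distanceToCalc()] (recompute or pass
#'   a frozen one for material-substitution comparisons).
#' @param mesh the [LabeledMesh-class].
#' @param thresholdMm zone threshold, mm.
#' @param referencePct reference stretch line, percent.
#' @return data.frame with one row per zone (`near`, `distant`) plus the
#'   ratio carried in the attribute `"ratio"` and as column `ratio_far_near`
#'   on the distant row; `NA` entries where a zone is empty.
#' @export
zoneStatistics <- function(stretch, distance, mesh, thresholdMm = 1,
                           referencePct = 12.5) {
  stopifnot(length(distance) == nrow(mesh@elements),
            length(stretch@pct) == nrow(mesh@elements))
  isM <- mesh@labels == "MATX"
  near <- isM & distance < thresholdMm
  far <- isM & distance >= thresholdMm
  zrow <- function(zone, sel) {
    v <- stretch@pct[sel]
    data.frame(case = stretch@caseName, pressure_mmHg = stretch@pressureMmHg,
               zone = zone, n = sum(sel),
               mean_pct = if (sum(sel)) mean(v) else NA_real_,
               median_pct = if (sum(sel)) median(v) else NA_real_,
               frac_above_ref = if (sum(sel)) mean(v > referencePct) else NA_real_,
               ratio_far_near = NA_real_)
  }
  out <- rbind(zrow("near", near), zrow("distant", far))
  ratio <- if (sum(near) && sum(far)) out$mean_pct[2] / out$mean_pct[1]
           else NA_real_
  out$ratio_far_near[2] <- ratio
  attr(out, "ratio") <- ratio
  attr(out, "single_zone") <- !sum(near) || !sum(far)
  out
}
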