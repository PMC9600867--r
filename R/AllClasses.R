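#' Parametric description of a labeled vessel-wall cross-section
#'
#' Describes an idealized atherosclerotic cross-section: a circular outer wall
#' of radius `outerRadius` centered at the origin, a circular lumen of radius
#' `lumenRadius` whose center may be offset (eccentric stenosis), and tissue
#' regions expressed in a polar chart anchored at the lumen center: angles in
#' degrees, radial position as a fraction of the local wall thickness
#' (0 = lumen boundary, 1 = outer boundary).
#'
#' @slot lumenCenter numeric(2), lumen center in mm relative to the wall center.
#' @slot lumenRadius lumen radius, mm.
#' @slot outerRadius outer wall radius, mm.
#' @slot calcArcs data.frame with columns `start_deg`, `span_deg`,
#'   `inner_frac`, `thickness_frac`: macro-calcification arcs.
#' @slot lrncPools data.frame with columns `center_deg`, `span_deg`,
#'   `center_frac`, `thickness_frac`: lipid-rich necrotic core pools.
#' @slot eccentricity unitless 0-1; used to derive `lumenCenter` when the
#'   center is not given explicitly.
#' @slot minWallThickness minimum admissible wall thickness, mm.
#' @slot jitterDeg amplitude of optional seeded angular jitter of the mesh
#'   grid lines (0 = fully deterministic generator).
#' @slot seed integer seed for the jitter stream.
#' @export
setClass("CrossSectionSpec", representation(
  lumenCenter = "numeric", lumenRadius = "numeric", outerRadius = "numeric",
  calcArcs = "data.frame", lrncPools = "data.frame",
  eccentricity = "numeric", minWallThickness = "numeric",
  jitterDeg = "numeric", seed = "integer"))

setValidity("CrossSectionSpec", function(object) {
  msg <- character()
  if (object@lumenRadius <= 0) msg <- c(msg, "lumenRadius must be > 0")
  if (object@outerRadius <= object@lumenRadius + object@minWallThickness)
    msg <- c(msg, sprintf(
      "outerRadius (%g) must exceed lumenRadius + minimum wall thickness (%g)",
      object@outerRadius, object@lumenRadius + object@minWallThickness))
  off <- sqrt(sum(object@lumenCenter^2))
  if (off + object@lumenRadius + object@minWallThickness > object@outerRadius)
    msg <- c(msg, "eccentric lumen violates the minimum wall thickness")
  for (nm in c("calcArcs", "lrncPools")) {
    df <- slot(object, nm)
    if (nrow(df)) {
      if (any(df$span_deg <= 0) || any(df$span_deg > 360))
        msg <- c(msg, sprintf("%s: span_deg must lie in (0, 360]", nm))
      if (any(df$thickness_frac <= 0))
        msg <- c(msg, sprintf("%s: thickness_frac must be > 0", nm))
    }
  }
  if (nrow(object@calcArcs)) {
    s0 <- object@calcArcs$inner_frac
    s1 <- s0 + object@calcArcs$thickness_frac
    if (any(s0 < 0) || any(s1 > 1))
      msg <- c(msg, "calcArcs must lie strictly inside the wall (0 <= inner_frac, inner_frac + thickness_frac <= 1)")
  }
  if (nrow(object@lrncPools)) {
    s0 <- object@lrncPools$center_frac - object@lrncPools$thickness_frac / 2
    s1 <- object@lrncPools$center_frac + object@lrncPools$thickness_frac / 2
    if (any(s0 < 0) || any(s1 > 1))
      msg <- c(msg, "lrncPools must lie strictly inside the wall annulus")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled planar cross-section geometry
#'
#' The polygonal product of [generateCrossSection()]: closed regions tiling
#' the wall annulus, each carrying a tissue label, together with the parametric
#' chart they were generated from.
#'
#' @slot regions list; each entry has `label`, `theta` (angular window, rad),
#'   `s` (radial-fraction window) and `polygon` (discretized boundary, mm).
#' @slot spec the originating [CrossSectionSpec-class].
#' @export
setClass("PlaqueGeometry", representation(regions = "list",
                                          spec = "CrossSectionSpec"))

#' Tissue-labeled quadratic-triangle finite-element mesh
#'
#' A conforming mesh of 6-node (quadratic, isoparametric) triangles over the
#' vessel-wall cross-section. Tissue regions are unions of whole elements.
#' Boundary loops are stored as quadratic edges (end, end, midside node) and
#' the LUMEN loop is oriented counterclockwise so that pressure loads act
#' from the lumen into the wall.
#'
#' @slot nodes numeric matrix (n x 2), coordinates in mm.
#' @slot elements integer matrix (ne x 6): corner nodes 1-3 (counterclockwise)
#'   then midside nodes on edges 1-2, 2-3, 3-1.
#' @slot labels factor of length ne with levels MATX, CALC, LRNC.
#' @slot boundary named list of integer matrices (edges x 3) for the LUMEN and
#'   OUTER loops.
#' @slot h target edge length used by the mesher, mm.
#' @slot lumenCenter numeric(2): lumen center (centroid of the LUMEN loop), mm.
#' @export
setClass("LabeledMesh", representation(
  nodes = "matrix", elements = "matrix", labels = "factor",
  boundary = "list", h = "numeric", lumenCenter = "numeric"))

setValidity("LabeledMesh", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 2) msg <- c(msg, "nodes must be an n x 2 matrix")
  if (ncol(object@elements) != 6) msg <- c(msg, "elements must be ne x 6")
  if (length(object@labels) != nrow(object@elements))
    msg <- c(msg, "one tissue label per element required")
  if (!identical(levels(object@labels), TISSUE_LEVELS))
    msg <- c(msg, "labels must be a factor with levels MATX, CALC, LRNC")
  if (!all(c("LUMEN", "OUTER") %in% names(object@boundary)))
    msg <- c(msg, "boundary must tag both LUMEN and OUTER loops")
  if (nrow(object@elements) &&
      (max(object@elements) > nrow(object@nodes) || min(object@elements) < 1))
    msg <- c(msg, "element connectivity indexes outside the node table")
  if (length(msg)) msg else TRUE
})

#' Three-parameter Yeoh hyperelastic material
#'
#' Strain-energy density
#' `W = c1*(Ib1-3) + c2*(Ib1-3)^2 + c3*(Ib1-3)^3 + kappa/2*(J-1)^2`
#' with the isochoric first invariant `Ib1 = J^(-2/3) tr(C)` and a quadratic
#' volumetric penalty enforcing quasi-incompressibility. The small-strain
#' shear modulus is `mu0 = 2*c1`.
#'
#' @slot c1,c2,c3 Yeoh constants, Pa.
#' @slot kappa volumetric penalty modulus, Pa; must be at least `1000 * 2*c1`.
#' @slot name material name.
#' @export
setClass("YeohMaterial", representation(
  c1 = "numeric", c2 = "numeric", c3 = "numeric",
  kappa = "numeric", name = "character"))

setValidity("YeohMaterial", function(object) {
  msg <- character()
  if (object@c1 <= 0) msg <- c(msg, "c1 must be > 0")
  if (object@kappa < 1000 * 2 * object@c1)
    msg <- c(msg, "kappa must be >= 1000 * 2*c1 (near-incompressible regime)")
  if (length(msg)) msg else TRUE
})

#' Tissue-to-material mapping
#'
#' @slot materials named list of [YeohMaterial-class] objects, one per tissue
#'   label (MATX, CALC, LRNC).
#' @export
setClass("MaterialTable", representation(materials = "list"))

setValidity("MaterialTable", function(object) {
  if (!all(TISSUE_LEVELS %in% names(object@materials)))
    return("materials must name all of MATX, CALC, LRNC")
  if (!all(vapply(object@materials, is, logical(1), class2 = "YeohMaterial")))
    return("all entries must be YeohMaterial objects")
  TRUE
})

#' Converged displacement field of one load case
#'
#' @slot displacement numeric matrix (n x 2), nodal displacements in mm.
#' @slot converged logical convergence flag.
#' @slot residualHistory list of numeric vectors (relative residual per Newton
#'   iteration, one vector per load step).
#' @slot pressureMmHg applied luminal pressure, mmHg.
#' @slot caseName load-case name, e.g. "diastole" or "systole".
#' @slot constraints data.frame of the rigid-body constraints applied
#'   (columns `node`, `dof`).
#' @export
setClass("SolutionField", representation(
  displacement = "matrix", converged = "logical", residualHistory = "list",
  pressureMmHg = "numeric", caseName = "character", constraints = "data.frame"))

#' Per-element principal stretch field
#'
#' Maximum in-plane principal stretch `lambda1 = sqrt(max eig F^T F)` from the
#' quadrature-point-averaged deformation gradient of each element, reported
#' also as percent elongation `(lambda1 - 1) * 100`. Under plane strain the
#' out-of-plane stretch is identically 1 and is not included, so values below
#' 1 (compression) are possible.
#'
#' @slot lambda1 numeric, per-element principal stretch (unitless).
#' @slot pct numeric, `(lambda1 - 1) * 100`.
#' @slot caseName load-case name.
#' @slot pressureMmHg pressure of the originating load case, mmHg.
#' @export
setClass("StretchField", representation(
  lambda1 = "numeric", pct = "numeric", caseName = "character",
  pressureMmHg = "numeric"))

#' Stretch report: per-tissue, per-zone and profile summaries
#'
#' @slot tissueSummary data.frame: per load case and tissue, element count and
#'   mean/median/5th/95th percentile of stretch percent.
#' @slot zoneSummary data.frame: per load case, the MATX population split at
#'   the distance threshold into near-CALC and distant zones, with mean
#'   stretch, fraction of elements above the reference stretch line, and the
#'   distant/near mean-stretch ratio.
#' @slot profiles list of data.frames (`position_mm`, `label`, `stretch_pct`)
#'   keyed by "case@angle".
#' @slot parameters list of analysis settings (threshold_mm, reference_pct,
#'   profile angles, mesh size, seed).
#' @export
setClass("StretchReport", representation(
  tissueSummary = "data.frame", zoneSummary = "data.frame",
  profiles = "list", parameters = "list"))
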