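#' @name plaqueStretch-accessors
#' @title Accessors for plaqueStretch S4 objects
#' @description Small accessor generics so downstream code never reaches into
#'   slots directly.
#' @param x an object from this package.
#' @param object an object from this package.
#' @keywords internal
NULL

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("elementConnectivity", function(x) standardGeneric("elementConnectivity"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("elementLabels", function(x) standardGeneric("elementLabels"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("elementLabels<-", function(x, value) standardGeneric("elementLabels<-"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("boundaryEdges", function(x, which = c("LUMEN", "OUTER"))
  standardGeneric("boundaryEdges"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("stretchPct", function(x) standardGeneric("stretchPct"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("tissueSummary", function(x) standardGeneric("tissueSummary"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("zoneSummary", function(x) standardGeneric("zoneSummary"))

#' @rdname plaqueStretch-accessors
#' @export
setGeneric("stretchProfiles", function(x) standardGeneric("stretchProfiles"))

setMethod("nodeCoords", "LabeledMesh", function(x) x@nodes)
setMethod("elementConnectivity", "LabeledMesh", function(x) x@elements)
setMethod("elementLabels", "LabeledMesh", function(x) x@labels)
setMethod("elementLabels<-", "LabeledMesh", function(x, value) {
  x@labels <- factor(as.character(value), levels = TISSUE_LEVELS)
  validObject(x)
  x
})
setMethod("boundaryEdges", "LabeledMesh", function(x, which = c("LUMEN", "OUTER")) {
  which <- match.arg(which)
  x@boundary[[which]]
})
setMethod("displacements", "SolutionField", function(x) x@displacement)
setMethod("isConverged", "SolutionField", function(x) x@converged)
setMethod("stretchPct", "StretchField", function(x) x@pct)
setMethod("tissueSummary", "StretchReport", function(x) x@tissueSummary)
setMethod("zoneSummary", "StretchReport", function(x) x@zoneSummary)
setMethod("stretchProfiles", "StretchReport", function(x) x@profiles)

setMethod("show", "CrossSectionSpec", function(object) {
  cat("CrossSectionSpec\n")
  cat(sprintf("  lumen: r = %.3g mm at (%.3g, %.3g) mm; outer wall: r = %.3g mm\n",
              object@lumenRadius, object@lumenCenter[1], object@lumenCenter[2],
              object@outerRadius))
  cat(sprintf("  CALC arcs: %d; LRNC pools: %d; jitter: %.3g deg (seed %d)\n",
              nrow(object@calcArcs), nrow(object@lrncPools),
              object@jitterDeg, object@seed))
})

setMethod("show", "LabeledMesh", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledMesh: %d nodes, %d quadratic triangles (h = %.3g mm)\n",
              nrow(object@nodes), nrow(object@elements), object@h))
  cat(sprintf("  labels: MATX %d, CALC %d, LRNC %d\n",
              tab["MATX"], tab["CALC"], tab["LRNC"]))
  cat(sprintf("  boundary edges: LUMEN %d, OUTER %d\n",
              nrow(object@boundary$LUMEN), nrow(object@boundary$OUTER)))
})

setMethod("show", "YeohMaterial", function(object) {
  cat(sprintf("YeohMaterial '%s': c1 = %.4g, c2 = %.4g, c3 = %.4g Pa; kappa = %.4g Pa (mu0 = %.4g Pa)\n",
              object@name, object@c1, object@c2, object@c3, object@kappa,
              2 * object@c1))
})

setMethod("show", "MaterialTable", function(object) {
  cat("MaterialTable\n")
  for (nm in TISSUE_LEVELS) show(object@materials[[nm]])
})

setMethod("show", "SolutionField", function(object) {
  umax <- if (nrow(object@displacement)) max(sqrt(rowSums(object@displacement^2))) else 0
  cat(sprintf("SolutionField '%s': %.4g mmHg, %s, max |u| = %.4g mm\n",
              object@caseName, object@pressureMmHg,
              if (object@converged) "converged" else "NOT converged", umax))
})

setMethod("show", "StretchField", function(object) {
  cat(sprintf("StretchField '%s' (%.4g mmHg): %d elements, stretch %% in [%.2f, %.2f]\n",
              object@caseName, object@pressureMmHg, length(object@pct),
              min(object@pct), max(object@pct)))
})

setMethod("show", "StretchReport", function(object) {
  cat("StretchReport\n  per-tissue summary:\n")
  print(object@tissueSummary, row.names = FALSE)
  if (nrow(object@zoneSummary)) {
    cat("  MATX zone summary (near vs distant of CALC):\n")
    print(object@zoneSummary, row.names = FALSE)
  }
  cat(sprintf("  profiles: %d\n", length(object@profiles)))
})
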