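# Legacy ASCII VTK unstructured-grid writer/reader for the subset this
# package emits: quadratic triangles (type 22), quadratic edges (type 21),
# integer cell data and vector point data. Numbers are written with full
# precision (%.17g) so round trips are exact.

#' Write a labeled mesh (optionally with solution fields) as legacy VTK
#'
#' Triangles carry the integer cell-data field `tissue_label` (1 = MATX,
#' 2 = CALC, 3 = LRNC) and `boundary_tag` 0; the LUMEN and OUTER loops are
#' written as quadratic edge cells with `tissue_label` 0 and `boundary_tag`
#' 1 / 2. Optional per-element fields and a nodal displacement vector are
#' appended.
#'
#' @param mesh a [LabeledMesh-class].
#' @param path output file path (conventionally `.vtk`).
#' @param cellData optional named list of numeric per-element vectors
#'   (e.g. `principal_stretch_pct`, `dist_to_calc_mm`).
#' @param displacement optional n x 2 nodal displacement matrix (mm).
#' @return the path, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, cellData = list(), displacement = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh@nodes)
  tri <- mesh@elements
  lum <- mesh@boundary$LUMEN
  out <- mesh@boundary$OUTER
  ncell <- nrow(tri) + nrow(lum) + nrow(out)
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("plaqueStretch labeled mesh (mm)")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nn)
  writeLines(sprintf("%.17g %.17g 0", mesh@nodes[, 1], mesh@nodes[, 2]), con)
  sizes <- nrow(tri) * 7L + (nrow(lum) + nrow(out)) * 4L
  w("CELLS %d %d", ncell, sizes)
  if (nrow(tri))
    writeLines(paste(6L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L,
                     tri[, 4] - 1L, tri[, 5] - 1L, tri[, 6] - 1L), con)
  for (ed in list(lum, out))
    if (nrow(ed))
      writeLines(paste(3L, ed[, 1] - 1L, ed[, 2] - 1L, ed[, 3] - 1L), con)
  w("CELL_TYPES %d", ncell)
  writeLines(as.character(c(rep(22L, nrow(tri)),
                            rep(21L, nrow(lum) + nrow(out)))), con)
  w("CELL_DATA %d", ncell)
  w("SCALARS tissue_label int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(c(as.integer(mesh@labels),
                            rep(0L, nrow(lum) + nrow(out)))), con)
  w("SCALARS boundary_tag int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(c(rep(0L, nrow(tri)), rep(1L, nrow(lum)),
                            rep(2L, nrow(out)))), con)
  for (nm in names(cellData)) {
    w("SCALARS %s double 1", nm)
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.17g", c(as.numeric(cellData[[nm]]),
                                  rep(0, nrow(lum) + nrow(out)))), con)
  }
  if (!is.null(displacement)) {
    w("POINT_DATA %d", nn)
    w("VECTORS displacement double")
    writeLines(sprintf("%.17g %.17g 0", displacement[, 1],
                       displacement[, 2]), con)
  }
  # private metadata so the chart-free reader can rebuild the full object
  w("FIELD plaqueStretch 2")
  w("target_h 1 1 double")
  w("%.17g", mesh@h)
  w("lumen_center 1 2 double")
  w("%.17g %.17g", mesh@lumenCenter[1], mesh@lumenCenter[2])
  invisible(path)
}

#' Read a labeled mesh written by [writeMeshVTK()]
#'
#' @param path VTK file path.
#' @return list with `mesh` (a [LabeledMesh-class]), `cellData` (named list
#'   of per-element vectors) and `displacement` (n x 2 matrix or NULL).
#' @export
readMeshVTK <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  nn <- as.integer(toks(lines[ip])[2])
  pts <- do.call(rbind, lapply(lines[(ip + 1):(ip + nn)],
                               function(s) as.numeric(toks(s))))[, 1:2, drop = FALSE]
  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(toks(lines[ic])[2])
  cellRows <- lapply(lines[(ic + 1):(ic + ncell)],
                     function(s) as.integer(toks(s)))
  it <- grep("^CELL_TYPES", lines)[1]
  ctype <- as.integer(unlist(lapply(lines[(it + 1):(it + ncell)], toks)))
  readScalar <- function(name, mode = as.numeric) {
    i <- grep(paste0("^SCALARS ", name, " "), lines)[1]
    if (is.na(i)) return(NULL)
    vals <- character(0)
    j <- i + 2
    while (length(vals) < ncell) {
      vals <- c(vals, toks(lines[j]))
      j <- j + 1
    }
    mode(vals[seq_len(ncell)])
  }
  tl <- readScalar("tissue_label", as.integer)
  bt <- readScalar("boundary_tag", as.integer)
  isTri <- ctype == 22L
  tri <- do.call(rbind, lapply(cellRows[isTri],
                               function(r) r[2:7] + 1L))
  edgeOf <- function(tag) {
    sel <- ctype == 21L & bt == tag
    if (!any(sel)) return(matrix(integer(0), 0, 3))
    do.call(rbind, lapply(cellRows[sel], function(r) r[2:4] + 1L))
  }
  extras <- setdiff(
    sub("^SCALARS (\\S+) .*$", "\\1", grep("^SCALARS", lines, value = TRUE)),
    c("tissue_label", "boundary_tag"))
  cellData <- lapply(setNames(extras, extras),
                     function(nm) readScalar(nm)[isTri])
  disp <- NULL
  iv <- grep("^VECTORS displacement", lines)
  if (length(iv)) {
    disp <- do.call(rbind, lapply(lines[(iv[1] + 1):(iv[1] + nn)],
                                  function(s) as.numeric(toks(s))))[, 1:2, drop = FALSE]
  }
  getField <- function(nm, len) {
    i <- grep(paste0("^", nm, " "), lines)
    if (!length(i)) return(NULL)
    as.numeric(toks(lines[i[1] + 1]))[seq_len(len)]
  }
  h <- getField("target_h", 1)
  ctr <- getField("lumen_center", 2)
  lum <- edgeOf(1L)
  if (is.null(ctr)) ctr <- colMeans(pts[unique(as.integer(lum[, 1])), , drop = FALSE])
  mesh <- new("LabeledMesh", nodes = pts, elements = tri,
              labels = factor(TISSUE_LEVELS[tl[isTri]], levels = TISSUE_LEVELS),
              boundary = list(LUMEN = lum, OUTER = edgeOf(2L)),
              h = if (is.null(h)) NA_real_ else h, lumenCenter = ctr)
  list(mesh = mesh, cellData = cellData, displacement = disp)
}

#' Export the labeled section surface as ASCII STL
#'
#' Writes the corner-node triangles of each tissue region as planar (z = 0)
#' facets, one `solid` block per tissue label, for interoperability with
#' STL-based meshing chains.
#'
#' @param mesh a [LabeledMesh-class].
#' @param path output path (conventionally `.stl`).
#' @return the path, invisibly.
#' @export
writeSectionSTL <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (lab in TISSUE_LEVELS) {
    sel <- which(mesh@labels == lab)
    if (!length(sel)) next
    writeLines(sprintf("solid %s", lab), con)
    for (e in sel) {
      v <- mesh@nodes[mesh@elements[e, 1:3], , drop = FALSE]
      writeLines(c("  facet normal 0 0 1", "    outer loop",
                   sprintf("      vertex %.9g %.9g 0", v[, 1], v[, 2]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", lab), con)
  }
  invisible(path)
}

#' Serialize a stretch report as deterministic JSON
#'
#' Fixed key order and fixed significant digits, so identical analyses give
#' byte-identical files.
#'
#' @param report a [StretchReport-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(
    parameters = report@parameters,
    tissue_summary = report@tissueSummary,
    zone_summary = report@zoneSummary,
    profiles = report@profiles)
  json <- jsonlite::toJSON(obj, dataframe = "columns", digits = I(10),
                           auto_unbox = TRUE, na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
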