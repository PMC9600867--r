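# Pipeline configuration: a YAML (or already-parsed list) document validated
# into a fully defaulted config. Unknown keys are rejected with a
# nearest-key suggestion so typos never silently fall back to defaults.

.configDefaults <- function() list(
  geometry = "reference",      # preset name, spec fields, or mesh path
  materials = "presets",       # "presets" or a material YAML path
  load_cases = c(80, 140),     # mmHg
  target_h = 0.2,              # mm
  solver = list(load_steps = 10L, newton_rtol = 1e-8, newton_max_iter = 50L,
                line_search = TRUE),
  analysis = list(threshold_mm = 1.0, reference_pct = 12.5,
                  profile_angles_deg = c(0, 60, 120)),
  output_dir = NULL,
  seed = 1L)

.knownKeys <- function(defaults, prefix = "") {
  out <- character(0)
  for (nm in names(defaults)) {
    out <- c(out, paste0(prefix, nm))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      out <- c(out, .knownKeys(defaults[[nm]], paste0(prefix, nm, "/")))
  }
  out
}

.geometryKeys <- c("preset", "lumen_radius", "outer_radius", "eccentricity",
                   "lumen_center", "calc_arcs", "lrnc_pools", "jitter_deg",
                   "mesh_path")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an already-parsed list, checks every key
#' against the schema (unknown keys are rejected with the nearest valid key
#' suggested), fills defaults (pressures 80/140 mmHg, 1 mm proximity
#' threshold, 12.5 percent reference line, three profile angles), and
#' validates values.
#'
#' @param config file path or named list.
#' @return the validated, fully defaulted config list (invisible class
#'   attribute `"plaqueStretchConfig"`).
#' @export
#' @examples
#' cfg <- validateConfig(list(geometry = "reference"))
#' cfg$load_cases
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- .configDefaults()
  known <- c(names(defaults), "geometry")
  for (key in names(config)) {
    if (!key %in% known) {
      sugg <- known[which.min(adist(key, known))]
      stop(sprintf("unknown config key '%s'; did you mean '%s'?", key, sugg),
           call. = FALSE)
    }
  }
  for (sub in c("solver", "analysis")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(defaults[[sub]]))
      if (length(bad)) {
        sugg <- names(defaults[[sub]])[which.min(adist(bad[1], names(defaults[[sub]])))]
        stop(sprintf("unknown config key '%s/%s'; did you mean '%s/%s'?",
                     sub, bad[1], sub, sugg), call. = FALSE)
      }
      defaults[[sub]][names(config[[sub]])] <- config[[sub]]
      config[[sub]] <- NULL
    }
  }
  if (is.list(config$geometry)) {
    bad <- setdiff(names(config$geometry), .geometryKeys)
    if (length(bad)) {
      sugg <- .geometryKeys[which.min(adist(bad[1], .geometryKeys))]
      stop(sprintf("unknown config key 'geometry/%s'; did you mean 'geometry/%s'?",
                   bad[1], sugg), call. = FALSE)
    }
  }
  cfg <- defaults
  cfg[names(config)] <- config
  cfg$load_cases <- as.numeric(unlist(cfg$load_cases))
  if (any(cfg$load_cases < 0))
    stop("config field 'load_cases': pressures must be >= 0", call. = FALSE)
  if (cfg$target_h <= 0)
    stop("config field 'target_h': mesh size must be > 0", call. = FALSE)
  if (cfg$analysis$threshold_mm <= 0)
    stop("config field 'analysis/threshold_mm' must be > 0", call. = FALSE)
  if (is.null(cfg$geometry) ||
      (is.list(cfg$geometry) && !length(cfg$geometry)))
    stop("config must name a geometry preset, spec fields, or a mesh path",
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("plaqueStretchConfig", class(cfg))
  cfg
}

# Resolve the geometry entry of a validated config into a LabeledMesh.
.configMesh <- function(cfg) {
  g <- cfg$geometry
  if (is.character(g)) {
    if (g %in% c("reference", "reference_stenotic"))
      return(meshGeometry(generateCrossSection(
        referenceStenoticSpec(seed = cfg$seed)), cfg$target_h))
    if (g == "annulus")
      return(meshGeometry(generateCrossSection(annulusSpec()), cfg$target_h))
    if (file.exists(g)) return(readMeshVTK(g)$mesh)
    stop("geometry '", g, "' is neither a preset nor an existing mesh file")
  }
  if (!is.null(g$mesh_path)) return(readMeshVTK(g$mesh_path)$mesh)
  if (!is.null(g$preset)) {
    cfg2 <- cfg; cfg2$geometry <- g$preset
    return(.configMesh(cfg2))
  }
  spec <- crossSectionSpec(
    lumenRadius = g$lumen_radius, outerRadius = g$outer_radius,
    calcArcs = if (!is.null(g$calc_arcs)) do.call(rbind, lapply(g$calc_arcs, as.data.frame)),
    lrncPools = if (!is.null(g$lrnc_pools)) do.call(rbind, lapply(g$lrnc_pools, as.data.frame)),
    eccentricity = if (!is.null(g$eccentricity)) g$eccentricity else 0,
    lumenCenter = g$lumen_center,
    jitterDeg = if (!is.null(g$jitter_deg)) g$jitter_deg else 0,
    seed = cfg$seed)
  meshGeometry(generateCrossSection(spec), cfg$target_h)
}

.configMaterials <- function(cfg) {
  if (identical(cfg$materials, "presets") || identical(cfg$materials, "table"))
    return(plaqueMaterialPresets())
  readMaterialTable(cfg$materials)
}

.configSolverSettings <- function(cfg) {
  s <- cfg$solver
  solverSettings(loadSteps = s$load_steps, newtonRtol = s$newton_rtol,
                 newtonMaxIter = s$newton_max_iter,
                 lineSearch = s$line_search)
}

#' Write the bundled example fixtures
#'
#' Generates the small test geometries used throughout the package's tests
#' and documentation, each as a VTK mesh plus a ready-to-run YAML config:
#' (a) a concentric MATX annulus, (b) the reference stenotic plaque, (c) the
#' stenotic plaque without its calcification, and (d) a tiny square patch
#' mesh for affine checks. Regeneration is bit-identical for a fixed seed.
#'
#' @param dir writable output directory (created if needed).
#' @param targetH mesh size for the vessel fixtures, mm.
#' @param seed generator seed recorded in the configs.
#' @return named list of the files written, invisibly.
#' @export
makeFixtures <- function(dir, targetH = 0.4, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  emit <- function(name, mesh, geometry) {
    meshPath <- file.path(dir, paste0(name, ".vtk"))
    writeMeshVTK(mesh, meshPath)
    cfgPath <- file.path(dir, paste0(name, ".yaml"))
    yaml::write_yaml(list(geometry = meshPath, target_h = targetH,
                          seed = seed), cfgPath)
    files[[name]] <<- c(mesh = meshPath, config = cfgPath)
  }
  emit("annulus_matx",
       meshGeometry(generateCrossSection(annulusSpec(3, 4)), targetH))
  emit("reference_stenotic",
       meshGeometry(generateCrossSection(referenceStenoticSpec(seed = seed)),
                    targetH))
  noCalc <- referenceStenoticSpec(seed = seed)
  noCalc@calcArcs <- noCalc@calcArcs[0, , drop = FALSE]
  emit("stenotic_no_calc",
       meshGeometry(generateCrossSection(noCalc), targetH))
  patchPath <- file.path(dir, "patch.vtk")
  writeMeshVTK(patchMesh(), patchPath)
  files[["patch"]] <- c(mesh = patchPath)
  invisible(files)
}

#' Tiny square patch mesh for affine verification
#'
#' A unit square split into 8 quadratic triangles, all MATX, with the left
#' edge tagged LUMEN and the right edge OUTER. Used for affine patch tests
#' of the stretch post-processing.
#'
#' @param n grid subdivisions per side.
#' @return a [LabeledMesh-class].
#' @export
patchMesh <- function(n = 2L) {
  n <- as.integer(n)
  xs <- seq(0, 1, length.out = n + 1)
  cornerId <- function(i, j) as.integer((j - 1L) * (n + 1L) + i)
  nCorner <- (n + 1L) * (n + 1L)
  coords <- cbind(rep(xs, times = n + 1), rep(xs, each = n + 1))
  midEnv <- new.env(hash = TRUE, parent = emptyenv())
  midCoord <- NULL
  midId <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    id <- midEnv[[key]]
    if (is.null(id)) {
      id <- as.integer(nCorner + NROW(midCoord) + 1L)
      midCoord <<- rbind(midCoord, (coords[a, ] + coords[b, ]) / 2)
      midEnv[[key]] <- id
    }
    id
  }
  elems <- NULL
  for (j in seq_len(n)) for (i in seq_len(n)) {
    A <- cornerId(i, j); B <- cornerId(i + 1L, j)
    C <- cornerId(i + 1L, j + 1L); D <- cornerId(i, j + 1L)
    elems <- rbind(elems,
                   c(A, B, C, midId(A, B), midId(B, C), midId(C, A)),
                   c(A, C, D, midId(A, C), midId(C, D), midId(D, A)))
  }
  leftEdges <- t(vapply(seq_len(n), function(j) {
    A <- cornerId(1L, j + 1L); B <- cornerId(1L, j)  # downward = CCW for x>0 side
    c(A, B, midId(A, B))
  }, integer(3)))
  rightEdges <- t(vapply(seq_len(n), function(j) {
    A <- cornerId(n + 1L, j); B <- cornerId(n + 1L, j + 1L)
    c(A, B, midId(A, B))
  }, integer(3)))
  new("LabeledMesh", nodes = rbind(coords, midCoord),
      elements = elems,
      labels = factor(rep("MATX", nrow(elems)), levels = TISSUE_LEVELS),
      boundary = list(LUMEN = leftEdges, OUTER = rightEdges),
      h = 1 / n, lumenCenter = c(0, 0.5))
}
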