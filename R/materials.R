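#' Construct a Yeoh material
#'
#' @param c1,c2,c3 Yeoh constants, Pa. `c1 > 0`; the small-strain shear
#'   modulus is `2*c1`.
#' @param kappa volumetric penalty modulus, Pa; defaults to `1000 * 2*c1`,
#'   the smallest value admitted by the near-incompressibility requirement.
#' @param name material name.
#' @return a [YeohMaterial-class].
#' @export
#' @examples
#' yeohMaterial(2.35e4, 1.26e5, 1.12e5, name = "MATX")
yeohMaterial <- function(c1, c2, c3, kappa = 1000 * 2 * c1, name = "") {
  new("YeohMaterial", c1 = as.numeric(c1), c2 = as.numeric(c2),
      c3 = as.numeric(c3), kappa = as.numeric(kappa),
      name = as.character(name))
}

#' Construct a tissue-to-material table
#'
#' @param MATX,CALC,LRNC [YeohMaterial-class] objects for the three tissue
#'   classes.
#' @return a [MaterialTable-class].
#' @export
materialTable <- function(MATX, CALC, LRNC) {
  new("MaterialTable", materials = list(MATX = MATX, CALC = CALC, LRNC = LRNC))
}

#' Literature-based Yeoh constants for carotid plaque tissue classes
#'
#' The package's default material table: experimentally derived three-term
#' Yeoh constants for fibrous/cellular matrix (MATX), macro-calcification
#' (CALC) and lipid-rich necrotic core (LRNC), in Pa, with the default
#' volumetric penalty `kappa = 1000 * 2*c1` per tissue. CALC is roughly 13x
#' stiffer than MATX at small strain (`mu0 = 2*c1`).
#'
#' @param kappaFactor multiplier on the small-strain shear modulus giving the
#'   volumetric penalty, default 1000 (the near-incompressible floor).
#' @return a [MaterialTable-class].
#' @export
#' @examples
#' tbl <- plaqueMaterialPresets()
#' materialOf(tbl, "CALC")
plaqueMaterialPresets <- function(kappaFactor = 1000) {
  materialTable(
    MATX = yeohMaterial(2.35e4, 1.26e5, 1.12e5,
                        kappa = kappaFactor * 2 * 2.35e4, name = "MATX"),
    CALC = yeohMaterial(3.02e5, -2.28e5, 2.61e5,
                        kappa = kappaFactor * 2 * 3.02e5, name = "CALC"),
    LRNC = yeohMaterial(2.96e4, -3.32e4, 1.29e5,
                        kappa = kappaFactor * 2 * 2.96e4, name = "LRNC"))
}

#' Look up the material for a tissue label
#'
#' @param table a [MaterialTable-class].
#' @param label one of "MATX", "CALC", "LRNC".
#' @return a [YeohMaterial-class].
#' @export
materialOf <- function(table, label) {
  stopifnot(is(table, "MaterialTable"), label %in% TISSUE_LEVELS)
  table@materials[[label]]
}

#' Replace the material assigned to a tissue label
#'
#' Useful for in-silico substitution experiments, e.g. assigning the MATX
#' material to CALC elements to isolate the material contribution of
#' calcification from its geometry.
#'
#' @param table a [MaterialTable-class].
#' @param label tissue label to reassign.
#' @param material the [YeohMaterial-class] to use for that label.
#' @return the modified [MaterialTable-class].
#' @export
substituteMaterial <- function(table, label, material) {
  stopifnot(is(table, "MaterialTable"), label %in% TISSUE_LEVELS,
            is(material, "YeohMaterial"))
  table@materials[[label]] <- material
  validObject(table)
  table
}

# ne x 4 matrix (c1, c2, c3, kappa) per element for the C++ kernels.
.materialParams <- function(mesh, table) {
  labs <- as.character(mesh@labels)
  pars <- t(vapply(TISSUE_LEVELS, function(l) {
    m <- table@materials[[l]]
    c(m@c1, m@c2, m@c3, m@kappa)
  }, numeric(4)))
  pars[match(labs, TISSUE_LEVELS), , drop = FALSE]
}

#' Read / write a material table as a YAML file
#'
#' The file lists `c1`, `c2`, `c3` (Pa) and optionally `kappa` per tissue
#' label, lower-case keys allowed.
#'
#' @param path file path.
#' @return [readMaterialTable()] returns a [MaterialTable-class].
#' @export
readMaterialTable <- function(path) {
  raw <- yaml::read_yaml(path)
  names(raw) <- toupper(names(raw))
  if (!all(TISSUE_LEVELS %in% names(raw)))
    stop("material file must define all of MATX, CALC, LRNC")
  mk <- function(lab) {
    v <- raw[[lab]]
    kappa <- if (!is.null(v$kappa)) v$kappa else 1000 * 2 * v$c1
    yeohMaterial(v$c1, v$c2, v$c3, kappa = kappa, name = lab)
  }
  materialTable(mk("MATX"), mk("CALC"), mk("LRNC"))
}

#' @rdname readMaterialTable
#' @param table a [MaterialTable-class] to serialize.
#' @export
writeMaterialTable <- function(table, path) {
  out <- lapply(table@materials[TISSUE_LEVELS], function(m)
    list(c1 = m@c1, c2 = m@c2, c3 = m@c3, kappa = m@kappa))
  yaml::write_yaml(out, path)
  invisible(path)
}
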