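#' Mesh a labeled cross-section geometry with quadratic triangles
#'
#' Builds a conforming 6-node-triangle mesh on a structured polar chart
#' anchored at the lumen center. The angular and radial-fraction boundaries of
#' every tissue region are inserted as grid lines, so tissue regions are
#' unions of whole elements and element labels (label of the region containing
#' the element's parametric centroid) are unambiguous. All nodes, including
#' midside nodes, are mapped through the chart, giving curved isoparametric
#' elements that follow the circular boundaries. Meshing is deterministic for
#' a fixed spec and seed.
#'
#' @param geometry a [PlaqueGeometry-class] from [generateCrossSection()], or
#'   a [CrossSectionSpec-class] (meshed via its geometry).
#' @param targetH target element edge length, mm.
#' @return a [LabeledMesh-class].
#' @export
meshGeometry <- function(geometry, targetH) {
  if (is(geometry, "CrossSectionSpec"))
    geometry <- generateCrossSection(geometry)
  stopifnot(is(geometry, "PlaqueGeometry"), targetH > 0)
  spec <- geometry@spec
  reg <- .specRegions(spec)

  thFine <- seq(0, 2 * pi, length.out = 721)[-721]
  rayLen <- .outerRay(spec, thFine)
  rMid <- mean(spec@lumenRadius + rayLen) / 2
  thickMean <- mean(rayLen) - spec@lumenRadius

  nTheta <- max(12L, ceiling(2 * pi * rMid / targetH))
  thetaU <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  if (spec@jitterDeg > 0) {
    saved <- get0(".Random.seed", envir = globalenv())
    set.seed(spec@seed)
    dth <- 2 * pi / nTheta
    jit <- runif(nTheta, -1, 1) * min(spec@jitterDeg * pi / 180, 0.3 * dth)
    thetaU <- (thetaU + jit) %% (2 * pi)
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
  }
  nS <- max(2L, ceiling(thickMean / targetH))
  sU <- seq(0, 1, length.out = nS + 1)

  thetaLines <- .mergeLines(thetaU, sort(unique(
    round(c(reg$theta0, reg$theta0 + reg$span) %% (2 * pi), 12))),
    minGap = 0.3 * 2 * pi / nTheta, wrap = 2 * pi)
  sLines <- .mergeLines(sU, sort(unique(round(c(reg$s0, reg$s1), 12))),
                        minGap = 0.3 / nS, wrap = NULL)
  sLines <- sLines[sLines >= -1e-12 & sLines <= 1 + 1e-12]
  sLines[1] <- 0; sLines[length(sLines)] <- 1

  nT <- length(thetaLines)
  nR <- length(sLines)
  cornerId <- function(j, k) (k - 1L) * nT + ((j - 1L) %% nT) + 1L
  nCorner <- nT * nR
  # parametric coordinates per corner node
  cornTheta <- rep(thetaLines, times = nR)
  cornS <- rep(sLines, each = nT)

  midEnv <- new.env(hash = TRUE, parent = emptyenv())
  midTheta <- numeric(0); midS <- numeric(0)
  midId <- function(a, b, tha, thb, sa, sb) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    id <- midEnv[[key]]
    if (is.null(id)) {
      id <- nCorner + length(midTheta) + 1L
      midTheta[id - nCorner] <<- (tha + thb) / 2
      midS[id - nCorner] <<- (sa + sb) / 2
      midEnv[[key]] <- id
    }
    id
  }

  elems <- matrix(0L, nrow = 2L * nT * (nR - 1L), ncol = 6L)
  labs <- character(nrow(elems))
  ee <- 0L
  for (k in seq_len(nR - 1L)) {
    for (j in seq_len(nT)) {
      th0 <- thetaLines[j]
      th1 <- if (j < nT) thetaLines[j + 1] else thetaLines[1] + 2 * pi
      s0 <- sLines[k]; s1 <- sLines[k + 1]
      A <- cornerId(j, k);     B <- cornerId(j + 1L, k)
      C <- cornerId(j + 1L, k + 1L); D <- cornerId(j, k + 1L)
      lab <- .labelAt(reg, ((th0 + th1) / 2) %% (2 * pi), (s0 + s1) / 2)
      mAB <- midId(A, B, th0, th1, s0, s0)
      mBC <- midId(B, C, th1, th1, s0, s1)
      mCA <- midId(C, A, th1, th0, s1, s0)
      mCD <- midId(C, D, th1, th0, s1, s1)
      mDA <- midId(D, A, th0, th0, s1, s0)
      ee <- ee + 1L; elems[ee, ] <- c(A, B, C, mAB, mBC, mCA); labs[ee] <- lab
      ee <- ee + 1L; elems[ee, ] <- c(A, C, D, mCA, mCD, mDA); labs[ee] <- lab
    }
  }

  nodes <- rbind(.chartMap(spec, cornTheta, cornS),
                 .chartMap(spec, midTheta, midS))

  # canonicalize orientation: positive corner-triangle area
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE]
  cc <- nodes[elems[, 3], , drop = FALSE]
  s2 <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  flip <- s2 < 0
  if (any(flip))
    elems[flip, ] <- elems[flip, c(1L, 3L, 2L, 6L, 5L, 4L), drop = FALSE]

  lumenEdges <- t(vapply(seq_len(nT), function(j) {
    A <- cornerId(j, 1L); B <- cornerId(j + 1L, 1L)
    key <- if (A < B) paste(A, B) else paste(B, A)
    c(A, B, midEnv[[key]])
  }, integer(3)))
  outerEdges <- t(vapply(seq_len(nT), function(j) {
    A <- cornerId(j, nR); B <- cornerId(j + 1L, nR)
    key <- if (A < B) paste(A, B) else paste(B, A)
    c(A, B, midEnv[[key]])
  }, integer(3)))

  mesh <- new("LabeledMesh", nodes = nodes, elements = elems,
              labels = factor(labs, levels = TISSUE_LEVELS),
              boundary = list(LUMEN = lumenEdges, OUTER = outerEdges),
              h = targetH, lumenCenter = spec@lumenCenter)
  areas <- elementAreas(mesh)
  if (any(areas <= 0))
    stop("mesher produced inverted elements (labels: ",
         paste(unique(labs[areas <= 0]), collapse = ", "), ")")
  mesh
}

# Merge uniform grid lines with mandatory (region-boundary) lines: mandatory
# lines are kept exactly; uniform lines closer than minGap to a mandatory one
# are dropped to avoid slivers.
.mergeLines <- function(uniform, mandatory, minGap, wrap = NULL) {
  if (!length(mandatory)) return(sort(uniform))
  keep <- vapply(uniform, function(u) {
    d <- abs(u - mandatory)
    if (!is.null(wrap)) d <- pmin(d, wrap - d)
    all(d >= minGap)
  }, logical(1))
  sort(unique(c(uniform[keep], mandatory)))
}

#' Element areas by quadrature
#'
#' Reference-configuration areas of the (possibly curved) quadratic triangles,
#' integrated with the element quadrature rule.
#'
#' @param mesh a [LabeledMesh-class].
#' @return numeric vector of areas, mm^2.
#' @export
elementAreas <- function(mesh) {
  d <- fem_defgrad_cpp(mesh@nodes, mesh@elements,
                       numeric(2L * nrow(mesh@nodes)))
  as.numeric(d$area)
}

#' Element centroids (mean of corner nodes)
#'
#' @param mesh a [LabeledMesh-class].
#' @return ne x 2 matrix, mm.
#' @export
elementCentroids <- function(mesh) {
  e <- mesh@elements
  (mesh@nodes[e[, 1], , drop = FALSE] + mesh@nodes[e[, 2], , drop = FALSE] +
     mesh@nodes[e[, 3], , drop = FALSE]) / 3
}

# Even-odd point-in-polygon test; poly is a closed ring (matrix n x 2).
.pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    cross <- ((y1[i] > py) != (y2[i] > py)) &
      (px < (x2[i] - x1[i]) * (py - y1[i]) / (y2[i] - y1[i]) + x1[i])
    inside <- xor(inside, cross)
  }
  inside
}

# Polygonal ring of corner nodes around a tagged boundary loop, in edge order.
.boundaryLoopPolygon <- function(mesh, which = "LUMEN") {
  edges <- mesh@boundary[[which]]
  mesh@nodes[edges[, 1], , drop = FALSE]
}

#' Locate points in a labeled mesh
#'
#' Classifies query points as belonging to an element (straight-corner-edge
#' barycentric test with tolerance), the lumen, or outside the section.
#'
#' @param mesh a [LabeledMesh-class].
#' @param points m x 2 matrix of query coordinates, mm.
#' @param tol barycentric tolerance.
#' @return integer vector of length m: element index, 0 for lumen, NA for
#'   outside.
#' @export
locateElements <- function(mesh, points, tol = 1e-9) {
  points <- matrix(points, ncol = 2)
  e <- mesh@elements
  ax <- mesh@nodes[e[, 1], 1]; ay <- mesh@nodes[e[, 1], 2]
  bx <- mesh@nodes[e[, 2], 1]; by <- mesh@nodes[e[, 2], 2]
  cx <- mesh@nodes[e[, 3], 1]; cy <- mesh@nodes[e[, 3], 2]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  lumenPoly <- .boundaryLoopPolygon(mesh, "LUMEN")
  outerPoly <- .boundaryLoopPolygon(mesh, "OUTER")
  out <- integer(nrow(points))
  inLumen <- .pointInPolygon(points[, 1], points[, 2], lumenPoly)
  inOuter <- .pointInPolygon(points[, 1], points[, 2], outerPoly)
  ctr <- elementCentroids(mesh)
  for (m in seq_len(nrow(points))) {
    if (inLumen[m]) { out[m] <- 0L; next }
    if (!inOuter[m]) { out[m] <- NA_integer_; next }
    px <- points[m, 1]; py <- points[m, 2]
    w1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / den
    w2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / den
    w3 <- 1 - w1 - w2
    hit <- which(w1 >= -tol & w2 >= -tol & w3 >= -tol)
    if (length(hit)) {
      out[m] <- hit[1]
    } else {
      # between curved boundary and straight corner edge: nearest centroid
      out[m] <- which.min((ctr[, 1] - px)^2 + (ctr[, 2] - py)^2)
    }
  }
  out
}

#' Mirror a labeled mesh across the x axis
#'
#' Flips node y coordinates and restores element orientation and boundary-loop
#' direction, keeping node numbering. Used to test that the solver is
#' equivariant under reflection: the mirrored problem's displacement field
#' must be the mirror image of the original one.
#'
#' @param mesh a [LabeledMesh-class].
#' @return the mirrored [LabeledMesh-class].
#' @export
mirrorMesh <- function(mesh) {
  nodes <- mesh@nodes
  nodes[, 2] <- -nodes[, 2]
  elems <- mesh@elements[, c(1L, 3L, 2L, 6L, 5L, 4L), drop = FALSE]
  flipEdges <- function(ed) ed[, c(2L, 1L, 3L), drop = FALSE]
  new("LabeledMesh", nodes = nodes, elements = elems, labels = mesh@labels,
      boundary = list(LUMEN = flipEdges(mesh@boundary$LUMEN),
                      OUTER = flipEdges(mesh@boundary$OUTER)),
      h = mesh@h, lumenCenter = c(mesh@lumenCenter[1], -mesh@lumenCenter[2]))
}
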