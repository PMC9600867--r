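#' Kinematic state derived from a deformation gradient
#'
#' Accepts the in-plane 2x2 block of a plane-strain motion (out-of-plane
#' stretch fixed at 1) or a full 3x3 deformation gradient, and returns the
#' quantities the Yeoh energy is built on: `J = det F`, the right
#' Cauchy-Green tensor `C = t(F) %*% F`, and the isochoric first invariant
#' `Ib1 = J^(-2/3) * tr(C)`.
#'
#' @param F 2x2 or 3x3 deformation gradient.
#' @return list with `F` (3x3), `J`, `C`, `I1`, `Ib1`, and `dim` (the input
#'   dimension).
#' @export
kinematicState <- function(F) {
  F <- as.matrix(F)
  d <- nrow(F)
  stopifnot(d %in% c(2, 3), ncol(F) == d)
  F3 <- if (d == 2) rbind(cbind(F, 0), c(0, 0, 1)) else F
  J <- det(F3)
  if (J <= 0)
    stop(sprintf("inverted state: det F = %.3g <= 0", J))
  C <- crossprod(F3)
  I1 <- sum(diag(C))
  list(F = F3, J = J, C = C, I1 = I1, Ib1 = J^(-2 / 3) * I1, dim = d)
}

#' Yeoh strain-energy density
#'
#' `W = c1*(Ib1-3) + c2*(Ib1-3)^2 + c3*(Ib1-3)^3 + kappa/2*(J-1)^2` with the
#' isochoric invariant `Ib1`. Zero at the reference state `F = I`.
#'
#' @param material a [YeohMaterial-class].
#' @param F 2x2 (plane strain) or 3x3 deformation gradient, or a state from
#'   [kinematicState()].
#' @return energy density, Pa.
#' @export
#' @examples
#' m <- materialOf(plaqueMaterialPresets(), "MATX")
#' lam <- 1.2
#' F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))  # incompressible uniaxial
#' strainEnergy(m, F)
strainEnergy <- function(material, F) {
  st <- if (is.list(F) && !is.null(F$Ib1)) F else kinematicState(F)
  x <- st$Ib1 - 3
  material@c1 * x + material@c2 * x^2 + material@c3 * x^3 +
    material@kappa / 2 * (st$J - 1)^2
}

# First Piola-Kirchhoff stress, 3x3.
.pk1 <- function(material, st) {
  x <- st$Ib1 - 3
  psi1 <- material@c1 + 2 * material@c2 * x + 3 * material@c3 * x^2
  FiT <- t(solve(st$F))
  Jm23 <- st$J^(-2 / 3)
  psi1 * (2 * Jm23 * st$F - (2 / 3) * st$Ib1 * FiT) +
    material@kappa * (st$J - 1) * st$J * FiT
}

#' Cauchy stress of the Yeoh model
#'
#' Push-forward `sigma = P %*% t(F) / J` of the first Piola-Kirchhoff stress
#' derived from [strainEnergy()]. Symmetric, and zero at `F = I`.
#'
#' @inheritParams strainEnergy
#' @return symmetric Cauchy stress (same dimension as the input `F`), Pa.
#' @export
cauchyStress <- function(material, F) {
  st <- if (is.list(F) && !is.null(F$Ib1)) F else kinematicState(F)
  sig <- .pk1(material, st) %*% t(st$F) / st$J
  sig <- (sig + t(sig)) / 2  # clean up roundoff asymmetry
  if (st$dim == 2) sig[1:2, 1:2] else sig
}

#' Material tangent of the Yeoh model
#'
#' Consistent linearization `A[i,J,k,L] = d P[i,J] / d F[k,L]` of the first
#' Piola-Kirchhoff stress. Possesses major symmetry `A[i,J,k,L] =
#' A[k,L,i,J]` since it is the second derivative of the energy.
#'
#' @inheritParams strainEnergy
#' @return a 4-dimensional array (d x d x d x d matching the input
#'   dimension).
#' @export
materialTangent <- function(material, F) {
  st <- if (is.list(F) && !is.null(F$Ib1)) F else kinematicState(F)
  d <- 3
  x <- st$Ib1 - 3
  psi1 <- material@c1 + 2 * material@c2 * x + 3 * material@c3 * x^2
  psi2 <- 2 * material@c2 + 6 * material@c3 * x
  kap <- material@kappa
  Fi <- solve(st$F)
  FiT <- t(Fi)
  Jm23 <- st$J^(-2 / 3)
  G <- 2 * Jm23 * st$F - (2 / 3) * st$Ib1 * FiT
  A <- array(0, c(d, d, d, d))
  for (i in 1:d) for (J in 1:d) for (k in 1:d) for (L in 1:d) {
    del <- (i == k) * (J == L)
    A[i, J, k, L] <- psi2 * G[i, J] * G[k, L] +
      psi1 * (2 * Jm23 * del -
                (4 / 3) * Jm23 * (st$F[i, J] * FiT[k, L] + st$F[k, L] * FiT[i, J]) +
                (4 / 9) * st$Ib1 * FiT[i, J] * FiT[k, L] +
                (2 / 3) * st$Ib1 * Fi[J, k] * Fi[L, i]) +
      kap * st$J * (2 * st$J - 1) * FiT[i, J] * FiT[k, L] -
      kap * (st$J - 1) * st$J * Fi[J, k] * Fi[L, i]
  }
  if (st$dim == 2) A[1:2, 1:2, 1:2, 1:2, drop = FALSE] else A
}

#' Small-strain shear modulus of a Yeoh material
#'
#' @param material a [YeohMaterial-class].
#' @return `mu0 = 2 * c1`, Pa.
#' @export
initialShearModulus <- function(material) 2 * material@c1

#' Energy positivity along incompressible loading paths
#'
#' Evaluates the Yeoh energy along incompressible uniaxial
#' (`diag(l, 1/sqrt(l), 1/sqrt(l))`) and equibiaxial (`diag(l, l, 1/l^2)`)
#' paths over a stretch range, guarding against the negative `c2` of the
#' CALC/LRNC presets producing nonphysical softening in the working range.
#'
#' @param material a [YeohMaterial-class].
#' @param lambdaRange stretch range to scan, default `c(0.8, 1.5)`.
#' @param n number of scan points per path.
#' @return the minimum energy over both paths (negative values flag a
#'   nonphysical parameter set in the scanned range).
#' @export
energyPathMinimum <- function(material, lambdaRange = c(0.8, 1.5), n = 201) {
  lam <- seq(lambdaRange[1], lambdaRange[2], length.out = n)
  wUni <- vapply(lam, function(l)
    strainEnergy(material, diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))), numeric(1))
  wBi <- vapply(lam, function(l)
    strainEnergy(material, diag(c(l, l, 1 / l^2))), numeric(1))
  min(c(wUni, wBi))
}
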