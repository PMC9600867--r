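# Shared fixtures (memoized per test run) and independent numerical oracles.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fxPresets <- function() fxMemo("presets", plaqueMaterialPresets())

fxAnnulusMesh <- function(h = 0.4, Ri = 3, Ro = 4) {
  fxMemo(sprintf("ann_%g_%g_%g", Ri, Ro, h),
         meshGeometry(generateCrossSection(annulusSpec(Ri, Ro)), h))
}

fxStenoticMesh <- function(h = 0.3) {
  fxMemo(sprintf("sten_%g", h),
         meshGeometry(generateCrossSection(referenceStenoticSpec()), h))
}

# Affine solution field u = (F - I) x on a given mesh, for patch tests.
affineSolution <- function(mesh, F2, name = "affine") {
  x <- nodeCoords(mesh)
  u <- t((F2 - diag(2)) %*% t(x))
  new("SolutionField", displacement = u, converged = TRUE,
      residualHistory = list(), pressureMmHg = 0, caseName = name,
      constraints = data.frame(node = integer(), dof = integer()))
}

# Independent finite-difference oracles built on the energy alone.
fdPK1 <- function(material, F, h = 1e-6) {
  F <- as.matrix(F)
  d <- nrow(F)
  P <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strainEnergy(material, Fp) - strainEnergy(material, Fm)) / (2 * h)
  }
  P
}

fdCauchy <- function(material, F, h = 1e-6) {
  F <- as.matrix(F)
  F3 <- if (nrow(F) == 2) rbind(cbind(F, 0), c(0, 0, 1)) else F
  sig <- fdPK1(material, F3, h) %*% t(F3) / det(F3)
  if (nrow(F) == 2) sig[1:2, 1:2] else sig
}

# Second central difference of the energy: A[i,J,k,L] = d2 W / dF_iJ dF_kL.
fdTangent <- function(material, F, h = 1e-4) {
  F <- as.matrix(F)
  d <- nrow(F)
  F3 <- if (d == 2) rbind(cbind(F, 0), c(0, 0, 1)) else F
  A <- array(0, c(3, 3, 3, 3))
  W <- function(Fm) strainEnergy(material, Fm)
  for (i in 1:3) for (J in 1:3) for (k in 1:3) for (L in 1:3) {
    Fpp <- F3; Fpp[i, J] <- Fpp[i, J] + h; Fpp[k, L] <- Fpp[k, L] + h
    Fpm <- F3; Fpm[i, J] <- Fpm[i, J] + h; Fpm[k, L] <- Fpm[k, L] - h
    Fmp <- F3; Fmp[i, J] <- Fmp[i, J] - h; Fmp[k, L] <- Fmp[k, L] + h
    Fmm <- F3; Fmm[i, J] <- Fmm[i, J] - h; Fmm[k, L] <- Fmm[k, L] - h
    A[i, J, k, L] <- (W(Fpp) - W(Fpm) - W(Fmp) + W(Fmm)) / (4 * h^2)
  }
  if (d == 2) A[1:2, 1:2, 1:2, 1:2, drop = FALSE] else A
}

# Random deformation gradients with J near 1.
randomStates <- function(n, d = 3, amp = 0.06, seed = 42) {
  set.seed(seed)
  out <- vector("list", n)
  k <- 0
  while (k < n) {
    F <- diag(d) + matrix(rnorm(d * d, sd = amp), d, d)
    if (det(if (d == 2) rbind(cbind(F, 0), c(0, 0, 1)) else F) > 0.5) {
      k <- k + 1
      out[[k]] <- F
    }
  }
  out
}

randomRotation3 <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

maxRel <- function(a, b) max(abs(a - b)) / max(abs(b))
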