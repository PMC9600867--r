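#' Solver settings for the quasistatic Newton continuation
#'
#' @param loadSteps number of uniform load increments from zero to the target
#'   pressure.
#' @param newtonRtol relative residual tolerance (residual norm over applied
#'   external force norm).
#' @param newtonMaxIter maximum Newton iterations per load step.
#' @param lineSearch logical; backtrack the Newton step to the largest
#'   fraction free of element inversion (admissibility line search). With
#'   `FALSE` an inadmissible full step immediately triggers load-step
#'   halving.
#' @param maxHalvings maximum number of automatic load-step halvings on
#'   divergence or element inversion before giving up.
#' @return a validated settings list.
#' @export
solverSettings <- function(loadSteps = 10L, newtonRtol = 1e-8,
                           newtonMaxIter = 50L, lineSearch = TRUE,
                           maxHalvings = 5L) {
  stopifnot(loadSteps >= 1, newtonRtol > 0, newtonMaxIter >= 1)
  list(loadSteps = as.integer(loadSteps), newtonRtol = newtonRtol,
       newtonMaxIter = as.integer(newtonMaxIter),
       lineSearch = isTRUE(lineSearch), maxHalvings = as.integer(maxHalvings))
}

#' Luminal pressure load case
#'
#' @param pressureMmHg luminal pressure, mmHg (converted internally with
#'   1 mmHg = 133.322 Pa).
#' @param name case name; defaults to "diastole" for 80 mmHg, "systole" for
#'   140 mmHg, otherwise "p<value>".
#' @return a list with `pressureMmHg`, `pressurePa`, `name`.
#' @export
loadCase <- function(pressureMmHg, name = NULL) {
  stopifnot(pressureMmHg >= 0)
  if (is.null(name))
    name <- if (pressureMmHg == 80) "diastole"
            else if (pressureMmHg == 140) "systole"
            else sprintf("p%g", pressureMmHg)
  list(pressureMmHg = pressureMmHg, pressurePa = pressureMmHg * MMHG_TO_PA,
       name = name)
}

#' Default rigid-body constraints for a pressurized cross-section
#'
#' The luminal pressure on a closed wall is self-equilibrated, so only the
#' three in-plane rigid-body modes need removing. Constraints are placed on
#' the OUTER boundary tangentially to the expected radial motion so they do
#' not obstruct inflation: `u_y = 0` at the outer nodes nearest angles 0 and
#' 180 degrees (about the outer-loop centroid) and `u_x = 0` at the node
#' nearest 90 degrees.
#'
#' @param mesh a [LabeledMesh-class].
#' @return data.frame with columns `node` and `dof` (1 = x, 2 = y).
#' @export
defaultConstraints <- function(mesh) {
  loop <- unique(as.integer(mesh@boundary$OUTER[, 1:2]))
  p <- mesh@nodes[loop, , drop = FALSE]
  ctr <- colMeans(p)
  ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1]) %% (2 * pi)
  nearest <- function(target) loop[which.min(pmin(abs(ang - target),
                                                  2 * pi - abs(ang - target)))]
  data.frame(node = c(nearest(0), nearest(pi), nearest(pi / 2)),
             dof = c(2L, 2L, 1L))
}

#' Solve the quasistatic inflation problem
#'
#' Finds the displacement field balancing the internal Yeoh stresses against
#' the luminal pressure applied as a follower load on the deformed LUMEN
#' boundary, with the OUTER boundary traction-free. Newton's method with
#' consistent tangent (including the unsymmetric follower-load stiffness),
#' uniform load stepping, optional backtracking line search, and automatic
#' step halving on divergence or element inversion. Deterministic for fixed
#' inputs.
#'
#' @param mesh a [LabeledMesh-class].
#' @param materials a [MaterialTable-class] covering all labels in the mesh.
#' @param load a load case from [loadCase()] or a pressure in mmHg.
#' @param settings a list from [solverSettings()].
#' @param constraints data.frame (`node`, `dof`) of homogeneous Dirichlet
#'   constraints; defaults to [defaultConstraints()].
#' @return a [SolutionField-class].
#' @export
solveQuasistatic <- function(mesh, materials, load,
                             settings = solverSettings(),
                             constraints = NULL) {
  if (is.numeric(load)) load <- loadCase(load)
  stopifnot(is(mesh, "LabeledMesh"), is(materials, "MaterialTable"))
  if (is.null(constraints)) constraints <- defaultConstraints(mesh)
  matpar <- .materialParams(mesh, materials)
  nn <- nrow(mesh@nodes)
  fixed <- sort(unique(2L * (constraints$node - 1L) + constraints$dof))
  free <- setdiff(seq_len(2L * nn), fixed)
  u <- numeric(2L * nn)
  history <- list()

  if (load$pressurePa == 0) {
    return(new("SolutionField",
               displacement = matrix(0, nn, 2), converged = TRUE,
               residualHistory = list(step1 = 0),
               pressureMmHg = load$pressureMmHg, caseName = load$name,
               constraints = constraints))
  }

  # The tangent is unsymmetric only through the follower-load stiffness,
  # which is small and confined to lumen-boundary dofs. Factor the symmetric
  # part with sparse Cholesky and solve the true unsymmetric system by
  # iterative refinement (preconditioned Richardson); fall back to general
  # sparse LU when the refinement stalls or the symmetric part is indefinite.
  solveLinear <- function(K, Ks, b) {
    ch <- tryCatch(suppressWarnings(Matrix::Cholesky(Ks, LDL = FALSE)),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      x <- as.numeric(Matrix::solve(ch, b))
      bn <- sqrt(sum(b^2))
      for (it in 1:10) {
        r <- b - as.numeric(K %*% x)
        if (sqrt(sum(r^2)) <= 1e-12 * bn) return(x)
        x <- x + as.numeric(Matrix::solve(ch, r))
      }
      r <- b - as.numeric(K %*% x)
      if (sqrt(sum(r^2)) <= 1e-9 * bn) return(x)
    }
    as.numeric(Matrix::solve(K, b))
  }

  resNorm <- function(uTry, p) {
    a <- fem_assemble_cpp(mesh@nodes, mesh@elements, matpar, uTry, p,
                          mesh@boundary$LUMEN, FALSE)
    if (!isTRUE(a$ok)) return(list(ok = FALSE))
    r <- a$fint - a$fext
    list(ok = TRUE, norm = sqrt(sum(r[free]^2)),
         ref = max(sqrt(sum(a$fext^2)), 1e-12))
  }

  newtonStep <- function(u0, p) {
    # returns list(ok, u, relres vector)
    u <- u0
    rel <- numeric(0)
    for (it in seq_len(settings$newtonMaxIter)) {
      a <- fem_assemble_cpp(mesh@nodes, mesh@elements, matpar, u, p,
                            mesh@boundary$LUMEN, TRUE)
      if (!isTRUE(a$ok)) return(list(ok = FALSE, u = u0, rel = rel))
      r <- a$fint - a$fext
      ref <- max(sqrt(sum(a$fext^2)), 1e-12)
      rn <- sqrt(sum(r[free]^2))
      rel[it] <- rn / ref
      if (rel[it] <= settings$newtonRtol)
        return(list(ok = TRUE, u = u, rel = rel))
      K <- Matrix::sparseMatrix(i = a$i, j = a$j, x = a$x,
                                dims = c(2L * nn, 2L * nn))
      Ks <- Matrix::forceSymmetric(Matrix::sparseMatrix(
        i = c(a$i, a$j), j = c(a$j, a$i), x = c(a$x, a$x) / 2,
        dims = c(2L * nn, 2L * nn)))
      du <- numeric(2L * nn)
      sol <- tryCatch(solveLinear(K[free, free, drop = FALSE],
                                  Ks[free, free, drop = FALSE], r[free]),
                      error = function(e) NULL)
      if (is.null(sol)) return(list(ok = FALSE, u = u0, rel = rel))
      du[free] <- -sol
      # Admissibility line search: take the largest step fraction that does
      # not invert an element. The residual norm is deliberately NOT used as
      # an acceptance criterion — the quadratic volumetric penalty makes it
      # overshoot transiently on convergent Newton steps (a norm-descent
      # search then crawls at tiny step fractions and stalls), while the
      # full step self-corrects within a few iterations. Divergence is
      # guarded by an explosion cap, the iteration cap, and load-step
      # halving in the outer continuation.
      alpha <- 1
      accepted <- FALSE
      for (ls in seq_len(if (settings$lineSearch) 8L else 1L)) {
        trial <- resNorm(u + alpha * du, p)
        if (trial$ok && is.finite(trial$norm) &&
            trial$norm < 1e10 * max(trial$ref, rn)) {
          u <- u + alpha * du
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!accepted) return(list(ok = FALSE, u = u0, rel = rel))
    }
    # did not reach tolerance
    list(ok = FALSE, u = u0, rel = rel)
  }

  advance <- function(u, pFrom, pTo, depth) {
    st <- newtonStep(u, pTo)
    if (st$ok) {
      history[[length(history) + 1L]] <<- st$rel
      return(st$u)
    }
    if (depth >= settings$maxHalvings)
      stop(sprintf(paste0("Newton divergence at %.4g Pa after %d step",
                          " halvings; last relative residuals: %s"),
                   pTo, depth,
                   paste(signif(tail(st$rel, 3), 3), collapse = ", ")),
           call. = FALSE)
    pMid <- (pFrom + pTo) / 2
    u <- advance(u, pFrom, pMid, depth + 1L)
    advance(u, pMid, pTo, depth + 1L)
  }

  pTargets <- load$pressurePa * seq_len(settings$loadSteps) / settings$loadSteps
  pPrev <- 0
  for (p in pTargets) {
    u <- advance(u, pPrev, p, 0L)
    pPrev <- p
  }

  new("SolutionField",
      displacement = matrix(u, ncol = 2, byrow = TRUE),
      converged = TRUE,
      residualHistory = setNames(history,
                                 paste0("step", seq_along(history))),
      pressureMmHg = load$pressureMmHg, caseName = load$name,
      constraints = constraints)
}

# interleaved (x1,y1,x2,y2,...) vector from an n x 2 displacement matrix
.flattenU <- function(disp) as.numeric(t(disp))

#' Volumetric deformation statistics of a solution
#'
#' Per-quadrature-point `J = det F`; near-incompressibility requires
#' `|J - 1|` small at convergence.
#'
#' @param mesh a [LabeledMesh-class].
#' @param solution a [SolutionField-class].
#' @return list with `Jqp` (matrix, elements x quadrature points), `p99`
#'   (99th percentile of `|J - 1|`) and `max`.
#' @export
jacobianStats <- function(mesh, solution) {
  d <- fem_defgrad_cpp(mesh@nodes, mesh@elements, .flattenU(solution@displacement))
  dev <- abs(as.numeric(d$Jqp) - 1)
  list(Jqp = d$Jqp, p99 = as.numeric(quantile(dev, 0.99)), max = max(dev))
}

#' Reaction balance of a converged solution
#'
#' The luminal pressure on a closed boundary is self-equilibrated, so at
#' convergence the rigid-body constraints should carry (numerically) zero
#' net reaction. Returns the residual force at the constrained dofs
#' normalized by the total applied pressure force scale
#' `p * deformed lumen perimeter`.
#'
#' @param mesh a [LabeledMesh-class].
#' @param materials the [MaterialTable-class] used for the solve.
#' @param solution a [SolutionField-class].
#' @return list with `netReaction` (2-vector, Pa*mm), `scale` and
#'   `relativeImbalance`.
#' @export
reactionBalance <- function(mesh, materials, solution) {
  matpar <- .materialParams(mesh, materials)
  u <- .flattenU(solution@displacement)
  a <- fem_assemble_cpp(mesh@nodes, mesh@elements, matpar, u,
                        solution@pressureMmHg * MMHG_TO_PA,
                        mesh@boundary$LUMEN, FALSE)
  r <- a$fint - a$fext
  fixed <- 2L * (solution@constraints$node - 1L) + solution@constraints$dof
  rx <- sum(r[fixed[solution@constraints$dof == 1L]])
  ry <- sum(r[fixed[solution@constraints$dof == 2L]])
  edges <- mesh@boundary$LUMEN
  y <- mesh@nodes + solution@displacement
  seg <- sqrt(rowSums((y[edges[, 2], , drop = FALSE] -
                         y[edges[, 1], , drop = FALSE])^2))
  scale <- max(solution@pressureMmHg * MMHG_TO_PA * sum(seg), 1e-12)
  list(netReaction = c(rx, ry), scale = scale,
       relativeImbalance = sqrt(rx^2 + ry^2) / scale)
}
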