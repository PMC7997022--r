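## Fitted, flattened configurations used by both the covariance build and
## the projection: frames at time >= cut, iteratively superposed onto their
## average structure over the selection (removing net translation/rotation),
## selected atoms flattened to length-3n rows, optionally sqrt(mass)-weighted.
.fittedConfigs <- function(traj, selection, cut = 0, massWeighted = FALSE,
                           fit = TRUE) {
  keep <- which(.frameTimes(traj) >= cut)
  if (length(keep) < 2)
    stop("equilibration cut leaves fewer than 2 frames")
  if (fit) {
    ref <- .averageStructure(traj, selection, frames = keep)
    confs <- lapply(keep, function(i)
      kabschSuperpose(frameCoords(traj, i), ref, selection)$fitted)
  } else {
    confs <- lapply(keep, function(i) frameCoords(traj, i))
  }
  w <- if (massWeighted) sqrt(atomData(traj)$mass[selection])
       else rep(1, length(selection))
  X <- t(vapply(confs, function(cf)
    as.numeric(t(cf[selection, , drop = FALSE] * w)),
    numeric(3 * length(selection))))
  X
}

#' Positional covariance matrix of a trajectory
#'
#' Each retained frame is least-squares superposed onto the average
#' structure (removing rigid-body translation and rotation), then
#' C = <(x - <x>)(x - <x>)'> over frames, a 3N x 3N matrix in nm^2
#' (amu nm^2 when mass-weighted).
#'
#' @param traj a \linkS4class{Trajectory}
#' @param selection atom indices (default backbone)
#' @param massWeighted weight coordinates by sqrt(mass)
#' @param cut equilibration cut, ns
#' @param fit superpose before accumulating (disable only for analytic
#'   single-atom checks)
#' @return symmetric 3N x 3N covariance matrix
#' @export
buildCovariance <- function(traj, selection = selectAtoms(traj, "backbone"),
                            massWeighted = FALSE, cut = 0, fit = TRUE) {
  if (3 * length(selection) > 3000)
    stop("selection gives 3N > 3000; pass a smaller selection ",
         "(or subset atoms explicitly) to keep the dense matrix desk-scale")
  X <- .fittedConfigs(traj, selection, cut, massWeighted, fit)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / nrow(Xc)
}

#' Leading principal components of a covariance matrix
#'
#' @param C symmetric covariance matrix
#' @param k number of components to keep
#' @return an \linkS4class{EDResult}: descending eigenvalues,
#'   contribution_i = 100 lambda_i / trace(C), eigenvectors for the top k
#' @export
principalComponents <- function(C, k = 2) {
  if (!is.matrix(C) || nrow(C) != ncol(C) ||
      max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300))
    stop("covariance matrix must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  tr <- sum(diag(C))
  k <- min(k, length(e$values))
  new("EDResult", trace = tr, eigenvalues = e$values,
      contributions = if (tr > 0) 100 * e$values / tr
                      else rep(0, length(e$values)),
      eigenvectors = e$vectors[, seq_len(k), drop = FALSE],
      projections = matrix(numeric(0), 0, 0))
}

#' Project a trajectory onto its leading eigenvectors
#'
#' Per-frame dot products of the mean-centred, superposed configuration with
#' the top eigenvectors (PC1/PC2 by default).  The projection is built from
#' the same fitted configurations as \code{\link{buildCovariance}}, so the
#' population variance along PC_i equals lambda_i.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param ed an \linkS4class{EDResult} from \code{\link{principalComponents}}
#'   computed on the same selection
#' @param selection atom indices used for the covariance
#' @param massWeighted,cut,fit as in \code{\link{buildCovariance}}
#' @return the EDResult with \code{projections} filled (frames x k, nm)
#' @export
projectTrajectory <- function(traj, ed,
                              selection = selectAtoms(traj, "backbone"),
                              massWeighted = FALSE, cut = 0, fit = TRUE) {
  X <- .fittedConfigs(traj, selection, cut, massWeighted, fit)
  if (ncol(X) != nrow(ed@eigenvectors))
    stop("eigenvector dimension ", nrow(ed@eigenvectors),
         " does not match selection dimension ", ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  ed@projections <- Xc %*% ed@eigenvectors
  ed
}
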