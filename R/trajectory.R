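#' Resolve an atom selection
#'
#' @param structure a \linkS4class{Structure} (or \linkS4class{Trajectory})
#' @param which "backbone" (atom names N, CA, C, O), "all", or "custom"
#' @param names atom names used when \code{which = "custom"}
#' @return integer vector of atom indices (non-empty)
#' @export
selectAtoms <- function(structure, which = c("backbone", "all", "custom"),
                        names = NULL) {
  which <- match.arg(which)
  a <- atomData(structure)
  idx <- switch(which,
    all = seq_len(nrow(a)),
    backbone = which(a$name %in% c("N", "CA", "C", "O")),
    custom = which(a$name %in% names))
  if (!length(idx)) stop("empty atom selection (", which, ")")
  idx
}

.checkSelectionGeometry <- function(xyz) {
  if (nrow(xyz) < 3)
    stop("superposition needs at least 3 selected atoms")
  s <- svd(scale(xyz, center = TRUE, scale = FALSE))$d
  if (s[2] < 1e-9 * max(s[1], 1e-300))
    stop("selected atoms are collinear; superposition is degenerate")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of \code{mobile} onto \code{reference} over the
#' selected atoms.  The returned rotation is proper (determinant +1; a
#' reflection is never chosen) and \code{rmsd} is the global minimum of the
#' selection RMSD over all rigid motions.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm)
#' @param selection integer atom indices to fit on (default all)
#' @return list(rotation 3x3, translation length-3, rmsd nm, fitted n x 3).
#'   \code{fitted} is the whole mobile frame moved by the fitted transform:
#'   \code{fitted = (mobile - cmMobile) \%*\% rotation + cmReference}.
#' @export
kabschSuperpose <- function(mobile, reference,
                            selection = seq_len(nrow(mobile))) {
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection size differs between frames")
  .checkSelectionGeometry(Q)
  cmP <- colMeans(P); cmQ <- colMeans(Q)
  Pc <- sweep(P, 2, cmP); Qc <- sweep(Q, 2, cmQ)
  H <- crossprod(Pc, Qc)                 # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)            # mobile %*% R aligns onto reference
  fittedSel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fittedSel - Qc)^2)))
  fitted <- sweep(sweep(mobile, 2, cmP) %*% R, 2, cmQ, "+")
  list(rotation = R, translation = cmQ - cmP %*% R, rmsd = rmsd,
       fitted = fitted)
}

.frameTimes <- function(traj) (seq_len(nFrames(traj)) - 1) * frameTime(traj)

#' Per-frame RMSD after optimal superposition
#'
#' @param traj a \linkS4class{Trajectory}
#' @param selection atom indices (default backbone)
#' @param reference n x 3 reference frame; default the first frame.  Pass
#'   \code{reference = "average"} to fit against the time-average structure.
#' @return numeric vector, one RMSD (nm) per frame
#' @export
rmsdSeries <- function(traj, selection = selectAtoms(traj, "backbone"),
                       reference = NULL) {
  if (is.character(reference) && identical(reference, "average"))
    reference <- .averageStructure(traj, selection)
  if (is.null(reference)) reference <- frameCoords(traj, 1)
  vapply(seq_len(nFrames(traj)), function(i)
    kabschSuperpose(frameCoords(traj, i), reference, selection)$rmsd,
    numeric(1))
}

## iteratively superpose all frames onto their running average structure;
## returns the converged average (n x 3) over all atoms
.averageStructure <- function(traj, selection, frames = seq_len(nFrames(traj)),
                              iterations = 3) {
  ref <- frameCoords(traj, frames[1])
  for (it in seq_len(iterations)) {
    acc <- 0
    for (i in frames)
      acc <- acc + kabschSuperpose(frameCoords(traj, i), ref,
                                   selection)$fitted
    ref <- acc / length(frames)
  }
  ref
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames at time >= \code{cut} are superposed onto their time-average
#' structure (gmx rmsf convention; disable with \code{fit = FALSE} for
#' analytic checks), atom-level RMSF_i = sqrt(<|r_i - <r_i>|^2>) is computed
#' over those frames, and atoms are averaged within each residue.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param selection atom indices (default backbone)
#' @param cut equilibration cut, ns (frames before it are discarded)
#' @param fit superpose onto the average structure first
#' @return named numeric vector, RMSF (nm) per residue index
#' @export
rmsfPerResidue <- function(traj, selection = selectAtoms(traj, "backbone"),
                           cut = 0, fit = TRUE) {
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
  arr <- simplify2array(confs)                 # atoms x 3 x frames
  mu <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mu)^2
  msf <- apply(dev2, 1, mean) * 3              # mean over dims+frames, x3 dims
  atomRMSF <- sqrt(msf)
  resid <- atomData(traj)$resid
  out <- tapply(atomRMSF[selection], resid[selection], mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Per-frame radius of gyration
#'
#' Rg = sqrt(sum m_i |r_i - r_cm|^2 / sum m_i); unit masses unless
#' \code{massWeighted}.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param selection atom indices (default backbone)
#' @param massWeighted weight by atomic masses
#' @return numeric vector, Rg (nm) per frame
#' @export
rgSeries <- function(traj, selection = selectAtoms(traj, "backbone"),
                     massWeighted = FALSE) {
  m <- if (massWeighted) atomData(traj)$mass[selection]
       else rep(1, length(selection))
  if (sum(m) <= 0) stop("total mass of the selection is zero")
  vapply(seq_len(nFrames(traj)), function(i) {
    xyz <- frameCoords(traj, i)[selection, , drop = FALSE]
    cm <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
  }, numeric(1))
}

#' Equilibration-aware series summary
#'
#' Mean and sample standard deviation (n - 1) of a per-frame series over the
#' frames at time >= \code{cut}.
#'
#' @param series per-frame values
#' @param frameTime ns between frames
#' @param cut equilibration cut, ns; default half the trajectory
#' @return list(mean, sd, n_frames_used, equilibration_cut)
#' @export
summarizeSeries <- function(series, frameTime, cut = NULL) {
  times <- (seq_along(series) - 1) * frameTime
  if (is.null(cut)) cut <- max(times) / 2
  keep <- series[times >= cut]
  if (length(keep) < 2)
    stop("equilibration cut leaves fewer than 2 frames")
  list(mean = mean(keep), sd = stats::sd(keep),
       n_frames_used = length(keep), equilibration_cut = cut)
}
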