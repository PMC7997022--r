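#' Configuration for the synthetic trajectory generator
#'
#' Modes emulate the qualitative features MD observables are sensitive to:
#' \code{static} (no motion), \code{harmonic} (independent Gaussian
#' fluctuation with a planted per-residue amplitude), \code{hinge} (a
#' residue subset rotating about an axis through a pivot,
#' theta_t = A sin(2 pi t / T), plus isotropic noise) and \code{two_state}
#' (switching between a compact and an extended conformation with geometric
#' dwell times, emulating flexed/extended domain transitions).
#'
#' @param mode one of static, harmonic, hinge, two_state
#' @param nParticles chain length (one CA-like particle per residue)
#' @param nFrames number of frames
#' @param amplitudes per-residue Gaussian sd, nm (recycled; harmonic mode)
#' @param hingeResidues residue indices forming the mobile domain; default
#'   the final third of the chain
#' @param hingeAngleAmplitude A, radians
#' @param hingePeriod T, frames
#' @param extension displacement of the mobile domain in the extended state,
#'   nm (two_state mode)
#' @param dwellFrames mean dwell time per state, frames (geometric)
#' @param noiseSd isotropic positional noise sd, nm
#' @param frameTime ns per frame
#' @param seed RNG seed
#' @return list of class \code{TrajSimConfig}
#' @export
trajSimConfig <- function(mode = c("harmonic", "static", "hinge",
                                   "two_state"),
                          nParticles = 50L, nFrames = 500L,
                          amplitudes = 0.05, hingeResidues = NULL,
                          hingeAngleAmplitude = 0.3, hingePeriod = 100L,
                          extension = 1.0, dwellFrames = 50L,
                          noiseSd = 0.02, frameTime = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nParticles >= 3, nFrames >= 1, all(amplitudes >= 0),
            dwellFrames > 0, noiseSd >= 0, frameTime > 0)
  if (is.null(hingeResidues))
    hingeResidues <- seq(floor(2 * nParticles / 3) + 1, nParticles)
  structure(list(mode = mode, nParticles = as.integer(nParticles),
                 nFrames = as.integer(nFrames),
                 amplitudes = rep_len(amplitudes, nParticles),
                 hingeResidues = as.integer(hingeResidues),
                 hingeAngleAmplitude = hingeAngleAmplitude,
                 hingePeriod = as.integer(hingePeriod),
                 extension = extension,
                 dwellFrames = as.integer(dwellFrames),
                 noiseSd = noiseSd, frameTime = frameTime,
                 seed = as.integer(seed)),
            class = "TrajSimConfig")
}

## random compact CA-only chain: fixed 0.38 nm bonds, random directions
.randomChain <- function(n, bond = 0.38) {
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(0, apply(dirs * bond, 2, cumsum))
}

.rotationMatrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic trajectory
#'
#' Builds a random compact reference chain and animates it per the
#' configured mode; bit-reproducible per seed.  The returned \code{info}
#' list carries the planted ground truth (amplitudes, hinge geometry, state
#' sequence) for parameter-recovery tests.
#'
#' @param cfg a \code{\link{trajSimConfig}}
#' @return list(structure, trajectory, info)
#' @export
generateTrajectory <- function(cfg = trajSimConfig()) {
  if (!cfg$mode %in% c("static", "harmonic", "hinge", "two_state"))
    stop("invalid mode: ", cfg$mode)
  set.seed(cfg$seed)
  n <- cfg$nParticles
  ref <- .randomChain(n)
  atoms <- data.frame(name = "CA", resid = seq_len(n), mass = 12.011,
                      radius = 0.17, stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(cfg$nFrames, n, 3))
  info <- list(mode = cfg$mode)
  noise <- function() matrix(stats::rnorm(3 * n, sd = cfg$noiseSd), n, 3)
  if (cfg$mode == "static") {
    for (t in seq_len(cfg$nFrames)) coords[t, , ] <- ref
  } else if (cfg$mode == "harmonic") {
    for (t in seq_len(cfg$nFrames))
      coords[t, , ] <- ref + matrix(stats::rnorm(3 * n, sd = cfg$amplitudes),
                                    n, 3)
    info$amplitudes <- cfg$amplitudes
  } else if (cfg$mode == "hinge") {
    hs <- cfg$hingeResidues
    pivot <- ref[max(1, min(hs) - 1), ]
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    for (t in seq_len(cfg$nFrames)) {
      theta <- cfg$hingeAngleAmplitude * sin(2 * pi * (t - 1) / cfg$hingePeriod)
      fr <- ref
      fr[hs, ] <- sweep(sweep(ref[hs, , drop = FALSE], 2, pivot) %*%
                          t(.rotationMatrix(axis, theta)), 2, pivot, "+")
      coords[t, , ] <- fr + noise()
    }
    info$hingeResidues <- hs; info$pivot <- pivot; info$axis <- axis
    info$angleAmplitude <- cfg$hingeAngleAmplitude
    info$noiseSd <- cfg$noiseSd
  } else {                               # two_state
    hs <- cfg$hingeResidues
    pivot <- ref[max(1, min(hs) - 1), ]
    dir <- colMeans(ref[hs, , drop = FALSE]) - pivot
    dir <- dir / sqrt(sum(dir^2))
    ext <- ref
    ext[hs, ] <- sweep(ref[hs, , drop = FALSE], 2, cfg$extension * dir, "+")
    states <- integer(cfg$nFrames)
    s <- 1L
    for (t in seq_len(cfg$nFrames)) {
      states[t] <- s
      if (stats::runif(1) < 1 / cfg$dwellFrames) s <- 3L - s
    }
    for (t in seq_len(cfg$nFrames))
      coords[t, , ] <- (if (states[t] == 1L) ref else ext) + noise()
    info$states <- states; info$extension <- cfg$extension
  }
  str <- Structure(atoms, matrix(coords[1, , ], ncol = 3))
  list(structure = str,
       trajectory = Trajectory(str, coords, frameTime = cfg$frameTime),
       info = info)
}
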