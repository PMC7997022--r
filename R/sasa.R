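#' Deterministic quasi-uniform sphere points (golden spiral)
#'
#' @param n number of points (>= 1)
#' @return n x 3 matrix of unit vectors
#' @export
spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points are placed quasi-uniformly (golden spiral, so
#' the result is bit-reproducible) on a sphere of radius r_i + probe; a
#' point is buried if it lies within r_j + probe of any other atom j.
#' area_i = 4 pi (r_i + probe)^2 x exposed fraction.
#'
#' @param structure a \linkS4class{Structure} (radii in nm, all > 0)
#' @param probe probe radius, nm (water: 0.14)
#' @param nPoints test points per atom (>= 32)
#' @return list(total nm^2, perParticle numeric vector nm^2)
#' @export
sasaStructure <- function(structure, probe = 0.14, nPoints = 960L) {
  if (nPoints < 32) stop("nPoints below the accuracy floor of 32")
  a <- atomData(structure)
  if (any(a$radius <= 0)) stop("all radii must be positive")
  xyz <- coords(structure)
  n <- nrow(xyz)
  R <- a$radius + probe
  pts <- spherePoints(nPoints)
  per <- numeric(n)
  for (i in seq_len(n)) {
    ## neighbours close enough to bury any of atom i's test points
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) { per[i] <- 4 * pi * R[i]^2; next }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= R[j]^2
    }
    per[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  list(total = sum(per), perParticle = per)
}

#' SASA per frame of a trajectory
#'
#' @param traj a \linkS4class{Trajectory}
#' @param probe probe radius, nm
#' @param nPoints test points per atom
#' @return numeric vector of total SASA (nm^2) per frame
#' @export
sasaSeries <- function(traj, probe = 0.14, nPoints = 960L) {
  a <- atomData(traj)
  vapply(seq_len(nFrames(traj)), function(i)
    sasaStructure(Structure(a, frameCoords(traj, i)), probe, nPoints)$total,
    numeric(1))
}
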