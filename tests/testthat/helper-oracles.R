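## Independent slow oracles used to cross-check the implementation.

## Brute-force rigid-body RMSD: coarse grid over Euler angles, refined with
## Nelder-Mead.  Independent of the Kabsch code path.
oracleRigidRMSD <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  f <- function(ang) {
    R <- rotZ(ang[1]) %*% rotY(ang[2]) %*% rotZ(ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  grid <- seq(0, 2 * pi, by = pi / 6)
  best <- c(0, 0, 0); bestVal <- f(best)
  for (a in grid) for (b in seq(0, pi, by = pi / 6)) for (c in grid) {
    v <- f(c(a, b, c))
    if (v < bestVal) { bestVal <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

## Literal two-pass covariance of raw (unfitted) flattened coordinates.
oracleCovariance <- function(coordsArray) {
  nf <- dim(coordsArray)[1]
  X <- t(vapply(seq_len(nf), function(i)
    as.numeric(t(matrix(coordsArray[i, , ], ncol = 3))),
    numeric(dim(coordsArray)[2] * 3)))
  mu <- colMeans(X)
  C <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(nf)) {
    d <- X[i, ] - mu
    C <- C + outer(d, d)
  }
  C / nf
}

## Literal per-variant recount of co-segregation tallies.
oracleSegregation <- function(calls, affected, unaffected) {
  t(vapply(colnames(calls), function(vid) {
    col <- calls[, vid]
    c(affected_carriers = sum(col[affected] == "present"),
      affected_noncarriers = sum(col[affected] == "absent"),
      unaffected_carriers = sum(col[unaffected] == "present"))
  }, numeric(3)))
}

## Tiny rigid helpers shared across test files.
rotZ90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

randomFrame <- function(n, sd = 1) matrix(stats::rnorm(3 * n, sd = sd), n, 3)

caStructure <- function(xyz, radius = 0.17, mass = 12.011) {
  Structure(data.frame(name = "CA", resid = seq_len(nrow(xyz)),
                       mass = mass, radius = radius), xyz)
}

caTrajectory <- function(frames, frameTime = 0.1) {
  n <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), n, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  Trajectory(caStructure(frames[[1]]), coords, frameTime)
}
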