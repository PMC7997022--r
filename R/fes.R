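#' Free-energy surface by Boltzmann inversion
#'
#' Bins the two order-parameter series (conventionally Rg on x and RMSD on
#' y) into a 2-D occupancy histogram P and inverts it:
#' dG = -kB T log(P / Pmax), so the most populated bin sits at dG = 0 and
#' every visited bin is >= 0.  Unvisited bins are flagged NA, never zero.
#' kB = 0.0083144621 kJ mol^-1 K^-1.
#'
#' @param x,y equal-length order-parameter series (nm)
#' @param temperature simulation temperature, K
#' @param bins number of bins per axis; edges span the data range with 1e-9
#'   padding
#' @return a \linkS4class{FESGrid}
#' @export
freeEnergySurface <- function(x, y, temperature = 300, bins = 32L) {
  if (length(x) != length(y))
    stop("order-parameter series have different lengths")
  if (temperature <= 0) stop("temperature must be positive")
  pad <- 1e-9
  xE <- seq(min(x) - pad, max(x) + pad, length.out = bins + 1)
  yE <- seq(min(y) - pad, max(y) + pad, length.out = bins + 1)
  xi <- findInterval(x, xE, rightmost.closed = TRUE)
  yi <- findInterval(y, yE, rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(xi))
    counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  P <- counts / sum(counts)
  dG <- matrix(NA_real_, bins, bins)
  vis <- counts > 0
  dG[vis] <- -.kB * temperature * log(P[vis] / max(P))
  new("FESGrid", xEdges = xE, yEdges = yE, dG = dG,
      temperature = temperature)
}

#' Count metastable minima on a free-energy surface
#'
#' A visited bin is a candidate when it is a strict minimum over its visited
#' 8-neighbourhood (unvisited neighbours are ignored).  A candidate at depth
#' v counts as metastable when no deeper bin (dG < v) can be reached through
#' bins below v + depthThreshold: the lowest escape barrier to any deeper
#' basin is at least depthThreshold.  The global minimum always counts.
#'
#' @param grid a \linkS4class{FESGrid}
#' @param depthThreshold minimum basin depth, kJ/mol; default 1 kB T at the
#'   grid temperature
#' @return integer number of metastable states
#' @export
countMinima <- function(grid, depthThreshold = NULL) {
  if (is.null(depthThreshold))
    depthThreshold <- .kB * grid@temperature
  g <- grid@dG
  nx <- nrow(g); ny <- ncol(g)
  isMin <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (is.na(g[i, j])) next
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ii <- i + nb$di; jj <- j + nb$dj
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    vals <- g[cbind(ii[ok], jj[ok])]
    vals <- vals[!is.na(vals)]
    isMin[i, j] <- length(vals) == 0 || all(vals > g[i, j])
  }
  mins <- which(isMin, arr.ind = TRUE)
  if (!nrow(mins)) return(0L)
  ## unvisited bins are unsampled, hence high free energy, not impassable:
  ## the flood treats them as sitting at the visited maximum
  e <- g
  e[is.na(e)] <- max(g, na.rm = TRUE)
  count <- 0L
  for (r in seq_len(nrow(mins))) {
    i0 <- mins[r, 1]; j0 <- mins[r, 2]
    v <- g[i0, j0]
    lid <- v + depthThreshold
    ## flood the sub-level set {E < lid} from the candidate; if it reaches
    ## a strictly deeper bin, the escape barrier is below the threshold
    seen <- matrix(FALSE, nx, ny)
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    escaped <- FALSE
    while (length(queue) && !escaped) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        if (seen[ii, jj]) next
        if (e[ii, jj] >= lid) next
        if (e[ii, jj] < v) { escaped <- TRUE; break }
        seen[ii, jj] <- TRUE
        queue[[length(queue) + 1]] <- c(ii, jj)
      }
    }
    if (!escaped) count <- count + 1L
  }
  count
}
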