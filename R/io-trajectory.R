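## Element masses (amu) and SASA radii (nm); radii per the shipped default
## table, overridable through the radii argument of readTrajectory.
.elementMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)
.defaultRadii  <- c(N = 0.155, C = 0.17, O = 0.152, S = 0.18,
                    H = 0.12, P = 0.18)

.elementOf <- function(name) {
  ## first alphabetic character of the atom name (PDB convention for
  ## standard protein atoms: N, CA, C, O, CB, SG, ...)
  el <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
  toupper(el)
}

#' Default van der Waals radii used for SASA (nm)
#' @return named numeric vector, one entry per element symbol
#' @export
defaultRadii <- function() .defaultRadii

#' Read a coordinate trajectory
#'
#' Dialects: multi-model PDB (MODEL/ENDMDL records, Angstrom, converted to nm
#' at the boundary) or the package's plain-text XYZ dialect (nm): line 1 the
#' particle count, line 2 a comment \code{t=<ns>}, then one
#' \code{name resindex mass radius x y z} line per particle, frames
#' concatenated.  The topology is taken from the first model; models with
#' differing atom counts are an error.
#'
#' @param path file to read
#' @param dialect "pdb_multimodel" or "xyz_text"
#' @param radii named vector of per-element radii (nm) for PDB input
#' @return list with elements \code{structure} (\linkS4class{Structure}) and
#'   \code{trajectory} (\linkS4class{Trajectory})
#' @export
readTrajectory <- function(path, dialect = c("pdb_multimodel", "xyz_text"),
                           radii = defaultRadii()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "pdb_multimodel") .readTrajPDB(path, radii)
  else .readTrajXYZ(path)
}

.readTrajPDB <- function(path, radii) {
  ## congruence check before handing to bio3d: equal ATOM counts per model
  lines <- readLines(path)
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1) {
    modelEnds <- grep("^ENDMDL", lines)
    if (length(modelEnds) != length(modelStarts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM|HETATM)", lines[s:e])), modelStarts, modelEnds)
    if (length(unique(counts)) != 1)
      stop("models with differing atom counts in ", path, ": ",
           paste(counts, collapse = ", "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  el <- atom$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- .elementOf(atom$elety)
  el[is.na(el) | el == ""] <- .elementOf(atom$elety[is.na(el) | el == ""])
  el <- toupper(trimws(el))
  mass <- unname(.elementMasses[el])
  mass[is.na(mass)] <- 12.011
  rad <- unname(radii[el])
  rad[is.na(rad)] <- 0.17
  atoms <- data.frame(name = atom$elety, resid = as.integer(atom$resno),
                      mass = mass, radius = rad, stringsAsFactors = FALSE)
  xyzA <- pdb$xyz                       # frames x 3N, Angstrom
  if (is.null(dim(xyzA))) xyzA <- matrix(xyzA, nrow = 1)
  nf <- nrow(xyzA); na <- nrow(atoms)
  coords <- array(NA_real_, c(nf, na, 3))
  for (i in seq_len(nf))
    coords[i, , ] <- matrix(xyzA[i, ], ncol = 3, byrow = TRUE) / 10
  str <- Structure(atoms, matrix(coords[1, , ], ncol = 3))
  list(structure = str,
       trajectory = Trajectory(str, coords, frameTime = 0.1))
}

.readTrajXYZ <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); atoms <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 1)
      stop("bad particle count at line ", i, " of ", path)
    tm <- suppressWarnings(
      as.numeric(sub("^.*t=\\s*([-0-9.eE+]+).*$", "\\1", lines[i + 1])))
    if (is.na(tm)) stop("missing t=<ns> comment at line ", i + 1)
    body <- lines[(i + 2):(i + 1 + n)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) != 7))
      stop("malformed particle line near line ", i + 1 + which(lengths(fields) != 7)[1])
    m <- do.call(rbind, fields)
    frameAtoms <- data.frame(name = m[, 1], resid = as.integer(m[, 2]),
                             mass = as.numeric(m[, 3]),
                             radius = as.numeric(m[, 4]),
                             stringsAsFactors = FALSE)
    if (is.null(atoms)) atoms <- frameAtoms
    else if (nrow(frameAtoms) != nrow(atoms))
      stop("frame at line ", i, " has a differing atom count")
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(m[, 5:7]), ncol = 3)
    times <- c(times, tm)
    i <- i + 2 + n
  }
  nf <- length(frames); na <- nrow(atoms)
  coords <- array(NA_real_, c(nf, na, 3))
  for (k in seq_len(nf)) coords[k, , ] <- frames[[k]]
  ft <- if (nf > 1) times[2] - times[1] else 0.1
  if (ft <= 0) ft <- 0.1
  str <- Structure(atoms, frames[[1]])
  list(structure = str, trajectory = Trajectory(str, coords, frameTime = ft))
}

#' Write a trajectory in the XYZ text dialect
#'
#' Fixed 6-decimal formatting so that write -> read -> write is
#' byte-identical.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param path output file
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  a <- atomData(traj)
  nf <- nFrames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nf)) {
    xyz <- frameCoords(traj, i)
    writeLines(c(sprintf("%d", nrow(a)),
                 sprintf("t=%.6f", (i - 1) * frameTime(traj)),
                 sprintf("%s %d %.6f %.6f %.6f %.6f %.6f",
                         a$name, a$resid, a$mass, a$radius,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}
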