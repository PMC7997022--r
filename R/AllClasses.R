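#' @import methods
NULL

## Column layout shared by the TSV dialect, the VCF INFO mapping and the
## in-memory table.  Score columns are NA when a tool did not score the
## variant; NA is "absent", never zero.
.variantColumns <- c(
  "gene", "cdna", "protein", "chrom", "pos", "ref", "alt",
  "consequence", "zygosity",
  "sift", "polyphen2", "mutationtaster", "gerp", "cadd", "condel",
  "ac", "an", "source"
)

.consequenceLevels <- c("synonymous", "missense", "other")
.zygosityLevels    <- c("het", "hom")
.gerpRange         <- c(-12.3, 6.17)

#' Annotated variant table
#'
#' One row per exome variant, with gene/HGVS labels, genomic coordinates,
#' consequence class, zygosity, per-tool in-silico scores (SIFT, PolyPhen-2,
#' MutationTaster, GERP++, CADD phred, Condel) and an optional population
#' allele-frequency record (allele count \code{ac} over allele number
#' \code{an}).  Missing scores and missing frequency records are \code{NA}:
#' a variant with no frequency record is "novel".
#'
#' @slot variants data.frame with the fixed column layout (see
#'   \code{variantColumns()}).
#' @export
setClass("VariantTable", representation(variants = "data.frame"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  msg <- character()
  if (!identical(colnames(v), .variantColumns))
    msg <- c(msg, "variant table must have the canonical column layout")
  if (nrow(v) > 0) {
    if (any(is.na(v$pos)) || any(v$pos < 1))
      msg <- c(msg, "pos must be a 1-based positive integer")
    if (any(v$ref == v$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (!all(v$consequence %in% .consequenceLevels))
      msg <- c(msg, "consequence must be synonymous/missense/other")
    if (!all(v$zygosity %in% .zygosityLevels))
      msg <- c(msg, "zygosity must be het/hom")
    g <- v$gerp[!is.na(v$gerp)]
    if (length(g) && (any(g < .gerpRange[1]) || any(g > .gerpRange[2])))
      msg <- c(msg, sprintf("GERP score outside [%g, %g]",
                            .gerpRange[1], .gerpRange[2]))
    ok <- !is.na(v$ac) & !is.na(v$an)
    if (any(ok & (v$ac > v$an | v$an <= 0 | v$ac < 0)))
      msg <- c(msg, "frequency record needs 0 <= ac <= an, an > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Pedigree with affection status
#'
#' @slot members data.frame with columns id, sex
#'   (\code{male/female/unknown}), affection
#'   (\code{affected/unaffected/unknown}) and logical \code{sequenced}.
#' @export
setClass("Pedigree", representation(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  msg <- character()
  need <- c("id", "sex", "affection", "sequenced")
  if (!all(need %in% colnames(m)))
    msg <- c(msg, "members needs columns id, sex, affection, sequenced")
  else {
    if (anyDuplicated(m$id))
      msg <- c(msg, "individual ids must be unique")
    if (!all(m$affection %in% c("affected", "unaffected", "unknown")))
      msg <- c(msg, "affection must be affected/unaffected/unknown")
  }
  if (length(msg)) msg else TRUE
})

#' Carrier-status matrix
#'
#' Individuals (rows) by variants (columns); entries are \code{"present"},
#' \code{"absent"} or \code{"untyped"}.
#'
#' @slot calls character matrix with dimnames (individual id, variant id).
#' @export
setClass("GenotypeMatrix", representation(calls = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@calls
  msg <- character()
  if (!is.character(g))
    msg <- c(msg, "calls must be a character matrix")
  else if (!all(g %in% c("present", "absent", "untyped")))
    msg <- c(msg, "calls must be present/absent/untyped")
  if ((nrow(g) > 0 && is.null(rownames(g))) ||
      (ncol(g) > 0 && is.null(colnames(g))))
    msg <- c(msg, "calls needs individual and variant dimnames")
  if (length(msg)) msg else TRUE
})

#' Molecular structure (topology + one set of coordinates)
#'
#' Coordinates are in nanometres throughout the package; PDB input is
#' converted from Angstrom at the read boundary.
#'
#' @slot atoms data.frame with columns name, resid (1-based residue index),
#'   mass (amu), radius (nm, used for SASA).
#' @slot xyz numeric n x 3 matrix, nm.
#' @export
setClass("Structure", representation(atoms = "data.frame", xyz = "matrix"))

setValidity("Structure", function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("name", "resid", "mass", "radius")
  if (!all(need %in% colnames(a)))
    msg <- c(msg, "atoms needs columns name, resid, mass, radius")
  if (nrow(a) < 1) msg <- c(msg, "structure needs at least one particle")
  if (!is.numeric(object@xyz) || ncol(object@xyz) != 3 ||
      nrow(object@xyz) != nrow(a))
    msg <- c(msg, "xyz must be an n x 3 matrix congruent with atoms")
  if (nrow(a) > 1 && any(diff(a$resid) < 0))
    msg <- c(msg, "residue indices must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Coordinate trajectory
#'
#' Ordered frames congruent with one \linkS4class{Structure} topology.
#'
#' @slot structure the topology (first frame's coordinates kept as reference).
#' @slot coords numeric array, frames x atoms x 3, nm.
#' @slot frameTime time step between frames, ns.
#' @export
setClass("Trajectory",
         representation(structure = "Structure", coords = "array",
                        frameTime = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "coords must be a frames x atoms x 3 array")
  else if (d[2] != nrow(object@structure@atoms))
    msg <- c(msg, "frame atom count differs from topology")
  if (length(object@frameTime) != 1 || object@frameTime <= 0)
    msg <- c(msg, "frameTime must be a single positive number (ns)")
  if (length(msg)) msg else TRUE
})

#' Essential-dynamics result
#'
#' @slot trace total positional variance (nm^2), the trace of the covariance
#'   matrix.
#' @slot eigenvalues descending eigenvalues, nm^2.
#' @slot contributions percent of the trace captured by each component.
#' @slot eigenvectors matrix, one column per component (3N rows).
#' @slot projections per-frame projections on the leading components (nm),
#'   empty until \code{projectTrajectory} fills it.
#' @export
setClass("EDResult",
         representation(trace = "numeric", eigenvalues = "numeric",
                        contributions = "numeric", eigenvectors = "matrix",
                        projections = "matrix"))

#' Free-energy surface over two order parameters
#'
#' Boltzmann inversion of the 2-D occupancy histogram:
#' dG = -kB T log(P / Pmax), so the most populated bin sits at 0 and
#' unvisited bins are NA (flagged, not zero).
#'
#' @slot xEdges,yEdges bin edges for the two order parameters (nm).
#' @slot dG matrix of free energies, kJ/mol; NA marks unvisited bins.
#' @slot temperature simulation temperature, K.
#' @export
setClass("FESGrid",
         representation(xEdges = "numeric", yEdges = "numeric",
                        dG = "matrix", temperature = "numeric"))

setValidity("FESGrid", function(object) {
  msg <- character()
  if (nrow(object@dG) != length(object@xEdges) - 1 ||
      ncol(object@dG) != length(object@yEdges) - 1)
    msg <- c(msg, "dG dimensions must match bin edges")
  vis <- object@dG[!is.na(object@dG)]
  if (length(vis)) {
    if (min(vis) < -1e-9 || abs(min(vis)) > 1e-9)
      msg <- c(msg, "visited bins must be >= 0 with minimum 0")
  }
  if (object@temperature <= 0)
    msg <- c(msg, "temperature must be positive")
  if (length(msg)) msg else TRUE
})

## Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.0083144621
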