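#' Canonical variant-table column names
#' @return character vector of the fixed TSV/in-memory column layout.
#' @export
variantColumns <- function() .variantColumns

#' Construct a VariantTable from a data.frame
#'
#' @param df data.frame carrying at least gene, cdna, protein, chrom, pos,
#'   ref, alt, consequence, zygosity; score and frequency columns default to
#'   NA (absent).
#' @return a \linkS4class{VariantTable}
#' @export
VariantTable <- function(df) {
  for (col in .variantColumns)
    if (!col %in% colnames(df)) df[[col]] <- NA
  df <- df[, .variantColumns]
  df$pos <- as.integer(df$pos)
  for (col in c("sift", "polyphen2", "mutationtaster", "gerp", "cadd",
                "condel"))
    df[[col]] <- as.numeric(df[[col]])
  df$ac <- as.integer(df$ac)
  df$an <- as.integer(df$an)
  for (col in setdiff(.variantColumns,
                      c("pos", "sift", "polyphen2", "mutationtaster", "gerp",
                        "cadd", "condel", "ac", "an")))
    df[[col]] <- as.character(df[[col]])
  rownames(df) <- NULL
  new("VariantTable", variants = df)
}

#' Construct a Pedigree
#'
#' @param id,sex,affection,sequenced parallel vectors describing the members.
#' @return a \linkS4class{Pedigree}
#' @export
Pedigree <- function(id, sex = "unknown", affection = "unknown",
                     sequenced = TRUE) {
  m <- data.frame(id = as.character(id),
                  sex = rep_len(as.character(sex), length(id)),
                  affection = rep_len(as.character(affection), length(id)),
                  sequenced = rep_len(as.logical(sequenced), length(id)),
                  stringsAsFactors = FALSE)
  new("Pedigree", members = m)
}

#' Construct a GenotypeMatrix
#' @param calls character matrix (individuals x variants) of
#'   present/absent/untyped with dimnames.
#' @export
GenotypeMatrix <- function(calls) new("GenotypeMatrix", calls = calls)

#' Construct a Structure
#' @param atoms data.frame(name, resid, mass, radius)
#' @param xyz n x 3 coordinate matrix, nm
#' @export
Structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  new("Structure", atoms = as.data.frame(atoms), xyz = xyz)
}

#' Construct a Trajectory
#' @param structure a \linkS4class{Structure} topology
#' @param coords frames x atoms x 3 array, nm
#' @param frameTime ns between consecutive frames
#' @export
Trajectory <- function(structure, coords, frameTime = 0.1) {
  new("Trajectory", structure = structure, coords = coords,
      frameTime = frameTime)
}

#' @rdname variantData
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' Extract the underlying data.frame of a VariantTable
#' @param x a \linkS4class{VariantTable}
#' @return data.frame, one row per variant
#' @export
setMethod("variantData", "VariantTable", function(x) x@variants)

#' @rdname pedMembers
#' @export
setGeneric("pedMembers", function(x) standardGeneric("pedMembers"))

#' Member table of a Pedigree
#' @param x a \linkS4class{Pedigree}
#' @export
setMethod("pedMembers", "Pedigree", function(x) x@members)

#' @rdname genotypeCalls
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Carrier-status matrix of a GenotypeMatrix
#' @param x a \linkS4class{GenotypeMatrix}
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname atomData
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Atom table (name, resid, mass, radius) of a Structure
#' @param x a \linkS4class{Structure} or \linkS4class{Trajectory}
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@structure@atoms)

#' @rdname coords
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Coordinates of a Structure (n x 3) or Trajectory (frames x atoms x 3), nm
#' @param x object
#' @param ... unused
#' @export
setMethod("coords", "Structure", function(x, ...) x@xyz)

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, ...) x@coords)

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of frames in a Trajectory
#' @param x a \linkS4class{Trajectory}
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname frameTime
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' Time between frames (ns)
#' @param x a \linkS4class{Trajectory}
#' @export
setMethod("frameTime", "Trajectory", function(x) x@frameTime)

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj a \linkS4class{Trajectory}
#' @param i frame index (1-based)
#' @return n x 3 coordinate matrix, nm
#' @export
frameCoords <- function(traj, i) {
  stopifnot(i >= 1, i <= nFrames(traj))
  matrix(traj@coords[i, , ], ncol = 3)
}

setMethod("show", "VariantTable", function(object) {
  v <- object@variants
  cat(sprintf("VariantTable with %d variant(s)\n", nrow(v)))
  if (nrow(v))
    print(utils::head(v[, c("gene", "protein", "consequence", "zygosity",
                            "cadd")], 10))
})

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree: %d member(s) (%d affected, %d unaffected, %d unknown)\n",
              nrow(m), sum(m$affection == "affected"),
              sum(m$affection == "unaffected"),
              sum(m$affection == "unknown")))
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@calls
  cat(sprintf("GenotypeMatrix: %d individual(s) x %d variant(s); %d present call(s)\n",
              nrow(g), ncol(g), sum(g == "present")))
})

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure: %d atom(s), %d residue(s)\n",
              nrow(object@atoms), length(unique(object@atoms$resid))))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frame(s) x %d atom(s), %.4g ns/frame (%.4g ns total)\n",
              nFrames(object), dim(object@coords)[2], object@frameTime,
              (nFrames(object) - 1) * object@frameTime))
})

setMethod("show", "EDResult", function(object) {
  k <- length(object@eigenvalues)
  cat(sprintf("EDResult: trace %.4g nm^2; top %d eigenvalue(s)\n",
              object@trace, k))
  cat(sprintf("  PC%d: %.4g nm^2 (%.1f%%)\n", seq_len(min(k, 5)),
              object@eigenvalues[seq_len(min(k, 5))],
              object@contributions[seq_len(min(k, 5))]), sep = "")
})

setMethod("show", "FESGrid", function(object) {
  vis <- sum(!is.na(object@dG))
  cat(sprintf("FESGrid: %d x %d bins at %g K; %d visited, max dG %.3g kJ/mol\n",
              nrow(object@dG), ncol(object@dG), object@temperature, vis,
              if (vis) max(object@dG, na.rm = TRUE) else NA_real_))
})
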