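#' Read a pedigree from a PED file
#'
#' Standard whitespace-delimited 6-column PED (family, individual, father,
#' mother, sex, phenotype) with an optional 7th column flagging whether the
#' individual was sequenced (1/0).  Phenotype coding: 1 = unaffected,
#' 2 = affected, 0 or -9 = unknown.  Sex coding: 1 = male, 2 = female,
#' anything else = unknown.
#'
#' @param path PED file
#' @return a \linkS4class{Pedigree}
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(ped) < 6)
    stop("PED file needs at least 6 columns, got ", ncol(ped))
  id <- ped[[2]]
  if (anyDuplicated(id))
    stop("duplicate individual id in PED: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sex <- c("1" = "male", "2" = "female")[ped[[5]]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[ped[[6]]]
  aff[is.na(aff)] <- "unknown"
  seqd <- if (ncol(ped) >= 7) ped[[7]] == "1" else rep(TRUE, nrow(ped))
  Pedigree(id = id, sex = unname(sex), affection = unname(aff),
           sequenced = seqd)
}

#' Write a pedigree as a 6+1-column PED file
#' @param ped a \linkS4class{Pedigree}
#' @param path output file
#' @param family family id used for column 1
#' @export
writePedigree <- function(ped, path, family = "FAM1") {
  m <- pedMembers(ped)
  out <- data.frame(
    fid = family, iid = m$id, pat = "0", mat = "0",
    sex = c(male = "1", female = "2", unknown = "0")[m$sex],
    pheno = c(unaffected = "1", affected = "2", unknown = "0")[m$affection],
    seqd = ifelse(m$sequenced, "1", "0"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
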