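#' Filtration and co-segregation settings
#'
#' Defaults encode a dominant-family analysis: non-synonymous heterozygous
#' variants at minor allele frequency <= 1\%, carried by every shared-in
#' affected, allowing one affected non-carrier (a phenocopy, common in
#' late-onset neurodegeneration) and no unaffected carriers.  Raising
#' \code{maxUnaffectedCarriers} models reduced penetrance.
#'
#' @param mafThreshold keep variants with MAF <= this (or with no frequency
#'   record at all, i.e. novel); default 0.01
#' @param maxPhenocopies affected non-carriers tolerated per variant
#' @param maxUnaffectedCarriers unaffected carriers tolerated per variant
#' @param requireHet drop homozygous variants (dominant model)
#' @param excludeSynonymous drop synonymous variants
#' @return a list of class \code{FilterConfig}
#' @export
filterConfig <- function(mafThreshold = 0.01, maxPhenocopies = 1L,
                         maxUnaffectedCarriers = 0L, requireHet = TRUE,
                         excludeSynonymous = TRUE) {
  stopifnot(mafThreshold >= 0, mafThreshold <= 1,
            maxPhenocopies >= 0, maxUnaffectedCarriers >= 0)
  structure(list(mafThreshold = mafThreshold,
                 maxPhenocopies = as.integer(maxPhenocopies),
                 maxUnaffectedCarriers = as.integer(maxUnaffectedCarriers),
                 requireHet = requireHet,
                 excludeSynonymous = excludeSynonymous),
            class = "FilterConfig")
}

#' Minor allele frequency from an allele count
#'
#' Folds to the minor allele: returns min(f, 1 - f) with
#' f = alleleCount / alleleNumber.
#'
#' @param alleleCount non-negative integer count of the alternate allele
#' @param alleleNumber positive total number of genotyped alleles
#' @return MAF in [0, 0.5]
#' @examples
#' computeMAF(25, 281690)   # 8.88e-5, the gnomAD frequency of a rare variant
#' @export
computeMAF <- function(alleleCount, alleleNumber) {
  if (any(alleleNumber <= 0)) stop("alleleNumber must be positive")
  if (any(alleleCount < 0) || any(alleleCount > alleleNumber))
    stop("need 0 <= alleleCount <= alleleNumber")
  f <- alleleCount / alleleNumber
  pmin(f, 1 - f)
}

#' MAF column for a variant table (NA when no frequency record)
#' @param vt a \linkS4class{VariantTable}
#' @return numeric vector of MAFs, NA for novel variants
#' @export
variantMAF <- function(vt) {
  v <- variantData(vt)
  ifelse(is.na(v$ac) | is.na(v$an), NA_real_, computeMAF(
    ifelse(is.na(v$ac), 0L, v$ac), ifelse(is.na(v$an), 1L, v$an)))
}

.variantIds <- function(vt) {
  v <- variantData(vt)
  paste0(v$gene, ":", v$protein)
}

#' Variant filtration cascade
#'
#' Retains variants that are (a) non-synonymous, (b) heterozygous, (c) at
#' MAF <= threshold or novel (no frequency record), and (d) present in every
#' individual of \code{sharedIn}.  Input order is preserved; the operation is
#' idempotent.
#'
#' @param vt a \linkS4class{VariantTable}
#' @param sharedIn ids of (sequenced) individuals that must all carry the
#'   variant
#' @param genotypes a \linkS4class{GenotypeMatrix} with a column per variant,
#'   in the same order as \code{vt}
#' @param cfg a \code{\link{filterConfig}}
#' @return filtered \linkS4class{VariantTable}
#' @export
filterCandidates <- function(vt, sharedIn, genotypes, cfg = filterConfig()) {
  v <- variantData(vt)
  calls <- genotypeCalls(genotypes)
  if (!all(sharedIn %in% rownames(calls)))
    stop("unknown individual id(s): ",
         paste(setdiff(sharedIn, rownames(calls)), collapse = ", "))
  if (ncol(calls) != nrow(v))
    stop("genotype matrix has ", ncol(calls), " variants, table has ",
         nrow(v))
  keep <- rep(TRUE, nrow(v))
  if (cfg$excludeSynonymous) keep <- keep & v$consequence != "synonymous"
  if (cfg$requireHet)        keep <- keep & v$zygosity == "het"
  maf <- variantMAF(vt)
  keep <- keep & (is.na(maf) | maf <= cfg$mafThreshold)
  if (length(sharedIn))
    keep <- keep & apply(calls[sharedIn, , drop = FALSE] == "present", 2, all)
  VariantTable(v[keep, , drop = FALSE])
}

#' Pedigree co-segregation with phenocopy allowance
#'
#' For each variant, counts affected carriers, affected non-carriers
#' (phenocopy budget consumed) and unaffected carriers among typed members.
#' Individuals with unknown affection or an untyped call contribute to no
#' count.  A variant passes when affected non-carriers <= maxPhenocopies and
#' unaffected carriers <= maxUnaffectedCarriers.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}
#' @param pedigree a \linkS4class{Pedigree} covering all matrix individuals
#' @param cfg a \code{\link{filterConfig}}
#' @return data.frame with one verdict row per variant: variant_id,
#'   affected_carriers, affected_noncarriers, unaffected_carriers, passes
#' @export
assessCosegregation <- function(genotypes, pedigree, cfg = filterConfig()) {
  calls <- genotypeCalls(genotypes)
  m <- pedMembers(pedigree)
  if (!all(rownames(calls) %in% m$id))
    stop("genotyped individual(s) missing from pedigree: ",
         paste(setdiff(rownames(calls), m$id), collapse = ", "))
  aff <- m$id[m$affection == "affected"]
  una <- m$id[m$affection == "unaffected"]
  affRows <- intersect(rownames(calls), aff)
  unaRows <- intersect(rownames(calls), una)
  anyTypedAffected <- length(affRows) > 0 &&
    any(calls[affRows, , drop = FALSE] != "untyped")
  if (!anyTypedAffected)
    stop("co-segregation needs at least one typed affected individual")
  res <- data.frame(
    variant_id = colnames(calls),
    affected_carriers = colSums(calls[affRows, , drop = FALSE] == "present"),
    affected_noncarriers = colSums(calls[affRows, , drop = FALSE] == "absent"),
    unaffected_carriers = colSums(calls[unaRows, , drop = FALSE] == "present"),
    stringsAsFactors = FALSE)
  res$passes <- res$affected_noncarriers <= cfg$maxPhenocopies &
    res$unaffected_carriers <= cfg$maxUnaffectedCarriers
  rownames(res) <- NULL
  res
}
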