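## VCF INFO keys carrying the annotation; absent key = absent value.
.vcfInfoKeys <- c(gene = "GENE", cdna = "CDNA", protein = "PROT",
                  consequence = "CSQ", zygosity = "ZYG",
                  sift = "SIFT", polyphen2 = "PP2", mutationtaster = "MT",
                  gerp = "GERP", cadd = "CADD", condel = "CONDEL",
                  ac = "AC", an = "AN", source = "SRC")

#' Read an annotated variant table
#'
#' Two dialects are supported: a fixed-header TSV (see
#' \code{variantColumns()} for the layout) and VCF 4.x with the annotation in
#' INFO keys (GENE, CDNA, PROT, CSQ, ZYG, SIFT, PP2, MT, GERP, CADD, CONDEL,
#' AC, AN, SRC).  Missing scores stay absent (NA), never zero.  GERP scores
#' outside the published range [-12.3, 6.17] are rejected at read time.
#'
#' @param path file to read
#' @param dialect "tsv" or "vcf"
#' @return a \linkS4class{VariantTable}
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") .readVariantTSV(path) else .readVariantVCF(path)
}

.readVariantTSV <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE)
  expected <- length(.variantColumns)
  bad <- which(nf != expected & nf > 0)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: %d field(s), expected %d",
                 bad[1], path, nf[bad[1]], expected))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          na.strings = c("NA", ""), quote = "",
                          check.names = FALSE)
  if (!identical(colnames(df), .variantColumns))
    stop("TSV header does not match the canonical variant column layout")
  VariantTable(df)
}

.readVariantVCF <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(vcf, element = key)
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }
  df <- data.frame(
    gene = info("GENE"), cdna = info("CDNA"), protein = info("PROT"),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    consequence = info("CSQ"), zygosity = info("ZYG"),
    sift = info("SIFT", TRUE), polyphen2 = info("PP2", TRUE),
    mutationtaster = info("MT", TRUE), gerp = info("GERP", TRUE),
    cadd = info("CADD", TRUE), condel = info("CONDEL", TRUE),
    ac = suppressWarnings(as.integer(info("AC"))),
    an = suppressWarnings(as.integer(info("AN"))),
    source = info("SRC"),
    stringsAsFactors = FALSE)
  VariantTable(df)
}

#' Write a variant table as canonical TSV
#'
#' Lossless counterpart of \code{readVariantTable(dialect = "tsv")}.
#'
#' @param vt a \linkS4class{VariantTable}
#' @param path output file
#' @export
writeVariantTable <- function(vt, path) {
  stopifnot(is(vt, "VariantTable"))
  utils::write.table(vt@variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.reportColumns <- c("rank", "gene", "protein", "segregation",
                    "affected_carriers", "affected_noncarriers",
                    "unaffected_carriers",
                    "sift_call", "polyphen2_call", "mutationtaster_call",
                    "cadd_call", "condel_call",
                    "deleterious_votes", "conserved", "unanimous", "maf",
                    "expressed_in_target_tissue")

#' Write the ranked candidate report
#'
#' One row per variant: gene, protein change, segregation verdict and counts,
#' per-tool categorical calls, deleterious-vote count, conservation flag,
#' MAF and rank.  The optional tissue-expression flag column is kept (NA when
#' no annotation was joined).
#'
#' @param ranked data.frame as returned by \code{rankCandidates}
#' @param path output TSV
#' @export
writeCandidateReport <- function(ranked, path) {
  if (nrow(ranked) == 0)
    ranked <- as.data.frame(matrix(nrow = 0, ncol = 0))
  for (col in .reportColumns)
    if (!col %in% colnames(ranked))
      ranked[[col]] <- rep(NA, nrow(ranked))
  utils::write.table(ranked[, .reportColumns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a candidate report
#' @param path report TSV written by \code{writeCandidateReport}
#' @return data.frame
#' @export
readCandidateReport <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    na.strings = "NA", quote = "",
                    stringsAsFactors = FALSE)
}
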