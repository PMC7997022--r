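#' Read a carrier-status matrix from TSV
#'
#' First column \code{id}, one column per variant id; cells are
#' present/absent/untyped.
#'
#' @param path TSV file
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  if (colnames(df)[1] != "id")
    stop("genotype TSV must start with an 'id' column")
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$id
  GenotypeMatrix(calls)
}

#' Write a carrier-status matrix as TSV
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param path output file
#' @export
writeGenotypeMatrix <- function(gm, path) {
  calls <- genotypeCalls(gm)
  df <- data.frame(id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
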