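#' Built-in worked-example fixtures
#'
#' The published worked example packaged with the package: the ZA253
#' pedigree (5 affected, 4 unaffected genotyped members; the three
#' exome-sequenced affecteds flagged), its genotyped carrier-status matrix
#' for the five Sanger-validated variants, the annotated variant table with
#' all per-tool scores, and a small local gene-to-tissue expression table.
#'
#' Genomic positions other than the CFAP65 variant (whose gnomAD record is
#' public) are synthetic placeholders: the source tables print gene, cDNA
#' and protein change only, and no downstream computation uses \code{pos}.
#' The gene symbol is spelled RFT1 as printed in the tables (the source
#' text also uses the spelling RTF1 in places).
#'
#' @return list(pedigree, genotypes, variants, tissue, sharedIn) where
#'   \code{sharedIn} holds the ids of the three exome-sequenced affecteds
#' @export
builtinFixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "prioMD",
                                 mustWork = TRUE)
  ped <- readPedigree(ext("za253.ped"))
  list(pedigree = ped,
       genotypes = readGenotypeMatrix(ext("table1_genotypes.tsv")),
       variants = readVariantTable(ext("table2_variants.tsv"), "tsv"),
       tissue = utils::read.delim(ext("tissue_expression.tsv"),
                                  stringsAsFactors = FALSE),
       sharedIn = pedMembers(ped)$id[pedMembers(ped)$sequenced])
}
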