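#' Run the full prioritization stage
#'
#' Chains reading, the filtration cascade, co-segregation, consensus
#' scoring and ranking into one deterministic report.  Filter rules are
#' applied in a fixed order (synonymous, homozygous, common, non-shared,
#' then segregation) and every excluded variant is logged with the first
#' rule that removed it, one JSON object per line.  Variants failing only
#' co-segregation stay in the report, ranked after all passing ones, and
#' are logged too.
#'
#' @param variantsPath annotated variant table (TSV or VCF)
#' @param pedigreePath PED file
#' @param genotypesPath carrier-status TSV (id x variant)
#' @param reportPath output report TSV
#' @param logPath optional decision log (JSON lines); NULL skips writing
#' @param dialect variant dialect, "tsv" or "vcf"
#' @param sharedIn ids that must all carry a candidate; default the
#'   sequenced affected members of the pedigree
#' @param cfg a \code{\link{filterConfig}}
#' @param thresholds a \code{\link{consensusThresholds}}
#' @param annotation optional data.frame(gene, tissue) joined into the
#'   report as expressed_in_target_tissue
#' @param targetTissue tissue tested by the annotation join
#' @return invisibly, list(report, log) — the ranked data.frame and the
#'   per-variant decision records
#' @export
runPrioritize <- function(variantsPath, pedigreePath, genotypesPath,
                          reportPath, logPath = NULL,
                          dialect = c("tsv", "vcf"), sharedIn = NULL,
                          cfg = filterConfig(),
                          thresholds = consensusThresholds(),
                          annotation = NULL,
                          targetTissue = "substantia nigra") {
  dialect <- match.arg(dialect)
  vt <- readVariantTable(variantsPath, dialect)
  ped <- readPedigree(pedigreePath)
  gm <- readGenotypeMatrix(genotypesPath)
  m <- pedMembers(ped)
  if (is.null(sharedIn))
    sharedIn <- m$id[m$sequenced & m$affection == "affected"]

  v <- variantData(vt)
  ids <- .variantIds(vt)
  decisions <- list()
  note <- function(id, rule)
    decisions[[length(decisions) + 1]] <<- list(variant_id = id, rule = rule)

  keep <- rep(TRUE, nrow(v))
  maf <- variantMAF(vt)
  calls <- genotypeCalls(gm)
  if (!all(sharedIn %in% rownames(calls)))
    stop("prioritize: unknown shared-in individual(s): ",
         paste(setdiff(sharedIn, rownames(calls)), collapse = ", "))
  if (nrow(v) && !all(ids %in% colnames(calls)))
    stop("prioritize: genotype matrix lacks column(s) for variant(s): ",
         paste(setdiff(ids, colnames(calls)), collapse = ", "))
  rules <- list(
    synonymous = if (cfg$excludeSynonymous) v$consequence == "synonymous"
                 else rep(FALSE, nrow(v)),
    homozygous = if (cfg$requireHet) v$zygosity == "hom"
                 else rep(FALSE, nrow(v)),
    common = !is.na(maf) & maf > cfg$mafThreshold,
    `non-shared` = if (length(sharedIn) && nrow(v))
      !apply(calls[sharedIn, ids, drop = FALSE] == "present", 2, all)
      else rep(FALSE, nrow(v)))
  for (rule in names(rules)) {
    hit <- keep & rules[[rule]]
    for (id in ids[hit]) note(id, rule)
    keep <- keep & !rules[[rule]]
  }
  vtKept <- VariantTable(v[keep, , drop = FALSE])
  keptIds <- ids[keep]

  if (nrow(variantData(vtKept)) == 0) {
    ranked <- data.frame()
    writeCandidateReport(ranked, reportPath)
  } else {
    gmKept <- GenotypeMatrix(calls[, keptIds, drop = FALSE])
    verdicts <- assessCosegregation(gmKept, ped, cfg)
    for (i in seq_len(nrow(verdicts))) {
      if (verdicts$passes[i]) next
      rule <- if (verdicts$unaffected_carriers[i] >
                  cfg$maxUnaffectedCarriers) "unaffected carriers"
              else "phenocopy budget exceeded"
      note(verdicts$variant_id[i], paste0("segregation: ", rule))
    }
    profiles <- consensusProfile(vtKept, thresholds)
    ranked <- rankCandidates(profiles, verdicts)
    if (!is.null(annotation))
      ranked <- annotateTissueExpression(ranked, annotation, targetTissue)
    writeCandidateReport(ranked, reportPath)
  }
  if (!is.null(logPath)) {
    lines <- vapply(decisions, function(d)
      jsonlite::toJSON(d, auto_unbox = TRUE), character(1))
    writeLines(lines, logPath)
  }
  invisible(list(report = ranked, log = decisions))
}
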