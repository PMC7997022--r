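#' Per-tool deleteriousness cutoffs
#'
#' Published or community-standard decision thresholds: SIFT calls a variant
#' deleterious at score <= 0.05; PolyPhen-2 (HumDiv) tiers at 0.447
#' (possibly damaging) and 0.909 (probably damaging), both counted as
#' deleterious; MutationTaster at probability >= 0.5; CADD phred at >= 15
#' (between the "top 10\%" and "top 1\%" tiers); Condel at its published
#' 0.522 operating point.  GERP++ >= 2.0 flags an evolutionarily conserved
#' site; conservation is reported alongside the five pathogenicity votes,
#' not as a sixth vote.
#'
#' @param sift,polyphen2Possibly,polyphen2Probably,mutationtaster,cadd,condel,gerpConserved numeric cutoffs
#' @return list of class \code{ConsensusThresholds}
#' @export
consensusThresholds <- function(sift = 0.05, polyphen2Possibly = 0.447,
                                polyphen2Probably = 0.909,
                                mutationtaster = 0.5, cadd = 15,
                                condel = 0.522, gerpConserved = 2.0) {
  structure(list(sift = sift, polyphen2Possibly = polyphen2Possibly,
                 polyphen2Probably = polyphen2Probably,
                 mutationtaster = mutationtaster, cadd = cadd,
                 condel = condel, gerpConserved = gerpConserved),
            class = "ConsensusThresholds")
}

.toolDomains <- list(sift = c(0, 1), polyphen2 = c(0, 1),
                     mutationtaster = c(0, 1), gerp = .gerpRange,
                     cadd = c(0, Inf), condel = c(0, 1))

#' Categorical call for one raw tool score
#'
#' Maps a numeric score to the label the tool itself would report:
#' deleterious/benign for SIFT, MutationTaster, CADD and Condel;
#' benign/possibly_damaging/probably_damaging for PolyPhen-2 (the damaging
#' tiers count as deleterious votes); conserved/not_conserved for GERP++.
#' An NA score returns "absent".
#'
#' @param tool one of sift, polyphen2, mutationtaster, gerp, cadd, condel
#' @param score raw score; must lie in the tool's documented domain
#' @param thresholds a \code{\link{consensusThresholds}}
#' @return character label
#' @export
classifyToolScore <- function(tool, score,
                              thresholds = consensusThresholds()) {
  if (!tool %in% names(.toolDomains)) stop("unknown tool: ", tool)
  if (is.na(score)) return("absent")
  dom <- .toolDomains[[tool]]
  if (score < dom[1] || score > dom[2])
    stop(sprintf("%s score %g outside its domain [%g, %g]",
                 tool, score, dom[1], dom[2]))
  th <- thresholds
  switch(tool,
    sift = if (score <= th$sift) "deleterious" else "benign",
    polyphen2 = if (score >= th$polyphen2Probably) "probably_damaging"
                else if (score >= th$polyphen2Possibly) "possibly_damaging"
                else "benign",
    mutationtaster = if (score >= th$mutationtaster) "deleterious"
                     else "benign",
    cadd = if (score >= th$cadd) "deleterious" else "benign",
    condel = if (score >= th$condel) "deleterious" else "benign",
    gerp = if (score >= th$gerpConserved) "conserved" else "not_conserved")
}

.isDeleterious <- function(call, tool) {
  if (tool == "polyphen2")
    call %in% c("possibly_damaging", "probably_damaging")
  else call == "deleterious"
}

#' Consensus deleteriousness profile per variant
#'
#' Applies \code{\link{classifyToolScore}} to the five pathogenicity tools
#' (SIFT, PolyPhen-2, MutationTaster, CADD, Condel) and the GERP++
#' conservation flag; counts deleterious votes (absent scores vote
#' non-deleterious but are reported distinctly) and flags unanimity (all
#' five deleterious AND conserved).  The rank key is the triple
#' (deleterious_votes, conserved, cadd), compared lexicographically.
#'
#' @param vt a \linkS4class{VariantTable}
#' @param thresholds a \code{\link{consensusThresholds}}
#' @return data.frame, one profile row per variant
#' @export
consensusProfile <- function(vt, thresholds = consensusThresholds()) {
  v <- variantData(vt)
  tools <- c("sift", "polyphen2", "mutationtaster", "cadd", "condel")
  if (nrow(v) == 0)
    return(data.frame(variant_id = character(), gene = character(),
                      protein = character(), sift_call = character(),
                      polyphen2_call = character(),
                      mutationtaster_call = character(),
                      cadd_call = character(), condel_call = character(),
                      conserved = logical(), deleterious_votes = integer(),
                      absent_scores = integer(), unanimous = logical(),
                      cadd = numeric(), maf = numeric(),
                      stringsAsFactors = FALSE))
  allAbsent <- apply(is.na(v[, c(tools, "gerp")]), 1, all)
  if (any(allAbsent))
    stop("variant(s) with no scores at all: ",
         paste(.variantIds(vt)[allAbsent], collapse = ", "))
  calls <- matrix("", nrow(v), length(tools),
                  dimnames = list(NULL, tools))
  delMat <- matrix(FALSE, nrow(v), length(tools))
  for (tl in tools) {
    calls[, tl] <- vapply(v[[tl]], function(s)
      classifyToolScore(tl, s, thresholds), "")
    delMat[, match(tl, tools)] <- vapply(calls[, tl], .isDeleterious, NA,
                                         tool = tl)
  }
  votes <- rowSums(delMat)
  absent <- rowSums(calls == "absent")
  conserved <- !is.na(v$gerp) & v$gerp >= thresholds$gerpConserved
  data.frame(
    variant_id = .variantIds(vt), gene = v$gene, protein = v$protein,
    sift_call = calls[, "sift"], polyphen2_call = calls[, "polyphen2"],
    mutationtaster_call = calls[, "mutationtaster"],
    cadd_call = calls[, "cadd"], condel_call = calls[, "condel"],
    conserved = conserved,
    deleterious_votes = as.integer(votes),
    absent_scores = as.integer(absent),
    unanimous = votes == 5L & conserved,
    cadd = v$cadd,
    maf = variantMAF(vt),
    stringsAsFactors = FALSE)
}

#' Rank candidate variants
#'
#' Variants failing co-segregation are ranked after every passing one;
#' within each block the rank key (deleterious_votes, conserved, cadd)
#' is compared lexicographically, descending, with alphabetical gene symbol
#' as the deterministic tie-break.
#'
#' @param profiles data.frame from \code{\link{consensusProfile}}
#' @param verdicts data.frame from \code{\link{assessCosegregation}}, keyed
#'   by the same variant ids
#' @return profiles joined with verdicts, ordered, with a \code{rank} column
#' @export
rankCandidates <- function(profiles, verdicts) {
  if (!setequal(profiles$variant_id, verdicts$variant_id))
    stop("profiles and verdicts are keyed by different variant ids")
  m <- merge(profiles, verdicts, by = "variant_id", sort = FALSE)
  m$segregation <- ifelse(m$passes, "pass", "fail")
  caddKey <- ifelse(is.na(m$cadd), -Inf, m$cadd)
  ord <- order(!m$passes,                      # passing block first
               -m$deleterious_votes, -as.integer(m$conserved), -caddKey,
               m$gene)
  m <- m[ord, , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}

#' Join a local gene-to-tissue annotation table
#'
#' Adds a logical \code{expressed_in_target_tissue} column: TRUE when the
#' gene is annotated to the target tissue in the supplied local table (no
#' web queries).
#'
#' @param ranked data.frame from \code{\link{rankCandidates}}
#' @param annotation data.frame with columns gene and tissue
#' @param targetTissue tissue name to test for
#' @return ranked with the expression flag column filled in
#' @export
annotateTissueExpression <- function(ranked, annotation,
                                     targetTissue = "substantia nigra") {
  hit <- annotation$gene[annotation$tissue == targetTissue]
  ranked$expressed_in_target_tissue <- ranked$gene %in% hit
  ranked
}
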