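## distribution specs are (name, parameters) lists so configurations are
## serializable; draw() realizes them and clips to the tool domain
.dist <- function(name, ...) c(list(name = name), list(...))

.drawDist <- function(spec, n) {
  x <- switch(spec$name,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$min, spec$max),
    constant = rep(spec$value, n),
    stop("unknown distribution: ", spec$name))
  if (!is.null(spec$clip)) x <- pmin(pmax(x, spec$clip[1]), spec$clip[2])
  x
}

#' Configuration for the synthetic family generator
#'
#' Defaults emulate the structure of a dominant Parkinsonism family study:
#' a handful of affected and unaffected relatives, one planted causal
#' variant (heterozygous, novel, carried by every affected except declared
#' phenocopies, absent from unaffecteds) among background polymorphisms
#' carried at random per their minor allele frequency.  Causal scores are
#' drawn deleterious-side (SIFT ~ Beta(1,20), CADD ~ Normal(28,3) truncated
#' at 0, GERP ~ Normal(5,0.5) clipped to its range); background scores
#' mirror them toward benign.
#'
#' @param nAffected,nUnaffected family sizes
#' @param nBackgroundVariants background polymorphisms to plant
#' @param phenocopyIds affected ids that do NOT carry the causal variant
#' @param causalScores,backgroundScores named lists of distribution specs
#'   per tool (names sift, polyphen2, mutationtaster, gerp, cadd, condel)
#' @param mafDistribution distribution spec for background MAFs
#' @param alleleNumber allele number used for background frequency records
#' @param seed RNG seed; the generator is bit-reproducible per seed
#' @return list of class \code{FamilySimConfig}
#' @export
familySimConfig <- function(nAffected = 4L, nUnaffected = 4L,
                            nBackgroundVariants = 20L,
                            phenocopyIds = character(),
                            causalScores = list(
                              sift = .dist("beta", shape1 = 1, shape2 = 20),
                              polyphen2 = .dist("beta", shape1 = 9, shape2 = 1),
                              mutationtaster = .dist("beta", shape1 = 9,
                                                     shape2 = 1),
                              gerp = .dist("normal", mean = 5, sd = 0.5,
                                           clip = .gerpRange),
                              cadd = .dist("normal", mean = 28, sd = 3,
                                           clip = c(0, 99)),
                              condel = .dist("beta", shape1 = 8, shape2 = 2)),
                            backgroundScores = list(
                              sift = .dist("beta", shape1 = 20, shape2 = 1),
                              polyphen2 = .dist("beta", shape1 = 1, shape2 = 9),
                              mutationtaster = .dist("beta", shape1 = 1,
                                                     shape2 = 9),
                              gerp = .dist("normal", mean = 0, sd = 1.5,
                                           clip = .gerpRange),
                              cadd = .dist("normal", mean = 5, sd = 3,
                                           clip = c(0, 99)),
                              condel = .dist("beta", shape1 = 2, shape2 = 8)),
                            mafDistribution = .dist("beta", shape1 = 0.6,
                                                    shape2 = 8),
                            alleleNumber = 250000L, seed = 1L) {
  stopifnot(nAffected >= 1, nUnaffected >= 0, nBackgroundVariants >= 0)
  structure(list(nAffected = as.integer(nAffected),
                 nUnaffected = as.integer(nUnaffected),
                 nBackgroundVariants = as.integer(nBackgroundVariants),
                 phenocopyIds = phenocopyIds,
                 causalScores = causalScores,
                 backgroundScores = backgroundScores,
                 mafDistribution = mafDistribution,
                 alleleNumber = as.integer(alleleNumber),
                 seed = as.integer(seed)),
            class = "FamilySimConfig")
}

.drawScores <- function(specs, n) {
  ## one column per tool, rounded so TSV round-trips are value-exact
  out <- lapply(specs, .drawDist, n = n)
  lapply(out, round, digits = 6)
}

#' Generate a synthetic family dataset
#'
#' Produces a pedigree (ids A1..An affected, U1..Um unaffected, all
#' sequenced), a carrier-status matrix and an annotated variant table with
#' exactly one planted causal variant (gene \code{CAND1}) plus background
#' variants.  Background genotypes are drawn per-individual as
#' Binomial(2, MAF); background consequences are missense or synonymous
#' (7:3).  Fully reproducible for a given \code{seed}.
#'
#' @param cfg a \code{\link{familySimConfig}}
#' @return list(pedigree, genotypes, variants, causalId)
#' @export
generateFamilyDataset <- function(cfg = familySimConfig()) {
  affIds <- paste0("A", seq_len(cfg$nAffected))
  unaIds <- if (cfg$nUnaffected) paste0("U", seq_len(cfg$nUnaffected))
            else character()
  if (!all(cfg$phenocopyIds %in% affIds))
    stop("phenocopy id(s) not among affected individuals: ",
         paste(setdiff(cfg$phenocopyIds, affIds), collapse = ", "))
  set.seed(cfg$seed)
  ped <- Pedigree(id = c(affIds, unaIds),
                  sex = sample(c("male", "female"),
                               cfg$nAffected + cfg$nUnaffected,
                               replace = TRUE),
                  affection = c(rep("affected", cfg$nAffected),
                                rep("unaffected", cfg$nUnaffected)),
                  sequenced = TRUE)
  nb <- cfg$nBackgroundVariants
  n <- nb + 1L
  causal <- .drawScores(cfg$causalScores, 1)
  bg <- .drawScores(cfg$backgroundScores, nb)
  mafs <- .drawDist(cfg$mafDistribution, nb)
  mafs <- pmin(pmax(mafs, 0), 0.5)
  bgGene <- sprintf("BG%03d", seq_len(max(nb, 0)))
  df <- data.frame(
    gene = c("CAND1", bgGene),
    cdna = sprintf("c.%dA>G", sample(100:9999, n)),
    protein = sprintf("p.A%dV", sample(10:999, n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1e4:1e8, n),
    ref = "A", alt = "G",
    consequence = c("missense",
                    sample(c("missense", "synonymous"), nb, replace = TRUE,
                           prob = c(0.7, 0.3))),
    zygosity = "het",
    sift = c(causal$sift, bg$sift),
    polyphen2 = c(causal$polyphen2, bg$polyphen2),
    mutationtaster = c(causal$mutationtaster, bg$mutationtaster),
    gerp = c(causal$gerp, bg$gerp),
    cadd = c(causal$cadd, bg$cadd),
    condel = c(causal$condel, bg$condel),
    ac = c(NA, as.integer(round(mafs * cfg$alleleNumber))),
    an = c(NA, rep(cfg$alleleNumber, nb)),
    source = c(NA, rep("synthetic_db", nb)),
    stringsAsFactors = FALSE)
  vt <- VariantTable(df)
  ids <- .variantIds(vt)
  members <- c(affIds, unaIds)
  calls <- matrix("absent", length(members), n,
                  dimnames = list(members, ids))
  carriers <- setdiff(affIds, cfg$phenocopyIds)
  calls[carriers, 1] <- "present"
  if (nb) for (j in seq_len(nb)) {
    alleles <- stats::rbinom(length(members), 2, mafs[j])
    calls[alleles > 0, j + 1] <- "present"
    if (any(alleles == 2)) {
      v <- vt@variants; v$zygosity[j + 1] <- "hom"
      vt <- VariantTable(v)
    }
  }
  list(pedigree = ped, genotypes = GenotypeMatrix(calls), variants = vt,
       causalId = ids[1])
}
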