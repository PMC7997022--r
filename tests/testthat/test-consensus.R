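fx <- builtinFixtures()

test_that("tool scores classify to the published categorical labels", {
  expect_equal(classifyToolScore("sift", 0.49), "benign")      # Tolerated
  expect_equal(classifyToolScore("sift", 0), "deleterious")
  expect_equal(classifyToolScore("sift", 0.05), "deleterious") # inclusive
  expect_equal(classifyToolScore("cadd", 29.50), "deleterious")
  expect_equal(classifyToolScore("cadd", 4.96), "benign")
  expect_equal(classifyToolScore("polyphen2", 0.973), "probably_damaging")
  expect_equal(classifyToolScore("polyphen2", 0.5), "possibly_damaging")
  expect_equal(classifyToolScore("polyphen2", 0.124), "benign")
  expect_equal(classifyToolScore("gerp", -8.29), "not_conserved")
  expect_equal(classifyToolScore("gerp", 4.93), "conserved")
  expect_equal(classifyToolScore("mutationtaster", 1), "deleterious")
  expect_equal(classifyToolScore("condel", 0.050), "benign")
  expect_equal(classifyToolScore("condel", 0.707), "deleterious")
  expect_equal(classifyToolScore("sift", NA), "absent")
  expect_error(classifyToolScore("provean", 0.5), "unknown tool")
  expect_error(classifyToolScore("sift", 1.2), "domain")
  expect_error(classifyToolScore("gerp", 7), "domain")
})

test_that("worked-example profiles reproduce every printed call", {
  prof <- consensusProfile(fx$variants)
  rownames(prof) <- prof$gene
  expected <- list(
    CFAP65 = c("deleterious", "benign", "deleterious", "deleterious",
               "deleterious"),
    RFT1   = c("benign", "benign", "benign", "benign", "benign"),
    NRXN2  = c("deleterious", "probably_damaging", "deleterious",
               "deleterious", "deleterious"),
    TEP1   = c("benign", "benign", "benign", "benign", "benign"),
    CCNF   = c("benign", "probably_damaging", "deleterious", "deleterious",
               "deleterious"))
  callCols <- c("sift_call", "polyphen2_call", "mutationtaster_call",
                "cadd_call", "condel_call")
  for (g in names(expected))
    expect_equal(unname(unlist(prof[g, callCols])), expected[[g]], label = g)
  expect_equal(prof[c("CFAP65", "RFT1", "NRXN2", "TEP1", "CCNF"),
                    "conserved"],
               c(TRUE, TRUE, TRUE, FALSE, TRUE), ignore_attr = TRUE)
  expect_equal(prof[c("CFAP65", "RFT1", "NRXN2", "TEP1", "CCNF"),
                    "deleterious_votes"],
               c(4L, 0L, 5L, 0L, 4L), ignore_attr = TRUE)
  expect_equal(prof$gene[prof$unanimous], "NRXN2")  # exactly one unanimous
})

test_that("a variant with no scores at all cannot be profiled", {
  v <- variantData(fx$variants)
  v[1, c("sift", "polyphen2", "mutationtaster", "gerp", "cadd",
         "condel")] <- NA
  expect_error(consensusProfile(VariantTable(v)), "no scores")
  ## a single missing score is fine and votes non-deleterious
  v <- variantData(fx$variants)
  v$sift[v$gene == "NRXN2"] <- NA
  prof <- consensusProfile(VariantTable(v))
  expect_equal(prof$deleterious_votes[prof$gene == "NRXN2"], 4L)
  expect_equal(prof$absent_scores[prof$gene == "NRXN2"], 1L)
  expect_false(prof$unanimous[prof$gene == "NRXN2"])
})

test_that("ranking puts the unanimous segregating candidate first", {
  verd <- assessCosegregation(fx$genotypes, fx$pedigree)
  ranked <- rankCandidates(consensusProfile(fx$variants), verd)
  expect_equal(ranked$gene[1], "NRXN2")
  expect_equal(ranked$gene[5], "CCNF")            # failed segregation: last
  expect_equal(ranked$segregation, c(rep("pass", 4), "fail"))
  ## deterministic under input permutation
  for (seed in 1:3) {
    set.seed(seed)
    perm <- sample(5)
    v <- variantData(fx$variants)[perm, ]
    ranked2 <- rankCandidates(consensusProfile(VariantTable(v)), verd)
    expect_equal(ranked2$variant_id, ranked$variant_id)
  }
  expect_error(rankCandidates(consensusProfile(fx$variants), verd[-1, ]),
               "different variant ids")
})

test_that("rank key breaks ties by CADD then gene symbol", {
  v <- variantData(fx$variants)[c(3, 3), ]
  v$gene <- c("AAA", "BBB"); v$pos <- 1:2
  v$cadd <- c(18.70, 29.50)
  prof <- consensusProfile(VariantTable(v))
  verd <- data.frame(variant_id = prof$variant_id,
                     affected_carriers = 4, affected_noncarriers = 0,
                     unaffected_carriers = 0, passes = TRUE)
  ranked <- rankCandidates(prof, verd)
  expect_equal(ranked$gene, c("BBB", "AAA"))      # higher CADD first
  v$cadd <- c(20, 20)
  ranked <- rankCandidates(consensusProfile(VariantTable(v)), verd)
  expect_equal(ranked$gene, c("AAA", "BBB"))      # alphabetical tie-break
  single <- rankCandidates(prof[1, ], verd[1, ])
  expect_equal(single$rank, 1)
})

test_that("votes are monotone as each score moves toward benign", {
  base <- variantData(fx$variants)[3, ]           # the unanimous row
  benignWard <- list(sift = seq(0, 1, 0.1), polyphen2 = seq(1, 0, -0.1),
                     mutationtaster = seq(1, 0, -0.1),
                     cadd = seq(40, 0, -4), condel = seq(1, 0, -0.1))
  for (tool in names(benignWard)) {
    votes <- vapply(benignWard[[tool]], function(s) {
      v <- base; v[[tool]] <- s
      consensusProfile(VariantTable(v))$deleterious_votes
    }, integer(1))
    expect_true(all(diff(votes) <= 0), label = tool)
  }
})

test_that("tissue annotation joins as a boolean report column", {
  verd <- assessCosegregation(fx$genotypes, fx$pedigree)
  ranked <- rankCandidates(consensusProfile(fx$variants), verd)
  ranked <- annotateTissueExpression(ranked, fx$tissue, "substantia nigra")
  expect_equal(ranked$expressed_in_target_tissue, ranked$gene == "NRXN2")
})
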