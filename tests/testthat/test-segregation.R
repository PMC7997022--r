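fx <- builtinFixtures()

test_that("minor allele frequency folds to the minor allele", {
  expect_equal(signif(computeMAF(25, 281690), 3), 8.88e-5)
  expect_equal(computeMAF(0, 1000), 0)
  expect_equal(computeMAF(140845, 281690), 0.5)
  expect_equal(computeMAF(900, 1000), 0.1)   # folded
  expect_error(computeMAF(1, 0), "positive")
  expect_error(computeMAF(-1, 10))
  expect_error(computeMAF(11, 10))
})

## 5-variant toy set exercising each filtration rule in isolation
toyFilterSet <- function() {
  v <- data.frame(
    gene = c("PLANT", "SYN", "HOM", "COMMON", "UNSHARED"),
    cdna = paste0("c.", 1:5, "A>G"), protein = paste0("p.A", 1:5, "V"),
    chrom = "1", pos = 1:5, ref = "A", alt = "G",
    consequence = c("missense", "synonymous", "missense", "missense",
                    "missense"),
    zygosity = c("het", "het", "hom", "het", "het"),
    sift = 0.01, polyphen2 = 0.5, mutationtaster = 0.5, gerp = 3,
    cadd = 20, condel = 0.6,
    ac = c(NA, NA, NA, 50000, NA), an = c(NA, NA, NA, 250000, NA),
    source = NA)
  vt <- VariantTable(v)
  ids <- paste0(v$gene, ":", v$protein)
  calls <- matrix("present", 3, 5,
                  dimnames = list(c("S1", "S2", "S3"), ids))
  calls["S3", "UNSHARED:p.A5V"] <- "absent"
  list(vt = vt, gm = GenotypeMatrix(calls))
}

test_that("the filtration cascade keeps only shared rare het missense", {
  toy <- toyFilterSet()
  kept <- filterCandidates(toy$vt, c("S1", "S2", "S3"), toy$gm)
  expect_equal(variantData(kept)$gene, "PLANT")
  expect_error(filterCandidates(toy$vt, "NOBODY", toy$gm), "unknown")
  empty <- VariantTable(variantData(toy$vt)[0, ])
  emptyGm <- GenotypeMatrix(matrix("present", 3, 0,
                                   dimnames = list(c("S1", "S2", "S3"),
                                                   character())))
  expect_equal(nrow(variantData(
    filterCandidates(empty, c("S1", "S2"), emptyGm))), 0)
})

test_that("the MAF threshold is inclusive at exactly 1 percent", {
  toy <- toyFilterSet()
  v <- variantData(toy$vt)
  v$ac[1] <- 2500L; v$an[1] <- 250000L    # MAF exactly 0.01
  kept <- filterCandidates(VariantTable(v), c("S1", "S2", "S3"), toy$gm)
  expect_true("PLANT" %in% variantData(kept)$gene)
})

test_that("filterCandidates is idempotent", {
  d <- generateFamilyDataset(familySimConfig(seed = 31))
  sharedIn <- paste0("A", 1:4)
  once <- filterCandidates(d$variants, sharedIn, d$genotypes)
  keptIds <- paste0(variantData(once)$gene, ":", variantData(once)$protein)
  gmOnce <- GenotypeMatrix(
    genotypeCalls(d$genotypes)[, keptIds, drop = FALSE])
  twice <- filterCandidates(once, sharedIn, gmOnce)
  expect_equal(variantData(twice), variantData(once))
})

test_that("published family genotypes segregate as reported", {
  verd <- assessCosegregation(fx$genotypes, fx$pedigree,
                              filterConfig(maxPhenocopies = 1,
                                           maxUnaffectedCarriers = 0))
  passGenes <- sub(":.*", "", verd$variant_id[verd$passes])
  expect_setequal(passGenes, c("CFAP65", "RFT1", "NRXN2", "TEP1"))
  ccnf <- verd[verd$variant_id == "CCNF:p.C363S", ]
  expect_false(ccnf$passes)
  expect_equal(ccnf$unaffected_carriers, 3)

  strict <- assessCosegregation(fx$genotypes, fx$pedigree,
                                filterConfig(maxPhenocopies = 0))
  expect_equal(sub(":.*", "", strict$variant_id[strict$passes]), "CFAP65")
})

test_that("an all-absent variant fails with zero affected carriers", {
  calls <- genotypeCalls(fx$genotypes)
  calls[, 1] <- "absent"
  verd <- assessCosegregation(GenotypeMatrix(calls), fx$pedigree)
  expect_equal(verd$affected_carriers[1], 0)
  expect_false(verd$passes[1])
})

test_that("a pedigree with no typed affecteds is rejected", {
  calls <- matrix("present", 1, 1, dimnames = list("U1", "v1"))
  ped <- Pedigree("U1", affection = "unaffected")
  expect_error(assessCosegregation(GenotypeMatrix(calls), ped),
               "typed affected")
})

randomMatrix <- function(seed, nInd = 10, nVar = 20) {
  set.seed(seed)
  ids <- paste0("I", seq_len(nInd))
  calls <- matrix(sample(c("present", "absent", "untyped"), nInd * nVar,
                         replace = TRUE, prob = c(0.4, 0.5, 0.1)),
                  nInd, nVar, dimnames = list(ids, paste0("v", seq_len(nVar))))
  aff <- sample(c("affected", "unaffected"), nInd, replace = TRUE)
  aff[1] <- "affected"
  calls[1, ] <- "present"                 # guarantee a typed affected
  list(gm = GenotypeMatrix(calls),
       ped = Pedigree(ids, affection = aff))
}

test_that("verdicts match a brute-force recount on random matrices", {
  for (seed in 1:5) {
    rm <- randomMatrix(seed)
    verd <- assessCosegregation(rm$gm, rm$ped)
    m <- pedMembers(rm$ped)
    oracle <- oracleSegregation(genotypeCalls(rm$gm),
                                m$id[m$affection == "affected"],
                                m$id[m$affection == "unaffected"])
    expect_equal(verd$affected_carriers, unname(oracle[, 1]))
    expect_equal(verd$affected_noncarriers, unname(oracle[, 2]))
    expect_equal(verd$unaffected_carriers, unname(oracle[, 3]))
    ## carrier + noncarrier tallies cover every typed affected
    typedAff <- colSums(
      genotypeCalls(rm$gm)[m$id[m$affection == "affected"], ,
                           drop = FALSE] != "untyped")
    expect_equal(verd$affected_carriers + verd$affected_noncarriers,
                 unname(typedAff))
  }
})

test_that("loosening phenocopy or carrier budgets never shrinks the pass set", {
  for (seed in 1:3) {
    rm <- randomMatrix(seed + 100)
    passSet <- function(p, u)
      with(assessCosegregation(rm$gm, rm$ped,
                               filterConfig(maxPhenocopies = p,
                                            maxUnaffectedCarriers = u)),
           variant_id[passes])
    for (p in 0:3) for (u in 0:2) {
      expect_true(all(passSet(p, u) %in% passSet(p + 1, u)))
      expect_true(all(passSet(p, u) %in% passSet(p, u + 1)))
    }
  }
})
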