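fx <- builtinFixtures()

test_that("packaged variant table reads with all printed scores intact", {
  v <- variantData(fx$variants)
  expect_equal(nrow(v), 5)
  expect_equal(v$cadd[v$gene == "NRXN2"], 29.50)
  expect_equal(v$gerp[v$gene == "TEP1"], -8.29)
  expect_true(all(v$consequence == "missense"))
  expect_true(all(v$zygosity == "het"))
})

test_that("VCF and TSV dialects load identical annotations", {
  vcfPath <- system.file("extdata", "table2_variants.vcf",
                         package = "prioMD")
  vv <- variantData(readVariantTable(vcfPath, "vcf"))
  tv <- variantData(fx$variants)
  ## VCF records are coordinate-sorted; align by gene
  vv <- vv[match(tv$gene, vv$gene), ]
  for (col in c("gene", "cdna", "protein", "sift", "polyphen2",
                "mutationtaster", "gerp", "cadd", "condel", "ac", "an"))
    expect_equal(vv[[col]], tv[[col]], ignore_attr = TRUE, label = col)
})

test_that("an empty TSV body yields an empty table", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(variantColumns(), collapse = "\t"), p)
  expect_equal(nrow(variantData(readVariantTable(p, "tsv"))), 0)
})

test_that("a synthetic 50-variant table round-trips losslessly", {
  d <- generateFamilyDataset(familySimConfig(nBackgroundVariants = 49,
                                             seed = 11))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(d$variants, p)
  back <- readVariantTable(p, "tsv")
  expect_equal(variantData(back), variantData(d$variants))
})

test_that("malformed rows are rejected with their line number", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(variantColumns(), collapse = "\t"),
               "too\tfew\tfields"), p)
  expect_error(readVariantTable(p, "tsv"), "line 2")
})

test_that("GERP scores outside the published range fail validation", {
  v <- variantData(fx$variants)
  v$gerp[1] <- 7.5
  expect_error(VariantTable(v), "GERP")
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(v, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readVariantTable(p, "tsv"), "GERP")
})

test_that("the family pedigree decodes affection and sequencing flags", {
  m <- pedMembers(fx$pedigree)
  expect_equal(nrow(m), 9)
  expect_equal(sum(m$affection == "affected"), 5)
  expect_equal(sum(m$affection == "unaffected"), 4)
  expect_equal(sort(m$id[m$sequenced]), sort(c("III-7", "III-8", "IV-2")))
})

test_that("PED edge cases: single founder, unknown status, duplicates", {
  p <- withr::local_tempfile(fileext = ".ped")
  writeLines("F1\tX1\t0\t0\t1\t2", p)
  expect_equal(nrow(pedMembers(readPedigree(p))), 1)

  writeLines(c("F1\tX1\t0\t0\t1\t2", "F1\tX2\t0\t0\t2\t0"), p)
  ped <- readPedigree(p)
  expect_equal(pedMembers(ped)$affection[2], "unknown")
  calls <- matrix("present", 2, 1, dimnames = list(c("X1", "X2"), "v1"))
  verd <- assessCosegregation(GenotypeMatrix(calls), ped)
  expect_equal(verd$affected_carriers, 1)   # unknown member contributes 0
  expect_equal(verd$unaffected_carriers, 0)

  writeLines(c("F1\tX1\t0\t0\t1\t2", "F1\tX1\t0\t0\t1\t2"), p)
  expect_error(readPedigree(p), "duplicate")
})

pdbLines <- function(frames) {
  out <- character()
  for (f in seq_along(frames)) {
    out <- c(out, sprintf("MODEL %8d", f))
    xyz <- frames[[f]]
    for (i in seq_len(nrow(xyz)))
      out <- c(out, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

test_that("multi-model PDB reads as a trajectory with Angstrom -> nm", {
  p <- withr::local_tempfile(fileext = ".pdb")
  f1 <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  f2 <- f1 + 1
  writeLines(pdbLines(list(f1, f2)), p)
  tr <- readTrajectory(p, "pdb_multimodel")
  expect_equal(nFrames(tr$trajectory), 2)
  expect_equal(frameCoords(tr$trajectory, 1)[1, ], c(1, 0, 0))  # 10 A = 1 nm
  expect_equal(atomData(tr$structure)$mass[1], 12.011)
})

test_that("models with differing atom counts are rejected", {
  p <- withr::local_tempfile(fileext = ".pdb")
  f1 <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  lines <- pdbLines(list(f1, f1))
  lines <- lines[-8]                      # drop one ATOM from model 2
  writeLines(lines, p)
  expect_error(readTrajectory(p, "pdb_multimodel"), "differing atom counts")
})

test_that("the XYZ text dialect round-trips byte-identically", {
  d <- generateTrajectory(trajSimConfig(nParticles = 8, nFrames = 5,
                                        seed = 21))
  p1 <- withr::local_tempfile(fileext = ".xyz")
  p2 <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectoryXYZ(d$trajectory, p1)
  back <- readTrajectory(p1, "xyz_text")
  writeTrajectoryXYZ(back$trajectory, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(frameTime(back$trajectory), frameTime(d$trajectory))
})

test_that("candidate reports round-trip through TSV", {
  verd <- assessCosegregation(fx$genotypes, fx$pedigree)
  ranked <- rankCandidates(consensusProfile(fx$variants), verd)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeCandidateReport(ranked, p)
  back <- readCandidateReport(p)
  expect_equal(back$gene, ranked$gene)
  expect_equal(back$rank, ranked$rank)
  expect_equal(back$deleterious_votes, ranked$deleterious_votes)
  expect_equal(back$maf, ranked$maf, tolerance = 1e-12)

  writeCandidateReport(data.frame(), p)   # empty input -> header only
  expect_equal(nrow(readCandidateReport(p)), 0)
})
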