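test_that("kdToPkd matches the nanomolar log transform and inverts", {
  expect_equal(kdToPkd(1e9), 0)
  expect_equal(kdToPkd(1), 9)
  expect_equal(kdToPkd(1e4), 5)
  withr::with_seed(5, {
    pkd <- runif(20, 0, 12)
    expect_equal(kdToPkd(1e9 * 10^-pkd), pkd, tolerance = 1e-9)
  })
  expect_error(kdToPkd(0), "positive")
  expect_error(kdToPkd(-3), "positive")
  expect_error(kdToPkd(NaN), "positive")
})

writeFixtureFiles <- function(dir) {
  pf <- file.path(dir, "prot.tsv")
  lf <- file.path(dir, "lig.tsv")
  writeLines(c("# proteins", "p1\tMKVLW", "p2\tMKILW"), pf)
  writeLines(c("l1\tCCO", "l2\tC=CN"), lf)
  list(proteins = pf, ligands = lf)
}

test_that("triples and dense loaders build referentially intact datasets", {
  dir <- withr::local_tempdir()
  fx <- writeFixtureFiles(dir)
  af <- file.path(dir, "aff.tsv")
  writeLines(c("p1\tl1\t7.5", "p2\tl2\t5.0", "p1\tl2\t6.1"), af)
  ds <- loadAffinityDataset(fx$proteins, fx$ligands, af, measure = "Kd")
  expect_s4_class(ds, "AffinityDataset")
  expect_equal(nrow(affinityRecords(ds)), 3)
  expect_identical(unique(affinityRecords(ds)$measure), "Kd")

  ## dense matrix: one NaN cell drops to 3 records
  dm <- file.path(dir, "dense.csv")
  writeLines(c("id,l1,l2", "p1,7.5,NaN", "p2,5.0,6.1"), dm)
  ds2 <- loadAffinityDataset(fx$proteins, fx$ligands, dm,
                             format = "dense_matrix")
  expect_equal(nrow(affinityRecords(ds2)), 3)
  ## FASTA protein input reads identically to TSV
  fa <- file.path(dir, "prot.fa")
  writeLines(c(">p1 desc", "MKVLW", ">p2", "MKILW"), fa)
  ds3 <- loadAffinityDataset(fa, fx$ligands, af)
  expect_identical(as.character(proteinSequences(ds3)),
                   as.character(proteinSequences(ds)))
})

test_that("loader errors are specific", {
  dir <- withr::local_tempdir()
  fx <- writeFixtureFiles(dir)
  af <- file.path(dir, "aff.tsv")
  writeLines("p1\tl9\t7.5", af)
  expect_error(loadAffinityDataset(fx$proteins, fx$ligands, af),
               "unknown ligand")
  writeLines("p1\tl1", af)
  expect_error(loadAffinityDataset(fx$proteins, fx$ligands, af),
               "line 1")
  writeLines(character(0), af)
  ds <- loadAffinityDataset(fx$proteins, fx$ligands, af)
  expect_equal(nrow(affinityRecords(ds)), 0)
  expect_error(loadAffinityDataset("nope.tsv", fx$ligands, af),
               "no such file")
})

test_that("duplicate ligand ids keep the first SMILES with a warning", {
  dir <- withr::local_tempdir()
  fx <- writeFixtureFiles(dir)
  lf2 <- file.path(dir, "lig2.tsv")
  writeLines(c("l1\tCCO", "l1\tOCC", "l2\tC=CN"), lf2)
  af <- file.path(dir, "aff.tsv")
  writeLines("p1\tl1\t7.5", af)
  expect_warning(
    ds <- loadAffinityDataset(fx$proteins, lf2, af),
    "multiple SMILES")
  expect_identical(unname(ligandSmiles(ds)["l1"]), "CCO")
  expect_identical(datasetMetadata(ds)$droppedSmiles, "l1")
})

test_that("harmonizeDuplicates applies the max/mean/error policies", {
  ds <- AffinityDataset(
    proteins = c(p1 = "MKVL"), ligands = c(l1 = "CCO"),
    records = data.frame(protein_id = "p1", ligand_id = "l1",
                         value = c(5.0, 7.2)))
  expect_equal(harmonizeDuplicates(ds, "max")@records$value, 7.2)
  expect_equal(harmonizeDuplicates(ds, "mean")@records$value, 6.1)
  expect_error(harmonizeDuplicates(ds, "error"), "duplicate")
  ## no duplicates: identity
  one <- AffinityDataset(proteins = c(p1 = "MKVL"), ligands = c(l1 = "CCO"),
                         records = data.frame(protein_id = "p1",
                                              ligand_id = "l1", value = 5))
  expect_identical(harmonizeDuplicates(one, "max")@records,
                   one@records)
})

test_that("deduplicateProteins is a deterministic greedy filter", {
  panel <- c(makePanel(3, 40, seed = 13),
             p4 = unname(makePanel(3, 40, seed = 13)[1]))  # p4 == p1
  ds <- AffinityDataset(
    proteins = panel, ligands = c(l1 = "CCO"),
    records = data.frame(protein_id = names(panel), ligand_id = "l1",
                         value = 5:8))
  sim <- swSimilarityMatrix(panel)
  thinned <- deduplicateProteins(ds, sim, 0.99)
  expect_identical(names(proteinSequences(thinned)), c("p1", "p2", "p3"))
  expect_equal(nrow(affinityRecords(thinned)), 3)
  expect_identical(datasetMetadata(thinned)$removedRedundant, "p4")
  ## threshold 1 keeps non-identical panels whole; threshold 0 keeps only
  ## the first entry
  expect_equal(length(proteinSequences(
    deduplicateProteins(ds, sim, 1.0))), 3)  # p4 still = p1, sim 1 >= 1
  expect_identical(names(proteinSequences(
    deduplicateProteins(ds, sim, 0))), "p1")
  noDup <- AffinityDataset(proteins = panel[1:3], ligands = c(l1 = "CCO"),
                           records = data.frame(protein_id = "p1",
                                                ligand_id = "l1", value = 5))
  expect_identical(
    names(proteinSequences(deduplicateProteins(
      noDup, swSimilarityMatrix(panel[1:3]), 1.0))),
    c("p1", "p2", "p3"))
})
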