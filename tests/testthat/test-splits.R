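gridDataset <- function(nProt, nLig, seed = 1L) {
  prot <- makePanel(nProt, 20, seed = seed)
  lig <- stats::setNames(rep("CCO", nLig), paste0("l", seq_len(nLig)))
  grid <- expand.grid(protein_id = names(prot), ligand_id = names(lig),
                      stringsAsFactors = FALSE)
  AffinityDataset(prot, lig,
                  data.frame(grid, value = seq_len(nrow(grid))))
}

test_that("warm folds partition records and are seed-deterministic", {
  ds <- gridDataset(6, 5)
  spec <- SplitSpec("warm", nFolds = 4L, seed = 9L)
  folds <- makeSplits(ds, spec)
  test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(test, seq_len(30L))            # disjoint cover
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:30)
  }
  expect_identical(makeSplits(ds, spec), folds)   # same seed, same folds
  expect_false(identical(makeSplits(ds, SplitSpec("warm", 4L, 10L)), folds))
})

test_that("cold modes never leak their held-out entities", {
  ds <- gridDataset(8, 6)
  rec <- affinityRecords(ds)
  for (mode in c("cold_protein", "cold_drug")) {
    folds <- makeSplits(ds, SplitSpec(mode, nFolds = 3L, seed = 2L))
    col <- if (mode == "cold_protein") "protein_id" else "ligand_id"
    test <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_identical(test, seq_len(nrow(rec)))
    for (f in folds)
      expect_length(intersect(rec[[col]][f$train], rec[[col]][f$test]), 0)
  }
})

test_that("cold_pair folds hold out proteins AND ligands simultaneously", {
  ds <- gridDataset(10, 10)
  rec <- affinityRecords(ds)
  folds <- makeSplits(ds, SplitSpec("cold_pair", nFolds = 2L, seed = 4L))
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(anyDuplicated(tests), 0)           # disjoint across folds
  for (f in folds) {
    expect_gt(length(f$test), 0)
    expect_length(intersect(rec$protein_id[f$train],
                            rec$protein_id[f$test]), 0)
    expect_length(intersect(rec$ligand_id[f$train],
                            rec$ligand_id[f$test]), 0)
  }
})

test_that("group_holdout isolates every record touching the group", {
  ds <- gridDataset(5, 4)
  rec <- affinityRecords(ds)
  spec <- SplitSpec("group_holdout", holdoutGroup = c("p2", "p4"))
  folds <- makeSplits(ds, spec)
  expect_length(folds, 1)
  expect_setequal(rec$protein_id[folds[[1]]$test], c("p2", "p4"))
  expect_false(any(c("p2", "p4") %in% rec$protein_id[folds[[1]]$train]))
  expect_error(makeSplits(ds, SplitSpec("group_holdout",
                                        holdoutGroup = "zz")), "unknown")
})

test_that("impossible fold requests fail as configuration errors", {
  ds <- gridDataset(3, 3)
  expect_error(makeSplits(ds, SplitSpec("cold_protein", nFolds = 5L)),
               "cannot make")
  expect_error(SplitSpec("warm", nFolds = 1L), "nFolds")
  expect_error(SplitSpec("group_holdout"), "holdoutGroup")
})

test_that("shuffleLabels permutes exactly the partitions it should", {
  ds <- gridDataset(6, 5, seed = 3L)
  folds <- makeSplits(ds, SplitSpec("warm", nFolds = 3L, seed = 1L))
  rec <- affinityRecords(ds)
  s1 <- shuffleLabels(ds, "S1", folds, seed = 11L)
  s2 <- shuffleLabels(ds, "S2", folds, seed = 11L)
  s3 <- shuffleLabels(ds, "S3", folds, seed = 11L)
  for (i in seq_along(folds)) {
    trueTr <- rec[folds[[i]]$train, ]
    trueTe <- rec[folds[[i]]$test, ]
    ## multisets preserved wherever shuffled
    expect_setequal(s1[[i]]$train$value, trueTr$value)
    expect_setequal(s1[[i]]$test$value, trueTe$value)
    ## S2: test untouched; S3: train untouched
    expect_identical(s2[[i]]$test, trueTe)
    expect_identical(s3[[i]]$train, trueTr)
    ## pairings broken but sequences untouched
    expect_identical(s1[[i]]$train[c("protein_id", "ligand_id")],
                     trueTr[c("protein_id", "ligand_id")])
    expect_false(identical(s1[[i]]$train$value, trueTr$value))
  }
  ## determinism under seed
  expect_identical(shuffleLabels(ds, "S3", folds, seed = 11L), s3)
})
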