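aa20sch <- flatScheme(c("M", "K", "V", "L", "W"), gapOpen = 1, gapExtend = 1)

test_that("swScore reproduces hand-checked local alignments", {
  expect_equal(swScore("MKV", "MKV", aa20sch), 6)           # 3 matches x 2
  expect_equal(swScore("MKV", "WWW", aa20sch), 0)           # empty alignment
  expect_equal(swScore("MKV", "WWW", aa20sch),
               swScore("WWW", "MKV", aa20sch))
  expect_error(swScore("MKB", "MKV", aa20sch), "not covered")
  expect_error(swScore("", "MKV", aa20sch), "non-empty")
})

test_that("swScore agrees with the BLOSUM62 brute-force oracle", {
  sch <- AlignmentScheme(gapOpen = 10, gapExtend = 1)
  expect_equal(swScore("HEAGAWGHEE", "PAWHEAE", sch),
               swOracle("HEAGAWGHEE", "PAWHEAE", sch))
  ## X is neutral: alignments never gain or lose through it
  expect_equal(swScore("MKXV", "MKXV", sch),
               swOracle("MKXV", "MKXV", sch))
})

test_that("the DP oracle itself matches exhaustive alignment enumeration", {
  sch <- flatScheme(c("A", "C", "G", "T"), gapOpen = 2, gapExtend = 1)
  cases <- withr::with_seed(42, replicate(12, paste(
    sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
    collapse = ""), simplify = TRUE))
  for (i in seq(1, 11, by = 2))
    expect_equal(swOracle(cases[i], cases[i + 1], sch),
                 swEnumerate(cases[i], cases[i + 1], sch),
                 info = paste(cases[i], cases[i + 1]))
})

test_that("normalizedSW is a unit-diagonal similarity in [0,1]", {
  expect_equal(normalizedSW("MKVL", "MKVL", aa20sch), 1)
  expect_equal(normalizedSW("MKV", "WWW", aa20sch), 0)
  expect_equal(normalizedSW("MKVL", "MKV", aa20sch), 6 / sqrt(8 * 6))
  expect_error(normalizedSW("X", "X", AlignmentScheme()), "degenerate")
})

test_that("swSimilarityMatrix matches entrywise normalizedSW calls", {
  panel <- makePanel(5, 40, seed = 101)
  sch <- AlignmentScheme()
  sm <- swSimilarityMatrix(panel, sch)
  expect_s4_class(sm, "SimilarityMatrix")
  expect_identical(similarityKind(sm), "SW")
  v <- as.matrix(sm)
  for (i in 1:5) for (j in 1:5)
    expect_identical(unname(v[i, j]),
                     if (i == j) 1 else normalizedSW(panel[i], panel[j], sch))
})

test_that("SW matrix contracts hold on random panels", {
  panel <- makePanel(10, 30, seed = 55)
  v <- as.matrix(swSimilarityMatrix(panel))
  expect_identical(v, t(v))
  expect_identical(unname(diag(v)), rep(1, 10))
  expect_true(all(v >= 0 & v <= 1))
  ## panel reordering permutes rows/columns consistently
  perm <- c(3, 1, 2, 5, 4, 10, 9, 6, 8, 7)
  v2 <- as.matrix(swSimilarityMatrix(panel[perm]))
  expect_equal(unname(v2), unname(v[perm, perm]))
  ## identical sequences give the all-ones matrix
  same <- stats::setNames(rep(panel[1], 3), c("a", "b", "c"))
  expect_identical(unname(as.matrix(swSimilarityMatrix(same))),
                   matrix(1, 3, 3))
})

test_that("self-concatenation never lowers the local alignment score", {
  sch <- AlignmentScheme()
  withr::with_seed(77, {
    for (rep in 1:10) {
      a <- makePanel(1, sample(5:25, 1), seed = rep)[[1]]
      b <- makePanel(1, sample(5:25, 1), seed = rep + 100)[[1]]
      expect_gte(swScore(a, paste0(b, b), sch), swScore(a, b, sch))
    }
  })
})

test_that("similarity matrices round-trip through CSV + sidecar", {
  panel <- makePanel(4, 25, seed = 9)
  sm <- swSimilarityMatrix(panel)
  path <- file.path(withr::local_tempdir(), "sw.csv")
  writeSimilarityMatrix(sm, path)
  back <- readSimilarityMatrix(path)
  expect_identical(similarityKind(back), "SW")
  expect_identical(similarityIds(back), similarityIds(sm))
  expect_equal(back@values, sm@values, tolerance = 1e-12)
  expect_equal(back@metadata$scheme$gapOpen, 10)
})
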