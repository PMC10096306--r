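mkSim <- function(v, kind, ids = letters[seq_len(nrow(v))]) {
  methods::new("SimilarityMatrix", ids = ids, values = v, kind = kind)
}

test_that("combineMatrices implements the four combiners exactly", {
  sw <- mkSim(matrix(c(1, 0.8, 0.8, 1), 2), "SW")
  nc <- mkSim(matrix(c(0.9, 0.5, 0.5, 0.92), 2), "NCD_SIM")
  prod <- combineMatrices(sw, nc, EncoderConfig("product"))
  expect_identical(similarityKind(prod), "BICOMP")
  expect_equal(prod@values[1, 2], 0.4)          # 0.8 * 0.5
  expect_equal(unname(diag(prod@values)), c(1, 1))
  ## weighted sum at w = 1 reduces to SW off-diagonal
  w1 <- combineMatrices(sw, nc, EncoderConfig("weighted_sum", weight = 1))
  expect_equal(w1@values[1, 2], sw@values[1, 2])
  w0 <- combineMatrices(sw, nc, EncoderConfig("weighted_sum", weight = 0))
  expect_equal(w0@values[1, 2], nc@values[1, 2])
  ## ablation pass-throughs
  expect_equal(combineMatrices(sw, nc, EncoderConfig("sw_only"))@values[1, 2],
               0.8)
  expect_equal(combineMatrices(sw, nc, EncoderConfig("ncd_only"))@values[1, 2],
               0.5)
  ## id-order mismatch is an integrity error
  nc2 <- mkSim(nc@values, "NCD_SIM", ids = c("b", "a"))
  expect_error(combineMatrices(sw, nc2), "id orders")
})

test_that("product combiner is the exact Hadamard product off-diagonal", {
  panel <- makePanel(6, 80, seed = 17)
  sw <- swSimilarityMatrix(panel)
  nc <- ncdSimilarityMatrix(panel)
  bc <- combineMatrices(sw, nc)
  off <- upper.tri(bc@values)
  expect_identical(bc@values[off], (sw@values * nc@values)[off])
  ## a product of unit-interval factors never exceeds either factor
  ## (off-diagonal; the combined diagonal is forced to 1 by convention)
  expect_true(all(bc@values[off] <= pmin(sw@values, nc@values)[off] + 1e-15))
  expect_equal(unname(diag(bc@values)), rep(1, 6))
})

test_that("encodeProtein equals matrix rows for panel members", {
  panel <- makePanel(7, 60, seed = 23)
  sw <- swSimilarityMatrix(panel)
  nc <- ncdSimilarityMatrix(panel)
  bc <- combineMatrices(sw, nc)
  v <- encodeProtein(panel[1], panel, cache = bc)
  expect_length(v, 7)
  expect_identical(unname(v), unname(bc@values[1, ]))
  ## same answer through the sw/ncd cache route
  v2 <- encodeProtein(panel[1], panel, cache = list(sw = sw, ncd = nc))
  expect_identical(v2, v)
  ## an unseen protein with identical sequence reproduces the row up to
  ## the forced self-similarity diagonal entry
  ghost <- stats::setNames(unname(panel[4]), "ghost")
  v3 <- encodeProtein(ghost, panel)
  expect_identical(names(v3), names(panel))
  expect_equal(unname(v3[-4]), unname(bc@values[4, -4]), tolerance = 1e-12)
  expect_lt(abs(v3[4] - 1), 0.2)   # NCD self-similarity < 1, SW = 1
})

test_that("SMILES vocabulary is first-appearance ordered and stable", {
  expect_identical(buildSmilesVocab("CCO"), c(C = 1L, O = 2L))
  expect_identical(buildSmilesVocab(c("CN", "NC")), c(C = 1L, N = 2L))
  smiles <- c("C1=CC=CC=C1", "CC(=O)O", "c1ccccc1")
  expect_identical(buildSmilesVocab(smiles), buildSmilesVocab(smiles))
  expect_error(buildSmilesVocab(character(0)), "at least one")
})

test_that("encodeLigand pads, truncates and flags unknown characters", {
  v <- c(C = 1L, O = 2L)
  expect_identical(encodeLigand("CCO", v, 5), c(1L, 1L, 2L, 0L, 0L))
  expect_identical(encodeLigand("CCO", v, 2), c(1L, 1L))
  expect_warning(got <- encodeLigand("CS", v, 4), "unknown")
  expect_identical(got, c(1L, 3L, 0L, 0L))     # unknown code = K + 1
  expect_error(encodeLigand("", v, 4), "empty")
  expect_error(encodeLigand("CCO", v, 0), "maxLen")
})

test_that("ligand encodings always have exactly maxLen entries", {
  alphabet <- c("C", "N", "O", "S", "=", "#", "(", ")", "1", "2", "c", "n")
  vocab <- buildSmilesVocab(paste(alphabet[1:8], collapse = ""))
  withr::with_seed(99, {
    for (i in 1:300) {
      L <- sample(1:30, 1)
      s <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
      maxLen <- sample(1:25, 1)
      codes <- suppressWarnings(encodeLigand(s, vocab, maxLen))
      expect_length(codes, maxLen)
      expect_true(all(codes >= 0))
      ## trailing padding stays contiguous zeros
      if (L < maxLen) expect_true(all(codes[(L + 1):maxLen] == 0L))
    }
  })
})

test_that("combined similarity separates planted families", {
  spec <- SyntheticSpec(nFamilies = 3L, membersPerFamily = 6L,
                        proteinLength = 300L, mutationRate = 0.1,
                        seed = 15L)
  prot <- generateProteins(spec)
  fam <- attr(prot, "family")
  bc <- combineMatrices(swSimilarityMatrix(prot),
                        ncdSimilarityMatrix(prot))
  v <- bc@values
  same <- outer(fam, fam, "==") & upper.tri(v)
  diff <- outer(fam, fam, "!=") & upper.tri(v)
  expect_gt(mean(v[same]) - mean(v[diff]), 0.05)
})
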