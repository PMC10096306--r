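vocab5 <- stats::setNames(1:5, c("C", "N", "O", "(", ")"))

test_that("model construction is seeded and shape-consistent", {
  cfg <- tinyModelConfig(seed = 4L)
  m1 <- buildModel(cfg, nPanel = 9L, vocab = vocab5, maxLen = 20L)
  m2 <- buildModel(cfg, nPanel = 9L, vocab = vocab5, maxLen = 20L)
  expect_identical(m1@weights, m2@weights)           # identical checksums
  m3 <- buildModel(tinyModelConfig(seed = 5L), 9L, vocab5, 20L)
  expect_false(identical(m1@weights, m3@weights))
  ## drug branch forward: (batch, pooled-feature-size)
  withr::with_seed(1, {
    P <- matrix(runif(6 * 9), 6, 9)
    D <- matrix(sample(0:6, 6 * 20, TRUE), 6, 20)
  })
  fw <- compDTA:::.netForward(m1@weights, cfg, P, D, FALSE,
                              codeScale = 6)
  expect_length(fw$pred, 6)
  ## too-short SMILES window for three valid convolutions
  expect_error(buildModel(cfg, 9L, vocab5, 5L), "too short")
  ## fc drug branch has no convolutional parameters
  mfc <- buildModel(tinyModelConfig(drugBranch = "fc"), 9L, vocab5, 20L)
  expect_false(any(grepl("conv|emb|sep", names(mfc@weights))))
})

test_that("parameter counts match the closed forms", {
  expect_identical(separableConv1dParams(8, 32, 32, bias = FALSE), 1280L)
  expect_identical(conv1dParams(8, 32, 32, bias = FALSE), 8192L)
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, nPanel = 9L, vocab = vocab5, maxLen = 20L)
  w <- m@weights
  F1 <- cfg@nFilters; f <- cfg@filterLength; D <- cfg@embeddingDim
  ## separable layer weights equal the closed-form decomposition
  expect_identical(length(w$sepDwW) + length(w$sepPwW),
                   as.integer(separableConv1dParams(f, F1, F1,
                                                    bias = FALSE)))
  expect_identical(length(w$conv2W),
                   as.integer(conv1dParams(f, F1, F1, bias = FALSE)))
  ## the separable substitution saves exactly the closed-form difference
  expect_lt(length(w$sepDwW) + length(w$sepPwW), length(w$conv2W))
  expect_identical(length(w$conv2W) - (length(w$sepDwW) + length(w$sepPwW)),
                   as.integer(conv1dParams(f, F1, F1, FALSE) -
                              separableConv1dParams(f, F1, F1, FALSE)))
  ## full count = sum of the per-layer closed forms
  manual <- (nrow(w$emb) * D) +
    conv1dParams(f, D, F1) + conv1dParams(f, F1, F1) +
    separableConv1dParams(f, F1, F1) +
    sum((c(9, cfg@proteinFcSizes[1:2]) + 1) * cfg@proteinFcSizes) +
    sum((c(cfg@proteinFcSizes[3] + F1,
           cfg@predictorFcSizes[1:2]) + 1) * cfg@predictorFcSizes) +
    (cfg@predictorFcSizes[3] + 1)
  expect_identical(countTrainableParameters(m), as.integer(manual))
  ## doubling filters strictly increases the count
  m2 <- buildModel(ModelConfig(nFilters = 16L, filterLength = 4L,
                               embeddingDim = 8L,
                               proteinFcSizes = c(16L, 16L, 8L),
                               predictorFcSizes = c(16L, 16L, 8L)),
                   9L, vocab5, 20L)
  expect_gt(countTrainableParameters(m2), countTrainableParameters(m))
})

test_that("analytic gradients match finite differences", {
  cfg <- ModelConfig(nFilters = 3L, filterLength = 3L, embeddingDim = 4L,
                     proteinFcSizes = c(5L, 4L, 3L),
                     predictorFcSizes = c(6L, 5L, 4L), dropout = 0,
                     seed = 9L)
  m <- buildModel(cfg, 7L, vocab5, 12L)
  w <- m@weights
  withr::with_seed(3, {
    P <- matrix(runif(4 * 7), 4, 7)
    D <- matrix(sample(0:6, 4 * 12, TRUE), 4, 12)
    y <- runif(4, 4, 10)
  })
  loss <- function(w)
    mean((compDTA:::.netForward(w, cfg, P, D, FALSE, 7)$pred - y)^2)
  fw <- compDTA:::.netForward(w, cfg, P, D, FALSE, 7)
  g <- compDTA:::.netBackward(w, cfg, fw$cache, 2 * (fw$pred - y) / 4)
  eps <- 1e-6
  withr::with_seed(4, {
    for (nm in names(g)) {
      i <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss(wp) - loss(wm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = paste("gradient of", nm))
    }
  })
})

## shared tiny training fixture: encode once, reuse across blocks
trainFixture <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      d <- tinyDataset(seed = 7L, nFamilies = 3L, members = 4L,
                       len = 80L, nLigands = 6L)
      enc <- buildEncoderSet(d, affinityRecords(d))
      ds <<- list(ds = d, enc = enc,
                  all = encodeRecordsForModel(d, affinityRecords(d), enc))
    }
    ds
  }
})

test_that("training reduces the loss and is exactly reproducible", {
  fx <- trainFixture()
  cfg <- tinyModelConfig(seed = 2L, epochs = 10L)
  m <- buildModel(cfg, length(fx$enc$panelIds), fx$enc$vocab, fx$enc$maxLen)
  m@panelIds <- fx$enc$panelIds
  t1 <- trainModel(m, fx$all, fx$all)
  expect_true(t1@trained)
  expect_lte(t1@history$trainLoss[10], t1@history$trainLoss[1])
  ## bit-identical reruns from the same seed
  t2 <- trainModel(m, fx$all, fx$all)
  expect_identical(tail(t1@history$valLoss, 1), tail(t2@history$valLoss, 1))
  expect_identical(t1@weights, t2@weights)
})

test_that("training on constant labels converges to the constant", {
  fx <- trainFixture()
  const <- fx$all
  const$y <- rep(7, length(const$y))
  cfg <- tinyModelConfig(seed = 3L, epochs = 120L)
  cfg@learningRate <- 0.01   # plain bias-learning task; take bigger steps
  m <- buildModel(cfg, length(fx$enc$panelIds), fx$enc$vocab, fx$enc$maxLen)
  m@panelIds <- fx$enc$panelIds
  t <- trainModel(m, const, const)
  pred <- predictAffinity(t, const$P, const$D)
  expect_lt(mean((pred - 7)^2), 0.01)
})

test_that("prediction is a pure, order-preserving batch function", {
  fx <- trainFixture()
  cfg <- tinyModelConfig(seed = 6L, epochs = 2L)
  m <- buildModel(cfg, length(fx$enc$panelIds), fx$enc$vocab, fx$enc$maxLen)
  m@panelIds <- fx$enc$panelIds
  m <- trainModel(m, fx$all, fx$all)
  P <- fx$all$P; D <- fx$all$D
  p <- predictAffinity(m, P, D)
  expect_true(all(is.finite(p)))
  perm <- rev(seq_len(nrow(P)))
  expect_identical(predictAffinity(m, P[perm, ], D[perm, ]), p[perm])
  dup <- predictAffinity(m, P[c(1, 1), ], D[c(1, 1), ])
  expect_identical(dup[1], dup[2])
  expect_error(predictAffinity(m, P[, -1], D), "panel size")
  expect_error(predictAffinity(m, P, D[, -1]), "maxLen")
  expect_error(predictAffinity(m, P[-1, , drop = FALSE], D), "batch")
})

test_that("checkpoints round-trip through save/load", {
  fx <- trainFixture()
  cfg <- tinyModelConfig(seed = 8L, epochs = 2L)
  m <- buildModel(cfg, length(fx$enc$panelIds), fx$enc$vocab, fx$enc$maxLen)
  m@panelIds <- fx$enc$panelIds
  m <- trainModel(m, fx$all, fx$all)
  path <- file.path(withr::local_tempdir(), "model.rds")
  saveDTAModel(m, path)
  back <- loadDTAModel(path)
  expect_equal(predictAffinity(back, fx$all$P, fx$all$D),
               predictAffinity(m, fx$all$P, fx$all$D), tolerance = 1e-6)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(side$nParameters, countTrainableParameters(m))
  expect_identical(side$config$drugBranch, "cnn_sep")
})
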