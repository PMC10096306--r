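#' Construct a ModelConfig
#'
#' @param nFilters,filterLength number and length of convolution filters
#'   (the two numbers quoted in architecture shorthand like "(32, 8)").
#' @param embeddingDim SMILES embedding dimension.
#' @param proteinFcSizes,predictorFcSizes three layer widths each.
#' @param dropout predictor dropout rate.
#' @param learningRate,batchSize,epochs,patience training settings.
#' @param seed initialization/data-order seed.
#' @param drugBranch `"cnn_sep"` or `"fc"`.
#' @return a [ModelConfig-class].
#' @export
ModelConfig <- function(nFilters = 32L, filterLength = 8L,
                        embeddingDim = 128L,
                        proteinFcSizes = c(1024L, 1024L, 512L),
                        predictorFcSizes = c(1024L, 1024L, 512L),
                        dropout = 0.1, learningRate = 1e-3,
                        batchSize = 256L, epochs = 100L, patience = 15L,
                        seed = 1L, drugBranch = "cnn_sep") {
  methods::new("ModelConfig",
               nFilters = as.integer(nFilters),
               filterLength = as.integer(filterLength),
               embeddingDim = as.integer(embeddingDim),
               proteinFcSizes = as.integer(proteinFcSizes),
               predictorFcSizes = as.integer(predictorFcSizes),
               dropout = as.numeric(dropout),
               learningRate = as.numeric(learningRate),
               batchSize = as.integer(batchSize),
               epochs = as.integer(epochs), patience = as.integer(patience),
               seed = as.integer(seed), drugBranch = drugBranch)
}

#' Build an untrained two-branch affinity regressor
#'
#' Protein branch: the panel-similarity vector through three
#' fully-connected rectifier layers. Drug branch (`cnn_sep`): the code
#' vector through a character embedding, two 1-D convolutions, a separable
#' convolution (depthwise over positions within each channel, then
#' pointwise channel mixing) and a global max-pool. Branch outputs are
#' concatenated and passed through three fully-connected layers and a
#' scalar linear output. Weight initialization is seeded by
#' `cfg@seed`, so two builds from the same config are identical.
#'
#' @param cfg a [ModelConfig-class].
#' @param nPanel reference-panel size (protein input length).
#' @param vocab SMILES vocabulary from [buildSmilesVocab()].
#' @param maxLen fixed SMILES encoding length.
#' @return an untrained [DTAModel-class].
#' @export
buildModel <- function(cfg, nPanel, vocab, maxLen) {
  stopifnot(methods::is(cfg, "ModelConfig"))
  nPanel <- as.integer(nPanel); maxLen <- as.integer(maxLen)
  if (nPanel < 1L || maxLen < 1L)
    stop("nPanel and maxLen must be positive")
  if (cfg@drugBranch == "cnn_sep") {
    minLen <- 3L * (cfg@filterLength - 1L) + 1L
    if (maxLen < minLen)
      stop("maxLen ", maxLen, " too short for three valid convolutions of ",
           "filterLength ", cfg@filterLength, " (need >= ", minLen, ")")
  }
  w <- withRNG(cfg@seed, .initWeights(cfg, nPanel, length(vocab), maxLen))
  methods::new("DTAModel", config = cfg, weights = w,
               vocab = vocab, panelIds = character(nPanel),
               maxLen = maxLen, history = data.frame(), trained = FALSE)
}

#' @describeIn countTrainableParameters exact scalar count over all weight
#'   arrays.
#' @export
setMethod("countTrainableParameters", "DTAModel", function(m) {
  sum(vapply(m@weights, length, integer(1)))
})

#' Closed-form layer parameter counts
#'
#' `conv1dParams` counts a standard 1-D convolution
#' (`filterLength * inChannels * outChannels` + biases);
#' `separableConv1dParams` counts its separable replacement
#' (`filterLength * inChannels` depthwise + `inChannels * outChannels`
#' pointwise + biases). The difference is the parameter economy bought by
#' the separable decomposition: e.g. 1280 vs 8192 for filter length 8 and
#' 32 -> 32 channels without biases.
#'
#' @param filterLength,inChannels,outChannels layer shape.
#' @param bias include one bias per output channel?
#' @return integer parameter count.
#' @export
conv1dParams <- function(filterLength, inChannels, outChannels,
                         bias = TRUE) {
  as.integer(filterLength * inChannels * outChannels +
               if (bias) outChannels else 0L)
}

#' @rdname conv1dParams
#' @export
separableConv1dParams <- function(filterLength, inChannels, outChannels,
                                  bias = TRUE) {
  as.integer(filterLength * inChannels + inChannels * outChannels +
               if (bias) outChannels else 0L)
}

## assemble (P, D, y) design blocks for a set of affinity records
.designFor <- function(records, proteinVectors, ligandCodes) {
  P <- proteinVectors[records$protein_id, , drop = FALSE]
  D <- ligandCodes[records$ligand_id, , drop = FALSE]
  list(P = unname(P), D = unname(D), y = records$value)
}

.valLoss <- function(w, cfg, data, codeScale) {
  mean((.netForward(w, cfg, data$P, data$D, training = FALSE,
                    codeScale = codeScale)$pred - data$y)^2)
}

#' Train an affinity regressor
#'
#' Minimizes mean-squared error with the Adam optimizer, seeded epoch
#' shuffling, early stopping on validation MSE (patience
#' `cfg@patience`) and restoration of the best-validation weights.
#' Deterministic for a fixed config seed (single-threaded BLAS).
#'
#' @param m an untrained (or previously trained) [DTAModel-class].
#' @param train,val `list(P=, D=, y=)` design blocks: protein encoding
#'   matrix, ligand code matrix, affinity vector (see
#'   [encodeRecordsForModel()]).
#' @return the trained [DTAModel-class] with per-epoch `history`.
#' @export
trainModel <- function(m, train, val) {
  stopifnot(methods::is(m, "DTAModel"), length(train$y) > 0)
  cfg <- m@config
  w <- m@weights
  codeScale <- length(m@vocab) + 1L
  withRNG(cfg@seed + 1L, {
    state <- .adamInit(w)
    n <- length(train$y)
    bestLoss <- Inf; bestW <- w; bestEpoch <- 0L; wait <- 0L
    hist <- vector("list", cfg@epochs)
    for (epoch in seq_len(cfg@epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
        fw <- .netForward(w, cfg, train$P[idx, , drop = FALSE],
                          train$D[idx, , drop = FALSE], training = TRUE,
                          codeScale = codeScale)
        resid <- fw$pred - train$y[idx]
        if (any(!is.finite(resid)))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               "; reduce the learning rate")
        epochLoss <- epochLoss + sum(resid^2)
        g <- .netBackward(w, cfg, fw$cache, 2 * resid / length(idx))
        upd <- .adamStep(w, g, state, cfg@learningRate)
        w <- upd$w; state <- upd$state
      }
      vLoss <- if (length(val$y)) .valLoss(w, cfg, val, codeScale)
               else epochLoss / n
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epochLoss / n,
                                  valLoss = vLoss)
      if (vLoss < bestLoss - 1e-12) {
        bestLoss <- vLoss; bestW <- w; bestEpoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg@patience) break
      }
    }
    m@weights <- bestW
    m@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    m@trained <- TRUE
    m
  })
}

#' Predict binding affinities
#'
#' Pure function of the inputs and weights: batch order is preserved,
#' duplicated pairs give duplicated predictions, and no RNG is consumed
#' (dropout is inference-disabled).
#'
#' @param m a [DTAModel-class].
#' @param proteinVectors numeric matrix (n x panel size) of protein
#'   encodings.
#' @param ligandCodes integer matrix (n x maxLen) of SMILES codes.
#' @return numeric vector of predicted affinities.
#' @export
predictAffinity <- function(m, proteinVectors, ligandCodes) {
  stopifnot(methods::is(m, "DTAModel"))
  proteinVectors <- as.matrix(proteinVectors)
  ligandCodes <- as.matrix(ligandCodes)
  if (nrow(proteinVectors) != nrow(ligandCodes))
    stop("protein and ligand batches differ in size")
  if (ncol(proteinVectors) != length(m@panelIds))
    stop("protein encoding length ", ncol(proteinVectors),
         " does not match the model's panel size ", length(m@panelIds))
  if (ncol(ligandCodes) != m@maxLen)
    stop("ligand code length does not match the model's maxLen")
  .netForward(m@weights, m@config, unname(proteinVectors),
              unname(ligandCodes), training = FALSE,
              codeScale = length(m@vocab) + 1L)$pred
}

#' @describeIn predictAffinity `predict` method; `newdata` is a list with
#'   elements `P` and `D`.
#' @param object a [DTAModel-class].
#' @param newdata list with protein matrix `P` and code matrix `D`.
#' @param ... ignored.
#' @export
setMethod("predict", "DTAModel", function(object, newdata, ...) {
  predictAffinity(object, newdata$P, newdata$D)
})

setMethod("show", "DTAModel", function(object) {
  cfg <- object@config
  cat("DTAModel (", if (object@trained) "trained" else "untrained", ")\n",
      sep = "")
  cat("  drug branch:", cfg@drugBranch, "| filters", cfg@nFilters,
      "x length", cfg@filterLength, "\n")
  cat("  panel size:", length(object@panelIds), "| vocab",
      length(object@vocab), "| maxLen", object@maxLen, "\n")
  cat("  trainable parameters:", countTrainableParameters(object), "\n")
  if (nrow(object@history))
    cat("  best val MSE:", signif(min(object@history$valLoss), 5), "at epoch",
        object@history$epoch[which.min(object@history$valLoss)], "\n")
})

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file of the weights plus a JSON manifest
#' (`<path>.json`) describing the config, vocabulary, panel ids and
#' encoding length, so a checkpoint is self-describing.
#'
#' @param m a [DTAModel-class].
#' @param path checkpoint path (`.rds`).
#' @return `saveDTAModel` returns `path` invisibly; `loadDTAModel` the
#'   restored [DTAModel-class].
#' @export
saveDTAModel <- function(m, path) {
  stopifnot(methods::is(m, "DTAModel"))
  saveRDS(m, path)
  cfg <- m@config
  jsonlite::write_json(
    list(config = list(nFilters = cfg@nFilters,
                       filterLength = cfg@filterLength,
                       embeddingDim = cfg@embeddingDim,
                       proteinFcSizes = cfg@proteinFcSizes,
                       predictorFcSizes = cfg@predictorFcSizes,
                       dropout = cfg@dropout, learningRate = cfg@learningRate,
                       batchSize = cfg@batchSize, epochs = cfg@epochs,
                       patience = cfg@patience, seed = cfg@seed,
                       drugBranch = cfg@drugBranch),
         vocab = as.list(m@vocab), panelIds = m@panelIds,
         maxLen = m@maxLen, trained = m@trained,
         nParameters = countTrainableParameters(m)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDTAModel
#' @export
loadDTAModel <- function(path) {
  m <- readRDS(path)
  stopifnot(methods::is(m, "DTAModel"))
  methods::validObject(m@config)
  m
}
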