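## S4 classes for the whole package. Validity functions enforce the data
## contracts; constructors with defaults live next to each module's code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.SIM_KINDS <- c("SW", "NCD_SIM", "BICOMP")
.SPLIT_MODES <- c("warm", "cold_protein", "cold_drug", "cold_pair",
                  "group_holdout")
.COMBINERS <- c("product", "sw_only", "ncd_only", "weighted_sum")
.MEASURES <- c("Kd", "Ki", "IC50", "KIBA", "pre-transformed")

#' AffinityDataset: proteins, ligands and measured affinities
#'
#' Container tying a panel of protein sequences (as a named
#' [Biostrings::AAStringSet]), a set of ligands in SMILES notation (named
#' character vector) and a table of affinity records referencing them by id.
#' Affinity values are dimensionless log-scale labels (pKd, pKi or KIBA
#' scores); the `measure` column records their provenance per record.
#'
#' @slot proteins named `AAStringSet`; sequences over the 20 amino acids
#'   plus `X`, ids unique.
#' @slot ligands named character vector of SMILES strings, ids unique.
#' @slot records `data.frame` with columns `protein_id`, `ligand_id`,
#'   `value` (finite numeric), `measure`.
#' @slot metadata free-form list (e.g. planted family ids for synthetic
#'   data, harmonization log).
#' @exportClass AffinityDataset
setClass("AffinityDataset",
  representation(proteins = "AAStringSet", ligands = "character",
                 records = "data.frame", metadata = "list"),
  prototype(ligands = character(0),
            records = data.frame(protein_id = character(0),
                                 ligand_id = character(0),
                                 value = numeric(0),
                                 measure = character(0)),
            metadata = list()))

setValidity("AffinityDataset", function(object) {
  msg <- character(0)
  pid <- names(object@proteins)
  lid <- names(object@ligands)
  if (length(object@proteins) && (is.null(pid) || anyDuplicated(pid) ||
      any(!nzchar(pid))))
    msg <- c(msg, "protein ids must be unique non-empty names")
  if (length(object@ligands) && (is.null(lid) || anyDuplicated(lid) ||
      any(!nzchar(lid))))
    msg <- c(msg, "ligand ids must be unique non-empty names")
  if (length(object@proteins) && any(Biostrings::width(object@proteins) < 1L))
    msg <- c(msg, "protein sequences must be non-empty")
  if (length(object@ligands) && any(!nzchar(object@ligands)))
    msg <- c(msg, "SMILES strings must be non-empty")
  bad <- setdiff(unique(unlist(strsplit(as.character(object@proteins), ""))),
                 c(AA20, "X"))
  if (length(bad))
    msg <- c(msg, paste0("invalid residue(s) in protein sequences: ",
                         paste(bad, collapse = " ")))
  rec <- object@records
  need <- c("protein_id", "ligand_id", "value", "measure")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records must have columns",
                        paste(need, collapse = ", ")))
  else if (nrow(rec)) {
    if (!all(rec$protein_id %in% pid))
      msg <- c(msg, "records reference unknown protein ids")
    if (!all(rec$ligand_id %in% lid))
      msg <- c(msg, "records reference unknown ligand ids")
    if (!all(is.finite(rec$value)))
      msg <- c(msg, "affinity values must be finite")
    if (!all(rec$measure %in% .MEASURES))
      msg <- c(msg, paste("measure must be one of",
                          paste(.MEASURES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: square symmetric protein-panel similarity
#'
#' @slot ids ordered protein ids (row/column order of `values`).
#' @slot values numeric matrix, symmetric, entries in \[0, 1\].
#' @slot kind one of `"SW"` (normalized Smith-Waterman), `"NCD_SIM"`
#'   (compression similarity, diagonal not forced to 1) or `"BICOMP"`
#'   (combined encoding, unit diagonal).
#' @slot metadata list recording the scheme/compressor/combiner parameters
#'   that produced the matrix, plus clamping counters.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(ids = "character", values = "matrix", kind = "character",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("SimilarityMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  n <- length(object@ids)
  if (length(object@kind) != 1L || !object@kind %in% .SIM_KINDS)
    msg <- c(msg, paste("kind must be one of",
                        paste(.SIM_KINDS, collapse = ", ")))
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique")
  if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "values must be a numeric n x n matrix matching ids")
  else {
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-9, check.attributes = FALSE)))
      msg <- c(msg, "matrix must be symmetric within 1e-9")
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      msg <- c(msg, "entries must lie in [0, 1]")
    if (length(object@kind) == 1L && object@kind %in% c("SW", "BICOMP") &&
        n > 0 && any(abs(diag(v) - 1) > 1e-9))
      msg <- c(msg, "diagonal must be 1 for SW and BICOMP matrices")
  }
  if (length(msg)) msg else TRUE
})

#' AlignmentScheme: substitution scores and affine gap penalties
#'
#' A gap of length L costs `gapOpen + L * gapExtend` (the convention of
#' [Biostrings::pairwiseAlignment]).
#'
#' @slot substitution symmetric numeric matrix with residue dimnames;
#'   positive self-scores for the 20 standard residues, `X` neutral (0).
#' @slot gapOpen,gapExtend non-negative penalties, `gapExtend <= gapOpen`.
#' @exportClass AlignmentScheme
setClass("AlignmentScheme",
  representation(substitution = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric"))

setValidity("AlignmentScheme", function(object) {
  msg <- character(0)
  s <- object@substitution
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    msg <- c(msg, "substitution matrix needs identical row/col residue names")
  else {
    if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE)))
      msg <- c(msg, "substitution matrix must be symmetric")
    std <- intersect(rownames(s), AA20)
    if (length(std) && any(diag(s[std, std, drop = FALSE]) <= 0))
      msg <- c(msg, "standard residues need positive self-scores")
  }
  if (length(object@gapOpen) != 1L || object@gapOpen < 0 ||
      length(object@gapExtend) != 1L || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be single non-negative numbers")
  else if (object@gapExtend > object@gapOpen)
    msg <- c(msg, "gapExtend must not exceed gapOpen")
  if (length(msg)) msg else TRUE
})

#' CompressorConfig: pinned LZMA settings for compressed lengths
#'
#' @slot algorithm fixed tag `"LZMA"`.
#' @slot level integer preset 0-9 (9 = maximum).
#' @slot streamMode `"container"` (xz stream written through R's linked
#'   liblzma) or `"raw"` (header-free LZMA2 stream via the external `xz`
#'   binary, when available).
#' @exportClass CompressorConfig
setClass("CompressorConfig",
  representation(algorithm = "character", level = "integer",
                 streamMode = "character"),
  prototype(algorithm = "LZMA", level = 9L, streamMode = "container"))

setValidity("CompressorConfig", function(object) {
  msg <- character(0)
  if (!identical(object@algorithm, "LZMA"))
    msg <- c(msg, "algorithm is fixed to LZMA")
  if (length(object@level) != 1L || is.na(object@level) ||
      object@level < 0L || object@level > 9L)
    msg <- c(msg, "level must be an integer in 0..9")
  if (length(object@streamMode) != 1L ||
      !object@streamMode %in% c("container", "raw"))
    msg <- c(msg, "streamMode must be 'container' or 'raw'")
  if (length(msg)) msg else TRUE
})

#' EncoderConfig: how the two similarity matrices are combined
#'
#' @slot combiner `"product"` (entrywise, the default unified measure),
#'   `"sw_only"` / `"ncd_only"` (feature ablations) or `"weighted_sum"`.
#' @slot weight mixing weight w in \[0, 1\] for `weighted_sum`
#'   (`w * SW + (1 - w) * NCD`); `NA` otherwise.
#' @slot referencePanel ordered protein ids of the encoding panel.
#' @exportClass EncoderConfig
setClass("EncoderConfig",
  representation(combiner = "character", weight = "numeric",
                 referencePanel = "character"),
  prototype(combiner = "product", weight = NA_real_,
            referencePanel = character(0)))

setValidity("EncoderConfig", function(object) {
  msg <- character(0)
  if (length(object@combiner) != 1L || !object@combiner %in% .COMBINERS)
    msg <- c(msg, paste("combiner must be one of",
                        paste(.COMBINERS, collapse = ", ")))
  if (identical(object@combiner, "weighted_sum")) {
    if (length(object@weight) != 1L || is.na(object@weight) ||
        object@weight < 0 || object@weight > 1)
      msg <- c(msg, "weighted_sum requires weight in [0, 1]")
  } else if (length(object@weight) != 1L || !is.na(object@weight))
    msg <- c(msg, "weight must be NA unless combiner = weighted_sum")
  if (length(msg)) msg else TRUE
})

#' SplitSpec: train/test split construction parameters
#'
#' @slot mode `"warm"` (record-level k-fold), `"cold_protein"`,
#'   `"cold_drug"`, `"cold_pair"` (entity-level k-folds with the respective
#'   unseen-entity guarantee) or `"group_holdout"` (all records touching a
#'   fixed protein set form the single test fold).
#' @slot nFolds number of folds (>= 2 for cross-validation modes).
#' @slot seed RNG seed controlling entity shuffling.
#' @slot holdoutGroup protein ids for `group_holdout` (empty otherwise).
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(mode = "character", nFolds = "integer", seed = "integer",
                 holdoutGroup = "character"),
  prototype(mode = "warm", nFolds = 5L, seed = 1L,
            holdoutGroup = character(0)))

setValidity("SplitSpec", function(object) {
  msg <- character(0)
  if (length(object@mode) != 1L || !object@mode %in% .SPLIT_MODES)
    msg <- c(msg, paste("mode must be one of",
                        paste(.SPLIT_MODES, collapse = ", ")))
  if (identical(object@mode, "group_holdout")) {
    if (!length(object@holdoutGroup))
      msg <- c(msg, "group_holdout requires a non-empty holdoutGroup")
  } else {
    if (length(object@holdoutGroup))
      msg <- c(msg, "holdoutGroup is only allowed for mode group_holdout")
    if (length(object@nFolds) != 1L || is.na(object@nFolds) ||
        object@nFolds < 2L)
      msg <- c(msg, "cross-validation modes need nFolds >= 2")
  }
  if (length(msg)) msg else TRUE
})

#' ModelConfig: architecture and training hyperparameters
#'
#' Defaults follow the conventions of character-CNN affinity regressors:
#' rectifier hidden activations, linear output, adaptive-moment optimizer,
#' early stopping on validation MSE.
#'
#' @slot nFilters,filterLength convolution filters per layer and their
#'   length (the two bracketed numbers of the drug branch).
#' @slot embeddingDim SMILES character embedding dimension.
#' @slot proteinFcSizes,predictorFcSizes exactly three layer widths each.
#' @slot dropout dropout rate in the predictor block, in \[0, 1).
#' @slot learningRate,batchSize,epochs optimizer settings.
#' @slot patience early-stopping patience (epochs without validation
#'   improvement); best-validation weights are restored.
#' @slot seed seed for weight initialization and data order.
#' @slot drugBranch `"cnn_sep"` (two CNN layers + separable CNN + global
#'   max-pool) or `"fc"` (fully-connected baseline, no convolutions).
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(nFilters = "integer", filterLength = "integer",
                 embeddingDim = "integer", proteinFcSizes = "integer",
                 predictorFcSizes = "integer", dropout = "numeric",
                 learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", patience = "integer", seed = "integer",
                 drugBranch = "character"),
  prototype(nFilters = 32L, filterLength = 8L, embeddingDim = 128L,
            proteinFcSizes = c(1024L, 1024L, 512L),
            predictorFcSizes = c(1024L, 1024L, 512L),
            dropout = 0.1, learningRate = 1e-3, batchSize = 256L,
            epochs = 100L, patience = 15L, seed = 1L,
            drugBranch = "cnn_sep"))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  pos1 <- function(x) length(x) == 1L && !is.na(x) && x >= 1L
  if (!pos1(object@nFilters)) msg <- c(msg, "nFilters must be positive")
  if (!pos1(object@filterLength)) msg <- c(msg, "filterLength must be positive")
  if (!pos1(object@embeddingDim)) msg <- c(msg, "embeddingDim must be positive")
  if (length(object@proteinFcSizes) != 3L || any(object@proteinFcSizes < 1L))
    msg <- c(msg, "proteinFcSizes must be 3 positive integers")
  if (length(object@predictorFcSizes) != 3L ||
      any(object@predictorFcSizes < 1L))
    msg <- c(msg, "predictorFcSizes must be 3 positive integers")
  if (length(object@dropout) != 1L || object@dropout < 0 ||
      object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(object@learningRate) != 1L || object@learningRate <= 0)
    msg <- c(msg, "learningRate must be positive")
  if (!pos1(object@batchSize)) msg <- c(msg, "batchSize must be positive")
  if (!pos1(object@epochs)) msg <- c(msg, "epochs must be positive")
  if (!pos1(object@patience)) msg <- c(msg, "patience must be positive")
  if (length(object@drugBranch) != 1L ||
      !object@drugBranch %in% c("cnn_sep", "fc"))
    msg <- c(msg, "drugBranch must be 'cnn_sep' or 'fc'")
  if (length(msg)) msg else TRUE
})

#' DTAModel: a built (possibly trained) two-branch affinity regressor
#'
#' @slot config the [ModelConfig-class] the model was built with.
#' @slot weights named list of parameter arrays (opaque; use
#'   [countTrainableParameters()] and [predictAffinity()]).
#' @slot vocab SMILES character vocabulary (named integer, codes 1..K;
#'   0 is padding, K+1 the unknown-character code).
#' @slot panelIds reference-panel protein ids (protein input length).
#' @slot maxLen fixed SMILES encoding length.
#' @slot history per-epoch train/validation loss (`data.frame`).
#' @slot trained logical flag.
#' @exportClass DTAModel
setClass("DTAModel",
  representation(config = "ModelConfig", weights = "list",
                 vocab = "integer", panelIds = "character",
                 maxLen = "integer", history = "data.frame",
                 trained = "logical"),
  prototype(history = data.frame(), trained = FALSE))

#' MetricsReport: CI, MSE, rm2 and AUPR with per-fold dispersion
#'
#' Aggregate values are means over folds; dispersion is the sample standard
#' deviation. `nPairsCI` counts the label-comparable pairs entering the
#' concordance index, summed over folds.
#'
#' @slot ci,mse,rm2,aupr aggregate metric values.
#' @slot perFold one row per fold with the four metrics.
#' @slot nPairsCI integer count of comparable pairs.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(ci = "numeric", mse = "numeric", rm2 = "numeric",
                 aupr = "numeric", perFold = "data.frame",
                 nPairsCI = "numeric"))

#' SyntheticSpec: planted-structure synthetic dataset parameters
#'
#' Proteins come in families (an ancestor per family, members derived by
#' i.i.d. substitutions), ligands are random SMILES-like strings, and the
#' affinity is a smooth function of protein family and ligand character
#' composition plus Gaussian noise, scaled into a pKd-like range \[4, 10\].
#'
#' @slot nFamilies,membersPerFamily,proteinLength family structure.
#' @slot mutationRate per-position substitution probability in \[0, 1).
#' @slot nLigands,ligandLengthRange,ligandAlphabet ligand generation.
#' @slot noiseSd Gaussian noise added to affinities (pKd units).
#' @slot seed master seed; the dataset is reproducible from (spec, seed).
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nFamilies = "integer", membersPerFamily = "integer",
                 proteinLength = "integer", mutationRate = "numeric",
                 nLigands = "integer", ligandLengthRange = "integer",
                 ligandAlphabet = "character", noiseSd = "numeric",
                 seed = "integer"),
  prototype(nFamilies = 3L, membersPerFamily = 10L, proteinLength = 400L,
            mutationRate = 0.1, nLigands = 20L,
            ligandLengthRange = c(20L, 60L),
            ligandAlphabet = c("C", "N", "O", "S", "P", "=", "#",
                               "(", ")", "1", "2", "c"),
            noiseSd = 0.3, seed = 1L))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  pos1 <- function(x) length(x) == 1L && !is.na(x) && x >= 1L
  if (!pos1(object@nFamilies)) msg <- c(msg, "nFamilies must be >= 1")
  if (!pos1(object@membersPerFamily))
    msg <- c(msg, "membersPerFamily must be >= 1")
  if (!pos1(object@proteinLength)) msg <- c(msg, "proteinLength must be >= 1")
  if (length(object@mutationRate) != 1L || object@mutationRate < 0 ||
      object@mutationRate >= 1)
    msg <- c(msg, "mutationRate must be in [0, 1)")
  if (!pos1(object@nLigands)) msg <- c(msg, "nLigands must be >= 1")
  if (length(object@ligandLengthRange) != 2L ||
      any(object@ligandLengthRange < 1L) ||
      object@ligandLengthRange[1] > object@ligandLengthRange[2])
    msg <- c(msg, "ligandLengthRange must be (min, max) with min <= max")
  if (!length(object@ligandAlphabet) ||
      any(nchar(object@ligandAlphabet) != 1L))
    msg <- c(msg, "ligandAlphabet must be single characters")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})
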