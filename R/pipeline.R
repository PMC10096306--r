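#' Build the full encoder set from training data
#'
#' Computes the alignment and compression similarity matrices over the
#' training protein panel, combines them per the encoder config, and
#' builds the SMILES vocabulary from the training ligands. The reference
#' panel is restricted to proteins appearing in `trainRecords`, so
#' cold-start test proteins never leak into the representation.
#'
#' @param ds an [AffinityDataset-class].
#' @param trainRecords training subset of `affinityRecords(ds)`.
#' @param scheme an [AlignmentScheme-class].
#' @param compressor a [CompressorConfig-class].
#' @param cfg an [EncoderConfig-class] (its `referencePanel` is filled in).
#' @param maxLen fixed SMILES length; default the longest training SMILES.
#' @return list with the panel, matrices (`sw`, `ncd`, `combined`), vocab
#'   and settings, consumed by [encodeRecordsForModel()].
#' @export
buildEncoderSet <- function(ds, trainRecords, scheme = AlignmentScheme(),
                            compressor = CompressorConfig(),
                            cfg = EncoderConfig(), maxLen = NULL) {
  panelIds <- intersect(names(ds@proteins), unique(trainRecords$protein_id))
  if (!length(panelIds)) stop("no training proteins to build a panel from")
  panel <- stats::setNames(as.character(ds@proteins[panelIds]), panelIds)
  sw <- swSimilarityMatrix(panel, scheme)
  ncdM <- ncdSimilarityMatrix(panel, compressor)
  cfg@referencePanel <- panelIds
  combined <- combineMatrices(sw, ncdM, cfg)
  trainLig <- unique(trainRecords$ligand_id)
  vocab <- buildSmilesVocab(unname(ds@ligands[trainLig]))
  if (is.null(maxLen))
    maxLen <- max(nchar(ds@ligands[trainLig]))
  list(panel = panel, panelIds = panelIds, scheme = scheme,
       compressor = compressor, cfg = cfg, sw = sw, ncd = ncdM,
       combined = combined, vocab = vocab, maxLen = as.integer(maxLen))
}

#' Encode affinity records into model design blocks
#'
#' Produces the protein encoding matrix, ligand code matrix and label
#' vector for a set of records. Panel proteins reuse their precomputed
#' matrix rows; proteins outside the panel (cold-start test entities) are
#' encoded fresh against the training panel.
#'
#' @param ds an [AffinityDataset-class].
#' @param records a subset of `affinityRecords(ds)`.
#' @param enc encoder set from [buildEncoderSet()].
#' @return `list(P=, D=, y=)` ready for [trainModel()] /
#'   [predictAffinity()].
#' @export
encodeRecordsForModel <- function(ds, records, enc) {
  pids <- unique(records$protein_id)
  pv <- matrix(0, length(pids), length(enc$panelIds),
               dimnames = list(pids, enc$panelIds))
  inPanel <- pids %in% enc$panelIds
  if (any(inPanel))
    pv[pids[inPanel], ] <-
      enc$combined@values[match(pids[inPanel], enc$combined@ids), ,
                          drop = FALSE]
  for (pid in pids[!inPanel])
    pv[pid, ] <- encodeProtein(
      stats::setNames(as.character(ds@proteins[pid]), pid), enc$panel,
      scheme = enc$scheme, compressor = enc$compressor, cfg = enc$cfg)
  lids <- unique(records$ligand_id)
  lc <- suppressWarnings(
    encodeLigands(ds@ligands[lids], enc$vocab, enc$maxLen))
  rownames(lc) <- lids
  .designFor(records, pv, lc)
}

## split a training record table into train/validation parts for early
## stopping (seeded, record-level)
.valSplit <- function(records, valFraction, seed) {
  n <- nrow(records)
  nVal <- max(1L, round(valFraction * n))
  if (n < 5L) return(list(train = records, val = records[0, ]))
  vi <- withRNG(seed, sample.int(n, nVal))
  list(train = records[-vi, , drop = FALSE],
       val = records[vi, , drop = FALSE])
}

## train on one fold's record tables and predict its test records
.runFold <- function(ds, trainRec, testRec, scheme, compressor, encCfg,
                     modelCfg, maxLen, valFraction = 0.1) {
  enc <- buildEncoderSet(ds, trainRec, scheme, compressor, encCfg, maxLen)
  parts <- .valSplit(trainRec, valFraction, modelCfg@seed + 17L)
  m <- buildModel(modelCfg, length(enc$panelIds), enc$vocab, enc$maxLen)
  m@panelIds <- enc$panelIds
  m <- trainModel(m,
                  encodeRecordsForModel(ds, parts$train, enc),
                  encodeRecordsForModel(ds, parts$val, enc))
  te <- encodeRecordsForModel(ds, testRec, enc)
  list(yTrue = te$y, yPred = predictAffinity(m, te$P, te$D), model = m,
       enc = enc)
}

.expandConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(experiment = "cv",
                   split = list(mode = "warm", nFolds = 5L, seed = 1L),
                   encoder = list(combiner = "product", weight = NA),
                   alignment = list(gapOpen = 10, gapExtend = 0.5),
                   compressor = list(level = 9L, streamMode = "container"),
                   model = list(), straw = list(setting = "S1"),
                   ablation = list(combiners = c("product", "sw_only",
                                                 "ncd_only")),
                   maxLen = NULL, auprThreshold = 7, valFraction = 0.1,
                   seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  config
}

.configError <- function(...) stop(..., call. = FALSE)

.datasetFromConfig <- function(config) {
  d <- config$data
  if (is.null(d)) .configError("config needs a 'data' section")
  if (!is.null(d$synthetic)) {
    spec <- do.call(SyntheticSpec, d$synthetic)
    list(ds = generateSyntheticDataset(spec), files = character(0))
  } else {
    need <- c("proteins", "ligands", "affinities")
    if (!all(need %in% names(d)))
      .configError("file-based data needs paths: ",
                   paste(need, collapse = ", "))
    ds <- loadAffinityDataset(d$proteins, d$ligands, d$affinities,
                              format = if (is.null(d$format)) "triples_tsv"
                                       else d$format)
    list(ds = harmonizeDuplicates(ds),
         files = c(d$proteins, d$ligands, d$affinities))
  }
}

#' Run a config-driven experiment
#'
#' Orchestrates the full protocols over one dataset: standard or
#' cold-start cross-validation (`experiment = "cv"`), label-shuffling
#' straw controls (`"straw"`, settings S1/S2/S3), or feature ablation over
#' combiners (`"ablation"`). The config is a JSON file (or equivalent
#' list) with sections `data`, `split`, `encoder`, `alignment`,
#' `compressor`, `model`, and per-experiment options; defaults are filled
#' in for anything omitted. Fails fast on configuration errors before any
#' heavy compute. All outputs (fold manifest, per-run metrics JSON, run
#' manifest with config snapshot, seeds, input hashes and timestamps) are
#' written under `outDir`; re-running an identical config and seed
#' reproduces identical metric files.
#'
#' @param config path to a JSON config or an equivalent named list.
#' @param outDir artifact directory (created if needed).
#' @return invisibly, a list of [MetricsReport-class] objects keyed by run
#'   tag, plus the manifest path.
#' @export
runExperiment <- function(config, outDir = tempfile("run")) {
  config <- .expandConfig(config)
  if (!config$experiment %in% c("cv", "straw", "ablation"))
    .configError("unknown experiment kind: ", config$experiment)
  if (!config$encoder$combiner %in% .COMBINERS)
    .configError("unknown combiner: ", config$encoder$combiner)
  if (config$experiment == "straw" &&
      !config$straw$setting %in% c("S1", "S2", "S3"))
    .configError("straw setting must be S1, S2 or S3")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  dat <- .datasetFromConfig(config)
  ds <- dat$ds
  scheme <- AlignmentScheme(gapOpen = config$alignment$gapOpen,
                            gapExtend = config$alignment$gapExtend)
  compressor <- CompressorConfig(level = config$compressor$level,
                                 streamMode = config$compressor$streamMode)
  modelCfg <- do.call(ModelConfig, config$model)
  spec <- SplitSpec(mode = config$split$mode,
                    nFolds = config$split$nFolds,
                    seed = config$split$seed,
                    holdoutGroup = if (is.null(config$split$holdoutGroup))
                      character(0) else unlist(config$split$holdoutGroup))
  folds <- makeSplits(ds, spec)
  writeSplitManifest(folds, spec, file.path(outDir, "folds.json"))

  encoderFor <- function(combiner) {
    w <- config$encoder$weight
    EncoderConfig(combiner = combiner,
                  weight = if (combiner == "weighted_sum") as.numeric(w)
                           else NA_real_)
  }
  rec <- ds@records
  foldTables <- function() lapply(folds, function(f)
    list(train = rec[f$train, , drop = FALSE],
         test = rec[f$test, , drop = FALSE]))

  runs <- switch(config$experiment,
    cv = list(cv = list(tables = foldTables(),
                        cfg = encoderFor(config$encoder$combiner),
                        shuffled = "none")),
    straw = {
      s <- config$straw$setting
      stats::setNames(
        list(list(tables = shuffleLabels(ds, s, folds, config$seed),
                  cfg = encoderFor(config$encoder$combiner),
                  shuffled = s)), paste0("straw_", s))
    },
    ablation = {
      combs <- unlist(config$ablation$combiners)
      stats::setNames(lapply(combs, function(cb)
        list(tables = foldTables(), cfg = encoderFor(cb),
             shuffled = "none")), paste0("ablation_", combs))
    })

  results <- list(); outputs <- "folds.json"
  for (tag in names(runs)) {
    run <- runs[[tag]]
    foldRes <- lapply(run$tables, function(tb)
      .runFold(ds, tb$train, tb$test, scheme, compressor, run$cfg,
               modelCfg, config$maxLen, config$valFraction)[c("yTrue",
                                                              "yPred")])
    rep <- evaluatePredictions(foldRes, config$auprThreshold)
    mf <- paste0("metrics_", tag, ".json")
    writeMetricsReport(rep, file.path(outDir, mf))
    outputs <- c(outputs, mf)
    results[[tag]] <- rep
  }

  manifest <- list(
    package = as.character(utils::packageVersion("compDTA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = list(split = spec@seed, model = modelCfg@seed,
                 experiment = config$seed),
    shuffledPartitions = vapply(runs, `[[`, "", "shuffled"),
    inputFiles = if (length(dat$files))
      as.list(tools::md5sum(dat$files)) else list(),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(c(results, list(dir = outDir,
                            manifest = file.path(outDir, "manifest.json"))))
}
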