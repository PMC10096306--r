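#' Construct a SplitSpec
#'
#' @param mode split mode; see [SplitSpec-class].
#' @param nFolds number of folds (ignored for `group_holdout`).
#' @param seed RNG seed for entity shuffling.
#' @param holdoutGroup protein ids held out entirely (mode
#'   `group_holdout` only), emulating family-level holdouts such as
#'   excluding all HIV-1 protease variants from training.
#' @return a [SplitSpec-class].
#' @export
SplitSpec <- function(mode = "warm", nFolds = 5L, seed = 1L,
                      holdoutGroup = character(0)) {
  if (identical(mode, "group_holdout")) nFolds <- 1L
  methods::new("SplitSpec", mode = mode, nFolds = as.integer(nFolds),
               seed = as.integer(seed),
               holdoutGroup = as.character(holdoutGroup))
}

## shuffle entities with the spec seed, then chunk into nFolds groups of
## near-equal size; deterministic for a given (entities, seed).
.chunkEntities <- function(entities, nFolds, seed) {
  if (length(entities) < nFolds)
    stop("cannot make ", nFolds, " folds from ", length(entities),
         " entities")
  perm <- withRNG(seed, sample.int(length(entities)))
  unname(split(entities[perm], rep_len(seq_len(nFolds), length(entities))))
}

#' Build train/test folds for an affinity dataset
#'
#' Split construction for the evaluation protocols:
#' \describe{
#'   \item{warm}{record-level k-fold; every record is tested exactly once.}
#'   \item{cold_protein}{protein-level k-fold; no test record's protein
#'     occurs in its training fold (unseen-target evaluation).}
#'   \item{cold_drug}{ligand-level k-fold; unseen-compound evaluation.}
#'   \item{cold_pair}{proteins and ligands are chunked independently; test
#'     fold k uses only proteins of protein-group k AND ligands of
#'     ligand-group k, while its training records avoid both groups
#'     entirely (unseen pair of unseen entities). Records pairing a
#'     held-out protein with a retained ligand (or vice versa) are used in
#'     neither side of that fold.}
#'   \item{group_holdout}{all records touching `holdoutGroup` proteins form
#'     the single test fold; everything else trains.}
#' }
#' Folds are deterministic under `spec@seed`; train and test are disjoint
#' in every fold.
#'
#' @param ds an [AffinityDataset-class].
#' @param spec a [SplitSpec-class].
#' @return list of `list(train=, test=)` integer row indices into
#'   `affinityRecords(ds)`.
#' @export
makeSplits <- function(ds, spec) {
  stopifnot(methods::is(ds, "AffinityDataset"), methods::is(spec, "SplitSpec"))
  rec <- ds@records
  n <- nrow(rec)
  if (!n) stop("dataset has no affinity records")
  k <- spec@nFolds
  switch(spec@mode,
    warm = {
      groups <- .chunkEntities(seq_len(n), k, spec@seed)
      lapply(groups, function(te)
        list(train = setdiff(seq_len(n), te), test = sort(te)))
    },
    cold_protein = {
      groups <- .chunkEntities(unique(rec$protein_id), k, spec@seed)
      lapply(groups, function(ids) {
        te <- which(rec$protein_id %in% ids)
        list(train = setdiff(seq_len(n), te), test = te)
      })
    },
    cold_drug = {
      groups <- .chunkEntities(unique(rec$ligand_id), k, spec@seed)
      lapply(groups, function(ids) {
        te <- which(rec$ligand_id %in% ids)
        list(train = setdiff(seq_len(n), te), test = te)
      })
    },
    cold_pair = {
      pg <- .chunkEntities(unique(rec$protein_id), k, spec@seed)
      lg <- .chunkEntities(unique(rec$ligand_id), k, spec@seed + 1L)
      lapply(seq_len(k), function(i) {
        te <- which(rec$protein_id %in% pg[[i]] & rec$ligand_id %in% lg[[i]])
        tr <- which(!(rec$protein_id %in% pg[[i]]) &
                    !(rec$ligand_id %in% lg[[i]]))
        list(train = tr, test = te)
      })
    },
    group_holdout = {
      unknown <- setdiff(spec@holdoutGroup, names(ds@proteins))
      if (length(unknown))
        stop("holdoutGroup contains unknown protein id(s): ",
             paste(unknown, collapse = ", "))
      te <- which(rec$protein_id %in% spec@holdoutGroup)
      list(list(train = setdiff(seq_len(n), te), test = te))
    })
}

#' Label-shuffling straw-model controls
#'
#' Produces per-fold copies of the affinity records with permuted affinity
#' values, for adversarial controls that detect leakage or confounding:
#' `S1` permutes values within the training fold AND within the test fold,
#' `S2` permutes training values only (honest test), and `S3` permutes test
#' values only (honest training). Only the `value` column moves; the
#' (protein, ligand) pairings and all sequences are untouched, so the value
#' multiset of each shuffled partition is preserved. Deterministic under
#' `seed`.
#'
#' @param ds an [AffinityDataset-class].
#' @param setting `"S1"`, `"S2"` or `"S3"`.
#' @param folds fold list from [makeSplits()].
#' @param seed permutation seed.
#' @return list (one element per fold) of
#'   `list(train = data.frame, test = data.frame)` record tables.
#' @export
shuffleLabels <- function(ds, setting = c("S1", "S2", "S3"), folds,
                          seed = 1L) {
  setting <- match.arg(setting)
  rec <- ds@records
  permuteValues <- function(d, s) {
    if (nrow(d) > 1L) d$value <- d$value[withRNG(s, sample.int(nrow(d)))]
    d
  }
  lapply(seq_along(folds), function(i) {
    tr <- rec[folds[[i]]$train, , drop = FALSE]
    te <- rec[folds[[i]]$test, , drop = FALSE]
    sTr <- as.integer(seed) + 2L * i
    sTe <- as.integer(seed) + 2L * i + 1L
    if (setting %in% c("S1", "S2")) tr <- permuteValues(tr, sTr)
    if (setting %in% c("S1", "S3")) te <- permuteValues(te, sTe)
    list(train = tr, test = te)
  })
}
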