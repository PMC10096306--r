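#' Construct an AffinityDataset
#'
#' @param proteins named character vector or named
#'   [Biostrings::AAStringSet] of protein sequences.
#' @param ligands named character vector of SMILES strings.
#' @param records `data.frame` with columns `protein_id`, `ligand_id`,
#'   `value` and optionally `measure` (defaults to `"pre-transformed"`).
#' @param metadata free-form list.
#' @return an [AffinityDataset-class].
#' @examples
#' ds <- AffinityDataset(
#'   proteins = c(p1 = "MKVL", p2 = "MKIL"),
#'   ligands = c(l1 = "CCO"),
#'   records = data.frame(protein_id = c("p1", "p2"),
#'                        ligand_id = "l1", value = c(7.1, 5.2)))
#' ds
#' @export
AffinityDataset <- function(proteins = character(0), ligands = character(0),
                            records = NULL, metadata = list()) {
  if (!methods::is(proteins, "AAStringSet")) {
    nm <- names(proteins)
    proteins <- Biostrings::AAStringSet(unname(as.character(proteins)))
    names(proteins) <- nm
  }
  if (is.null(records))
    records <- data.frame(protein_id = character(0), ligand_id = character(0),
                          value = numeric(0), measure = character(0))
  if (is.null(records$measure))
    records$measure <- rep("pre-transformed", nrow(records))
  records <- as.data.frame(records)[, c("protein_id", "ligand_id",
                                        "value", "measure")]
  rownames(records) <- NULL
  methods::new("AffinityDataset", proteins = proteins,
               ligands = ligands, records = records, metadata = metadata)
}

#' @rdname compDTA-accessors
#' @export
setMethod("proteinSequences", "AffinityDataset", function(x) x@proteins)

#' @rdname compDTA-accessors
#' @export
setMethod("ligandSmiles", "AffinityDataset", function(x) x@ligands)

#' @rdname compDTA-accessors
#' @export
setMethod("affinityRecords", "AffinityDataset", function(x) x@records)

#' @rdname compDTA-accessors
#' @export
setMethod("datasetMetadata", "AffinityDataset", function(x) x@metadata)

setMethod("show", "AffinityDataset", function(object) {
  cat("AffinityDataset with", length(object@proteins), "proteins,",
      length(object@ligands), "ligands,", nrow(object@records), "records\n")
  if (nrow(object@records)) {
    m <- table(object@records$measure)
    cat("  measures:", paste(names(m), m, sep = ":", collapse = ", "), "\n")
    cat("  value range:",
        paste(signif(range(object@records$value), 4), collapse = " .. "),
        "\n")
  }
})

#' Transform a dissociation constant to pKd
#'
#' `pKd = -log10(Kd / 1e9)` for `Kd` in nanomolar, so a 1 nM binder maps to
#' pKd 9. Monotone decreasing in `kd`.
#'
#' @param kd dissociation constant(s) in nanomolar; must be positive and
#'   finite.
#' @return numeric vector of pKd values.
#' @examples
#' kdToPkd(c(1e9, 1, 1e4))  # 0, 9, 5
#' @export
kdToPkd <- function(kd) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be positive and finite (nanomolar)")
  -log10(kd / 1e9)
}

#' Collapse duplicate affinity measurements
#'
#' Ensures each (protein, ligand) pair occurs at most once. The default
#' `max` policy keeps the maximum affinity value for replicated pairs (the
#' harmonization rule used for Kd-type data); `mean` averages them (suited
#' to already-aggregated KIBA scores); `error` refuses duplicates. Ligand
#' ids mapping to several distinct SMILES strings are also collapsed to
#' their first occurrence, with the discarded alternatives logged in
#' `datasetMetadata(ds)$droppedSmiles`.
#'
#' @param ds an [AffinityDataset-class].
#' @param policy `"max"`, `"mean"` or `"error"`.
#' @return a harmonized [AffinityDataset-class].
#' @export
harmonizeDuplicates <- function(ds, policy = c("max", "mean", "error")) {
  policy <- match.arg(policy)
  rec <- ds@records
  key <- paste(rec$protein_id, rec$ligand_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && policy == "error")
    stop("duplicate affinity pair: ", sub("\r", " / ", key[dup][1]))
  meta <- ds@metadata
  ## duplicate ligand ids with conflicting SMILES cannot arise inside a
  ## valid object (names are unique), but loaders funnel raw tables through
  ## here; the log records what the loader dropped.
  if (any(dup)) {
    agg <- if (policy == "max") max else mean
    keep <- !duplicated(key)
    val <- vapply(split(rec$value, key), agg, numeric(1))
    out <- rec[keep, , drop = FALSE]
    out$value <- unname(val[paste(out$protein_id, out$ligand_id,
                                  sep = "\r")])
    meta$harmonization <- list(policy = policy, nCollapsed = sum(dup))
    rec <- out
  }
  AffinityDataset(ds@proteins, ds@ligands, rec, meta)
}

#' Drop near-duplicate proteins from a dataset
#'
#' Greedy filter in dataset order: a protein is removed when its similarity
#' to an already-kept protein is at least `threshold`; its affinity records
#' go with it. Deterministic by construction (first occurrence wins).
#'
#' @param ds an [AffinityDataset-class].
#' @param similarity a [SimilarityMatrix-class] covering the dataset's
#'   protein ids (any kind; normalized Smith-Waterman is the usual choice).
#' @param threshold redundancy cutoff in \[0, 1\]; default 0.99.
#' @return filtered [AffinityDataset-class]; removed ids are recorded in
#'   `datasetMetadata()$removedRedundant`.
#' @export
deduplicateProteins <- function(ds, similarity, threshold = 0.99) {
  stopifnot(methods::is(similarity, "SimilarityMatrix"),
            threshold >= 0, threshold <= 1)
  ids <- names(ds@proteins)
  if (!all(ids %in% similarity@ids))
    stop("similarity matrix does not cover all dataset protein ids")
  v <- similarity@values[match(ids, similarity@ids),
                         match(ids, similarity@ids), drop = FALSE]
  kept <- integer(0)
  for (i in seq_along(ids)) {
    if (!length(kept) || all(v[i, kept] < threshold))
      kept <- c(kept, i)
  }
  keepIds <- ids[kept]
  rec <- ds@records[ds@records$protein_id %in% keepIds, , drop = FALSE]
  meta <- ds@metadata
  meta$removedRedundant <- setdiff(ids, keepIds)
  AffinityDataset(ds@proteins[keepIds], ds@ligands, rec, meta)
}
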