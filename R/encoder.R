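#' Construct an EncoderConfig
#'
#' @param combiner how the alignment and compression similarity matrices
#'   are merged: `"product"` (entrywise/Hadamard, the unified measure and
#'   the default), `"sw_only"` / `"ncd_only"` (feature ablations), or
#'   `"weighted_sum"` (`w * SW + (1 - w) * NCD`).
#' @param weight mixing weight for `weighted_sum`, in \[0, 1\].
#' @param referencePanel ordered protein ids of the encoding panel; in
#'   cold-start settings this is the TRAINING panel only, so the
#'   representation never sees test identities.
#' @return an [EncoderConfig-class].
#' @export
EncoderConfig <- function(combiner = "product", weight = NA_real_,
                          referencePanel = character(0)) {
  methods::new("EncoderConfig", combiner = combiner,
               weight = as.numeric(weight),
               referencePanel = as.character(referencePanel))
}

#' Combine alignment and compression similarity matrices
#'
#' Builds the unified protein-encoding matrix from the normalized
#' Smith-Waterman matrix and the compression-similarity matrix over the
#' same panel in the same id order. The default `product` combiner takes
#' the entrywise (Hadamard) product; `weighted_sum` mixes the factors
#' linearly; the `*_only` modes pass one factor through for feature
#' ablation. The output is clamped into \[0, 1\] and its diagonal is
#' forced to 1 (a protein is maximally similar to itself in its own
#' encoding, even though raw compression self-similarity is below 1).
#'
#' @param sw [SimilarityMatrix-class] of kind `"SW"`.
#' @param ncd [SimilarityMatrix-class] of kind `"NCD_SIM"`.
#' @param cfg an [EncoderConfig-class].
#' @return a [SimilarityMatrix-class] of kind `"BICOMP"`; the combiner and
#'   factor provenance are recorded in its metadata.
#' @export
combineMatrices <- function(sw, ncd, cfg = EncoderConfig()) {
  stopifnot(methods::is(sw, "SimilarityMatrix"),
            methods::is(ncd, "SimilarityMatrix"),
            methods::is(cfg, "EncoderConfig"))
  if (!identical(sw@ids, ncd@ids))
    stop("matrix id orders differ; reorder one operand first")
  v <- switch(cfg@combiner,
    product = sw@values * ncd@values,
    sw_only = sw@values,
    ncd_only = ncd@values,
    weighted_sum = cfg@weight * sw@values + (1 - cfg@weight) * ncd@values)
  v <- clamp01(v)
  diag(v) <- 1
  methods::new("SimilarityMatrix", ids = sw@ids, values = v, kind = "BICOMP",
               metadata = list(combiner = cfg@combiner, weight = cfg@weight,
                               sw = sw@metadata, ncd = ncd@metadata))
}

#' Encode a protein as a similarity vector against a reference panel
#'
#' The encoding of protein `p` is its vector of combined similarities to
#' each panel member, in panel order. If a cached combined matrix is
#' supplied and `p`'s id is a panel member, its precomputed row is returned
#' exactly; otherwise (unseen proteins under cold-start evaluation) the
#' similarities are computed fresh against the panel. If `p` matches a
#' panel id, that coordinate is 1 by the self-encoding convention.
#'
#' @param p a single named protein sequence (named character of length 1).
#' @param panel named character vector or named `AAStringSet`, the
#'   reference (training) panel.
#' @param scheme an [AlignmentScheme-class].
#' @param compressor a [CompressorConfig-class].
#' @param cfg an [EncoderConfig-class].
#' @param cache optional precomputed `list(sw=, ncd=)` of panel matrices or
#'   a combined `"BICOMP"` [SimilarityMatrix-class].
#' @return numeric vector of length `length(panel)` named by panel ids.
#' @export
encodeProtein <- function(p, panel, scheme = AlignmentScheme(),
                          compressor = CompressorConfig(),
                          cfg = EncoderConfig(), cache = NULL) {
  stopifnot(length(p) == 1L, !is.null(names(p)))
  pid <- names(p)
  seqs <- as.character(panel)
  ids <- names(panel)
  if (methods::is(cache, "SimilarityMatrix") && cache@kind == "BICOMP" &&
      identical(cache@ids, ids) && pid %in% ids)
    return(stats::setNames(cache@values[match(pid, ids), ], ids))
  if (is.list(cache) && all(c("sw", "ncd") %in% names(cache)) &&
      pid %in% ids) {
    comb <- combineMatrices(cache$sw, cache$ncd, cfg)
    return(stats::setNames(comb@values[match(pid, ids), ], ids))
  }
  s <- as.character(p)
  swv <- vapply(seqs, function(q) normalizedSW(s, q, scheme), numeric(1))
  ncdv <- vapply(seqs, function(q) ncdSimilarity(s, q, compressor),
                 numeric(1))
  v <- switch(cfg@combiner,
    product = swv * ncdv,
    sw_only = swv,
    ncd_only = ncdv,
    weighted_sum = cfg@weight * swv + (1 - cfg@weight) * ncdv)
  v <- clamp01(v)
  v[ids == pid] <- 1  # self-encoding convention, as in the matrix diagonal
  stats::setNames(unname(v), ids)
}

#' Build a SMILES character vocabulary
#'
#' Assigns codes 1..K to characters in order of first appearance over the
#' training SMILES strings. Code 0 is reserved for padding and code K+1 for
#' characters unseen at training time.
#'
#' @param smiles character vector of training SMILES strings.
#' @return named integer vector mapping character to code.
#' @examples
#' buildSmilesVocab(c("CCO", "CN"))  # C=1, O=2, N=3
#' @export
buildSmilesVocab <- function(smiles) {
  if (!length(smiles)) stop("need at least one SMILES string")
  chars <- unlist(strsplit(smiles, ""), use.names = FALSE)
  u <- unique(chars)
  stats::setNames(seq_along(u), u)
}

#' Label-encode a SMILES string to a fixed-length code vector
#'
#' Characters map to their vocabulary codes in order; strings longer than
#' `maxLen` are truncated, shorter ones right-padded with 0. Characters
#' missing from the vocabulary map to the reserved unknown code K+1 (with a
#' warning), so unseen compounds never crash cold-drug evaluation.
#'
#' Typical `maxLen` values by dataset style: 85 for kinase-panel data,
#' 100 for KIBA-style data, 200 for the broader public sets.
#'
#' @param smiles a single SMILES string.
#' @param vocab vocabulary from [buildSmilesVocab()].
#' @param maxLen fixed encoding length (>= 1).
#' @return integer vector of exactly `maxLen` codes.
#' @examples
#' v <- buildSmilesVocab("CCO")
#' encodeLigand("CCO", v, 5)  # 1 1 2 0 0
#' @export
encodeLigand <- function(smiles, vocab, maxLen) {
  stopifnot(length(smiles) == 1L, is.character(smiles))
  maxLen <- as.integer(maxLen)
  if (is.na(maxLen) || maxLen < 1L) stop("maxLen must be >= 1")
  if (!nzchar(smiles)) stop("empty SMILES string")
  chars <- strsplit(smiles, "")[[1]]
  codes <- unname(vocab[chars])
  unk <- is.na(codes)
  if (any(unk)) {
    warning("unknown SMILES character(s) mapped to reserved code: ",
            paste(unique(chars[unk]), collapse = " "))
    codes[unk] <- length(vocab) + 1L
  }
  length(codes) <- maxLen            # truncate or NA-extend
  codes[is.na(codes)] <- 0L          # zero padding
  as.integer(codes)
}

#' Encode many ligands into a code matrix
#'
#' @param smiles named character vector of SMILES strings.
#' @inheritParams encodeLigand
#' @return integer matrix, one row per ligand (rownames = ids),
#'   `maxLen` columns.
#' @export
encodeLigands <- function(smiles, vocab, maxLen) {
  m <- t(vapply(smiles, encodeLigand, integer(maxLen),
                vocab = vocab, maxLen = maxLen))
  rownames(m) <- names(smiles)
  m
}
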