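#' Construct an AlignmentScheme
#'
#' Default scoring: BLOSUM62 with the ambiguous residue `X` set to score 0
#' against everything (neutral), gap opening 10 and gap extension 0.5
#' (water-style protein defaults). A gap of length L costs
#' `gapOpen + L * gapExtend`. The scheme is recorded in the metadata of
#' every matrix it produces.
#'
#' @param substitution symmetric numeric substitution matrix with residue
#'   dimnames; default BLOSUM62 with neutral `X`.
#' @param gapOpen,gapExtend non-negative gap penalties,
#'   `gapExtend <= gapOpen`.
#' @return an [AlignmentScheme-class].
#' @examples
#' sch <- AlignmentScheme()
#' swScore("MKVL", "MKIL", sch)
#' @export
AlignmentScheme <- function(substitution = NULL, gapOpen = 10,
                            gapExtend = 0.5) {
  if (is.null(substitution)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution <- e$BLOSUM62
    substitution["X", ] <- 0
    substitution[, "X"] <- 0
  }
  methods::new("AlignmentScheme", substitution = substitution,
               gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

setMethod("show", "AlignmentScheme", function(object) {
  cat("AlignmentScheme:", nrow(object@substitution), "x",
      ncol(object@substitution), "substitution matrix, gapOpen",
      object@gapOpen, "gapExtend", object@gapExtend, "\n")
})

.checkAlphabet <- function(s, scheme, what = "sequence") {
  if (!nzchar(s)) stop(what, " must be non-empty")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), rownames(scheme@substitution))
  if (length(bad))
    stop("residue(s) not covered by the scoring scheme: ",
         paste(bad, collapse = " "))
}

#' Smith-Waterman local alignment score
#'
#' Best local-alignment score under affine gap penalties; the empty
#' alignment floors the score at zero, and the score is symmetric in its
#' arguments. Scoring is delegated to [Biostrings::pairwiseAlignment].
#'
#' @param a,b protein sequences (character or `AAString`-coercible).
#' @param scheme an [AlignmentScheme-class].
#' @return non-negative numeric score.
#' @export
swScore <- function(a, b, scheme = AlignmentScheme()) {
  a <- as.character(a); b <- as.character(b)
  .checkAlphabet(a, scheme); .checkAlphabet(b, scheme)
  s <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = scheme@substitution,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
    scoreOnly = TRUE)
  max(0, s)
}

## vectorized column of SW scores against one subject; one C call per subject
.swScoreMany <- function(patterns, subject, scheme) {
  s <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local",
    substitutionMatrix = scheme@substitution,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
    scoreOnly = TRUE)
  pmax(0, s)
}

#' Normalized Smith-Waterman similarity
#'
#' `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`, clamped into \[0, 1\]. The
#' geometric-mean normalization makes self-similarity exactly 1 and puts
#' all pairs on a common scale.
#'
#' @inheritParams swScore
#' @return similarity in \[0, 1\].
#' @export
normalizedSW <- function(a, b, scheme = AlignmentScheme()) {
  saa <- swScore(a, a, scheme)
  sbb <- swScore(b, b, scheme)
  if (saa <= 0 || sbb <= 0)
    stop("degenerate sequence: zero self-alignment score")
  clamp01(swScore(a, b, scheme) / sqrt(saa * sbb))
}

#' Normalized Smith-Waterman similarity matrix over a panel
#'
#' Entry (i, j) is [normalizedSW()] of panel members i and j. Only the
#' upper triangle is computed and mirrored; the diagonal is exactly 1.
#'
#' @param panel named character vector or named `AAStringSet` of protein
#'   sequences with unique ids.
#' @param scheme an [AlignmentScheme-class].
#' @return a [SimilarityMatrix-class] of kind `"SW"`.
#' @export
swSimilarityMatrix <- function(panel, scheme = AlignmentScheme()) {
  seqs <- as.character(panel)
  ids <- names(panel)
  if (is.null(ids) || anyDuplicated(ids))
    stop("panel needs unique ids")
  n <- length(seqs)
  if (!n) stop("panel must be non-empty")
  for (s in seqs) .checkAlphabet(s, scheme, "panel sequence")
  self <- vapply(seqs, function(s) swScore(s, s, scheme), numeric(1))
  if (any(self <= 0))
    stop("degenerate sequence: zero self-alignment score")
  v <- diag(1, n)
  for (j in seq_len(n)[-1]) {
    i <- seq_len(j - 1L)
    v[i, j] <- clamp01(.swScoreMany(seqs[i], seqs[j], scheme) /
                         sqrt(self[i] * self[j]))
    v[j, i] <- v[i, j]
  }
  methods::new("SimilarityMatrix", ids = ids, values = v, kind = "SW",
               metadata = list(scheme = list(gapOpen = scheme@gapOpen,
                                             gapExtend = scheme@gapExtend)))
}

#' @rdname compDTA-accessors
#' @export
setMethod("similarityIds", "SimilarityMatrix", function(x) x@ids)

#' @rdname compDTA-accessors
#' @export
setMethod("similarityKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname compDTA-accessors
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
})

setMethod("show", "SimilarityMatrix", function(object) {
  n <- length(object@ids)
  cat("SimilarityMatrix (", object@kind, "), ", n, " x ", n, "\n", sep = "")
  if (n) {
    off <- object@values[upper.tri(object@values)]
    if (length(off))
      cat("  off-diagonal range:",
          paste(signif(range(off), 4), collapse = " .. "), "\n")
  }
})
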