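## Shared fixtures and independent oracles for the test suite. Everything
## is generated in code; no stored data files.

## random protein panel over the full 20-letter alphabet
makePanel <- function(n, len, seed) {
  withr::with_seed(seed, {
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(aa, len, replace = TRUE), collapse = ""),
      character(1)),
      paste0("p", seq_len(n)))
  })
}

## uniform scoring scheme over an arbitrary residue set
flatScheme <- function(letters, match = 2, mismatch = -1,
                       gapOpen = 1, gapExtend = 1) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  AlignmentScheme(substitution = m, gapOpen = gapOpen, gapExtend = gapExtend)
}

## ---- independent Smith-Waterman oracle -----------------------------------
## Plain-R affine-gap local DP, written against the same gap convention as
## the package contract (gap of length L costs open + L * extend) but
## sharing no code with the implementation under test.
swOracle <- function(a, b, scheme) {
  sub <- scheme@substitution
  open <- scheme@gapOpen; ext <- scheme@gapExtend
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) +
                                  sub[A[i], B[j]])
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

## exhaustive local-alignment enumeration for tiny sequences: recursively
## enumerates every gapped alignment path with free start/stop. Used only
## to validate swOracle itself on a handful of cases.
swEnumerate <- function(a, b, scheme) {
  sub <- scheme@substitution
  open <- scheme@gapOpen; ext <- scheme@gapExtend
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  go <- function(i, j, state) {
    best <- 0   # stop the local alignment here
    if (i <= length(A) && j <= length(B))
      best <- max(best, sub[A[i], B[j]] + go(i + 1, j + 1, "m"))
    if (i <= length(A))
      best <- max(best, -(if (state == "x") ext else open + ext) +
                          go(i + 1, j, "x"))
    if (j <= length(B))
      best <- max(best, -(if (state == "y") ext else open + ext) +
                          go(i, j + 1, "y"))
    best
  }
  best <- 0
  for (i in seq_len(length(A) + 1))
    for (j in seq_len(length(B) + 1))
      best <- max(best, go(i, j, "m"))
  best
}

## ---- independent metric oracles ------------------------------------------

ciOracle <- function(yTrue, yPred) {
  num <- 0; den <- 0
  for (i in seq_along(yTrue)) for (j in seq_len(i - 1)) {
    if (yTrue[i] == yTrue[j]) next
    den <- den + 1
    hi <- which.max(c(yTrue[i], yTrue[j]))
    lo <- 3 - hi
    p <- c(yPred[i], yPred[j])
    num <- num + if (p[hi] > p[lo]) 1 else if (p[hi] == p[lo]) 0.5 else 0
  }
  num / den
}

rm2Oracle <- function(yTrue, yPred) {
  r2 <- summary(stats::lm(yPred ~ yTrue))$r.squared
  fit0 <- stats::lm(yPred ~ 0 + yTrue)
  r02 <- 1 - sum(stats::residuals(fit0)^2) / sum((yPred - mean(yPred))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

auprOracle <- function(yTrue, yPred, threshold) {
  lab <- yTrue >= threshold
  pts <- lapply(sort(unique(yPred), decreasing = TRUE), function(t) {
    pos <- yPred >= t
    c(rec = sum(pos & lab) / sum(lab), prec = sum(pos & lab) / sum(pos))
  })
  prevRec <- 0; area <- 0
  for (p in pts) {
    area <- area + (p["rec"] - prevRec) * p["prec"]
    prevRec <- p["rec"]
  }
  unname(area)
}

## small model configuration used across the model/pipeline tests
tinyModelConfig <- function(seed = 1L, epochs = 3L, drugBranch = "cnn_sep") {
  ModelConfig(nFilters = 8L, filterLength = 4L, embeddingDim = 8L,
              proteinFcSizes = c(16L, 16L, 8L),
              predictorFcSizes = c(16L, 16L, 8L),
              dropout = 0.1, learningRate = 1e-3, batchSize = 16L,
              epochs = epochs, patience = max(5L, epochs), seed = seed,
              drugBranch = drugBranch)
}

tinyDataset <- function(seed = 7L, nFamilies = 2L, members = 3L,
                        len = 60L, nLigands = 4L) {
  generateSyntheticDataset(SyntheticSpec(
    nFamilies = nFamilies, membersPerFamily = members, proteinLength = len,
    nLigands = nLigands, seed = seed))
}
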