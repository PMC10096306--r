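#' Construct a SyntheticSpec
#'
#' Stated world for the synthetic generator: proteins come in families of
#' shared ancestry (so both alignment and compression similarity carry the
#' family signal), ligands are random SMILES-like strings over a
#' 12-character alphabet, and affinity decomposes into a protein-family
#' effect plus a ligand character-composition effect plus Gaussian noise,
#' scaled into a pKd-like range of \[4, 10\]. The two signal components are
#' standardized to equal variance so that both network branches matter.
#'
#' @param nFamilies,membersPerFamily,proteinLength family structure
#'   (defaults 3 x 10, length 400).
#' @param mutationRate per-position substitution probability (default 0.1).
#' @param nLigands number of ligands (default 20).
#' @param ligandLengthRange (min, max) ligand string lengths.
#' @param ligandAlphabet SMILES-plausible single characters.
#' @param noiseSd affinity noise, pKd units (default 0.3, a typical assay
#'   repeatability).
#' @param seed master seed; everything is reproducible from (spec, seed).
#' @return a [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(nFamilies = 3L, membersPerFamily = 10L,
                          proteinLength = 400L, mutationRate = 0.1,
                          nLigands = 20L, ligandLengthRange = c(20L, 60L),
                          ligandAlphabet = c("C", "N", "O", "S", "P", "=",
                                             "#", "(", ")", "1", "2", "c"),
                          noiseSd = 0.3, seed = 1L) {
  methods::new("SyntheticSpec",
               nFamilies = as.integer(nFamilies),
               membersPerFamily = as.integer(membersPerFamily),
               proteinLength = as.integer(proteinLength),
               mutationRate = as.numeric(mutationRate),
               nLigands = as.integer(nLigands),
               ligandLengthRange = as.integer(ligandLengthRange),
               ligandAlphabet = as.character(ligandAlphabet),
               noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Generate a planted-family protein panel
#'
#' Draws one random ancestor per family, then derives each member by
#' independent per-position substitutions at `mutationRate` (substitutions
#' always change the residue). Family membership is returned as the
#' `family` attribute and also encoded in the ids (`F<f>_M<m>`).
#'
#' @param spec a [SyntheticSpec-class].
#' @return named character vector of sequences with attribute `family`
#'   (integer vector).
#' @export
generateProteins <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  withRNG(spec@seed, {
    L <- spec@proteinLength
    fams <- integer(0); seqs <- character(0); ids <- character(0)
    for (f in seq_len(spec@nFamilies)) {
      anc <- sample(AA20, L, replace = TRUE)
      for (m in seq_len(spec@membersPerFamily)) {
        s <- anc
        mut <- which(stats::runif(L) < spec@mutationRate)
        if (length(mut)) {
          ## draw a *different* residue at each mutated site
          repl <- vapply(s[mut], function(r)
            sample(setdiff(AA20, r), 1L), character(1))
          s[mut] <- repl
        }
        seqs <- c(seqs, paste(s, collapse = ""))
        ids <- c(ids, sprintf("F%d_M%d", f, m))
        fams <- c(fams, f)
      }
    }
    structure(stats::setNames(seqs, ids), family = fams)
  })
}

#' Generate random SMILES-like ligand strings
#'
#' Uniform random strings over `spec@ligandAlphabet` with lengths uniform
#' in `spec@ligandLengthRange`. Not chemically valid molecules; they only
#' exercise the character-level encoding paths.
#'
#' @param spec a [SyntheticSpec-class].
#' @return named character vector (`L1`, `L2`, ...).
#' @export
generateLigands <- function(spec) {
  stopifnot(methods::is(spec, "SyntheticSpec"))
  withRNG(spec@seed + 1L, {
    lo <- spec@ligandLengthRange[1]; hi <- spec@ligandLengthRange[2]
    lens <- lo + sample.int(hi - lo + 1L, spec@nLigands, replace = TRUE) - 1L
    s <- vapply(lens, function(L)
      paste(sample(spec@ligandAlphabet, L, replace = TRUE), collapse = ""),
      character(1))
    stats::setNames(s, sprintf("L%d", seq_len(spec@nLigands)))
  })
}

## deterministic part of the affinity surface; exported via metadata$truth
## so tests can evaluate the generative formula as an oracle predictor
.affinityTruth <- function(proteins, ligands, spec) {
  fams <- attr(proteins, "family")
  withRNG(spec@seed + 2L, {
    famEff <- stats::rnorm(spec@nFamilies)
    w <- stats::setNames(stats::rnorm(length(spec@ligandAlphabet)),
                         spec@ligandAlphabet)
    famVec <- famEff[fams]
    comp <- vapply(ligands, function(s) {
      ch <- strsplit(s, "")[[1]]
      f <- table(factor(ch, levels = spec@ligandAlphabet)) / length(ch)
      sum(w * as.numeric(f))
    }, numeric(1))
    std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
           else x - mean(x)
    raw <- outer(std(famVec), std(comp), "+")
    lo <- min(raw); hi <- max(raw)
    surface <- if (hi > lo) 4 + 6 * (raw - lo) / (hi - lo)
               else matrix(7, nrow(raw), ncol(raw))
    dimnames(surface) <- list(names(proteins), names(ligands))
    list(surface = surface, familyEffects = famEff, charWeights = w,
         family = fams, scale = c(lo = lo, hi = hi))
  })
}

#' Generate a full synthetic affinity dataset
#'
#' Affinity(p, l) = scaled(family effect of p + composition effect of l)
#' + Gaussian noise, over the full protein x ligand grid. The noiseless
#' surface, family assignments, family effects and character weights are
#' stored in `datasetMetadata()$truth` for recovery tests; the noiseless
#' surface is an oracle predictor achieving CI = 1 at `noiseSd = 0`.
#'
#' @param proteins output of [generateProteins()].
#' @param ligands output of [generateLigands()].
#' @param spec the same [SyntheticSpec-class] used to generate them.
#' @return an [AffinityDataset-class] with measure `"pre-transformed"`.
#' @export
generateAffinities <- function(proteins, ligands, spec) {
  stopifnot(length(proteins) > 0, length(ligands) > 0)
  truth <- .affinityTruth(proteins, ligands, spec)
  grid <- expand.grid(protein_id = names(proteins),
                      ligand_id = names(ligands),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- truth$surface[cbind(grid$protein_id, grid$ligand_id)]
  noise <- if (spec@noiseSd > 0)
    withRNG(spec@seed + 3L, stats::rnorm(nrow(grid), 0, spec@noiseSd))
  else 0
  rec <- data.frame(grid, value = base + noise,
                    measure = "pre-transformed")
  AffinityDataset(proteins, ligands, rec,
                  metadata = list(truth = truth,
                                  spec = list(seed = spec@seed,
                                              noiseSd = spec@noiseSd)))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: [generateProteins()] + [generateLigands()] +
#' [generateAffinities()] from a single spec.
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [AffinityDataset-class].
#' @examples
#' ds <- generateSyntheticDataset(SyntheticSpec(nFamilies = 2,
#'   membersPerFamily = 3, proteinLength = 60, nLigands = 4, seed = 7))
#' ds
#' @export
generateSyntheticDataset <- function(spec = SyntheticSpec()) {
  p <- generateProteins(spec)
  l <- generateLigands(spec)
  generateAffinities(p, l, spec)
}
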