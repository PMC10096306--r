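---
title: "Unified alignment- and compression-based protein encoding for binding-affinity regression"
author: "compDTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{compDTA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Predicting the strength of a protein–ligand interaction (a dimensionless
log-scale label: pKd, pKi or a KIBA score) from the protein's amino-acid
sequence and the ligand's SMILES string is a regression task at the front of
virtual screening. Sequence-only methods must choose a protein
representation. compDTA represents each protein by its vector of
similarities to a reference panel, under a similarity that fuses two
complementary views of sequence relatedness:

* **alignment view** — the Smith–Waterman local-alignment score, normalized
  by the geometric mean of the self-scores,

  $$S_{SW}(p_i, p_j) = \frac{SW(p_i, p_j)}{\sqrt{SW(p_i, p_i)\,SW(p_j, p_j)}},$$

  which is 1 for identical sequences, 0 when no positive-scoring local
  alignment exists, and captures homology through conserved, co-linear
  regions;

* **compression view** — one minus the normalized compression distance,

  $$NCD(p_i, p_j) = \frac{C(p_i p_j) - \min\{C(p_i), C(p_j)\}}{\max\{C(p_i), C(p_j)\}},
  \qquad S_{NCD} = 1 - NCD,$$

  where $C(\cdot)$ is the LZMA-compressed length in bytes. NCD approximates
  the normalized information distance and is alignment-free: it sees shared
  content regardless of rearrangement.

The unified similarity is their entrywise product,
$S(p_i,p_j) = S_{NCD}(p_i,p_j) \cdot S_{SW}(p_i,p_j)$, computed over the
panel as the Hadamard product of the two similarity matrices. A protein's
encoding is its row of this matrix; proteins unseen at training time (cold
starts) are encoded against the *training* panel only.

Ligands are label-encoded at character level: each SMILES character maps to
a small integer, strings are truncated or zero-padded to a fixed length
(85/100/200 are typical choices per dataset style). The two encodings feed
a deliberately light two-branch network: the protein vector passes through
three fully-connected rectifier layers; the ligand codes pass through an
embedding, two 1-D convolutions, a separable convolution and a global
max-pool; the concatenated branch outputs pass through three
fully-connected layers and a scalar linear output trained on mean squared
error.

## Why a separable convolution

The last drug-branch layer is a depthwise convolution (one length-$f$
kernel per channel) followed by a pointwise $1{\times}1$ channel mixing.
For $f = 8$ and $32 \to 32$ channels this costs $8\cdot32 + 32\cdot32 =
1280$ weights against $8\cdot32\cdot32 = 8192$ for a standard convolution
of the same shape — the parameter economy that keeps the whole model small
enough to train comfortably on a CPU. `conv1dParams()` and
`separableConv1dParams()` expose the closed forms; the test suite checks
the built model's weight arrays against them exactly.

## Tunable parameters that matter

| parameter | default | units / range | why this default |
|---|---|---|---|
| substitution matrix | BLOSUM62, `X` := 0 | log-odds scores | standard protein scoring; neutral `X` avoids hard failures on ambiguous residues |
| gap open / extend | 10 / 0.5 | score penalty | water-style protein defaults; gap of length $L$ costs open $+ L\cdot$extend |
| LZMA level | 9 | preset 0–9 | maximal compression gives NCD the most contrast on short proteins |
| LZMA stream | container (xz) | – | see numerical choices below |
| combiner | product | product / sw_only / ncd_only / weighted_sum | the unified measure; the others exist for ablations and sweeps |
| SMILES max length | longest training SMILES | characters | dataset-dependent; 85/100/200 for the common public sets |
| filters / length | 32 / 8 | – | the small end of the published sweet spot |
| embedding dim | 128 | – | character-CNN lineage convention |
| FC widths | 1024/1024/512 | neurons | lineage convention; tests use a scaled-down 64/64/32 profile |
| dropout | 0.1 | rate, predictor block | light regularization |
| optimizer | Adam, lr $10^{-3}$, batch 256 | – | lineage convention |
| early stopping | patience 15, best-weights restore | epochs | guards the long default schedule |

## Numerical and design choices

* **Eq-layout ambiguity in the normalization.** The normalized SW score is
  computed as $SW(i,j)/\sqrt{SW(i,i)SW(j,j)}$; the geometric-mean form is
  the one that makes self-similarity exactly 1, which the matrix contracts
  require. Values are clamped to $[0,1]$ as a guard against pathological
  scoring schemes.
* **LZMA access.** R's own liblzma is reachable through `xzfile()`
  connections, which is how `"container"` mode computes lengths — fully
  deterministic, levels 0–9, no external process. A raw (header-free)
  LZMA2 mode is available through the `xz` binary when present; the xz
  container adds a constant ~60-byte overhead that cancels in the NCD
  numerator and only mildly dilutes the denominator, and every distance
  contract in the test suite holds under container mode, so container is
  the default rather than raw.
* **Symmetrization.** Real compressors are not exactly order-invariant, so
  $S_{NCD}$ averages both concatenation orders; the similarity matrix is
  then symmetric by construction rather than approximately.
* **Diagonal convention.** Compression self-similarity is genuinely below
  1 (overhead is real); the NCD matrix records it as-is. The combined
  encoding forces its diagonal to 1 — in its own representation a protein
  should be maximally similar to itself. Clamping events are counted in
  the matrix metadata.
* **Cold-start reference panel.** Encoding unseen proteins against the
  training panel only is a deliberate leakage-free choice: building the
  panel from all sequences of a dataset would let test identities shape
  the representation.
* **Unknown SMILES characters** map to a reserved code $K{+}1$ with a
  warning instead of erroring: cold-drug evaluation must survive unseen
  characters.
* **Gap-cost convention.** A gap of length $L$ costs
  $\mathrm{open} + L\cdot\mathrm{extend}$ (the convention of the
  underlying alignment engine); the independent dynamic-programming oracle
  in the test suite uses the same convention.
* **Ties.** The concordance index counts only pairs with distinct true
  values and scores tied predictions 0.5. The PR curve is traversed one
  distinct score at a time and integrated stepwise, so constant scores
  give exactly the positive prevalence.
* **rm2 radicand.** $r_m^2 = r^2(1 - \sqrt{|r^2 - r_0^2|})$ uses the
  absolute difference under the root, the standard guard against negative
  radicands.
* **Duplicate records** collapse to the maximum affinity by default
  (the harmonization rule used for Kd-type data); `mean` suits KIBA-style
  scores that are already aggregated; `error` makes duplicates fatal.
  Redundant-protein filtering is a greedy first-kept pass at a
  configurable similarity threshold (default 0.99) — the criterion behind
  published "refined" panels is not documented, so this is a mechanism,
  not a reproduction.
* **Determinism.** All stochastic steps (entity shuffling, weight
  initialization, batch order, dropout, label permutation) draw from
  seeded streams scoped with an RNG guard, so identical configs and seeds
  reproduce folds, initial checkpoints and metric files bit-for-bit under
  a single-threaded BLAS.

## The synthetic world

The generator plants exactly the structure the method assumes, so every
stage is testable without downloads:

* proteins form `nFamilies` families (default 3×10, length 400): one
  random ancestor each, members derived by i.i.d. substitutions at
  `mutationRate` 0.1 — within-family similarity is then visible to both
  the alignment and the compression view;
* ligands are uniform random strings over 12 SMILES-plausible characters,
  lengths 20–60;
* affinity = standardized family effect + standardized ligand
  character-composition effect, rescaled into a pKd-like $[4, 10]$, plus
  Gaussian noise (`noiseSd` 0.3, a typical assay repeatability). The two
  components are standardized to equal variance *on purpose*: the protein
  branch alone cannot explain the composition part nor vice versa, so
  end-to-end tests exercise the wiring of both branches.

The noiseless surface and the planted parameters ride along in the dataset
metadata, giving tests a closed-form oracle predictor (CI exactly 1 at
zero noise, degrading monotonically with noise).

What a green synthetic run does **not** establish: the generator has no
chemistry (random strings, not molecules), no realistic evolutionary model
(i.i.d. substitutions, no indels — so the alignment and compression views
are more redundant here than on real proteins, and feature-ablation
differences are small), and no assay artifacts. Benchmark-scale accuracy
claims on Davis/Kiba-class data are out of scope for the test suite.

## Known limitations

* The network is implemented in plain R; it is comfortably fast at the
  tested scales (thousands of records, tens of epochs) but not tuned for
  benchmark-scale corpora.
* Affinity measures are tagged per record but never interconverted; mixing
  pKd and pKi in one dataset is allowed and left to the user's judgment.
* Raw-stream LZMA depends on an external `xz` binary; container mode is
  the portable path.
* `weighted_sum` exists for encoder sweeps; the product combiner is the
  method. No claim is made that any fixed weight dominates the product.
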