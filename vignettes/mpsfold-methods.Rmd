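---
title: "Probability-matrix folding: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-matrix folding: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsfold)
```

## The problem and the approach

An RNA secondary structure is the set of base pairs a single-stranded RNA
forms by folding back on itself; for nested (pseudoknot-free) structures it
is fully described by a dot-bracket string over `(`, `)`, `.`. Classical
predictors search for a minimum-free-energy configuration. `mpsfold`
implements a learning-based alternative with three stages:

1. **Encoding.** Each sequence becomes an `n x n` pairing matrix whose
   entry `(i, j)` measures how plausibly bases `i` and `j` sit inside a
   stem. Per-base slices of this matrix are the classifier's input.
2. **Classification.** A small convolutional network assigns every base a
   probability triple over the three dot-bracket labels.
3. **Decoding.** A Nussinov-style dynamic program returns the valid nested
   structure with the maximum summed label probability.

The package also provides the surrounding tooling a study needs: readers
and writers for FASTA, CT, BPSEQ and dot-bracket files, dataset cleaning
(pseudoknot filtering, redundancy removal, stratified 7:2:1 splits),
base-pair-level evaluation, a synthetic data generator, and a CLI.

## The pairing-matrix encoding

The pair weight of two bases follows their hydrogen-bond count: 2 for A-U,
3 for G-C, and a configurable `x` for the G-U wobble with default
`x = 0.8`, the value at which classification accuracy was found optimal;
values must stay in `(0, 2)`, i.e. strictly between "no pair" and a
Watson-Crick A-U. All other combinations weigh 0.

A pair is credible mainly when it sits inside a *stem* — a run of stacked
pairs `(i-t, j+t), ..., (i, j), ..., (i+t, j-t)`. The encoding therefore
sums the weights of the contiguous candidate stem through `(i, j)`, damped
by a Gaussian `g(t) = exp(-t^2 / (2*sigma^2))` in the offset `t`:

```
W[i,j] = sum_{t>=0} g(t) P(R[i-t], R[j+t]) + sum_{t>=1} g(t) P(R[i+t], R[j-t])
```

Each directional sum truncates at the sequence boundary, where the inward
indices meet, or at the first offset whose own pair weight is zero, so
only contiguous stems accumulate. Real stems show up as anti-diagonal
streaks that peak in the stem interior and decay toward the ends — the
signature the classifier exploits.

Two numerical choices here were genuinely open and are ours: the Gaussian
width `sigma` (default 1.0 — with contiguous-stem truncation the precise
width matters little, and 1.0 makes the weight effectively vanish within
±3 offsets) and the truncation horizon `max_offset` (default 30, far past
where `g(t)` underflows at `sigma = 1`; it exists to bound work for large
`sigma`). The matrix diagonal needs no special-casing: a base cannot pair
with itself, so `W[i,i] = 0` falls out of the weight table.

### Windows and rescaling

Base `i`'s model input is the `d`-row band of `W` centred on row `i`
(`d` odd; rows outside the matrix are zero-filled — zero is the natural
neutral value since it is also the "cannot pair" code), rescaled from `n`
to a fixed `L` columns by corner-aligned linear interpolation along the
length axis. Interpolation is the minimal deterministic reading of
"image-style rescaling": it preserves constants and endpoints, and rows
are never resampled because `d` is fixed by configuration. The two
reference configurations are `11 x 120` (single-family, stems up to 11,
mean length near 120 nt) and `19 x 128` (multi-family). The helper
`dataset_stats()` computes exactly these two quantities — maximum stacked
stem length and rounded mean sequence length — so a user can derive `d`
and `L` from their own data.

## The classifier

The network is deliberately small: `conv_blocks` blocks of sixteen 3x3
same-padded kernels with ReLU followed by 3x3 max-pooling, then two
32-node ReLU dense layers and a 3-way softmax. The single-family setup
uses 3 blocks, batch 256 and 400 optimiser steps; the general setup uses
2 blocks, batch 512 and 2000 steps. Weights are Xavier-initialised;
training is plain mini-batch SGD on the categorical cross-entropy.

Choices the architecture description leaves open, fixed here:

* **Pooling stride and padding.** 3x3 pooling with stride 2 and SAME
  padding (output `ceiling(in/2)`), same-padded convolutions. This is the
  minimal scheme under which an `11 x 120` input survives three blocks and
  a `19 x 128` input two.
* **Learning rate.** Not reported anywhere; default 0.01, configurable.
* **"Iterations".** Read literally as optimiser steps (batches), not
  epochs.
* **Class balance.** Unpaired bases outnumber each bracket class, so
  minority classes are upsampled with replacement to the majority count
  before training; no original window is ever discarded.
* **Weights are artifacts, not assets.** No pretrained checkpoint ships
  with the package; models are trained reproducibly (bit-for-bit given
  seed, config and data) on the user's or the generator's data, and a
  checkpoint stores the encoding configuration in a JSON sidecar that
  prediction verifies, so a model can never be fed differently-encoded
  inputs.

## Maximum-probability-sum decoding

Given per-base probabilities `(p_left, p_right, p_point)`, the decoder
fills `N(i, j)`, the best attainable summed label probability on
`[i, j]`, by interval length:

```
N(i,i) = p_point(i);  N(i,j) = 0 for j < i
N(i,j) = max( N(i+1,j) + p_point(i),
              N(i,j-1) + p_point(j),
              N(i+1,j-1) + delta(i,j),
              max_{i<k<j} N(i,k) + N(k+1,j) )
delta(i,j) = p_left(i) + p_right(j)   if (R_i,R_j) pairable and j-i-1 >= min_loop
           = p_point(i) + p_point(j)  otherwise
```

This is the Nussinov recursion with pair counts replaced by label
probabilities. Decisions worth recording:

* **Base cases** are not forced by the recursion itself; the ones above
  make the two-base interval behave correctly.
* **Minimum hairpin loop.** Sterically, a hairpin needs ~3 unpaired bases;
  `min_loop = 3` is the default, with 0 reproducing the unconstrained
  recursion. Without the constraint the decoder emits impossible one-base
  loops.
* **Tie-breaking.** Traceback evaluates the cases in the order written
  above (bifurcation at the smallest `k`) and takes the first achieving
  the maximum, so output is deterministic. When the maximum is achieved
  through the `delta` fallback (ends not pairable), both ends are labelled
  unpaired — the fallback equals unpairing both ends and never creates a
  pair.
* **No re-normalisation.** Probabilities are used as given; any
  non-negative per-base scores work, so the decoder composes with external
  predictors.
* **Verification.** `enumerate_structures()` exhaustively lists all valid
  nested structures for small `n`; the test suite checks on hundreds of
  seeded random instances (`n <= 12`, Dirichlet probability rows) that the
  DP score equals the brute-force maximum, and that with unit pair scores
  and `min_loop = 0` the DP collapses to classic Nussinov pair counting
  against an independent implementation.

## Evaluation conventions

Predictions are scored at the base-pair level: sensitivity is the fraction
of reference pairs predicted (recall), "specificity" — following the
folding literature — is the fraction of predicted pairs that are correct
(precision/PPV), and the F-score is their harmonic mean. Pair matching is
exact-index by default; a ±1 slip tolerance exists behind a flag for
comparison with slip-tolerant literature. Because published tables rarely
state their pooling, `evaluate_structures()` reports both the micro
average (pool tp/fp/fn, then take ratios) and the macro average (mean of
per-sequence scores; sequences without reference pairs have undefined
sensitivity and are dropped from macro means).

## The synthetic data generator

`simulate_dataset()` draws valid nested structures by a recursive process
(each position opens a pair with probability `pair_density` when a partner
respecting `min_loop` fits; the partner is uniform among feasible
positions), then fills in compatible sequences (Watson-Crick pairs with a
`gu_fraction` of wobbles, uniform unpaired bases) and, optionally, noisy
probability tables (mass `1 - eps` on the true label, Dirichlet
perturbation with concentration 50 — one interpretable difficulty knob,
`eps`, rather than two). Defaults emulate a 5sRNA-like family: lengths
60–120 nt, `min_loop = 3`, `pair_density = 0.5`, 10% wobbles.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: thermodynamic plausibility, family-specific
sequence composition and covariation, conserved multi-branch
architectures, and modified or ambiguous nucleotides. Synthetic results
validate the machinery (encode, learn, decode, score), not biological
accuracy; published dataset-level accuracies require the real family
datasets and are deliberately out of scope here.

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen to exercise
every stage meaningfully: the end-to-end check trains on 500 synthetic
sequences (about 45,000 windows before balancing) for 300 SGD steps at
batch 256 and evaluates on 50 held-out sequences against the all-unpaired
baseline. Oracle-equivalence checks use 500 instances at `n <= 12`, where
exhaustive enumeration is tractable; recovery checks use 200 structures at
`n = 80`.

A caveat worth stating plainly: on *randomly generated* structures the
window representation carries only a weak cue for distinguishing `(` from
`)` — that distinction leans on where the stem streak lies relative to the
base's own position, and in a real, structurally conserved family it is
additionally (and strongly) correlated with relative sequence position,
which the rescaled window encodes implicitly. The synthetic family has no
such conservation by design, so desk-scale classification stays close to
the class prior and the end-to-end F-score, while reliably above the
all-unpaired baseline, is far below what a conserved family permits. We
verified this is not an optimiser artefact: raising the learning rate to
0.05 or 0.1 changes the outcome only marginally, and the same network
reaches >95% accuracy on a separable toy family within 150 steps (see the
model tests).

## Known limitations

* Pseudoknots are excluded by construction, in the data filters, the
  dot-bracket representation and the decoder.
* The decoder returns a single optimal structure; no suboptimal ensembles
  or partition functions.
* Per-base label probabilities ignore *which* partner a base pairs with;
  the DP restores consistency, but two mutually incompatible
  high-probability stems are resolved purely by score.
* The classifier is an ordinary CNN trained from scratch per dataset;
  with little training data its probabilities are close to uniform and
  the decoder then behaves like a weighted Nussinov algorithm.
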