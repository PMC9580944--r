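---
title: "synfold: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synfold: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package is for

Deep models for RNA secondary structure are usually trained on curated
structure databases that are dominated by a handful of RNA families, which
makes it hard to tell whether a model has learned folding or has memorized
the database. `synfold` takes the complementary route: it generates unlimited
*synthetic* ground truth by folding random sequences with a thermodynamic
oracle, trains small reference predictors on that data, and measures what
they do and do not learn — structural statistics, length-distribution bias,
the scaling of predicted pair counts with sequence length, and
structure-bias overfitting.

Because every dataset is generated from a seeded sampler and a deterministic
oracle, train/validation/test independence is guaranteed by construction and
any bias present is a bias we put there on purpose.

## The folding oracle

The ground-truth engine is a Zuker-style minimum-free-energy (MFE) dynamic
program over the standard nearest-neighbor model: energies for helix
stacking, hairpin/bulge/interior loop initiation by size, terminal
mismatches per loop context, 5'/3' dangles, an affine multiloop model
(closing penalty `a = 9.3` kcal/mol, branch term `b = -0.9` kcal/mol, zero
per-unpaired-base cost), the Ninio asymmetry penalty for interior loops,
terminal-AU penalties, and tabulated special tri-/tetra-/hexaloop hairpins.
Helix ends in exterior and multiloops receive both-side mismatch terms
regardless of neighbor pairing (the "dangles = 2" convention of standard MFE
folders). Minimum hairpin size is 3 unpaired nucleotides; interior loops are
capped at 30 unpaired nucleotides (standard); energies are integer
dacal/mol at 37 °C.

Two deliberate departures from a full reference implementation:

* The measured lookup tables for 1x1, 2x1 and 2x2 interior loops (about
  15,000 values) are **not** embedded; these loops are scored by the generic
  interior-loop rule (size initiation + asymmetry + terminal mismatches).
  The engine is therefore labeled `turner2004-core`.
* No co-axial stacking, no G-quadruplexes, no lonely-pair suppression
  (`--noLP` off is also the reference default).

Consequences, measured once against an external reference folder before the
parameterization was frozen: individual MFE structures agree exactly for
most short sequences (20/20 at 40 nt) and for roughly half of random 70-nt
sequences, while *pooled* statistics — the quantities this package actually
studies — agree closely: paired-base fraction within ~0.007, mean helix
count within ~1%, and an identical median multiloop length (9 nt at 100 nt
over 2000 structures). All quantitative claims in the package are therefore
made at the level of dataset statistics, not per-sequence structure
identity.

A clearly labeled non-thermodynamic fallback (`folding_oracle("nussinov")`,
base-pair maximization with minimum hairpin 3) exists for environments and
tests that need an engine-independent oracle, and
`folding_oracle("viennarna")` shells out to an external `RNAfold` binary
when one is installed (it raises an explicit environment error otherwise).

## Structure algebra

`pair_table` is the lossless representation: one partner index per position
(1-based in R, `NA` = unpaired; the compiled kernels are 0-based). Crossing
pairs are representable and flagged; positions with multiple partners — which
raw network output can produce — live in `raw_pair_assignment`.

* **Pseudoknot removal** maximizes the number (or total weight) of retained
  pairs over all mutually non-crossing, endpoint-disjoint subsets by interval
  dynamic programming, with ties broken toward the lexicographically smallest
  pair. The objective is a package choice (the source procedure is described
  only as "removing pseudoknots"); maximum cardinality/weight is deterministic,
  oracle-checkable (the test suite compares against exhaustive enumeration up
  to 12 pairs) and matches common practice.
* **Matrix postprocessing** (`matrix_to_structure`) keeps the per-row maximum
  (ties toward the smallest column), drops entries below the threshold
  (default 0.5), symmetrizes — by default a pair survives if it is the row
  maximum in *either* row and the symmetrized score still clears the
  threshold; a stricter `"both"` mode is a switch — and resolves the remaining
  multi-partner and crossing conflicts in one weighted pseudoknot-removal
  pass.
* **Loop decomposition** classifies unpaired bases by the loop that encloses
  them: hairpin (no branch), bulge (one branch, unpaired on one side),
  interior (one branch, both sides), multiloop (two or more branches),
  exterior (not enclosed). Multiloop "length" is the number of unpaired
  nucleotides in the loop, a definition chosen for consistency with the
  reference statistics (multiloop base fraction x sequence length / loop
  count ~ printed median). The exterior loop counts as one element when at
  least one external unpaired base or at least two top-level branches exist;
  a single helix spanning the whole sequence has none. This matches the
  reference tables, where the mean exterior-loop count is slightly below 1.
* **Multi-pairing census**: every pair incident to a position with two or
  more partners counts one multi-pairing per (position, pair) incidence; a
  `"pairs"` rule (each such pair once) is exposed because the reference
  counting convention is not stated.

## Synthetic datasets

* Sequences are i.i.d. over {A, C, G, U} (uniform by default; the composition
  is a parameter), with duplicates re-drawn. For degenerate compositions
  where uniqueness is impossible the sampler warns and returns duplicates
  rather than failing, since the degenerate case is a documented contract.
* The four preset length distributions on 25–100 nt are package choices (the
  source figure is not numerically specified): D1 uniform; D2 `Beta(5, 1.5)`
  discretized (skewed long); D3 `Beta(4, 4)` (symmetric, mode near 62 nt);
  D4 `Beta(1.2, 6)` (strongly skewed short). Cross-distribution conclusions
  are expected to be robust to the exact shapes, and the shapes are exposed
  through `length_distribution()`.
* **Dinucleotide shuffling** uses the Altschul–Erickson Euler-walk
  construction: a random last-out edge per vertex forming an arborescence
  into the terminal vertex, remaining out-edges in random order, then one
  Eulerian walk. Dinucleotide counts (hence mononucleotide composition and
  the first and last residue) are conserved exactly.
* **Inverse folding** seeds a sequence from the target structure (helices
  GC-biased, loops A-rich) and hill-climbs under the oracle: mutate one
  unpaired base or one paired couple at a time, accept non-worsening
  base-pair distance, best of `tries` restarts (default 6, the reference
  protocol). Distance 0 means the design folds exactly into the target.
* The **bias emulator** stands in for a family-dominated database: a handful
  of frozen shape templates (hairpin, bulged hairpin, two-hairpin,
  cloverleaf) jittered slightly per variant, all nested, 25–120 nt,
  sequence-free. `replicate_bias_dataset()` then applies the reference
  filters (25–120 nt; drop structures with more than 6 crossing-involved
  pairs; remove pseudoknots from the rest), designs sequences by inverse
  folding and — deliberately — takes the *refold* of the designed sequence as
  ground truth, not the target structure.

What a green test on these data does **not** establish: that any model would
perform comparably on experimentally determined structures. The oracle world
has no pseudoknots, no base triples, no tertiary effects and no measurement
noise; its value is that failures on it are unambiguous model failures.

## Predictors

All models are implemented on a small batched matrix-algebra engine (dense,
1-D/2-D convolution and LSTM layers with hand-written backpropagation, Adam,
binary cross-entropy on logits; every layer's gradient is verified
numerically in the test suite). This keeps the package free of heavyweight
runtime dependencies; the cost is that full-scale training (10^4–10^5
sequences, 100 epochs) is hours of CPU, so tests and the worked examples run
scaled-down. Scaled-down MCCs are lower than the reference full-scale
values; qualitative contrasts (matrix models far above the pairedness
ceiling; quadratic pair-count growth; bias gaps; grid structure) are the
claims under test.

* Pairedness: sliding-window FFN (two hidden layers) and 1-D CNN
  (convolution + max-pool + dense head) over one-hot windows with an
  explicit padding channel, and a window-less bidirectional LSTM (1 or 3
  layers, 40 or 80 units). The exact reference FFN/CNN layer sizes are not
  public; sizes here are configuration defaults, not claimed faithful.
* Matrix models: the n x n x 8 outer-concatenation encoding; variants 0 and
  1 are convolutional residual networks of different depth, variant 3 (and
  only variant 3) adds a bidirectional row/column ("2-D") LSTM block.
  Faithfulness is claimed at the block-structure level; widths and depths
  are parameters.
* Training selects the epoch with maximum validation MCC (up to the
  protocol's epoch cap). Matrix training auto-balances the positive class in
  the loss (pairs are ~1% of matrix entries; unweighted training collapses
  to the all-unpaired prediction at small scale). MCC on a degenerate
  confusion matrix is reported as 0.

## Numerical and procedural choices

* Quadratic-term significance in scaling fits: nested-model F-test at
  alpha = 0.01.
* Matrix-model MCC is computed per-entry (upper triangle, binarized at 0.5)
  for model selection and grids; `evaluate_predictions()` also reports
  per-pair (after postprocessing) and per-base granularities, since the
  reference does not state which it used.
* Pair counts from matrices are upper-triangle by default so the count of a
  ground-truth matrix equals its pair number; `full_matrix = TRUE` replicates
  the raw "entries > 0.5" convention.
* All randomness flows through integer seeds; derived seeds stay below 2^31.
  Identical seeds give byte-identical bundles for a fixed oracle version.

## Known limitations

* The oracle is Turner-2004-*core*: per-sequence MFE structures can differ
  from a full reference implementation in the placement of small interior
  loops; pooled statistics agree to well within the package's test
  tolerances, and the oracle id is recorded in every bundle and manifest.
* The NN engine is CPU-bound R; it is meant for controlled scaled-down
  experiments, not for training competitive predictors.
* `bias_emulator` is a synthetic stand-in for a real structure database and
  is labeled as such; experiments on real collections should read them via
  the bpseq/dot-bracket interfaces.
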