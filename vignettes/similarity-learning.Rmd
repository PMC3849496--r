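---
title: "Learning gene similarity to optimise association networks"
author: "similearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning gene similarity to optimise association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(similearn)
```

## The model

`similearn` treats gene function prediction as a three-stage problem on
a functional association network: learn a per-category similarity,
rebuild the network with it, propagate labels on the rebuilt network.

**Feature map.** Given a combined network over `n` genes with
non-negative weights `a_ij`, and `d` annotated training genes, every
gene is represented by its weight vector to the training genes,
`Φ(g_l) = (a_l1, …, a_ld)ᵀ`. Because the input network is sparsified to
the `k` strongest connections per node, each `Φ` has at most `k`
non-zeros and the bilinear score below costs `O(k²)` regardless of `d`.

**Bilinear similarity.** For a category `C` the similarity is
`S_W(g_i, g_j) = Φ(g_i)ᵀ W_C Φ(g_j)` with `W_C` a dense `d × d` matrix
initialised to the identity. `W_C` is *not* constrained to be symmetric
or positive; asymmetry is resolved only at reconstruction, and
negativity only by clamping reconstructed weights.

**Online learning.** Training signals are triplets `(g, g⁺, g⁻)`:
anchor and positive drawn uniformly without replacement from the
category's positives, the negative drawn from genes that are annotated
neither to `C` nor to any descendant of `C` *and* whose semantic
similarity to the anchor falls below a threshold (default 0.4). On
each margin-violating triplet (hinge loss
`l = max(1 − S_W(g,g⁺) + S_W(g,g⁻), 0) > 0`) the Passive–Aggressive
step `W ← W + τ V`, `V = Φ(g)(Φ(g⁺) − Φ(g⁻))ᵀ`,
`τ = min(α, l/‖V‖²_F)`, makes the smallest Frobenius-norm change that
satisfies the margin; `α` caps the step ("soft margin"). When `τ` is
unclamped, the triplet's post-update loss is exactly zero — the test
suite asserts this to 1e−9 on a thousand random violating triplets.
Since `V` has one non-zero row per non-zero of `Φ(g)` and non-zero
columns only where `Φ(g⁺)` and `Φ(g⁻)` differ, each update touches an
at most `k × 2k` block of `W`.

**Semantic similarity.** The negative-eligibility score `r` is a
best-match-average (BMA) of normalised Resnik term similarities:
`IC(t) = −log(n_t / n_root)` over the closed annotation corpus,
`sim(t₁, t₂) = IC(MICA)/max IC` with MICA the most informative common
ancestor (each term counts as its own ancestor), and the gene-level
score averages each term's best cross-gene match in both directions
(`|T_A| + |T_B|` addends). Normalising by the corpus maximum IC keeps
`r ∈ [0, 1]`, which the 0.4 threshold and the `(1−r)/z`, `r/z`
sampling weights presuppose; the threshold is configurable for users
who prefer a different calibration. Terms annotating zero genes are
omitted from the IC table instead of being given infinite IC, so they
can never dominate a BMA. The probability denominator is the count of
genes reaching the root — i.e. all annotated genes — the standard
corpus convention.

**Reconstruction.** `a′_ij = (S_W(g_i,g_j) + S_W(g_j,g_i))/2`,
negatives clamped to 0 (the Laplacian downstream requires non-negative
weights), exact zeros dropped, then union-of-per-node-top-`k`
sparsification. The union rule (an edge survives if either endpoint
ranks it) keeps the graph symmetric, which propagation requires. At
the scales this package targets (`n` up to a few thousand) the full
score matrix is formed blockwise as `Φ W Φᵀ`; no candidate-pair
pruning is needed.

**Propagation.** Scores minimise
`∑(y_i − f_i)² + σ ∑ a′_ij (f_i − f_j)²`, i.e. `f = (I + σL)⁻¹y` with
`L = D − A′`. The system is solved by a sparse symmetric
positive-definite factorisation (never by forming the inverse), and
the residual is checked against `1e−8 · ‖y‖`. Positives get `y = +1`;
negatives (genes lacking the category and all its descendants) get
`−1`; everything else gets the imbalance prior `(d⁺ − d⁻)/(d⁺ + d⁻)`.
Isolated genes keep `f_i = y_i` — their system row is the identity.
Scores are used directly for AUC ranking; `thresholdCalls()` exists
for users who need hard calls but plays no role in evaluation.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | 50 | per-node strongest connections kept, for both the input and reconstructed networks; the conventional sparsification for association networks of this kind |
| `threshold` | 0.4 | BMA similarity below which a gene counts as unrelated to the anchor; on the normalised `r ∈ [0,1]` scale |
| `strategy` | `favor_borderline` | negative sampling weights: uniform, `(1−r)/z`, or `r/z`; borderline-favouring concentrates updates on hard negatives and saturates in the fewest iterations |
| `alpha` | 0.1 | PA aggressiveness (cap on `τ`, dimensionless); small values keep single noisy triplets from derailing `W` |
| `checkInterval` | 2000 | iterations between validation-AUC checks |
| `patience`, `minDelta` | 3, 1e−4 | "saturation": stop after `patience` consecutive checks without a `> minDelta` AUC gain, return the best `W` seen |
| `sigma` | 1 | propagation trade-off between fitting the prior labels and smoothing over edges |
| `nFolds`, `valFraction` | 3, 0.25 | cross-validation folds and the per-fold validation holdout used for early stopping |

`alpha` and `sigma` are genuinely open choices — no canonical value
exists for them in this model family — so both are plain configuration
with conservative defaults; every result the package reports is
recomputed, not cached, so changing them is safe.

Two further design points were open and are resolved as follows. The
saturation rule needed an operational definition: best-validation-AUC
selection with patience, plus an immediate stop (returning `W⁰ = I`)
when the very first check already falls below the identity baseline —
categories whose structure the bilinear model cannot capture then
gracefully degrade to the untrained baseline instead of getting worse.
And validation AUC during training uses the full
reconstruct-then-propagate path on the training+validation genes: it
is the quantity the method ultimately optimises, and a cheaper proxy
(e.g. raw triplet accuracy) can disagree with it near saturation.

## The synthetic benchmark

`generateBenchmark()` emulates the statistical shape of a real study:
a random rooted DAG with diamond-style multiple inheritance
(`generateOntology`), multi-label annotations drawn from power-law
leaf-term popularity and then ancestor-closed, with a hidden truth
split emulating not-yet-annotated genes (`generateAnnotations`), and
heterogeneous sources from a Gaussian latent-factor model — genes
sharing leaf terms share loading vectors, so within-term feature
correlation grows with `signal/noise`; one source is thresholded into
a binary interaction list (`generateSources`). Everything regenerates
bit-identically from the seed.

Default conditions are 300 genes, 20 terms, 4 sources, `signal = 1`,
`noise = 1`: small enough to cross-validate in minutes, large enough
that categories span the [3–100]-positive range used in reporting. For
the end-to-end checks the training schedule is scaled to the corpus:
validation checks every 500 iterations with a 3000-iteration cap,
since on a ~200-gene training fold saturation arrives within a few
thousand triplets (the full-genome default of 2000-iteration checks is
meant for corpora with thousands of training genes).

What passing on this benchmark does show: the whole chain — parsers,
semantic similarity, sampling, PA learning, reconstruction,
propagation, evaluation — recovers planted co-functionality and the
learned `W_C` ranks no worse (and typically better) than its identity
initialisation. What it does not show: performance on real genomes.
The generator's modules are conditionally independent given leaf
memberships, its noise is Gaussian and homoscedastic, its DAG has none
of GO's depth or fan-out statistics, and its class imbalance, while
strong, is milder than a real annotation corpus. Absolute AUCs here
transfer to no real dataset; only the relative behaviour of the
pipeline's variants is informative.

## Numerical choices and degenerate inputs

* Top-`k` ties break by (weight descending, partner identifier
  ascending) so results are platform-independent.
* `IC(root)` is set to exactly 0 (not `−log(1)` with rounding noise),
  and IC monotonicity along parent links holds by construction on
  closed corpora.
* Triplets with `‖V‖ = 0` (zero anchor vector, or `Φ(g⁺) = Φ(g⁻)`)
  skip the update with a warning; zero-loss triplets leave `W`
  bit-identical (passivity).
* Anchors without eligible negatives are redrawn a bounded number of
  times (default 50) before the category is declared too small; such
  categories return the untrained identity model rather than failing
  the run.
* Constant gene rows in a PCC source get zero-weight edges plus a
  warning; self-loop rows in edge lists are dropped with a warning;
  duplicate (and reversed) edges collapse.
* Categories are evaluated only when every fold can hold at least one
  positive and the corpus has at least `nFolds` positives *and*
  negatives; others are excluded with a warning, and per-term AUC is
  the mean of fold AUCs (pooling scores across folds would mix
  propagation scales).
* BMA similarities are cached per unordered gene pair
  (`geneSimilarityMatrix`) because the same pairs recur across
  millions of sampling iterations.

## Limitations

* One `W_C` per category: memory is `O(d²)` per term, and nothing is
  shared across related terms.
* The learner sees only associations among training genes; categories
  whose signal lives in negative–negative structure gain nothing
  (and fall back to the identity model via early stopping).
* Resnik/BMA only; no Lin, Jiang–Conrath or Wang similarity, no
  cross-ontology terms, and only `is_a` edges are read from OBO
  (`part_of` is ignored with a message).
* Equal-weight integration is deliberate — the method's premise is to
  improve a network built by any integration scheme — so learned
  integration weights are out of scope.
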