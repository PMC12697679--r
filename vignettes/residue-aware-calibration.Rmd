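---
title: "Residue-aware calibration of variant effect predictor scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-aware calibration of variant effect predictor scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racoon)
```

## The problem

A variant effect predictor assigns each missense variant a raw score — for
protein language models, a log-likelihood ratio (LLR) between mutant and
wild-type amino-acid probabilities, with more negative values indicating
stronger predicted deleteriousness. Two distinct failure modes motivate
this package:

* **Label (prior) shift.** The pathogenic fraction differs sharply across
  residue subgroups: benign variants dominate intrinsically disordered
  regions, while interface residues are pathogenic-enriched. A single
  global score-to-probability mapping cannot be right in both.
* **Class-conditional feature shift.** At a *fixed* label, the score
  distribution itself moves across subgroups — disordered residues and
  sulfur-binding residues draw systematically different LLRs, and long
  proteins scored through sliding windows shift again. Where such shifts
  exist, a subgroup-specific mapping both restores calibration and can
  improve global ranking, because cross-subgroup comparisons stop being
  confounded by context.

The package separates the two diagnostically (label shift vs conditional
Jensen–Shannon divergence) and corrects both with one construction: a
calibration tree over binary residue attributes whose nodes carry their
own score-to-probability maps.

## The model

**Tree construction.** The root split is fixed to the protein-length class
(long means > 1022 residues, the context length that forces sliding-window
scoring). Below the root, each node is split greedily on the available
attribute with the largest class-conditional divergence within the node,

$$\mathrm{div}(M) = \sum_{l\in\{0,1\}}
  \mathrm{JSD}\!\left(P(X\mid M,l)\,\|\,P(X\mid\neg M,l)\right),$$

estimated on 100 equal-width histograms over the unit interval with a
smoothing mass of $e^{-12}$ per bin, natural logarithms throughout (so one
JSD term is bounded by $\log 2$). Greedy ordering puts the attributes that
matter near the root, so pruning removes the least informative splits
first. Ties are broken by the declared attribute order; an attribute not
observed both true and false inside a node (or with an empty
label-by-side cell) is skipped for that node. The divergence is estimated
on a seeded subsample of up to 400 records per class per side; the
subsample keeps construction cost independent of node size, and with
~1600+ records per surviving node the attribute ranking is stable.
The divergence feature defaults to the score itself (min–max mapped into
the unit interval); per-variant normalized-entropy vectors can be supplied
instead when available, since entropies summarize the whole prediction
vector rather than two of its entries.

**Pruning.** Leaves with fewer than `min_total = 1600` variants,
`min_pos = 400` pathogenic, or `min_neg = 400` benign are removed
iteratively until a sweep removes nothing. A removed leaf's variants are
still present in every ancestor, so they are calibrated at the deepest
surviving node on their path. The thresholds guarantee each calibrated
subgroup supports both the 400-per-class mixture fits and a meaningful
pathogenic-fraction estimate.

**Per-node models.** The pathogenic fraction is the mean of
`n_frac = 500` labels sampled without replacement (a census below that
size). Under a normal approximation, a Bernoulli proportion estimated from
$n$ samples has a 95% CI half-width of at most
$1.96\sqrt{0.25/n}$; half-width 0.05 requires $n = 385$, so 500 leaves a
conservative margin. The benign and pathogenic score distributions are
each fitted with a $K=2$-component 1-D Gaussian mixture by EM on
`n_gmm = 400` scores per class, reusing the fraction-estimation sample and
topping up at random. EM uses a seeded k-means initialization (single
start), a variance floor of $10^{-6}$, tolerance $10^{-3}$ on the
log-likelihood, and at most 100 iterations; components are reported sorted
by mean. A degenerate class (all scores identical) falls back to a
near-point mixture with a warning. `gmm_bic_profile()` reports BIC across
$K$ as a diagnostic; the default stays at two components, which is where
the BIC curve plateaus for unimodal-to-bimodal score distributions and
deliberately limits expressiveness so the mixtures denoise rather than
memorize.

**Histograms.** Each node draws `n_sample = 40000` synthetic scores from
its two mixtures — `round(n_sample * fraction)` pathogenic-sourced (R's
round-half-even, so the split is deterministic and unbiased) — and cuts
the pooled draw into `n_bins = 50` equal-frequency bins. Bin edges are
midpoints between the order statistics flanking each cut; outer edges are
$\mp\infty$ sentinels so every score lands in a bin. The bin value is the
pathogenic-sourced proportion, so the count-weighted mean of the bin
values reproduces the draw fraction exactly. Under heavy ties midpoint
edges can make re-binning by edge disagree with the construction chunks;
bin counts are guaranteed to differ by at most one only for distinct
values. Because bins are equal-frequency, resolution concentrates where
scores are dense.

**Mapping.** A variant traverses the tree by its tri-state attributes and
stops at a leaf, at a pruned branch, or when the next split's attribute is
missing. Every surviving node is calibrated — a superset of the strictly
necessary set (leaves, single-child nodes, ancestors of splits on
incompletely annotated attributes) — so traversal always terminates at a
node with a histogram; the cost is a few cheap extra histograms and the
benefit is that no missingness pattern can fall through. Missing
annotations are never imputed: a variant without an interface call is
calibrated at the pre-split node, whose membership includes the annotated
records, so under annotations missing at random the fallback node is the
correct population for it.

**Outliers.** Before any fitting, extreme scores are removed from the
pooled dataset (classes together) by the modified z-score
$z_i = 0.6745\,|x_i-\tilde x|/\mathrm{MAD}$ with the stringent cutoff
$z > 4.25$; with a zero MAD nothing is removed (warning) since $z$ is then
undefined. The logistic baselines use a 0.1-percentile tail filter instead,
which needs no per-model threshold adjustment. LLR scores are used as-is
inside the calibration path (no flipping): the histograms encode direction
implicitly.

## Baselines and evaluation

The logistic baseline fits `sigmoid(c1*x + c2)` by unpenalized maximum
likelihood on a balanced subsample (majority class down-sampled without
replacement); the subgroup variant fits independent parameters per
subgroup under interface, disorder, or joint schemes, falling back to the
global fit for subgroups without a feasible balanced sample and for
variants with missing annotations. Direct equal-frequency binning of raw
labeled scores and the hybrid synthetic-plus-raw pool are provided as the
comparison calibrators for the mixture-based construction.

Evaluation uses rank-based AUROC with midrank ties; per-protein AUROC as
the unweighted mean over proteins with both classes (count-weighting is
available but changes little); Youden-J thresholds scanned over midpoints
between distinct scores plus the infinite cuts, classifying pathogenic at
score ≥ threshold, smallest maximizer on ties, with a bootstrap sd;
reliability histograms over 10 equal-width probability bins (final bin
closed at 1), ECE as the count-weighted mean absolute confidence-frequency
gap and MCE as the maximal gap over bins with more than 50 samples
(undefined when none qualifies). The per-protein qualification threshold
defaults to one variant of each class and is exposed as a parameter
(a stricter ≥10-variant filter is a common reporting choice).

## What the synthetic generator emulates — and what it does not

`paper_like_config()` draws variants from four subgroups over the
attributes disordered / sulfur-binding / interface, with pathogenic priors
0.10 (disordered), 0.61 (interface) and 0.35 elsewhere, weighted
(0.25 / 0.10 / 0.08 / 0.57) so the pooled prior is ≈ 0.31 — the published
subgroup and baseline rates for high-quality clinical missense data.
Interface annotations are missing completely at random for 26% of
variants (the published annotation coverage is 74%) and 47% of proteins
are long. Scores are class-conditional two-component mixtures on an
LLR-like scale (pathogenic centered well below benign); the disordered
subgroup's means are shifted downward (benign by −3, pathogenic by −2.5),
giving the class-conditional feature shift that residue-aware calibration
exists to exploit. Mixture locations and variances are otherwise the
package's own choice of a realistic score scale, fixed once.

The generator reproduces the *statistical structure* the method assumes —
subgroup-dependent priors, mixture-shaped class-conditional scores,
attribute missingness, protein grouping — but not real-data features such
as per-protein score autocorrelation, annotation bias correlated with
attributes, label noise, or attribute correlations beyond the subgroup
patterns. Passing tests therefore demonstrate correctness and calibration
*within the assumed model family*; they do not certify performance on any
particular clinical dataset. Protein assignment is independent of subgroup
(except through length) so that residue-level effects are isolated from
protein-level ones.

## Numerical and design choices

* **Seeding.** One master seed; every stochastic step (divergence
  subsampling, fraction sampling, mixture training, histogram draws)
  derives its own seed from the master seed and the node path, so refits
  are byte-identical and independent of traversal order.
* **Serialization.** Models round-trip through JSON with 17 significant
  digits (bit-exact for doubles); infinite sentinel edges are encoded as
  the strings `"-inf"`/`"+inf"`. The in-memory fit timestamp is
  deliberately excluded from the file so identical fits produce identical
  files.
* **Quantiles** are linear-interpolation empirical quantiles (R type 7);
  at the stated tail sizes the choice is immaterial.
* **Min–max orientation.** Scores already bounded in the unit interval
  are only flipped, never rescaled. Otherwise the 0.1-percentile tails are
  set aside, inliers are min–max normalized, orientation is fixed so the
  pathogenic mean is the larger, and reinstated outliers are clamped by
  tail side after orientation (above-range to 1, below-range to 0). The
  clamping is deliberately label-free at transform time — an
  outlier-labeling rule that consults labels would leak them into a
  transform applied at inference — and coincides with label-based
  assignment whenever extreme tails align with classes.
* **Ensembling.** Across randomly initialized models, the central 75 of
  100 per-model probabilities (sorted, tails trimmed equally) are
  summarized by median and sd, giving an outlier-robust server-style
  prediction with an uncertainty estimate.
* **LLR modes.** Both published formulations are implemented: the default
  evaluates the log-softmax of the wild-type-shifted logits at the mutant
  entry (equivalently, by shift invariance, the mutant log-softmax of the
  raw logits); `naive_diff` is the raw logit difference, which is exactly
  what log-softmax-then-subtract reduces to. The two differ by the
  wild-type's own log-softmax term; both are exposed since either may be
  encountered in precomputed score sets.
* **Homology cutoff.** The low-homology attribute defaults to "ten or
  fewer homologs" with the cutoff exposed as a parameter, as published
  descriptions of this threshold vary between nine and ten.

## Problem sizes used in the checks

The test suite and the acceptance script run the pipeline at 50 000
training and 20 000 evaluation variants over 500 proteins — large enough
that every default-threshold node survives pruning with headroom, while a
full fit takes about two seconds. The seen-vs-held-out leakage comparison
uses a 400 000-variant cohort so that the pooled per-node balanced halves
(~120 000 records a side) make the AUROC difference estimate sharp; the
mapping fits ~800 samples per node regardless, so any memorization would
appear as a seen-side advantage, and none is observed (gaps well below
0.005). Per-node expected calibration errors on held-out data stay below
0.05 at these sizes.

## Known limitations

* Splits are binary; continuous attributes must be thresholded upstream
  (the package ships the standard disorder 0.7, homology ≤ 10 and length
  1022 rules).
* Node probabilities are piecewise-constant in the score; within-node
  ranking is preserved only up to the 50-bin resolution.
* The pathogenic-fraction estimate inherits any annotation bias of the
  labels; restricting calibration to attributes with demonstrated
  class-conditional shifts mitigates, but cannot eliminate, this.
* Very small subgroups are unavoidably pruned; their variants receive the
  ancestor's coarser calibration.
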