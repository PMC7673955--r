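---
title: "Predicting lysine succinylation sites: encoders, feature selection and tuning"
author: "succpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine succinylation sites: encoders, feature selection and tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(succpred)
```

## The problem

Succinylation is a lysine posttranslational modification implicated in
metabolic regulation and several disease processes. Experimentally mapping
modified lysines is slow and expensive, so sequence-based classifiers are
used to triage candidate sites. `succpred` implements such a pipeline end
to end: every candidate lysine is represented by a fixed-length peptide
window, the window is encoded as a 2501-dimensional numeric vector drawn
from four complementary featurizations, features are ranked by
gradient-boosting gain importance, an incremental feature selection (IFS)
scan picks the subset size that maximizes cross-validated F-measure, and
the classifier's hyperparameters are tuned by Gaussian-process Bayesian
optimization.

## Windows

A site is the center of a `2r + 1` window with `r = 10`: ten residues
upstream and downstream of the lysine, 21 residues in total. Sites close
to a terminus are padded with `'X'`, the conventional ambiguity letter,
and the pad counts are recorded. Published descriptions of this window
scheme typically leave terminal handling unstated; padding (rather than
dropping terminal sites) was chosen here because it keeps every labeled
site usable, and the encoders treat pads explicitly as missing data, so
the choice is visible and reversible downstream. A site list that points
at a non-lysine residue is a hard error rather than a silent skip —
silently relabeling sites is the kind of data corruption no training run
should survive.

## The four encoders

**CKSAAP (2000 values).** For each spacing `k = 0..4` and each ordered
pair of standard amino acids, the count of pairs `(i, i+k+1)` divided by
`N_total = L - k - 1` (20, 19, 18, 17, 16 for `L = 21`). Pairs touching a
pad or ambiguity letter are not counted while the denominator stays
`L - k - 1`; heavily padded windows therefore shrink toward zero rather
than being renormalized, which keeps the encoding monotone in the amount
of real sequence present.

**Disorder (21 values).** Per-residue intrinsic-disorder scores in
`[0, 1]` from a VSL2B-style predictor, passed through untransformed. The
conventional 0.5 order/disorder threshold is exposed as a predicate
(`is_disordered()`) but never applied to the features: thresholding would
discard resolution the classifier can use.

**Type-1 PseAAC (40 values).** Twenty composition fractions plus
`lambda = 20` sequence-order correlation factors weighted by `w = 0.05`.
The j-th factor averages, over residue pairs `(i, i+j)`, the mean of
squared differences of three standardized physicochemical properties:
hydrophobicity, hydrophilicity and side-chain mass. The property scales
are the ones popularized with the original pseudo amino acid composition
web server; they are built in code (`aaindex_table()`) with raw and
standardized columns so they can be audited or swapped. Standardization
divides by the population standard deviation over the 20 amino acids (the
PseAAC convention). With `L = 21` and `lambda = 20` the last tier
averages a single pair; this is permitted and tested. Pads and ambiguity
letters are excluded from composition counts, and correlation terms that
touch them are dropped with the divisor reduced — missing data is
skipped, not imputed. All `20 + lambda` components share one denominator
and so sum to exactly 1.

**PSSM (440 values).** The window rows of the protein's PSI-BLAST
position-specific scoring matrix, flattened residue-major (420 values)
and summarized by 20 per-column means. Profiles are parsed from the
standard `-out_ascii_pssm` dialect; columns are remapped from the file
header to one canonical order so features are stable across PSI-BLAST
builds. Padded window rows are all-zero — zero is neutral for both the
flatten and the mean.

The blocks fuse in the order CKSAAP, disorder, PseAAC, PSSM with stable
global names (`"PSSM:421:mean_A"` and so on), 2501 values in total.

## Ranking, IFS and evaluation

The feature ranking fits one boosted-tree ensemble on all features and
sorts by total gain (the summed objective reduction from splits on each
feature); unused features get gain 0 and ties break by original column
index so the list is deterministic. The gradient-boosted learner itself
is a pluggable dependency — this package deliberately does not
re-implement tree boosting; xgboost provides the histogram-based trainer
behind `gbdt_config()`, and any object with `fit`/`predict` can stand in.
`gbdt_config()` speaks the usual histogram-GBDT vocabulary
(`num_leaves` maps to leaf-wise growth, `"rf"` to per-round subsampling);
`"goss"` — gradient one-side sampling, an internal acceleration of one
particular implementation — has no equivalent here and falls back to
plain boosting, so tuning over the full categorical space stays
expressible. A one-way ANOVA-F ranker is included as an independent
baseline; other rankers plug in through the same `ranked_features`
contract.

IFS evaluates nested prefixes of the ranked list (step 1 by default) with
stratified k-fold cross-validation and picks the smallest size attaining
the maximal fitness; the tie rule matters because flat stretches of the
curve are common and fewer features are always preferable. Metrics
(accuracy, recall, precision, MCC, F-measure) are computed on the pooled
out-of-fold confusion table — pooling keeps MCC defined when folds are
small — with per-fold macro-averages also returned. Zero-denominator
conventions are fixed (0 for precision/recall/F with empty denominators,
0 for MCC with an empty marginal) and unit-tested. The repeated-CV
harness (`repeated_cv()`) reruns CV under distinct seeds and reports
mean/SD/max per metric, the standard stability protocol for comparing
classifiers.

## Hyperparameter tuning

`bo_minimize()` minimizes a black-box objective (here: negative
cross-validated F-measure via `cv_objective()`) over a declared space of
reals, integers and categoricals. The surrogate is a Gaussian process
with a Matérn 5/2 ARD kernel plus observation noise, hyperparameters fit
by L-BFGS-B on the log marginal likelihood with a Cholesky factorization;
points are encoded to the unit cube (log scale for `learning_rate` and
`reg_alpha`, whose ranges span decades; one-hot for categoricals).
Acquisition is expected improvement,

EI(x) = sigma(x) * (gamma * Phi(gamma) + phi(gamma)),  gamma = (f_best - mu(x)) / sigma(x),

with probability of improvement `Phi(gamma)` also available; at
`sigma = 0` the exact limits are used. The acquisition is maximized over
2048 random candidate draws per round — simple, seedable and adequate for
a 7-dimensional space. Defaults are `n_init = 10` Latin-hypercube points
and `n_iter = 50` guided evaluations, both configurable since the
appropriate budget is data-dependent. `grid_search()` provides the
exhaustive alternative; grid densities must be user-supplied because any
default grid implies a cost the user should choose knowingly.

The bundled `default_gbdt_space()` spans learning_rate (0.01–1),
max_depth (1–50), max_bin (10–100), reg_alpha (1e-9–1), boosting_type
{gbdt, goss, rf, dart}, num_leaves (2–50; a lower bound of 1 is not a
meaningful tree and is clamped with a warning) and n_estimators
(100–600).

## The synthetic-data generator

`synthetic_spec()` + `generate_dataset()` produce datasets in exactly the
formats the pipeline reads (FASTA, ASCII PSSM, disorder TSV), which makes
them both test fixtures and format documentation. Each sample is an
independent 21-residue protein with a central lysine. Default class sizes
mirror the published succinylation training sets (5049 positive, 5526
negative). Signal enters through three orthogonal channels so each
pipeline stage can be probed in isolation: motif enrichment rules
(sequence-level, drives CKSAAP/PseAAC), PSSM score shifts at motif
positions (drives exactly one flatten cell per rule — the sharpest way to
plant a known-informative feature), and class-dependent disorder means.
With all channels off the generator is an exact null. Background
composition defaults to uniform; a Swiss-Prot-like composition is
available (`aa_background("swissprot")`). PSSM background scores are
small integers in `[-5, 5]`, inside the conventional log-odds range, so a
planted shift of +6 is strong but not degenerate.

What the generator does **not** emulate: real succinylation motif
biology, homology between proteins (every sample is independent, so there
is no train/test leakage of the kind redundancy reduction addresses in
real data), realistic PSSM row correlations, or predictor-specific
disorder score autocorrelation. Passing tests therefore demonstrate that
the machinery recovers statistical structure it was pointed at, not that
any particular accuracy will be reached on biological data.

## Problem sizes used in the checks

The bundled verification suites run at desk scale, chosen once as
realistic for a laptop-class reproduction: signal-recovery datasets of
n = 1000 (500/500) with 20 planted PSSM cells, ranked with a
100-round, depth-3 ensemble over 20 seeds; IFS scans to subset size 50
under 10-fold CV with a 50-round classifier; null calibration on
n = 120 datasets over 10 seeds; a million-draw Monte-Carlo check of the
EI closed form; and ten-seed BO runs of 5 + 15 evaluations on a 1-D
quadratic. A full-scale run (2501-step IFS, 100× repeated 10-fold CV) is
cluster work and is exposed through the same functions via `max_size`,
`n_repeats` and seeds.

## Known limitations

- The PseAAC property scales are a documented choice; published numeric
  PseAAC values computed with other scales will differ (dimensions and
  invariants will not).
- Gain importances depend on the backend's tree construction; rankings
  from other GBDT implementations will correlate but not coincide.
- The GP surrogate fits hyperparameters from a single optimizer start;
  for rugged objectives in higher dimensions a multi-start would be more
  robust (the acquisition-over-candidates design bounds the damage).
- `predict` mode scores every lysine of a protein independently; no
  cross-site smoothing is attempted.
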