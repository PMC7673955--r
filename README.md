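# succpred

Prediction of lysine succinylation sites from protein sequence, built as a
reusable R toolkit: peptide windowing, four sequence encoders fused into a
2501-dimensional feature vector, gain-based feature ranking with
incremental feature selection (IFS), five-metric cross-validated
evaluation, and Gaussian-process Bayesian optimization of the classifier's
hyperparameters.

## Who this is for

Anyone building or auditing sequence-based posttranslational-modification
(PTM) site classifiers: the package separates the standard but
error-prone parts — window extraction with terminal padding, PSI-BLAST
ASCII PSSM parsing, formula-exact encoders, deterministic feature ranking,
leakage-free stratified cross-validation — into small, individually tested
functions, and ships a synthetic-data generator that plants known signal
so the whole chain can be verified without any database download or
predictor run.

## The method

Each candidate site is a 21-residue window centered on a lysine
(`r = 10` residues each side; termini padded with `X`). A window is
encoded as:

| block    | dims | content |
|----------|------|---------|
| CKSAAP   | 2000 | k-spaced amino-acid pair composition, `N_{i,j}(k) / (L − k − 1)` for `k = 0..4` over the 400 ordered pairs |
| disorder |   21 | per-residue intrinsic-disorder scores in [0, 1] |
| PseAAC   |   40 | Type-1 pseudo amino acid composition: 20 composition terms + λ = 20 correlation factors over standardized hydrophobicity / hydrophilicity / side-chain mass, weight w = 0.05 |
| PSSM     |  440 | window rows of the PSI-BLAST profile, flattened residue-major (420) + 20 column means |

for 2501 features in total. Features are ranked by total gain in a
boosted-tree ensemble; IFS evaluates nested top-i subsets under
stratified 10-fold cross-validation and keeps the smallest subset
maximizing the F-measure. Metrics are accuracy, recall, precision, MCC
and F-measure from the pooled out-of-fold confusion table.
Hyperparameters (learning rate, depth, leaves, bins, L1, boosting type,
rounds) are tuned by minimizing the negative CV F-measure with a GP
surrogate (Matérn 5/2 ARD) and the expected-improvement acquisition

    EI(x) = σ(x) · (γ Φ(γ) + φ(γ)),   γ = (f_best − μ(x)) / σ(x),

or by exhaustive grid search. The gradient-boosted learner itself is a
pluggable dependency (xgboost by default); any `fit`/`predict` pair can
stand in.

## Worked example

Plant a sequence motif (L at offset −1, E at +2, 80 % enrichment) plus a
PSSM shift into a 300-sample synthetic dataset, encode, rank, and scan:

```r
library(succpred)

motif <- data.frame(offset = c(-1L, 2L), residue = c("L", "E"), prob = 0.8)
spec  <- synthetic_spec(n_positive = 150, n_negative = 150, motif = motif,
                        pssm_signal = 4, seed = 42)
ds <- generate_dataset(spec)

X <- encode_windows(ds$windows, ds$pssms, ds$disorder)
dim(X)
#> [1]  300 2501

y <- attr(X, "labels")
ranked <- rank_by_gain(X, y, gbdt_config(n_estimators = 100, max_depth = 3, seed = 0))
head(ranked[, 1:2], 5)
#>           feature importance
#>  CKSAAP:212:k0_LK 0.49393703
#>  CKSAAP:627:k1_KE 0.21334534
#>    PSSM:191:p10_L 0.05994206
#>  PseAAC:12:comp_K 0.02224780
#>    PSSM:211:p11_L 0.01031628

ifs <- run_ifs(ranked, X, y, gbdt_config(n_estimators = 50, max_depth = 3),
               k = 5, seed = 0, max_size = 20)
ifs$optimum
#> [1] 15
ifs$curve[ifs$curve$size == ifs$optimum, ]
#>  size  accuracy recall precision       mcc f_measure
#>    15 0.9466667   0.96 0.9350649 0.8936511 0.9473684
```

The top-ranked features are exactly the planted signal: `k0_LK` is the
adjacent L-K pair created by the motif at offset −1, `k1_KE` the
one-spaced K-E pair from offset +2, and `p10_L` the shifted PSSM cell at
window position 10 (offset −1), column L. The IFS optimum (15 features,
F-measure 0.947) reports the cross-validated operating point of the
selected subset.

Real data enters the same way: `read_fasta_proteins()` +
`read_site_table()` + `extract_windows_all()` for windows,
`read_ascii_pssm()` / `read_disorder_profile()` for per-protein profiles
from PSI-BLAST and a VSL2B-like predictor, then `encode_windows()` as
above. A thin command-line wrapper over these functions, with
`simulate | encode | rank | ifs | tune | train | evaluate | predict`
subcommands, is installed at `inst/cli/succpred`.

## Vignette

`vignettes/succinylation-pipeline.Rmd` documents the model choices:
padding and missing-data conventions, the PseAAC property scales and
normalization, tie-breaking in ranking and IFS, pooled versus per-fold
metrics, the GP surrogate and acquisition details, and what the
synthetic generator does and does not emulate.
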