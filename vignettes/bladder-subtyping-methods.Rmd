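---
title: "Methods: luminal/basal subtyping, the BLT score, and the synthetic cohorts"
author: "bltsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: luminal/basal subtyping, the BLT score, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Muscle-invasive bladder cancer splits into two intrinsic expression
subtypes, *luminal* (KRT20, GATA3, FOXA1, XBP1, CD24, uroplakins —
the signature of differentiated intermediate/luminal urothelium) and
*basal* (KRT5/6, KRT14, CDH3, CD44 — undifferentiated basal urothelium),
plus a small *double-negative* minority expressing neither panel, with an
activated epithelial–mesenchymal transition (EMT) programme and the heaviest
immune infiltrate. The subtypes behave differently clinically, so a
quantitative, reproducible classifier matters. `bltsub` implements the full
analytical chain: marker-panel clustering, cluster-validity statistics, a
unidimensional basal-to-luminal transition (BLT) discriminant score with a
grid-searched cutoff and ROC machinery, EMT and immune signature scores, and
a two-marker immunohistochemistry (IHC) surrogate classifier — all runnable
end to end on seeded synthetic cohorts.

## Normalization

Linear-scale expression is transformed as
`log2(x) - median(log2(x))` per sample, so every sample's median is exactly
zero. Log base 2 is the microarray convention; the median is taken over all
genes in the matrix, not a panel subset, because arrays are normalized whole
before any subsetting. Missing values are a hard error: the pipeline targets
complete matrices, and silent imputation would leak into every downstream
score. A second call on already-normalized input is refused rather than
silently re-applied.

## Subtype assignment

Stage 1 clusters samples by Ward's criterion (`ward.D2` on Euclidean
distances) over the z-scored union of the two marker panels, cut at k = 2;
genes are z-scored across samples first so that every marker contributes on
the same scale to the Euclidean metric (heatmap row-standardization, made
explicit). Clusters are named by which panel's mean z-score is higher among
their members — naming is therefore invariant to panel listing order.

Double-negative tumours are historically separated by eye. A repository
needs a deterministic rule, so stage 2 relabels as double-negative every
sample whose cohort-wide mean z-score is below `dn_threshold` on **both**
panels (default −0.5 z-units, exposed as an argument), then repeats the
k = 2 clustering on the remaining samples. The separation is a single pass:
re-clustering cannot create new double-negatives, which keeps the procedure
idempotent and order-independent.

## Cluster validity

*Prediction strength* for a pair of subtypes pools their samples, halves
them at random, fits k-means (k = 2, 10 restarts, 300-iteration cap — the
stock Hartigan–Wong implementation, seeded) to each half, and takes

    ps(k) = min_j  1/(n_kj (n_kj − 1)) Σ_{i≠i′ ∈ A_kj} D[C(X_tr, k), X_te]_{ii′}

— the worst-case proportion of test-cluster sample pairs that the
nearest-training-centroid rule keeps together. Fifty random halvings are
averaged; the split count is a default (the statistic's source describes the
estimator, not a split budget). Test clusters with fewer than two members
are skipped with a warning; k = 1 is definitionally 1. The statistic is
computed on the same z-scored marker space used for clustering, for
consistency with subtype discovery.

*Per-sample strength* is the Bayes posterior under Gaussian class densities
with shared covariance and frequency priors:
`P(g|x) = f_g(x) P(g) / Σ_k f_k(x) P(k)`. The pooled within-group covariance
is convexly shrunk toward its diagonal with the standard analytic intensity
(minimizing the expected squared error of the off-diagonal correlations,
clipped to [0, 1]) because the marker dimension (48) can exceed the
double-negative group size. Log densities are stabilized by subtracting the
row maximum before exponentiation, so posteriors are overflow-safe and sum
to 1 to machine precision. A posterior ≥ 0.80 for the assigned class counts
as a *strong* assignment.

## The BLT score

Marker selection is an L1-regularized multinomial fit (glmnet, grouped
penalty so a gene enters or leaves for all classes together) over the full
lambda path; the path point whose non-zero gene count is closest to the
target (default 28, from a 28-luminal + 20-basal candidate panel) is taken,
ties resolved toward the sparser model. The multinomial flavour matches the
three-subtype discriminant framing; the realized luminal/basal split of the
28 genes is reported rather than enforced per panel.

The discriminant itself solves the between/within generalized eigenproblem
on the selected genes, with the same diagonal-shrinkage contract as the
posterior model. The BLT score is `Σ_i W_i · E_i` with `W_i` the *negated*
first-discriminant coefficients, globally sign-fixed so that luminal
training samples score above basal ones: positive scores mean luminal-like,
negative basal-like. LD1 is −BLT by construction; LD2 (available with three
training groups) completes the two-dimensional projection.

The score cutoff is grid-searched: 1000 evenly spaced candidates across the
training score range, minimizing total misclassification of the luminal and
basal groups (double-negatives excluded); tied candidates resolve to the one
nearest the median of the tied set, which centres the cutoff in a
zero-error gap. The ROC curve uses luminal as the positive class, thresholds
at all unique scores plus ±∞, trapezoid AUC (exactly the Mann–Whitney
U statistic divided by n₁n₂, ties as half-counts — an identity the tests
assert), and an optimal operating point minimizing
`(1 − sens)² + (1 − spec)²`. Cross-validated accuracy uses stratified folds
(class proportions preserved to within one sample), refits the discriminant
per training fold on the **fixed** selected gene set — selection is not
re-run inside CV, mirroring the original design and its acknowledged
optimism — and classifies held-out samples by the Gaussian posterior rule.

## Phenotype scores

The EMT score is a weighted sum over a 76-gene signature,
`score_j = Σ_i w_i G_ij`, with `w_i` the Pearson correlation of gene *i*
with E-cadherin (CDH1) across the cohort, then centred to cohort mean zero.
Epithelial adhesion genes correlate positively with CDH1 and EMT
transcription factors negatively, so negative scores indicate an activated
EMT state. Weights are fitted on the analysed cohort itself — the definition
is a within-cohort correlation — and Pearson is the default reading of
"correlation coefficient" (a `method` argument allows Spearman). Genes
missing from the matrix are dropped with a warning; zero-variance genes get
weight 0.

The immune (and checkpoint) score of a sample is the median expression over
the panel genes minus the grand mean of those medians, so scores sum to
zero; at least half the panel must be present. Both score types are
invariant to sample order and to adding a global constant.

## The IHC surrogate classifier

Quantitative staining proportions (GATA3 on nuclei, KRT5/6 on tumour tissue)
feed two classifiers. The *rule-based* caller encodes reciprocal staining:
GATA3-positive with KRT5/6 at or below the 10% positivity threshold is
luminal (scattered KRT5/6 in under 10% of cells does not veto the call, and
symmetrically for basal); both below 10% is double-negative; both above the
50% strong threshold — or both intermediate — is noninformative. The 10%
threshold is the repeatedly observed scattered-staining bound; 50% for
"strong uniform" staining is qualitative in origin and therefore an exposed
argument. Contingency summaries round percentages to the nearest integer,
halves away from zero. The *quantitative* classifier is a logistic
regression of luminal-vs-basal on the two raw proportions (no interaction),
assessed by leave-one-out cross-validation at probability 0.5; complete
separation — common with reciprocal markers — triggers a refit with a small
L2 ridge (1e−4) and a warning rather than divergent coefficients.

## The synthetic-cohort generator

The generator defines the study conditions for every test. Defaults:
100 luminal, 85 basal and 15 double-negative samples (a 200-tumour cohort
with a luminal majority and a basal group of which 20% co-expresses luminal
markers — the co-expressing subset observed in real basal clusters — and a
double-negative minority large enough to be testable); marker effect size
2 log2 units against per-gene noise of sd 1; per-gene baselines drawn once
per seed from Normal(6, 1), a microarray-like log2-intensity scale.
Double-negative samples are unshifted on both marker panels, shifted
−2 log2 units on the epithelial EMT genes (CDH1, CLDN1, TJP1 and company)
and +2 on the EMT transcription factors (ZEB2 and company); the immune and
checkpoint panels are graded 0 / +1 / +2 for luminal / basal /
double-negative. The EMT and immune effect sizes are not quantified in the
cohorts this emulates; 2 log2 units — the same order as the marker contrast —
was chosen once as a realistic bulk-expression effect and not revisited.
IHC proportions are Beta-distributed per subtype (luminal GATA3 ~ Beta(8,2),
KRT5/6 ~ Beta(1,19); basal reversed; double-negative low on all), which
reproduces the reciprocal staining pattern with realistic overlap.

What the generator does *not* emulate: probe-level artifacts, batch and
platform effects, RNA degradation (the force that inflates double-negative
calls in FFPE material), correlated co-expression structure beyond the
block shifts, and intra-tumour heterogeneity. Passing tests therefore
demonstrate that the statistical machinery recovers the structure it
assumes, not that the pipeline is robust to real-world noise sources.

## Numerical choices and problem sizes

Determinism throughout: every stochastic step (generation, splits, k-means
restarts, fold assignment) takes an explicit seed; `run_all()` fans a global
seed out to per-stage derived seeds recorded in the manifest, so stages
reproduce standalone. Ward clustering uses `ward.D2` (Ward's criterion on
squared Euclidean distances). Covariance shrinkage touches only the
off-diagonal; intensity 1 gives an exactly diagonal model. The test suite
and the acceptance script run the full pipeline at the default n = 200
cohort (ten seeds for the recovery experiment) and use n = 2000 draws for
distributional checks — sizes at which the Monte-Carlo bounds in the tests
are sharp but the whole suite completes in well under a minute.

## Known limitations

The default effect size (2 log2 units) makes the synthetic subtypes cleanly
separable, so headline recovery metrics sit near their ceilings; the
generator's dials exist precisely so harder regimes can be explored. Marker
selection outside CV inherits the original optimism. The double-negative
threshold rule is a deterministic stand-in for expert curation and its
default (−0.5) is a judgement call. Real-cohort loaders are plain TSV/GMT/CSV
readers: reproducing published cohort-level AUCs requires the external
matrices and is out of scope.
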