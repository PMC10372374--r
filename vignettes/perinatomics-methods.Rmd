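---
title: "Methods: models, parameters and design choices in perinatomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in perinatomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perinatomics)
```

# Scope

`perinatomics` re-implements, as tested and reusable functions, the
statistical workflow of a multi-omics liver study in offspring of
hyperglycemic versus normoglycemic mothers: lipidomics quality control,
proteomics post-quantification processing, feature-wise differential
abundance, multivariate statistics, and protein–protein-interaction
(PPI) network analysis. A synthetic-data generator reproduces the
statistical structure of such a study — an unbalanced 2 (group) × 2
(sex) design with PHG = 5 female + 4 male and PNG = 6 female + 4 male
biological samples, 5 QC-pool injections and 3 blanks — so every stage
can be validated against known planted truth without any external
download.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were chosen once, up front.

**Omics matrices** (`gen_omics_matrix()`). Log2 intensities are Normal
around a per-feature baseline (mean 20, SD 1.5 across features —
typical of log2 LFQ intensities), with biological SD `sigma_bio` = 0.3
on the log2 scale, a mid-range value for tissue proteomes. Planted
effects shift whole groups: a fraction of features receives a group
effect, a sex effect or a one-cell interaction, with linear fold
changes drawn from 1.5–5.3, the span between the usual significance
floor and the strongest single-protein effect such studies report.
Missingness, when enabled, is left-censored: dropout probability follows
a logistic curve rising as intensity falls below the first quartile,
because low abundance, not chance, drives most missing values in mass
spectrometry. The truth ledger records each feature's effect label and
true log2 fold change.

**Raw lipidome** (`gen_lipid_raw()`). A species-by-sample concentration
table (nmol/g) in which a chosen number of species violates each QC
stage *on the realized finite sample* while passing all earlier stages;
every species is re-checked against the actual stage criteria and
resampled (up to 1,000 retries) until its planted assignment holds, so
the sequential QC recovers the planted counts exactly and
deterministically. Clean species carry ~5% pool CV and ~30% biological
CV; D-ratio-planted species are built with pool SD = 0.20 × mean and
biological SD = 0.10 × mean, giving a construction D-ratio of
0.2/√(0.04 + 0.01) ≈ 0.894. Clean species also carry a ~2% biological
missing rate (capped at 2 cells per group, far from the group-wise
removal rule) so the kNN imputation stage has realistic work to do.

**PPI graphs** (`gen_ppi()`). Preferential attachment (2 edges per new
node) gives the heavy-tailed degree distribution of curated
interactomes and a connected graph, so shortest paths are defined;
modules are planted by adding internal edges among random node sets,
and module edges carry combined scores above 0.7 so they survive
high-confidence filtering. **Disease catalogues**
(`gen_disease_catalog()`) plant a disease overlapping the module with
association scores above the 0.3 screening cutoff, while background
diseases avoid the module entirely. **Clinical tables**
(`gen_clinical()`) draw insulin (μU/mL) and glucose (mg/dL) per
group × sex cell; defaults put normoglycemic-mother offspring near
10 μU/mL and 90 mg/dL and elevate both for the hyperglycemic group,
physiologically plausible neonatal values.

What the generator does **not** emulate: peptide-level interference,
batch and run-order drift, correlated feature blocks beyond the planted
effects, isotope or isobaric artifacts, and real interactome curation
bias. Passing recovery tests therefore demonstrates the statistical
machinery is correct, not that real data meet its assumptions.

# Lipidomics quality control

Four filters are applied **sequentially**, so a species failing several
criteria is counted only at the first stage that removes it:

1. *Pool missingness*: missing fraction among QC-pool samples > 35%
   (strict).
2. *Group-wise missingness*: missing fraction ≥ 50% in **every**
   biological group (boundary inclusive). The narrative description of
   this rule ("observed in only one of the biological groups") and its
   quantitative statement differ; the quantitative 50%-in-all-groups
   reading is implemented and both the threshold and the rule are
   configurable.
3. *QC-pool CV* > 25%, computed as sample SD / mean on the **linear**
   concentration scale from observed pool values (n − 1 denominator);
   the linear scale matches standard QC-pool practice.
4. *D-ratio* > 50%, where D = σ~tech~/√(σ~biol~² + σ~tech~²), σ~tech~
   from observed QC pools and σ~biol~ from observed biological samples.
   D > 50% means technical variance exceeds biological variance. The
   degenerate 0/0 case is defined as 0 with a warning.

Survivors are completed by k-nearest-neighbour imputation (k = 10):
neighbours must have an observed value in the target sample
("obs-sel"), distances are root-mean-square Euclidean distances between
row-standardized profiles over jointly observed samples (so similarly
shaped species of different absolute abundance are close), votes are
inverse-distance-weighted means of raw neighbour values, and exact-zero
distances share the vote equally. Fewer than k eligible neighbours
triggers a warning and uses all available; none at all falls back to
the species mean.

# Proteomics post-quantification

The chain is fixed: q-value filtering → charge-state aggregation →
MaxLFQ → detection filter → imputation.

*Filtering* keeps precursors with global, run-specific and
protein-group q-values ≤ 1% that are proteotypic and not contaminants.
A signal-quality floor is available but off by default — reports do not
agree on a quality column, so the criterion only activates when mapped.

*MaxLFQ* (`maxlfq()`): for each sample pair the protein-level log2
ratio is the median of shared-peptide log2 ratios (even counts take the
mean of the central pair in log space, i.e. the geometric midpoint);
per-sample log2 abundances solve the least-squares system over all
valid pairs. The least-squares level is undetermined by ratios alone;
we anchor each connected block of samples so its mean log2 protein
abundance equals the mean log2 of per-sample peptide sums — any other
constant cancels in downstream fold changes. Samples in no valid pair
stay missing.

*Detection filter*: proteins observed in ≥ 60% of all samples
(inclusive: 12 of 19 passes, 11 of 19 does not).

*Imputation* (`impute_iterative()`): iterative regression imputation on
the log2 scale — each incomplete protein is regressed on its most
correlated predictors, imputed cells are refreshed, and the cycle
repeats until the largest change falls below 1e-4 or 10 iterations.
Because samples are far fewer than proteins, a full regression on all
other proteins is singular; predictors are capped at 5 and must reach
|r| ≥ 0.4, otherwise the row mean is kept — guarding against
overfitting spurious correlations at n ≈ 19. Observed values are never
altered and results are deterministic for a fixed seed.

# Differential statistics

Each feature of a log2 matrix is fit with the 2 × 2 linear model
`value ~ group * sex`. Because the design is unbalanced (6/4 vs 5/4),
order-dependent Type I sums of squares are rejected; **Type II** is the
default (each main effect adjusted for the other, interaction last),
with Types I and III available. The computation is vectorized over
features via QR projections — the row-wise-testing idiom — and agrees
with per-feature `car::Anova()` to 1e-10 in the tests.

All 3 × n p-values of one omics dataset enter a **single**
Benjamini–Hochberg step-up ("pooled BH"), pooled per dataset (proteome,
metabolome, lipidome separately). Features with a significant
interaction can be followed up with Tukey HSD over the four cells
(Tukey–Kramer SEs for unequal cell sizes).

Fold change is log2 of the ratio of linear-scale group means after
imputation (the difference-of-log-means alternative is a flag away).
Significance requires adjusted p ≤ 0.05 **and** linear fold ≥ 1.5
(|log2 fc| ≥ 0.585), both boundaries inclusive; the fold criterion is
read as linear fold change, since published hit lists of this design
include proteins with |log2 fc| well under 1.5 linear-log ambiguity.
Both thresholds are arguments.

HOMA-IR = insulin (μU/mL) × glucose (mg/dL) / 405; QUICKI =
1/[log10 insulin + log10 glucose] (base 10, the standard for this
index; natural logs would redefine the conventional 0.45
low-sensitivity cutoff, which `quicki()` flags). Group comparisons of
clinical indices use the two-tailed Student's t-test (equal variances).

# Multivariate analysis

Scaling follows the per-analysis conventions: PCA on log2 data
(optionally unit-variance for metabolite panels), OPLS-DA and
co-inertia on log2 + Pareto (centered, divided by √SD). PCA is a
centered SVD with a deterministic sign convention (largest-|loading|
entry positive); Ward clustering uses `hclust` "ward.D2" on Euclidean
distances and is verified against exhaustive agglomeration.

**OPLS-DA** is fit by NIPALS: orthogonal components are stripped one at
a time, then a single predictive component is fit. The number of
orthogonal components maximizes leave-one-out cross-validated Q2,
growing from 0 while the gain is ≥ 0.01, capped at min(5, n − 2) — the
selection rule is otherwise under-determined. R2X/R2Y come from the
fitted model, Q2 = 1 − PRESS/TSS from held-out predictions (training
folds re-centered). VIP is computed over the predictive component, so
mean(VIP²) = 1 by construction, asserted on every fit. Permutation
tests use the add-one estimator p = (1 + #{perm ≥ obs})/(1 + n~perm~),
whose floor at 200 permutations is 1/201 ≈ 0.005 — a reported
permutation p below that floor cannot come from this estimator, so we
report Q2 and its permutation p separately rather than chase a
fitted-distribution p.

**Co-inertia** of two blocks on common samples comes from the SVD of
the cross-covariance of the centered blocks: axis variance fractions
are the squared singular values' shares, and block similarity is the RV
coefficient, RV = tr(XX′YY′)/√(tr(XX′)² tr(YY′)²) ∈ [0, 1], tested by
row-permuting one block. Each block is Pareto-scaled separately — a
joint scaling would let the larger block dominate.

# Network analysis

Edge lists in the STRING dialect (scores 0–1000) are rescaled to [0,1];
confidence filtering is strict (score > 0.7 for the high-confidence
variant). **LCC significance** compares the largest connected component
of the seed-induced subgraph with uniformly drawn node sets of the same
size (no degree matching — the null here asks only whether *this many*
proteins cohere). Because 10,000 draws cannot resolve extreme
significance, both the empirical add-one p and a normal-tail p from the
null mean/SD are reported.

**Random walk with restart** iterates p ← α·p0 + (1 − α)·Wp with W the
column-normalized adjacency, restart α = 0.9 (staying close to the
seeds), p0 uniform over seeds; isolated columns redistribute to p0 so
scores always sum to 1. **Expansion** adds non-seed nodes in RWR-score
order (ties: higher degree, then lexicographic — an explicit schedule
keeps runs reproducible) until ≥ 90% of seeds lie in one connected
component of the induced subgraph, or a cap flags failure.

**Network proximity** is the closest distance d~c~ = mean over the
query set of the minimum shortest-path length into the disease set,
z-scored against random sets drawn from logarithmic degree bins (bins
merged upward until each holds ≥ 100 candidates), preserving each set's
size and bin-degree composition — the correction for the heavy-tailed
degree distribution. The query set is the averaged one; a symmetric
variant is a flag. Unreachable pairs are excluded from the average with
a warning by default (a penalty constant is available), and the same
choice applies inside the null. Disease screening filters associations
at GDA score > 0.3 (strict), computes Jaccard and proximity per
disease, and BH-adjusts the empirical proximity p-values across
diseases. Over-representation uses the hypergeometric upper tail
against file-based GMT sets.

# Problem sizes and numerical choices

Test and validation runs use sizes chosen to exercise every code path
at desk scale: the full 1,204-species lipid fixture for QC count
recovery; 100-feature matrices over 100 replicate seeds for planted
group-effect recovery (sensitivity ≥ 0.90 at empirical FDR ≤ 0.10);
2,000-node PPI graphs with a planted 10-node module and a 50-disease
catalogue over 100 seeds for LCC (z > 2) and proximity-screening
recovery (null draws: 200 for LCC, 100 per disease); oracle-equivalence
checks run on ≤ 50-node graphs where brute-force BFS/union-find/
enumeration oracles are exact. Convergence tolerances: RWR L1 < 1e-8,
imputation 1e-4 with 10 iterations; permutation and resampling p-values
always use add-one estimators; all stochastic results carry their seed
and draw count and are bit-reproducible.

# Known limitations

- The iterative imputation is a deterministic regression scheme, not a
  random-forest ensemble; at n ≪ p its capped-predictor form is robust
  but less flexible than forest-based imputation on strongly nonlinear
  structure.
- The precursor filter's signal-quality criterion activates only when a
  quality column is mapped, as no universal definition exists across
  report dialects.
- OPLS-DA component selection, the MaxLFQ anchoring constant and the
  proximity unreachable-pair convention are principled defaults for
  under-specified steps; all are exposed as arguments.
- Real headline counts of any particular study (numbers of significant
  proteins or metabolites, RV, Q2 on real matrices) depend on the
  deposited data; this package validates the machinery on synthetic
  ground truth and provides the same interfaces for user-supplied
  tables.
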