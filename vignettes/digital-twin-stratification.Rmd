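---
title: "Digital-twin manifold stratification: models, parameters and design choices"
author: "oncotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin manifold stratification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adjuvant-treatment decisions for women aged 70 and older with HER2-negative
early breast cancer are poorly served by prognostic tools trained on younger
cohorts. `oncotwin` implements a prognostic and treatment-guidance pipeline
for this population built from nine routine predictors available before any
treatment decision: age, tumor size (mm), SBR grade (binarized, 3 = high),
number of involved lymph nodes, hormone-receptor status (positive when ER or
PR staining reaches 10% of tumor cells), hemoglobin (g/dL), lymphocyte count
(G/L), BMI, and the presence of any comorbidity. Treatment variables and
creatinine are deliberately excluded: treatment effects are an *outcome* of
the analysis, and creatinine tracks age and non-cancer kidney disease. The
outcome is overall survival at 5 years, so only patients whose 5-year status
is resolvable (at least 60 months of follow-up, or death before then) enter
the analysis, and records missing any of the nine predictors are deleted
rather than imputed.

## The model

The pipeline has four stages.

**1. Reference calibration ("digital twins").** Patients alive at five
years without relapse form the good-outcome *reference class*; a seeded
random half of them calibrates the model, and everyone else becomes the
*model data* that populates the manifold (the two sets are disjoint, so no
calibration patient is ever scored against itself). Each predictor gets a
robust center (median) and scale (IQR/1.349) from the reference group, and a
patient's **deviation vector** is its predictor vector standardized in these
reference units — a signed, unit-free description of how the patient departs
from the good-outcome population. The *k* nearest standardized reference
profiles (default `k_twins = 15`, Euclidean distance, ties broken by
reference row order) are the patient's digital twins; the residual from the
twin-neighborhood centroid (`twin_residual()`) is exposed as a typicality
diagnostic — it is zero exactly when the patient coincides with the centroid
of its twins.

A design note on what the deviation is measured against. Measuring the
deviation used downstream from the *local* twin centroid instead of the
reference distribution would subtract each patient's own neighborhood mean —
a high-pass filter that erases population structure (in our experiments it
collapses all six generator clusters onto the origin, adjusted Rand index
about 0 against truth, versus about 0.99 for reference-standardized
deviations). Since the whole point of the manifold is to stratify the
population into clinically distinct profiles, the embedding consumes the
reference-standardized deviations, and the twin residual remains a
per-patient diagnostic.

A second note on scaling: the IQR of a binary predictor whose reference
prevalence lies outside the quartiles (ER positivity is ~97% in a
good-outcome reference) is zero, and a tiny positive floor would make that
dimension dominate every distance by orders of magnitude. Degenerate spreads
therefore fall back to a scale of 1, leaving such predictors on their natural
0/1 scale; truly constant predictors still standardize to all-zero columns.

**2. 3D embedding (PaCMAP).** Deviation vectors are reduced to three
dimensions with a pairwise-controlled manifold approximation, implemented in
the package: nearest-neighbor pairs chosen on locally scaled distances
(scale = mean squared distance to the 4th–6th neighbor), mid-near pairs
(second-closest of six random candidates, `0.5 × n_neighbors` per point) and
further pairs (`2 × n_neighbors` random non-neighbors), optimized with Adam
(learning rate 1, 450 iterations) under the standard three-phase weight
schedule (mid-near weight annealed 1000 → 3, then 3, then 0; neighbor weight
2 / 3 / 1; repulsion 1 throughout), from a PCA initialization shrunk by
0.01. The fit is fully seeded and deterministic.

`n_neighbors` defaults to 30 rather than the more customary 10. Binary
predictors split every patient subgroup into Bernoulli sub-cells ~1 scale
unit apart, and a 10-neighbor graph oversegments these sub-cells into
separate islands (the overseparation binary features are known to induce in
this family of embeddings). Thirty neighbors are enough to bridge the
sub-cells of a subgroup while still being far fewer than a subgroup's
membership at the cohort sizes the package targets (several hundred to a few
thousand patients).

**3. Mean-shift stratification.** Embedded points are clustered by
Gaussian-kernel mean-shift (each point ascends the kernel density of the
fixed point cloud; converged modes are merged by single linkage at half the
bandwidth; clusters are relabelled by decreasing size). The bandwidth
defaults to the 0.1 quantile of pairwise embedded distances, computed on a
deterministic subsample of at most 1000 points. The quantile must stay below
the within-cluster fraction of pairs — about 1/k for k balanced clusters —
or the bandwidth jumps to between-cluster separations and everything merges;
with six expected clusters that bound is ~0.17, so 0.1 leaves a margin while
remaining insensitive to outliers. Clusters with fewer than 10 members are
reported but flagged *minor* and excluded from prognosis labelling. Major
clusters are labelled **good** when observed 5-year survival exceeds 80%,
**poor** when 5-year mortality reaches 35%, and **intermediate** between
those published anchor points.

**4. Individual treatment-benefit estimation.** A new patient is scored,
projected into the manifold, and compared with the 15 nearest
chemotherapy-treated and 15 nearest untreated patients (Euclidean distance
in 3D, arms selected independently, ties by index). Kaplan–Meier curves of
the two neighborhoods (via the survival package) and a log-rank test
summarize the apparent benefit. Because nearest-neighbor arms need not be
exchangeable, the comparison is guarded by a *comparability test*: the
symmetrized Kullback–Leibler divergence between the two neighborhoods' 3D
distributions, with significance from a permutation test (pool the 30
points, re-split preserving arm sizes, B = 1000 by default). When the arms
are not comparable (p ≤ 0.05) the verdict carries an explicit heterogeneity
warning. No causal adjustment (propensity weighting, matching) is attempted
— the method is a transparent nearest-neighbor comparison, and that
limitation is inherited by design.

### Numerical choices in the KL machinery

Densities are Gaussian product-kernel estimates with Scott's-rule
bandwidths per dimension and a 1e-12 floor so log-densities stay finite.
Own-group densities are evaluated leave-one-out: the plug-in alternative
inflates each point's own density and overestimates the divergence by a
large margin (≈ +0.26 at n = 2000 on the unit-Gaussian oracle, where the
truth for a mean offset δ is exactly δ²). Cross-group densities are
evaluated in full — excluding exact matches there would delete the dominant
kernel whenever projected test points coincide with training coordinates,
which the nearest-anchor projection produces by design. The symmetrized
estimate is truncated at zero: identical samples give exactly 0, the
divergence is never negative, and truncation cannot change the permutation
test's upper tail, hence neither its p-values for separated samples nor its
type-I error (measured ≈ 0.06 over 200 null replicates at B = 200). The
p-value is the literal count fraction `#{permuted ≥ observed}/B`, so p = 0
is possible; a `plus_one` option gives the standard (count+1)/(B+1)
estimator.

### Projection of new patients

Out-of-sample points are placed by nearest-anchor assignment: a new
deviation vector takes the embedded coordinate of its nearest training
deviation (exactly, when it duplicates a training row). Inverse-distance
interpolation over several anchors is available (`k > 1`) but shrinks
projected clouds toward cluster interiors, which the stability protocol
correctly flags as a distribution change; nearest-anchor assignment
preserves the embedded distribution of projected samples.

## The synthetic cohort generator

Because the study cohort is not publicly deposited, the package ships a
seeded generator that emulates its published structure and is the test bed
for every downstream stage. It draws cluster membership from six profiles
whose feature means equal the published per-cluster values (hemoglobin,
BMI, nodes, tumor size, age, lymphocytes, comorbidity prevalence,
ER-positive prevalence, SBR-high prevalence), with equal weights (cluster
sizes are not published). Dispersions are not published either; each
feature's spread defaults to 15% of its cross-cluster range (with a floor
for the node count), a choice that keeps clusters distinct but overlapping
in single features, as Table-style cluster means suggest. Continuous
features are truncated normals (age at 70, sizes and blood values at 0;
node counts rounded to integers), binaries are Bernoulli with the cluster
prevalence. ER/PR percentages are generated consistently with the 10%
positivity rule, with PR positivity only among ER-positive tumors so that
hormone-receptor prevalence tracks the cluster's ER prevalence.

Survival is exponential within cluster with rate λ = −ln(1 −
mortality)/60 per month, pinned so the 5-year death probability equals the
cluster's `mortality_5y`; defaults are 0.12 for the three good-prognosis
clusters, 0.25 and 0.30 for the intermediate ones and 0.40 for the worst —
inside the published anchor bounds (>80% survival for the good clusters, ≥
35% mortality for the worst). Chemotherapy is Bernoulli at a 12% marginal
rate (optionally biased toward high-mortality clusters on the log-odds
scale, recentred so the marginal is preserved) and multiplies the hazard by
a configurable per-cluster ratio (default 1 — no fabricated benefit).
Survivors are administratively censored uniformly on [60, 120] months, so
every record passes the eligibility filter; an event before the censoring
time is recorded as a death at its time even beyond month 60, keeping
realistic late tails in Kaplan–Meier displays while leaving 5-year labels
untouched. Relapse, which only matters for reference-class selection, is
set for all deaths and drawn among 5-year survivors at half the cluster's
mortality rate.

What the generator does *not* emulate: the real cohort's missingness
pattern, the joint TNM distribution beyond marginals, within-cluster
feature–outcome correlations (survival is independent of features given the
cluster), or measurement error. Passing tests on generated cohorts
therefore demonstrate that the machinery recovers known structure under
realistic noise — not that the published clinical findings replicate on
real data.

## Validation protocols

**Stability.** The clustered model data are split 70/30 within every
cluster (training share rounded up; singletons go to training), the
embedding is refit on the training share alone, the test share is projected
onto the fresh manifold, and each original cluster's training and projected
test points are compared with the KL permutation test. The protocol repeats
over 10 seeded initializations and passes when every cluster's median
p-value exceeds 0.05. Deviation scoring is refit on the training share in
each repetition. On generated cohorts (n = 600–2000) the protocol passes
across seeds; translating the test data off-support makes it fail, as it
should.

**Predictive power.** The nine predictors are evaluated for 5-year
mortality prediction with a random forest and an RBF support vector
classifier under stratified 5-fold cross-validation (SVC decision values
feed the ROC), reporting mean/SD AUC and accuracy plus an impurity-based
importance ranking (percentages summing to 100) from a forest refit on all
data. No hyperparameter search is performed; classifier defaults are those
of randomForest and e1071. On the synthetic cohort these checks are
calibration limits (AUC ≈ 1 for a separable outcome, ≈ 0.5 for permuted
labels), not reproductions of real-data scores: the generator's survival is
cluster-level, so feature-level AUC on generated data has no reason to
match values estimated on the clinical cohort.

## Problem sizes and runtimes

The package's own test-bed sizes: cohorts of 2000 for cluster recovery
(about half a minute end to end on one core), 1200 for the full 10-
initialization stability protocol (about a minute), 200 null replicates at
B = 200 for permutation-test calibration. Larger cohorts scale quadratically
in the embedding's pair-selection and mean-shift steps; bandwidth estimation
subsamples at 1000 points regardless of n.

## Known limitations

* The published twin-scoring algorithm is proprietary; the open
  re-specification here (robust reference standardization + k-nearest
  twin neighborhoods) matches its published contract but makes no claim of
  numerical equivalence.
* Nearest-neighbor treatment comparison is not causal inference;
  confounding by indication survives the comparability guard.
* Mean-shift cluster counts depend on the bandwidth rule; the quantile
  default is principled but config-exposed for a reason.
* Clusters in embedding space are assumed to correspond to clusters in
  deviation space; clustering is performed in 3D, as the visual analytics
  workflow implies.
* HER2-positive disease, electronic-health-record extraction, and
  missing-data imputation are out of scope.
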