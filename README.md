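# oncotwin

Prognostic stratification and individual chemotherapy-benefit estimation
for women aged 70+ with HER2-negative early breast cancer.

Older patients are underrepresented in the trials and web tools that guide
adjuvant-therapy decisions. `oncotwin` implements a "digital twin"
pipeline for this population built from nine routine pre-treatment
predictors — age, tumor size (mm), SBR grade (high = 3), involved lymph
nodes, hormone-receptor status (ER or PR ≥ 10% of tumor cells),
hemoglobin (g/dL), lymphocyte count (G/L), BMI, comorbidity — with
5-year overall survival as the outcome:

1. **Reference calibration.** Good-outcome patients (alive at 5 years,
   no relapse) define a reference population; a seeded half of them fixes
   per-predictor robust centers and scales (median, IQR/1.349). Every
   other patient is expressed as a *deviation vector* — its standardized
   departure from that reference — and its *k* nearest reference profiles
   (default 15) are its digital twins, whose centroid residual serves as a
   typicality diagnostic.
2. **Manifold.** Deviation vectors are embedded in 3D with a
   pairwise-controlled manifold approximation (PaCMAP; implemented in the
   package) and stratified with Gaussian mean-shift clustering. Clusters
   are labelled *good* (5-year survival > 80%), *poor* (mortality ≥ 35%)
   or *intermediate*.
3. **Treatment benefit.** For a new patient projected into the manifold,
   the 15 nearest chemotherapy-treated and 15 nearest untreated patients
   are compared via Kaplan–Meier curves and a log-rank test, guarded by a
   comparability check: a permutation test on the symmetrized
   Kullback–Leibler divergence D(P‖Q) + D(Q‖P) between the two arms' 3D
   distributions, with p = #{permuted ≥ observed}/B. Non-comparable arms
   trigger an explicit heterogeneity warning.
4. **Validation.** A stability protocol (70/30 per-cluster splits, refit
   embedding, project the test share, KL-compare per cluster over 10
   initializations) and a predictive-power protocol (random forest and
   SVC, stratified 5-fold CV AUC, importance ranking).

Because the clinical cohort is not publicly deposited, the package ships a
seeded synthetic-cohort generator emulating its published six-cluster
structure (per-cluster feature means, 12% chemotherapy, cluster-specific
5-year mortality), which is the test bed for the whole pipeline. See the
methods vignette (`vignettes/digital-twin-stratification.Rmd`) for the
model, parameter defaults and design rationale.

## Worked example

```r
library(oncotwin)

# a synthetic cohort with a real chemotherapy benefit (hazard ratio 0.4)
# confined to the worst-prognosis cluster
cfg <- cohort_config(n = 1500, seed = 42, chemo_rate = 0.5,
                     chemo_hazard_ratio = c(1, 1, 1, 0.4, 1, 1))
cohort <- complete_case_filter(eligibility_filter(generate_cohort(cfg)))

split      <- split_reference_model(cohort, fraction = 0.5, seed = 42)
reference  <- fit_reference(split$reference)
deviations <- score_cohort(reference, split$model)
manifold   <- fit_clusters(fit_embedding(deviations, seed = 42))
summarize_clusters(manifold, split$model)
```

```
  cluster_id size tumor_size hemoglobin n_nodes mortality_5y prognosis_label
1          1  189       65.6       13.0   6.185        0.354            poor
2          2  173       30.1       11.9   0.919        0.410            poor
3          3  165       18.9       13.3   0.867        0.230    intermediate
4          4  161       26.3       13.0   1.540        0.398            poor
5          5  138       22.1       13.3   0.993        0.174            good
6          6  134       18.9       13.4   0.679        0.187            good
```

Six clusters re-emerge with their distinguishing profiles: a large
node-positive tumor cluster (65.6 mm, 6.2 nodes), a low-hemoglobin cluster
(11.9 g/dL), and good-prognosis clusters of small low-grade tumors.
(Model-data mortality runs higher than in the full population because half
of the good-outcome patients were set aside as the reference group.)

A new high-risk patient is then assessed individually:

```r
new_patient <- c(age = 77, tumor_size = 64, grade_high = 1, n_nodes = 6,
                 hr_positive = 1, hemoglobin = 13, lymphocytes = 1.6,
                 bmi = 28.9, comorbidity = 0)
assemble_benefit_report(score_cohort(reference, new_patient),
                        manifold, split$model, seed = 42)
```

```
Chemotherapy-benefit report
  query point: (-19.29, 2.83, -1.46)
  neighbors per arm: 15 
  5-year survival 67% with vs 47% without chemotherapy (log-rank p = 0.227).
```

The 15 nearest treated neighbors show a 20-point survival advantage at five
years — consistent with the benefit built into this cluster — while the
log-rank test at n = 15 per arm remains (honestly) inconclusive, and the
absence of a heterogeneity warning says the two arms occupy comparable
regions of the manifold. `plot(report)` draws the two KM curves and the
permutation histogram; `plot(manifold, cohort)` draws the cluster map.

A command-line front end (`inst/cli/oncotwin.R`) exposes `simulate`,
`summarize`, `fit`, `benefit`, `validate-stability` and `evaluate`
subcommands over the same functions.

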