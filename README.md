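# dceradiomics

Heterogeneity and radiomics analysis of dynamic contrast-enhanced (DCE)
breast MRI for discriminating **luminal vs non-luminal** breast-cancer
subtypes — for imaging scientists and biostatisticians who want a tested,
reproducible R implementation of this pipeline rather than opaque clinical
software.

The package implements, end to end:

* **Voxel-wise kinetic typing** of three-phase enhancement curves
  (pre-contrast, initial ~90 s, delayed): with relative late change
  `r = (s_delayed − s_initial)/s_initial`, a voxel is persistent (type I,
  `r > 0.10`), washout (type III, `r < −0.10`) or plateau (type II), with
  non-enhancing voxels excluded.
* The **entropy heterogeneity index** of the curve-type proportions,
  `H = −Σ Pk log Pk` (natural log, `0 ≤ H ≤ ln 3`), plus the three
  proportions themselves — the four heterogeneity parameters.
* **3D GLCM texture features** with the AK-style naming grammar
  `<Statistic>_<angle|AllDirection>_offset<d>[_SD]` (Correlation,
  HaralickCorrelation in the ITK convention, GLCMEntropy, ClusterShade; 4
  planar angles, 13-direction AllDirection aggregates, offsets in mm on the
  1 mm isotropic grid).
* **Feature screening** by per-feature logistic regression at P < 0.05
  (optional two-stage joint pruning), standard scaling, min-max scaling,
  point-biserial checks, ICC(2,1) inter-reader reliability, and Table-1-style
  cohort statistics (Student's t, chi-square/Fisher).
* A **five-classifier benchmark** — logistic regression, naive Bayes, KNN,
  decision tree, XGBoost — with stratified 7:3 splitting, confusion-matrix
  metrics and stratified-bootstrap AUC CIs.
* **Clinical translation**: nomogram point scales with an exact
  points-to-probability mapping, and decision-curve (net-benefit) analysis
  against treat-all/treat-none.
* A **synthetic phantom and cohort generator** with known ground truth
  (NIfTI in/out), so every stage is testable without patient data.

## Worked example

```r
library(dceradiomics)
library(dplyr)

# a 388-patient synthetic cohort emulating the target study conditions
ft <- simulate_feature_table(cohort_config(), seed = 42) |>
  split_cohort(seed = 42)                      # 272 train / 116 validation

bench <- compare_models(
  ft,
  features = c("Heterogeneity", "Washout", grep("offset", names(ft), value = TRUE)),
  boot = 500, seed = 42)

bench |> as_tibble() |> filter(set == "validation") |>
  select(model, auc, auc_low, auc_high, accuracy, sensitivity, specificity)
#> # A tibble: 5 × 7
#>   model      auc auc_low auc_high accuracy sensitivity specificity
#> 1 logistic 0.933   0.886    0.974    0.836       0.864       0.807
#> 2 nb       0.873   0.800    0.927    0.784       0.780       0.789
#> 3 knn      0.816   0.731    0.885    0.759       0.797       0.719
#> 4 dt       0.766   0.688    0.835    0.767       0.831       0.702
#> 5 xgboost  0.895   0.828    0.947    0.836       0.847       0.825
attr(bench, "best")
#> [1] "logistic"
```

The logistic model leads the validation set (AUC 0.93 here) because the
cohort's generative log-odds is linear in the features; naive Bayes pays for
its independence assumption on the correlated texture panel, and the tree
learners overfit. The fitted logistic model converts into the clinical
artifacts:

```r
fit <- attr(bench, "models")$logistic
nom <- build_nomogram(fit)
tidy(nom)            # per-feature point scales; strongest feature spans 0-100
#> 5 HaralickCorrelation_angle0_offset1  -2.60  2.36  20.1  100

val <- standard_scale(ft, fit_rows = ft$split == "train",
                      columns = fit$features)[ft$split == "validation", ]
dc <- decision_curve(predict_prob(fit, val), val$label)
autoplot(dc)         # net benefit vs treat-all / treat-none
```

At the voxel level, phantoms with known curve-type mixtures are recovered
exactly when noiseless:

```r
les <- simulate_lesion(lesion_spec(curve_mixture = c(0.2, 0.5, 0.3),
                                   noise_sd = 0), seed = 7)
analyze_lesion(les$series, les$mask)
#> # A tibble: 1 × 6
#>      P1    P2    P3     H n_voxels n_excluded
#> 1 0.200 0.500 0.300  1.03     1419          0
```

`H = 1.03` is the entropy of the realized (0.2, 0.5, 0.3) mixture; a pure
lesion gives `H = 0` and the uniform mixture the maximum `ln 3 ≈ 1.099`.

The methods vignette (`vignettes/dce-heterogeneity-radiomics.Rmd`) documents
the model, every tunable parameter with its default and rationale, the
generator's design, numerical choices and limitations.

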