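# radprog

Radiomics prognostic signatures from segmented MRI tumor volumes.

Advanced nasopharyngeal carcinoma (and solid tumors generally) shows
strikingly heterogeneous outcomes within a clinical stage, and routine MRI
carries texture information about intratumoral heterogeneity that staging
ignores. `radprog` implements the full analysis chain that turns two
co-registered MRI sequences (T2-weighted and contrast-enhanced
T1-weighted) plus a binary tumor mask into a validated prognostic
signature for progression-free survival (PFS):

1. **Image variants** — the original volume, Laplacian-of-Gaussian
   band-pass responses at σ ∈ {1.0, 1.5, 2.0, 2.5} pixels (fine to coarse
   texture), and the 8 subbands of a single-level undecimated Coiflet-1
   wavelet transform: 13 variants per sequence.
2. **Feature catalog** — per sequence: 11 shape and 19 first-order
   features on the original image, plus 24 gray-level co-occurrence (GLCM)
   and 11 run-length (GLRLM) features on each variant; 485 per sequence,
   **970 per patient**, with deterministic keys like
   `T2w_3_GLCM_homogeneity1`.
3. **Signature** — features are z-scored (discovery-set statistics frozen
   for validation), selected by lasso-penalized Cox regression
   (`glmnet`, cross-validated penalty), and combined into a linear
   **Rad-score**

   Rad-score = c + Σᵢ βᵢ zᵢ,

   dichotomized at the discovery-set median into low/high risk. The
   published five-feature signature (coefficients 2.495, 1.474, −1.203,
   −0.809, −3.839; constant −7.995; cutoff −6.863) ships as
   `published_radscore_model()`.
4. **Validation** — multivariate Cox proportional-hazards models without
   (model 1) and with (model 2) the Rad-score, Kaplan–Meier estimation,
   log-rank tests, and stratified subgroup analyses (age ≤40/40–50/>50,
   sex, overall stage III/IV, hemoglobin ≤156/>156 g/L, platelets
   ≤158/>158 ×10⁹/L).
5. **Synthetic cohort generator** — seeded 3D Gaussian-random-field tumors
   whose texture drives a proportional-hazards PFS model, with clinical
   covariates drawn independently of outcome, so the whole pipeline is
   testable end to end without patient data.

## Worked example

Score a patient against the published signature (feature values are
z-scores of the five signature features):

```r
library(radprog)
m <- published_radscore_model()
z <- setNames(c(0.8, -0.2, 0.1, -0.5, 0.3), m$terms$key)
score <- compute_radscore(z, m)
score
#> [1] -7.1613
as.character(assign_risk_group(score, m))
#> [1] "low"
```

A score of −7.16 falls below the −6.863 cutoff, so this patient is
predicted low risk (longer PFS). Run the whole pipeline on a small
synthetic cohort:

```r
cfg <- cohort_config(n_patients = 40, seed = 2718,
                     grid_shape = c(18, 18, 14))
report <- run_pipeline(pipeline_config(cohort = cfg))
report
#> radprog run report
#>   patients: 40  features: 970
#>   selected terms: 1  cutoff: -0.005962533
#>   stages: simulate -> extract -> normalize -> fit-signature -> score -> validate
subset(report$cox, covariate == "radscore",
       c(set, model_label, HR, ci_low, ci_high, p_value))
#>          set model_label       HR   ci_low  ci_high    p_value
#>    discovery      model2 244.7818 1.304018 45948.87 0.03946082
```

Each patient gets 970 features; the lasso kept one planted texture
feature at this small size, and in model 2 the resulting Rad-score is a
significant predictor of PFS on the discovery set (the huge hazard ratio
per Rad-score unit reflects the score's small scale here) while the
clinical covariates are not. At the reference cohort size (n = 100) the
generator's five planted features are recovered; see the methods
vignette.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "radprog.R", package = "radprog")` with subcommands
`simulate`, `extract`, `fit-signature`, `score`, `validate` and `run`.

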