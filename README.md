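# capnopred

Estimate spirometric pulmonary-function parameters — FEV1 and FVC, in
liters — from single-breath **volumetric capnography** (expired CO₂
partial pressure against expired volume) plus basic demographics.
Spirometry needs a maximal forced maneuver that many patients cannot
produce; a relaxed CO₂ breath is far easier to collect. The package is
aimed at respiratory-device and biosignal researchers who want a fully
reproducible, testable implementation of a capnography-to-spirometry
pipeline.

## The combination algorithm

Three cooperating structures produce the final estimate:

1. **Medical feature regression** — ten capnogram features (boundary
   coordinates C12/V12, C23/V23; phase volumes V2, V3; phase slopes
   S2, S3 in mmHg/L; S3/S2; the phase II/III angle `Angle23 = 180° −
   atan S2 + atan S3`) plus sex, age, height, weight and BMI. A
   radial-kernel SVM classifies airflow limitation at the GOLD
   fixed-ratio cutoff FEV1/FVC < 0.7; its decision score z becomes a
   probability via the sigmoid `p = 1/(1+e^(−z))`, which is appended to
   the features; gradient-boosted trees (XGBoost) then regress FEV1 and
   FVC on the fused 16-vector.
2. **Sequence feature regression** — a 1-D convolutional network on the
   first 12 s of the raw CO₂ series (2400 samples @ 200 Hz): three
   blocks of `Conv1D(k=5) → MaxPool(5) → Dropout` with 32/64/32
   filters, a 576-wide flatten, and a dense head; ~22k trainable
   parameters, trained with Adam on the MSE.
3. **KNN error correction** — each subject's four first-stage outputs
   `(FEV1_med, FVC_med, FEV1_seq, FVC_seq)` form a point in a 4-D
   space of liters; the final estimate is the mean measured (FEV1,
   FVC) of the K = 5 Euclidean-nearest training subjects.

Evaluation uses RMSE and R² plus a percentage-error family — maximum
(MPE), mean absolute (MAPE) and root-mean-square (RMSPE, normalized by
the mean truth) percentage errors — combined into the comprehensive
percentage error `CPE = (MPE + MAPE + RMSPE)/3` and the accuracy rate
`ACC = 100% − CPE`, under stratified 10-fold cross-validation.

Because no clinical recordings are distributable, the package ships a
**synthetic cohort generator** calibrated to a mixed adult population
(35% airflow-limited), which drives all tests and examples; an
**adaptive exponential-smoothing flow controller** for the acquisition
side is included as well.

## Worked example

```r
library(capnopred)

# a 300-subject synthetic cohort (demographics, capnogram features,
# raw CO2 sequences, spirometric truths)
cohort <- generate_cohort(cohort_config(300, seed = 20260101))

# extract features from one synthetic breath
trace <- generate_cohort(cohort_config(1, seed = 1, noise_sd = 0),
                         keep_traces = TRUE)$subjects[[1]]$trace
round(unlist(compute_features(trace)), 3)
#>        C12        C23        V12        V23         V2         V3         S2
#>      3.294     23.238    221.172    683.264    462.092   1933.118     43.159
#>         S3 S3_over_S2    Angle23
#>      2.614      0.061    160.395

# cross-validate the three algorithm variants (reduced settings,
# ~6 minutes on one CPU)
report <- run_cv(cohort, plan = cv_plan(k = 10, repeats = 1, seed = 7),
                 epochs = 20)
print(report)
#> Cross-validated results (averaged over folds and repeats)
#>       variant parameter  RMSE    R2     MPE   MAPE  RMSPE    CPE    ACC
#> 1 combination      FEV1 0.526 0.539  66.699 17.182 20.439 34.774 65.226
#> 2     medical      FEV1 0.497 0.581  59.852 16.255 19.330 31.812 68.188
#> 3    sequence      FEV1 0.749 0.082 114.529 26.578 29.103 56.737 43.263
#> 4 combination       FVC 0.338 0.857  26.577  8.230  9.574 14.794 85.206
#> 5     medical       FVC 0.308 0.882  25.211  7.671  8.731 13.871 86.129
#> 6    sequence       FVC 0.840 0.165  92.397 21.940 23.844 46.060 53.940
```

Each row is one algorithm variant × parameter; the error metrics are
averaged over the ten held-out folds. The feature-driven variants
recover FVC with R² above 0.85 on this synthetic cohort, the
sequence-only network is much weaker at this reduced scale (n = 300,
20 epochs), and every row satisfies `ACC = 100 − (MPE + MAPE +
RMSPE)/3` exactly. FEV1 is harder than FVC throughout: the capnogram
features carry obstruction (ratio) information only coarsely.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/capnopred.R simulate    --n 50 --seed 1 --out cohort_dir
Rscript inst/cli/capnopred.R features    --breaths cohort_dir --out features.csv
Rscript inst/cli/capnopred.R flow-replay --trace cohort_dir/breath_0001.csv --out flow_log.csv
Rscript inst/cli/capnopred.R evaluate    --n 300 --seed 1 --epochs 20 --repeats 1
```

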