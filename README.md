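# qusresponse

Quantitative ultrasound (QUS) feature extraction and classification for
**a-priori prediction of breast tumour response to neoadjuvant
chemotherapy**, with survival stratification.

Conventional B-mode imaging discards the frequency content of the raw
radiofrequency (RF) backscatter, which carries information about tissue
microstructure. This package implements the full pre-treatment QUS pipeline
for locally advanced breast cancer:

* **Spectral parameters** — midband fit (MBF), spectral slope (SS) and 0-MHz
  intercept (SI) from a least-squares line over the reference-phantom
  normalized power spectrum `S(f) = 10 log10(P_sample/P_ref)`, computed in
  2 × 2 mm analysis blocks with 80% overlap.
* **Backscatter model parameters** — effective scatterer diameter (ASD) and
  acoustic concentration (AAC) by fitting the Gaussian form-factor model
  `M(f) = AAC + 10 log10(f⁴) + 10 log10(exp(−0.827 k² a_eff²))`,
  `k = 2πf/c`, `ASD = 2 a_eff`.
* **Attenuation** — the attenuation coefficient estimate (ACE, dB/cm/MHz) by
  the spectral difference method over the tumour core.
* **Regions** — a manually outlined tumour core plus an automatic margin
  ring of 3, 5 or 10 mm built by an exact physical-millimetre distance
  transform; parametric images of each parameter over both regions.
* **Features** — region means, GLCM Haralick textures (contrast,
  correlation, energy, homogeneity), and core-to-margin ratio features
  `CMR = μ_core/μ_margin`, `CMCR = |μ_core − μ_margin|/√(σ²_core+σ²_margin)`;
  61 QUS features per patient (averaged over 4–7 image planes), optionally
  plus ER/PR/HER2.
* **Classification** — p-value feature ranking (normality-gated t /
  Mann-Whitney, one-tailed), sequential forward feature selection, and FLD,
  RBF-SVM and weighted k-NN (posterior = ratio of inverse-distance
  neighbour weights) under leave-one-patient-out cross-validation, with
  sensitivity/specificity/accuracy and bootstrap AUC CIs.
* **Survival** — Kaplan-Meier recurrence-free-survival curves by true and by
  QUS-predicted response with log-rank comparison.

Because no clinical RF dataset is deposited, the package includes a
frequency-domain pulse-echo speckle simulator (point-scatterer phantoms with
known ASD/AAC/attenuation ground truth, 6 MHz pulse, 40 MHz sampling), a
matched reference-phantom simulator, spectrum-level oracles, and two-class
feature / censored-survival cohort generators, so the entire pipeline runs
and is tested end-to-end on synthetic data.

## Worked example

Classify a synthetic 56-patient cohort (42 good / 14 poor responders) with
three moderately separated features, then stratify survival by the
predictions:

```r
library(qusresponse)

spec <- cohort_spec(n_good = 42, n_poor = 14,
                    feature_names = c("ACE_core_MEAN", "SI_core_CON", "SI_CMCR"),
                    mean_good = c(1.0, 0.8, 0.9), mean_poor = c(0, 0, 0),
                    covariance = diag(3), seed = 7)
coh <- generate_feature_cohort(spec)
res <- loocv_evaluate(coh$features, coh$labels, classifier = "knn",
                      positive = "good", B = 1000, seed = 7)
summary(res)
#> Leave-one-patient-out cross-validation, knn classifier
#> Patients: 56  (positive class: good)
#> Confusion: TP 40  FN 2  TN 8  FP 6
#> Sensitivity 95.2%  Specificity 57.1%  Accuracy 85.7%
#> AUC 0.842, 95% CI (0.701, 0.953)
#> Posterior group-separation p = 2.562e-05
#> Features: ACE_core_MEAN, SI_core_CON, SI_CMCR

rec <- generate_survival_cohort(c(42, 14), hazards = c(good = 0.002, poor = 0.02),
                                censor_rate = 0.2, seed = 7)
rec$patient_id <- coh$features$patient_id
st <- stratify_by_prediction(res, rec)
sprintf("log-rank chi-square = %.2f, p = %.4f", st$log_rank$chisq, st$log_rank$p_value)
#> "log-rank chi-square = 2.74, p = 0.0980"
```

Each patient's posterior `P(good | x)` comes from the weighted k-NN rule
with inverse-distance weights; the AUC CI is a 1000-replicate
patient-resampled bootstrap. The log-rank test here compares
recurrence-free survival between the two *predicted* response groups.

The full RF-level pipeline — simulate frames, extract the 61 features,
classify, stratify survival — runs from one call:

```r
report <- run_pipeline(pipeline_config(seed = 7), out_dir = "out")
print(report)
```

writing `out/features.csv` and a deterministic `out/report.json`.

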