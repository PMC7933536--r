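# tilquant

Automated assessment of tumour-infiltrating lymphocytes (TILs) for breast
cancer prognostics, built for triple negative breast cancer (TNBC) — a
subtype with no established prognostic biomarker, where a denser lymphocytic
infiltrate is repeatedly associated with better outcome. The package takes
what modern computational-pathology pipelines produce — a tumour-bulk
outline drawn on an H&E whole-slide image, an epithelium/stroma segmentation
of the bulk, and per-marker point detections of positive lymphocytes (CD3,
CD8, FOXP3) — and turns them into the standard panel of TIL measures and
their prognostic analysis.

## What it computes

For each case, seven measurement regions are built from the bulk outline
(micrometre coordinates) and the compartment mask:

| Measure | Region |
|---|---|
| ITA | intratumoural area — the whole outlined bulk |
| ITT | epithelial (tumour-cell) pixels within the bulk |
| ITS | stromal pixels within the bulk |
| IM1 | invasive margin: within 500 µm of the bulk boundary on both sides (effective width 1 mm) |
| IM2 | within 1 mm on both sides (effective width 2 mm) |
| IM1IO / IM2IO | ratio of the inner (tumour-side) to outer half density of IM1 / IM2 |

Margin bands follow the Euclidean-distance definition (isotropic width),
implemented by thresholding an exact distance transform of the rasterized
bulk; the outer half is clipped to the tissue extent. Densities are
expressed per 1 mm² and scaled into regression covariates per increment of
100 positive cells (CD3, CD8) or 10 (FOXP3, which is sparse); between-marker
ratios (CD8/CD3, FOXP3/CD3, CD8/FOXP3) use absolute counts. Sliding-window
density heatmaps use a circle-shaped window of area 1 mm².

Prognostic analysis per measure: univariable Cox proportional-hazards
regression (Efron ties) of relapse-free and overall survival, `HR = exp(β̂)`
per covariate unit, with a percentile bootstrap confidence interval over
patient resamples (5000 by default) and the full-sample Wald p-value; plus
median-dichotomized Kaplan–Meier curves with two-sample log-rank tests.
Undefined measures (zero denominators) are excluded case-wise and counted,
never imputed.

A synthetic-cohort generator (perturbed-disk tumours, thresholded-noise
compartment masks, inhomogeneous Poisson infiltrates with inflamed /
excluded / desert phenotypes, and Weibull proportional-hazards outcomes
linked to a chosen measure) exercises the whole pipeline without any imaging
data.

## Worked example

```r
library(tilquant)

cfg    <- sim_config(n_cases = 40, seed = 11)   # synthetic TNBC-like cohort
cohort <- generate_cohort(cfg)                  # geometry + detections + outcomes

round(cohort$measures[1:3, c("CD3_ITA", "CD3_ITS", "CD3_IM1",
                             "CD3_IM1IO", "FOXP3_ITA", "CD8_CD3_ratio_ITA")], 3)
#>   CD3_ITA CD3_ITS CD3_IM1 CD3_IM1IO FOXP3_ITA CD8_CD3_ratio_ITA
#> 1   3.609   5.486   3.029     1.257     2.854             0.244
#> 2   2.212   3.338   1.941     1.420     1.971             0.410
#> 3   1.878   2.897   1.716     1.632     2.140             0.428

tab <- til_survival_table(cohort$measures, cohort$outcomes,
                          n_boot = 1000, seed = 11,
                          measure_cols = c("CD3_ITA", "CD3_ITS", "CD3_IM1"))
tab[tab$outcome == "OS", c("measure", "hr", "ci_low", "ci_high", "p", "n_used")]
#>   measure    hr ci_low ci_high      p n_used
#> 2 CD3_ITA 0.623  0.290   0.834 0.0269     40
#> 4 CD3_ITS 0.734  0.417   0.899 0.0263     40
#> 6 CD3_IM1 0.600  0.246   0.826 0.0326     40

km_median(cohort$measures$CD3_ITA, cohort$outcomes$os_months, cohort$outcomes$os_event)
#> <km_fit> log-rank chi2 = 4.844, p = 0.02774; n = low:20, high:20; cutoff = 3.544
```

`CD3_ITA = 3.609` means 360.9 CD3⁺ cells/mm² over the whole intratumoural
area (the covariate is density per increment of 100 cells). The generator's
default hazard model makes higher CD3 density protective (true HR 0.85 per
covariate unit), and the fitted hazard ratios below 1 with CIs excluding 1
recover that: each additional 100 CD3⁺ cells/mm² multiplies the hazard of
death by ~0.6–0.7 in this small cohort. The KM fit dichotomizes the cohort
at the median covariate (3.544) and finds significantly better survival in
the high-TIL half.

The full pipeline — simulate (or load a cohort manifest), build regions,
quantify, survive, write CSVs/heatmaps — is one call
(`run_pipeline(config, out_dir)`) or one CLI invocation
(`Rscript inst/cli/tilquant.R all --out-dir out`).

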