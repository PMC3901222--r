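# burndex

Quantifying burn-injury severity from blood metabolites. `burndex`
implements a complete indicator-identification pipeline for liver
arteriovenous metabonomic data from a rat burn model with three injury
levels (sham, 20% and 40% of total body surface area, %TBSA): preprocessing
per-animal measurements, clustering dose-response profiles, counting the
independent response patterns, and selecting a minimal variable set for a
quantitative severity index.

The scientific core, in brief:

- **Dose-response profiles.** For each of 165 measurement series (55
  analytes × hepatic artery / portal vein / suprahepatic vena cava), the
  per-group average across injury levels is normalized to [−1, 1]. Net
  hepatic fluxes can be derived per rat as
  `(C_SHVC·(Q_PV+Q_HA) − C_PV·Q_PV − C_HA·Q_HA) / W_liver`.
- **Clustering with tandem k selection.** Euclidean k-means over the
  profiles; the number of clusters k is the silhouette elbow — the smallest
  k whose forward relative gain in mean silhouette drops below 5% while the
  clustering error still falls. On the packaged data this gives k = 4.
- **Independent patterns by SVD.** The singular values of the 3×k cluster
  centroid matrix count the independent dose-response patterns (non-zero,
  mutually distinct, and carrying more than 2% of squared-singular-value
  mass). Two patterns explain ~98% of the variability, so the severity
  index gets a two-variable budget.
- **Wrapper selection and the index.** A genetic algorithm over variable
  subsets with cross-validated accuracy as fitness, followed by a
  best-first ranking to exactly the budgeted size; models are scored by
  relative absolute error, `RAE = 100·Σ|ŷ−y| / Σ|ȳ−y|`, under five
  repetitions of 10-fold cross-validation. Available regressors: linear,
  multilayer perceptron, normalized-Gaussian RBF network, linear-kernel
  SVR, and an M5-style model tree.

Because the study's per-animal data were never deposited, the package ships
a transcription of the published group summaries (median ± IQR per burn
group for all 165 series, with the published cluster labels) and a
calibrated synthetic-cohort generator, so every stage is testable end to
end.

## Worked example

```r
library(burndex)

summ <- burndex_summary()                  # packaged 165-series summary table
profiles <- profiles_from_summary(summ)    # normalized dose-response profiles

scan <- scan_k(profiles, cluster_config(seed = 1))
scan
#> # A tibble: 7 × 3
#>       k within_ss mean_silhouette
#>   <int>     <dbl>           <dbl>
#> 1     2     187.            0.468
#> 2     3     119.            0.490
#> 3     4      79.9           0.520
#> 4     5      58.2           0.528
#> 5     6      38.5           0.559
#> 6     7      26.9           0.608
#> 7     8      20.9           0.600
choose_k(scan)
#> [1] 4
```

The error curve keeps falling by construction; the silhouette curve's first
flattening (a 5.98% gain into k = 4, then 1.68% to k = 5) marks four
dose-response patterns. Counting how many of those are independent, using
the published cluster labels:

```r
assignment <- data.frame(variable = paste0(summ$analyte, "@", summ$vessel),
                         cluster = summ$paper_cluster)
svd_patterns(centroid_matrix(profiles, assignment))
#> Independent dose-response patterns (SVD of cluster centroids)
#>   singular values: 2.2249, 2.1045, 0.40342
#>   independent patterns: 2
#>   top-2 explained fraction: 98.29%
#>   dominant clusters: 2, 4
```

Two independent patterns — a peak at the intermediate burn and a monotone
decrease — so two variables suffice for the index. Analytes whose cluster
changes between the liver inflows and outflow (a hint of altered hepatic
handling):

```r
cross_vessel_membership(assignment)
#> # A tibble: 3 × 4
#>   analyte                               cluster_ha cluster_pv cluster_shvc
#> 1 Fraction of Carboxyhemoglobin (FCOHb)          1          1            4
#> 2 Partial pressure of CO2 (pCO2)                 2          2            3
#> 3 Alkaline phosphatase (ALP)                     3          3            4
```

The error metric reproduces the published per-rat index predictions
exactly, and a two-variable MLP index on a synthetic 21-rat cohort with the
two headline indicators (VLDL in the hepatic artery, acetoacetate in the
vena cava) lands in the published accuracy regime:

```r
t5 <- burndex_index_predictions()
rae(t5$pred_2var, t5$actual_tbsa)
#> [1] 8.488571        # printed as 8.49%

cohort <- gen_planted_cohort(summ, group_sizes = c(`0` = 7, `20` = 7, `40` = 7),
                             seed = 5)
cross_validate(regressor_spec("mlp"), cohort, attr(cohort, "planted"), seed = 5)
#> 5 x 10-fold CV of mlp on {Very low density lipoprotein (VLDL)@HA, Acetoacetate@SHVC}
#>   relative accuracy: 90.78 +/- 7.87 (RAE 9.22%)

train_index(regressor_spec("mlp", seed = 5), cohort, attr(cohort, "planted"))
#> Burn-severity index (mlp) on Very low density lipoprotein (VLDL)@HA, Acetoacetate@SHVC
#>   training RAE: 0.11% (n = 21)
```

`run_pipeline(pipeline_config(...))` chains all stages from one seeded
config and returns a manifest of every stage output. The methods vignette
(`vignettes/burn-severity-index.Rmd`) documents the model, parameter
defaults, the synthetic-cohort design, and numerical conventions.

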