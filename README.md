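# florastat

Statistical evaluation of automated plant-identification accuracy.

Automated identification apps return a ranked list of taxa for a plant
photograph. Given a table of identification attempts — an expert-verified
species name, the application's first suggestion, the study setting
(database images vs. field use) and image annotations — `florastat` scores
each attempt into four ordered classes (correct **species**, correct
**genus**, correct **family**, **none**) and analyses accuracy the way an
evaluation study should:

* **Iterated one-per-species subsampling.** Species differ wildly in photo
  counts, so percentages are computed over species: one random observation
  per species per iteration, 1000 iterations, averaged. A paired
  comparison reports, per class, the proportion of iterations in which the
  field percentage strictly exceeds the database percentage.
* **Fixed-marginal randomization tests.** Group × class cross tables
  (families, growth forms, Raunkiær life forms, habitats) are tested with
  a Monte-Carlo/exact Fisher test per iteration, and screened cell-wise
  against random tables with the observed margins — sampled by a
  from-scratch sequential conditional-hypergeometric (Patefield)
  generator — using *z* = (obs − mean<sub>rand</sub>)/sd<sub>rand</sub>
  and flags at Φ(z) < 0.05 / > 0.95.
* **A median-frequency null model** asking whether the species of a class
  are systematically rarer or commoner (regional frequency in occupied
  atlas grid cells) than a random draw of as many species.
* **A binomial random-intercept model** (lme4) of species-level success on
  image characteristics, with type-III Wald chi-square tests, estimated
  marginal means on the logit scale and Holm-adjusted compact-letter
  grouping.
* **Training-image association**: Pearson correlation of per-species
  success with ln(training images), and group comparisons of training
  effort.
* **A synthetic-data generator** with exported ground truth (hierarchical
  replicates, covariate-dependent sequential outcomes, species random
  effects, a frequency–training Gaussian copula), so every stage is
  testable by calibration and parameter recovery.

## Worked example

```r
library(florastat)
cfg <- validate_config(list(
  simulate = list(n_species = 60, n_families = 6, seed = 11),
  n_iterations = 40, fisher_B = 100, cell_n_rand = 100,
  min_group_size = 5, output_dir = "scratch/run1"))
run <- run_pipeline(cfg)
print(run)
#> florastat_run: 19 files in 'scratch/run1'
#> florastat run summary
#> =====================
#>
#> database: 81.2% species, 92.0% at least genus, 96.0% at least family (60 species)
#> field: 78.4% species, 85.2% at least genus, 92.7% at least family (60 species)
#> paired comparison over 60 common species: exceedance species 0.250, genus 0.150, family 0.725, none 0.800
#> family analysis: Fisher median P = 0.3564, max P = 1
#> training-image correlation: r = 0.531 (n = 60, P = 1.28e-05)
```

Reading the output: of the 60 simulated species, 81.2 % were identified to
species level in the database setting (78.4 % in the field), rising to 96.0 %
when genus- and family-level matches count. No class's exceedance
proportion falls outside (0.05, 0.95), so the two settings do not differ
significantly. The positive correlation (r = 0.53) recovers the
generator's training-image effect. The output directory holds one CSV per
stage (`class_percentages.csv`, `grouped_family.csv`, `glmm_emmeans.csv`,
…), a `manifest.json` and this summary; identical config + seed reproduce
the bundle byte for byte.

Individual stages are exported too — `classify_observations()`,
`iterate_subsample()`, `compare_settings()`, `grouped_class_analysis()`,
`fisher_exact_mc()`, `cell_randomization_test()`, `fit_binary_mixed()`,
`estimated_marginal_means()`, `training_correlation()` — see the vignette
in `vignettes/` for the methods and their assumptions.

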