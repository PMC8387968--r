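---
title: "Evaluating automated plant-identification accuracy with florastat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating automated plant-identification accuracy with florastat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florastat)
```

## The problem

Automated plant-identification applications return a ranked list of taxa for
a photograph. To evaluate such a tool against expert-verified observations,
each identification attempt is scored into one of four ordered classes based
on the *first* suggestion: correct **species**, correct **genus** (wrong
species), correct **family** (wrong genus), or **none** (not even the family
right). Two features of such data complicate naive summaries:

* **Pseudoreplication.** Some species are photographed once, others dozens
  of times. Raw per-observation percentages over-weight well-photographed
  species, so all percentages here are computed *over species*, with one
  randomly chosen observation per species, repeated (1000 iterations by
  default) and averaged.
* **Species heterogeneity.** Species differ intrinsically in how
  identifiable they are. Analyses of image characteristics therefore use a
  binomial mixed model with a species random intercept.

`florastat` implements this evaluation pipeline end to end, together with a
synthetic-data generator whose ground truth is exported, so that every stage
can be checked by calibration and parameter-recovery simulation.

## Class assignment

Verified and suggested names pass through the same harmonization
(`harmonize_name()`): hybrid markers are removed, infraspecific epithets
(anything after the binomial, including "subsp."/"var." markers) are
stripped, and synonyms are resolved against a pluggable two-file backbone
(`taxonomy_map()`). Comparison is case- and whitespace-insensitive. The
class is then a pure function of the two harmonized names: species on exact
match, else genus when the first name tokens agree, else family when the
backbone maps both names into the same family. An empty suggestion is
`none`. When the application returns several taxa only the first is scored;
`use_alternatives = TRUE` scores a `;`-separated list by its best class, but
is off by default because first-suggestion accuracy is the quantity of
record.

Genus is derived as the first token of the accepted binomial rather than
carried as data: with a consistent backbone the two are equivalent, and it
keeps the backbone format minimal (accepted name, genus, family). A
genus-level suggestion (e.g. an unresolved aggregate) is scored `genus`
when the genera match.

## Subsampling engine

`iterate_subsample()` draws, independently in each iteration, one
observation per species uniformly at random and computes the percentage of
species in each class; the per-iteration species-to-class assignment is kept
(`$stream`) and shared by the downstream contingency and frequency analyses
so all analyses of one run see the same resamples.

The paired comparison of two study settings (`compare_settings()`) restricts
to species present in both, draws the two settings independently per
iteration, and reports per class the proportion of iterations in which the
field percentage strictly exceeds the database percentage. Ties count as
"not higher" (the proportion is of *strict* exceedance) and the tie mass is
reported separately; flags are two-tailed, at `alpha` and `1 - alpha`.
Whether the two settings should be resampled jointly or independently is a
genuinely open choice; independence is used because nothing links a
particular database photo to a particular field observation.

## Fixed-marginal randomization

Group-by-class cross tables (families, growth forms, Raunkiær life forms,
habitats) are screened two ways:

1. **Fisher exact test per iteration** (`fisher_exact_mc()`). The two-sided
   P value is the total multiple-hypergeometric probability of tables no
   more probable than the observed one, conditional on both margins. Small
   problems (a cheap composition bound below `exact_cap`) are enumerated
   exactly; larger ones use the add-one Monte-Carlo estimator
   $(1 + \#\{p(T_b) \le p(T_{obs})\})/(B+1)$ on fixed-margin samples. Note
   the estimator cannot fall below $1/(B+1)$; `B` must exceed $1/p$ to
   resolve a P value of $p$. The median and maximum P across iterations are
   reported.
2. **Cell randomization** (`cell_randomization_test()`). The table
   *averaged over iterations* is compared cell-wise against `n_rand` random
   tables with the same margins: $z = (\mathrm{obs} -
   \overline{\mathrm{rand}})/\mathrm{sd}(\mathrm{rand})$, converted to a
   lower-tail standard-normal probability $\Phi(z)$; cells with
   $\Phi(z) > 0.95$ are flagged `higher`, below $0.05$ `lower`. The screen
   runs once on the averaged table; a per-iteration variant would multiply
   the randomization cost a thousandfold for little gain, since the
   averaged table is the quantity displayed.

Both rest on `sample_fixed_margin_tables()`, a from-scratch implementation
of sequential conditional-hypergeometric table generation (Patefield's
construction): filling cells row by row, each count is hypergeometric given
what remains of its row and of the column margins. This samples exactly
from the independence distribution conditional on margins, and is
vectorized over tables so Monte-Carlo testing stays cheap. Base R's
`r2dtable()` implements the same distribution and serves as an independent
cross-check in the test suite, never as the implementation.

Because the averaged table has non-integer cells but a fixed-margin sampler
needs integer margins, the margins are integerized by largest remainder
(floors plus one unit to the largest fractional parts, rows and columns
forced to the same grand total); the observed cell values stay real for the
z computation. Cells with zero randomization SD (margins that force the
cell) get $z = 0$, probability $0.5$, no flag.

## Median-frequency null model

To ask whether, say, never-identified species are systematically rarer,
each iteration's median regional frequency (occupied atlas grid cells, at
most 540) per class is compared with the median after randomly permuting
class labels over species (preserving class sizes). The per-class P is the
proportion of iterations where the null median strictly exceeds the
empirical one. The empirical median is computed *within* each iteration
(and summarized as the across-iteration median): the species set of a class
changes from iteration to iteration, so a single pre-computed median would
compare incommensurable quantities. Classes empty in an iteration are
skipped for that iteration; classes empty everywhere are reported `NA`.

## Image-characteristics model

`fit_binary_mixed()` models success (identified to species level or not) on
the three image annotations — organs (reproductive / both / vegetative),
focus (single / multiple species), background (no vegetation / non-natural
/ vegetation) — with a species random intercept, via `lme4::glmer`
(Laplace approximation; adaptive Gauss–Hermite via `nAGQ`). Ordered-class
models are deliberately out of scope: with class frequencies as skewed as
these (species-level success around 80 %, `none` a few percent), ordinal
fits are fragile, and the binary outcome carries the substance. Species
with fewer than three observations are excluded (too little information to
separate the random intercept from noise).

Inference is Wald-based throughout:

* `type3_wald()` tests each factor's full treatment-coded coefficient block
  $b$ with $\chi^2 = b^\top V^{-1} b$, df = block size. With no
  interactions this equals the classical type-III construction; treatment
  coding with alphabetical reference levels is recorded in the fit object.
* `estimated_marginal_means()` averages the linear predictor over the other
  factors' levels with equal weights, at random effect zero, with
  delta-method standard errors — the standard reference-grid construction,
  implemented directly on the model matrix (and cross-checked against the
  emmeans package in the tests).
* Pairwise contrasts are z-tests on the logit scale with **Holm**
  adjustment. Holm was chosen over the more common Tukey because it is
  exact for any correlation structure, implementation-independent and
  conservative; users comparing letters against Tukey-based displays should
  expect slightly fewer separations.
* `compact_letter_display()` encodes the contrasts by insert-and-absorb:
  start from one all-levels group; each significant pair splits every group
  containing both; absorbed subsets are removed. Levels sharing a letter do
  not differ significantly, levels differing significantly never share one;
  the assignment is deterministic given level order.

## Training-image association

`species_success()` gives per-species success proportions (unweighted by
observation count — the species, not the photograph, is the analysis unit);
`training_correlation()` correlates them with `ln`(training images)
(Pearson, two-sided t). `group_training_comparison()` models `ln`(training
images) on a grouping trait (one-way linear model, type-III F — identical
to the classical one-way F with a single factor), with Holm-adjusted
pairwise contrasts and letters. Species with no training images are
excluded from the log-scale analyses; groups with one species are dropped.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analyses
assume, not the images themselves:

* a species pool spread over families (genera nested in families, at least
  two genera per family where size allows), with categorical growth-form /
  life-form / habitat traits;
* regional frequency (integer 1–540, truncated normal, mean 270, SD 120)
  and training-image count (log-normal, meanlog 5, sdlog 1) coupled by a
  latent Gaussian copula so `ln`(training) and frequency correlate at a
  configured value (default 0.35, positive as in real training corpora);
  the truncated-normal frequency marginal was chosen so the latent
  correlation carries through essentially unattenuated;
* per species a uniform number of replicates per setting — 1–16 in the
  database setting, 1–5 in the field, matching the replicate spread of a
  realistic two-setting study;
* a sequential (continuation-ratio) outcome model: species-level success is
  Bernoulli with logit = baseline + effect(ln training) + organ effect +
  focus penalty + background effect + species intercept
  $u_s \sim N(0, \sigma^2)$; on failure the suggestion keeps the right
  genus with probability 0.5, else the right family with probability 0.55,
  else nothing. The defaults (baseline −0.4, training effect 0.35 per log
  unit, reproductive-organ bonus 0.4, multiple-species penalty −0.6, no
  background effect, $\sigma = 1$) give roughly 80 % species-level success,
  90 % correct to genus and 95 % to family — the regime a well-trained
  identification tool operates in. A sequential model was chosen because
  the classes are nested first-suggestion outcomes; it is the simplest
  structure every downstream stage can consume.

Suggested names are written so the classifier reproduces the drawn class
exactly: the verified name on success, a same-genus decoy for genus-level
outcomes, a cross-genus same-family decoy for family-level outcomes (decoys
are registered in the generated taxonomy), and an empty suggestion for
`none`. Ground truth (config echo, species intercepts, realized class
counts) is returned for parameter-recovery tests.

What the generator does **not** emulate: image content and quality,
spatial/temporal structure, correlation between annotations and species
traits (a fern is as likely to be photographed flowering as an orchid),
setting-specific covariate shifts, or real nomenclatural messiness beyond
synonym/infraspecific handling. Passing tests therefore demonstrate that
the *statistical machinery* is correct and calibrated, not that any
particular real-world accuracy figure is reproduced.

## Reproducibility and numerical choices

All randomness derives from one master seed through named substreams (a
31-bit hash of a stage label folded into the seed), so adding or reordering
stages never shifts another stage's draws, and `run_pipeline()` produces
byte-identical CSV bundles under a fixed config and seed. Monte-Carlo P
values use the add-one estimator (never exactly zero); ties in exceedance
and null-median comparisons are resolved by strict inequality, with tie
mass reported where it matters. Degenerate inputs are defined, not fatal:
forced tables give $z = 0$ and no flag, empty classes give `NA`, an
all-zero table gives Fisher P 1.

## Problem sizes

The test suite exercises the machinery at sizes chosen to give tight Monte
Carlo error at interactive runtimes: sampler distribution checks at
$10^5$ draws; Fisher Monte-Carlo-versus-enumeration equivalence over every
2×3 table with total ≤ 12 at $B = 10^4$; randomization calibration over 500
independence datasets; mixed-model recovery at 150 species × 8 observations
over 20 seeds and null calibration over 200 refits; pipeline determinism on
a 300-species study. The acceptance script runs the full pipeline on a
simulated 300-species, two-setting study at the default 1000 iterations.

## Worked example

```{r example, eval = FALSE}
cfg <- validate_config(list(
  simulate = list(n_species = 300, seed = 1),
  n_iterations = 1000, output_dir = "florastat_run"))
run <- run_pipeline(cfg)
print(run)
print(run$grouped$family)
print(run$emmeans$organs)
```

## Known limitations

* Exact Fisher enumeration is only attempted under a cheap composition
  bound; moderately large tables always take the Monte-Carlo path even if
  their feasible set happens to be small.
* The cell-randomization screen assumes the normal approximation for
  $\Phi(z)$; for cells with expected counts below ~5 the flags are
  conservative and discrete.
* Wald inference (type III, EMM contrasts) is asymptotic; no profile or
  bootstrap intervals are provided.
* The exceedance proportion of the paired comparison is a descriptive
  resampling statistic, not a calibrated hypothesis test; its null
  distribution is not uniform when tie mass is large (rare classes, few
  species).
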