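# mvtrial

Monte Carlo power analysis of univariate and multivariate tests for
small-sample, multi-endpoint preclinical trials.

Preclinical efficacy studies — a vehicle control plus a few dose groups —
usually measure several correlated endpoints repeatedly over time on very
few animals. `mvtrial` helps biostatisticians and preclinical researchers
decide *how to analyse* such trials (and how large they must be) by
simulation:

* **Trial simulation.** Correlated multivariate normal, lognormal (closed-form
  log-scale moment matching) and gamma (Gaussian copula) data for a control
  and k dose groups, with treatment means placed by Cohen's d
  (μ₁ = μ₀ ± s·d, s the average SD under variance heterogeneity) and
  treatment variances inflated by a ratio v ∈ {1, 2, 5}. Population
  parameters (μ, σ², R) come from a built-in generator, from bootstrapping a
  pilot dataset (whole-subject resampling, B = 10,000, nearest-PD repair),
  or from CSV.
* **Test battery.** Per-variable one-way ANOVA and Welch's ANOVA; per-endpoint
  linear mixed effects omnibus tests (`value ~ group + time + (1 | subject)`);
  ANOVA on Kaiser-retained principal component scores of the population
  correlation matrix; and per-endpoint MANOVA evaluated with Wilks' Λ,
  Pillai's trace, the Lawley–Hotelling trace and Roy's largest root
  (conventional upper-bound F, reproducing its notorious anticonservatism).
* **Empirical error rates.** Type I error and power as *pooled rejection
  rates* — significant tests / all tests, pooled over variables and
  replicates at α = 0.05 — over a 252-cell factorial grid (7 sample sizes ×
  4 effect sizes × 3 distributions × 3 variance ratios), with per-replicate
  seeding and resumable streaming output.
* **Ordination pattern analysis.** 2-D PCA / LDA / RDA / PLS-DA score plots
  with 95% confidence ellipses per group; a treatment-effect *pattern* is
  detected when the control ellipse is disjoint from every dose-group
  ellipse. False-pattern and sensitivity rate studies quantify which
  ordinations can be trusted at n = 5 per group.

Everything is tidyverse-shaped: functions take and return tibbles,
ordinations have `tidy()` / `glance()` / `autoplot()` methods, and results
tables pipe straight into dplyr/ggplot2.

## Worked example

Simulate one scenario — n = 20 per group, large effects (d = 0.8),
multivariate normal, equal variance — 200 times and compare the battery:

```r
library(mvtrial)

pop <- default_population()     # 6 endpoints x 3 days, correlated
r <- run_scenario(scenario_spec(20, 0.8), pop,
                  methods = c("anova", "welch", "lmm", "pca_anova", "manova_wilks"),
                  n_reps = 200, base_seed = 1)
r[, c("method", "n_significant", "n_tests", "rate", "mc_se")]
#> # A tibble: 5 × 5
#>   method       n_significant n_tests  rate   mc_se
#>   <chr>                <int>   <int> <dbl>   <dbl>
#> 1 anova                 2543    3600 0.706 0.00759
#> 2 welch                 2461    3600 0.684 0.00775
#> 3 lmm                    997    1200 0.831 0.0108
#> 4 pca_anova              231    1200 0.192 0.0114
#> 5 manova_wilks           760    1200 0.633 0.0139
```

Each rate pools significant tests over 200 replicates (18 per-variable tests
or 6 per-endpoint tests each). The mixed model, which uses the repeated
measures, is the only method near the conventional 80% power mark at this
sample size; ANOVA on PC scores trails far behind; Welch matches plain ANOVA
under equal variances, as it should.

The two-stage "ordination first, then targeted testing" workflow on a tiny
trial (n = 5 per group) with huge effects (d = 2) on 9 of the 18 variables:

```r
ex <- demo_practical_example(seed = 42)
ex
#> <practical_example> PLS-DA + mixed-model post-hoc walkthrough (seed 42 )
#>   axis 1 explains 45% of the variance
#>   variables with simulated effects (9):
#>     edema_volume.day1, lesion_volume.day14, limb_placing.day1, limb_placing.day7,
#>     neuroscore.day1, neuroscore.day7, t2_lesion_contra.day1, t2_lesion_contra.day7,
#>     t2_lesion.day7
#>   flagged by PLS-DA axis-1 |r| >= 0.50: 12 variables (9 of 9 true effects)
#>   post-hoc contrasts with p < 0.05: 26 of 54
```

PLS-DA's axis-1 correlation filter (|r| < 0.5 zeroed) recovers all nine
effect-bearing variables (plus three false flags); the mixed-model post-hoc
contrasts (18 variables × 3 dose-vs-control comparisons) confirm a subset.
`autoplot(ex$ordination)` draws the score plot with group ellipses, and
`ordination_study(pop)` reproduces the full false-pattern/sensitivity
comparison across PCA, LDA, RDA and PLS-DA.

## Documentation

The methods vignette (`vignettes/mvtrial-methods.Rmd`) documents the
population model, the effect-placement and copula constructions, the exact
balanced-design shortcut behind the fast mixed-model engine, the MANOVA
F approximations, the ellipse conventions, and the package's known
limitations.
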