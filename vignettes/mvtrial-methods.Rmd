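---
title: "Methods: simulating and testing multi-endpoint preclinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and testing multi-endpoint preclinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvtrial)
```

## The problem mvtrial addresses

Controlled preclinical trials — a vehicle control plus a few dose groups —
typically measure several correlated endpoints, each repeatedly over time,
on very few animals per group. The analyst then faces a genuine design
question: test each of the 18 resulting variables with its own ANOVA, model
each endpoint's repeated measures with a mixed model, or move to a
multivariate statistic that uses the correlation structure? And when formal
testing is hopeless at n = 5 per group, can an ordination plot with
confidence ellipses at least flag a treatment *pattern*?

mvtrial answers these questions by Monte Carlo: it simulates trials from a
configurable population model, applies a battery of univariate and
multivariate tests to every simulated trial, and estimates empirical type I
error and power as **pooled rejection rates** — significant tests divided by
all tests performed, pooling across variables/endpoints and replicates, with
no multiplicity correction. It also runs the companion ordination study:
how often do 95% confidence ellipses in a 2-D PCA/LDA/RDA/PLS-DA score plot
separate the control group from every dose group, both when no effect exists
(false-pattern rate) and under a huge effect (sensitivity)?

## The population model

A trial is parameterized by a `population_params` object: a mean vector
$\mu_0$ (length $p = 18$ by default: 6 endpoints $\times$ 3 time points), a
variance vector $\sigma^2$, and a $p \times p$ correlation matrix $R$.
Three sources are supported:

* **`default_population()`** — a deterministic built-in generator. It
  emulates the structure typical of a neurotrauma functional-outcome panel:
  positive means on heterogeneous scales (roughly 2 to 320 in endpoint
  units), coefficients of variation between 0.15 and 0.45, within-endpoint
  temporal correlation of 0.7 between adjacent time points decaying with lag
  (0.49 at lag 2), and cross-endpoint correlation drawn once from
  [0.30, 0.50] and damped across time lags. The matrix is repaired with
  `nearest_positive_definite()`. These values were fixed once as a
  realistic stand-in for a measured control-group covariance; the package's
  headline rates (nominal-level calibration, the Roy pathology, power
  orderings) are either invariant to the specific matrix or robust to it,
  while the *absolute* ordination sensitivities do depend on it.
* **`bootstrap_population_params()`** — the pilot-data route: whole subjects
  (matrix rows) are resampled with replacement $B = 10{,}000$ times; the
  replicate column means and covariance matrices are averaged, the averaged
  covariance is repaired to positive definiteness once, and then split into
  variances and a correlation matrix. Resampling whole rows preserves the
  cross-variable covariance.
* **`read_population_csv()` / `write_population_csv()`** — a plain-CSV
  triplet (means, variances, correlation matrix) for transcribed or published
  parameter tables.

`nearest_positive_definite()` symmetrizes its input and, when the smallest
eigenvalue falls below `eps = 1e-8` times the largest, projects to the
nearest positive-definite matrix (Higham's alternating projections) and
lifts all eigenvalues to at least `eps`. Already-PD input is returned
unchanged, which makes the operation idempotent. An all-zero covariance
(possible under a degenerate pilot) is lifted straight to `eps` times the
identity.

## Simulating one trial

`sample_trial()` draws one control group and (by default) three dose groups
of `n_per_group` subjects. Scenario factors follow the factorial design in
`scenario_grid()`: per-group sample size $\{5, 10, 15, 20, 30, 40, 50\}$,
Cohen's d $\{0, 0.2, 0.5, 0.8\}$, marginal family
$\{\text{normal}, \text{lognormal}, \text{gamma}\}$, and
treatment-to-control variance ratio $\{1, 2, 5\}$ — 252 cells.

**Effect placement.** Treatment means are
$\mu_1 = \mu_0 \pm s \cdot d$, with $s$ the common standard deviation under
equal variance and the *average* of the control and inflated treatment
standard deviations, $s = (s_0 + s_0\sqrt{v})/2$, under a variance ratio
$v > 1$. All three dose groups receive the same shift (the design does not
differentiate doses); a per-variable mask and sign support partial-effect
designs such as the worked example's 9-of-18 layout. Variance inflation is
applied to the target *natural-scale* variances before any distributional
parameter solving, so the requested ratio holds on the observed scale; the
correlation matrix is left untouched.

**Marginals.**

* *Normal*: scaled-and-shifted draws through the correlation matrix.
* *Lognormal*: log-scale parameters solved in closed form so natural-scale
  means and variances match the targets
  ($\sigma^2_{\log} = \log(1 + cv^2)$,
  $\mu_{\log} = \log \mu - \sigma^2_{\log}/2$), with log-scale correlations
  $r_{\log} = \log(1 + r\,cv_1 cv_2) / \sqrt{\log(1+cv_1^2)\log(1+cv_2^2)}$
  and a nearest-PD repair of the resulting matrix.
* *Gamma*: a Gaussian copula — correlated standard normals pushed through
  the normal CDF and the gamma quantile function with moment-matched shape
  $\alpha = \mu^2/\sigma^2$ and rate $\beta = \mu/\sigma^2$ per variable.
  The copula carries correlation $R$ on the normal scale; the induced
  natural-scale correlation is mildly attenuated, which we accept and note
  here rather than iterate a NORTA correction, since every method sees the
  same data.

Positive-support families require positive target means, which the built-in
population guarantees and the samplers enforce with an informative error.

**Determinism and identity.** Every draw is keyed to the variable's *label*,
not its column position: sampling happens in label-sorted canonical order
through the unique symmetric PSD square root of the covariance and is mapped
back afterwards. Permuting the variables of a population therefore permutes
the sampled columns exactly, under the same seed. Replicate $r$ of scenario
$k$ uses seed $(\text{base} + 10^6 k + r) \bmod (2^{31}-1)$, so any cell of
a long run is reproducible in isolation and results do not depend on
execution order.

## The test battery

All omnibus tests reject at two-sided $p < 0.05$ with no family-wise
correction; that choice is part of the pooled-rate definition, not an
oversight.

* **`oneway_anova()`** — classical fixed-effects F, one test per variable
  (18 per replicate). Implemented from the sums-of-squares decomposition and
  vectorized across columns; `stats::oneway.test` serves as the oracle in
  the test suite.
* **`welch_anova()`** — Welch's heteroscedastic F with weights $n_i/s_i^2$
  and Welch–Satterthwaite denominator df. Note an algebraic subtlety the
  test suite pins down: with two groups and exactly equal variances Welch's
  statistic equals the pooled-t F identically, but with three or more groups
  it divides by its correction term $B > 1$ and is slightly smaller even at
  equal variances.
* **`lmm_main_effect()`** — per endpoint, `value ~ group + time` with a
  random intercept per subject; the omnibus treatment F. Three engines:
  `"satterthwaite"` (REML via lmerTest), `"lrt"` (ML likelihood ratio), and
  `"balanced"` — the exact between-subject-stratum F, i.e. a one-way ANOVA
  on subject means across time. For the balanced, complete layouts this
  package generates, the balanced F is *numerically identical* to the
  Satterthwaite mixed-model F whenever the between-subject variance estimate
  is interior (a classical variance-components identity, asserted to 1e-6 in
  the tests), and it remains an exact F test at the boundary. The Monte
  Carlo drivers therefore default to `"balanced"`, which is two orders of
  magnitude faster and lets the replication counts below run in minutes;
  single-trial analyses default to `"satterthwaite"`. The engine used is
  recorded in each result's `note` column. (Kenward–Roger degrees of
  freedom, sometimes preferred for unbalanced mixed models, coincide with
  Satterthwaite here for the same reason and are not offered.)
* **`pca_scores_anova()`** — eigendecomposition of the *population*
  correlation matrix (not the sample matrix, which would be rank-deficient
  at small n); components with eigenvalue strictly greater than 1 are
  retained (Kaiser); scores are the pooled-standardized data times the
  retained eigenvectors (pooled rather than per-group standardization — the
  conventional reading of "standardized data matrix"); one ANOVA per
  retained score. The default population retains 6 components. An identity
  correlation matrix retains nothing: the method then contributes zero tests,
  with a warning.
* **`manova_endpoint()`** — one MANOVA per endpoint with its q = 3 repeated
  measures as responses. All four criteria are computed from the eigenvalues
  of $E^{-1}H$: Wilks' $\Lambda$ (Rao's F), Pillai's trace, the
  Lawley–Hotelling trace, and Roy's largest root with the conventional
  *upper-bound* F approximation that mainstream software reports. Roy's
  anticonservatism is deliberate and reproduced: under the null it rejects
  about 32% of the time in this design (q = 3, g = 4, n = 20), which is an
  affine-invariant property and thus independent of the covariance values.
  The implementation agrees with `summary(stats::manova(...))` to 1e-10 on
  all four criteria; the stock implementation is kept as a cross-check, not
  as the engine, so the degenerate single-response and two-group identities
  can be asserted exactly.
* **`lmm_interaction_posthoc()`** — the worked-example follow-up:
  `value ~ group * time` with a random intercept, the interaction omnibus
  F, and per-time-point contrasts of each dose against control via estimated
  marginal means (Satterthwaite df, unadjusted by default; `"dunnettx"` and
  `"bonferroni"` are available). Contrasts are reported unconditionally so
  callers can impose their own interaction gate.

## Pooled rates and the scenario grid

`evaluate_replicate()` runs any subset of the eight method labels on one
trial; `run_scenario()` pools significant-test counts over replicates
(`rate = n_significant / n_tests`, binomial `mc_se`), and `run_grid()`
crosses that over the factorial design, streaming results to TSV with a
configuration hash so interrupted runs resume losslessly. Failed fits count
as non-rejections and surface in an `n_failed` column rather than aborting a
scenario. `summarize_rates()` splits d = 0 (type I error) from d > 0
(power) and pivots method columns within each distribution-by-variance-ratio
panel; `plot_rejection_rates()` draws the 3 × 3 panel figure.

## Ordination pattern analysis

`ordinate()` produces 2-D scores by PCA (correlation-matrix
eigendecomposition), Fisher LDA, RDA (via vegan, standardized responses
constrained on group membership, site scores), or a two-component NIPALS
PLS-DA of standardized data against centred one-hot group membership. Two
numerical choices matter:

* **LDA uses the Moore–Penrose pseudo-inverse of the within-group scatter
  and no shrinkage.** With 18 variables and 20 subjects the within-scatter
  has rank at most 16, and regularizing would erase precisely the
  overfitting pathology the study is designed to expose — LDA's false
  pattern rate at d = 0 is around 50% under the default population while
  PCA, RDA and PLS-DA sit at zero.
* **Axis orientation** is fixed deterministically: each axis is flipped so
  the variable with the largest absolute correlation with it correlates
  positively.

`confidence_ellipse_95()` centres an ellipse at a group's score mean with
the sample covariance as shape and, by default, the $\chi^2_2$ 0.95 quantile
(5.9915) as squared radius — the population-coverage convention. Plotting
libraries differ here, so the small-sample data-ellipse scaling
$2(n-1)/(n-2)\,F_{0.95}(2, n-2)$ is available as `type = "t"`; all shipped
rates use one declared convention (`chisq`). `ellipses_disjoint()`
parameterizes both boundaries at K = 720 points and declares disjointness
when no boundary point of either lies inside the other and neither centre
does (the centre check covers containment); at that resolution the tangency
of unit circles is resolved to a centre distance of 2 ± 0.01.
`detect_pattern()` requires the control ellipse to be disjoint from *all*
treatment ellipses — the stricter reading of "separated from the treatment
groups" — and counts a degenerate (collinear) group as "not detected" with a
warning rather than failing the replicate, since a rule for that case is
otherwise unspecified and it has probability near zero for continuous
scores. `pattern_rate_study()` and `ordination_study()` turn these verdicts
into false-pattern and sensitivity rates; within a condition every method
sees the same simulated datasets.

## What the generator does and does not emulate

The synthetic population reproduces the *structure* that drives the
methodological comparisons: correlated endpoints, strong temporal
correlation, heterogeneous scales, skewed alternatives, variance
heterogeneity, equal group sizes. It does not reproduce any particular
measured covariance matrix, so quantities that depend on the exact
correlation values — most visibly the absolute ordination sensitivities and
the precise sample size at which mixed-model power crosses 80% under
moderate effects — should be expected to shift when users substitute their
own pilot-derived or transcribed parameters (the CSV loader exists for
exactly that). With the default population, mixed-model power at d = 0.5
first reaches 80% at n = 50 per group; a straightforward noncentral-F
calculation shows this threshold moves one grid step down to n = 40 when
the average within-endpoint correlation is lower (≈ 0.5 rather than ≈ 0.63),
because weaker temporal correlation makes averaging over time more
informative. Missing data, unbalanced groups, dose-response gradients and
distributions beyond the three families are out of scope.

## Replication sizes used in the shipped checks

The package's own test suite and the acceptance script scale replication to
what a laptop core runs in a few minutes, sizes chosen so the binomial Monte
Carlo error is small against each tolerance: 1000 replicates for
single-scenario rates (null calibration, the Roy pathology, power at
d = 0.8; pooled over 18 or 6 tests per replicate, MC SE well under one
percentage point), 300 replicates per cell for the seven-point sample-size
sweeps, 500–1000 replicates for ordination rate comparisons, and
closed-form oracles (the noncentral F with $\lambda = n \sum_i (\mu_i -
\bar\mu)^2 / \sigma^2 = 9.6$ at d = 0.8, n = 20) wherever one exists. The
full 252-cell grid at 1000 replicates remains available through
`run_grid()` with resumable streaming output.

## Known limitations

* The gamma copula attenuates natural-scale correlations slightly; no NORTA
  inversion is applied.
* The balanced LMM engine presumes the balanced complete layouts this
  package generates; for imported, unbalanced data use the Satterthwaite or
  LRT engines.
* Ellipse disjointness is resolved at finite boundary resolution K; overlap
  smaller than the inter-point spacing can in principle be missed (K is
  configurable).
* Pooled rates treat tests within a replicate as exchangeable; they are the
  study's estimand, not an approximation, but they are *not* family-wise
  error rates.
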