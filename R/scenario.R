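#' Construct a single simulation scenario
#'
#' One cell of the factorial design: per-group sample size, standardized
#' effect size (Cohen's d), marginal distribution family and
#' treatment-to-control variance ratio.
#'
#' @param n_per_group Subjects per group (>= 3).
#' @param cohens_d Standardized mean difference applied to treatment groups
#'   (>= 0; 0 simulates the null).
#' @param distribution One of `"normal"`, `"lognormal"`, `"gamma"`.
#' @param variance_ratio Treatment-group variance divided by control-group
#'   variance (>= 1).
#' @param n_treatment_groups Number of dose groups in addition to control.
#' @return A one-row tibble with the scenario factors.
#' @export
scenario_spec <- function(n_per_group, cohens_d = 0, distribution = "normal",
                          variance_ratio = 1, n_treatment_groups = 3) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 3) stop("n_per_group must be >= 3")
  if (cohens_d < 0) stop("cohens_d must be >= 0")
  distribution <- match.arg(distribution, c("normal", "lognormal", "gamma"))
  if (variance_ratio < 1) stop("variance_ratio must be >= 1")
  if (n_treatment_groups < 1) stop("n_treatment_groups must be >= 1")
  tibble::tibble(n_per_group = n_per_group, cohens_d = cohens_d,
                 distribution = distribution, variance_ratio = variance_ratio,
                 n_treatment_groups = as.integer(n_treatment_groups))
}

#' Build the factorial scenario grid
#'
#' Full Cartesian product of the factor levels in deterministic order: sample
#' size varies slowest, then effect size, then distribution, with the variance
#' ratio fastest. The default levels reproduce the 7 x 4 x 3 x 3 = 252-cell
#' design.
#'
#' @param n_per_group,cohens_d,distribution,variance_ratio Factor levels.
#' @param n_treatment_groups Number of dose groups (constant over the grid).
#' @return A tibble with one row per scenario and a `scenario_id` column.
#' @export
scenario_grid <- function(n_per_group = c(5, 10, 15, 20, 30, 40, 50),
                          cohens_d = c(0, 0.2, 0.5, 0.8),
                          distribution = c("normal", "lognormal", "gamma"),
                          variance_ratio = c(1, 2, 5),
                          n_treatment_groups = 3) {
  for (f in list(n_per_group, cohens_d, distribution, variance_ratio)) {
    if (length(f) == 0) stop("every factor needs at least one level")
  }
  distribution <- match.arg(distribution, c("normal", "lognormal", "gamma"),
                            several.ok = TRUE)
  grid <- tidyr::expand_grid(
    n_per_group = as.integer(n_per_group),
    cohens_d = cohens_d,
    distribution = distribution,
    variance_ratio = variance_ratio)
  grid$n_treatment_groups <- as.integer(n_treatment_groups)
  dplyr::bind_cols(tibble::tibble(scenario_id = seq_len(nrow(grid))), grid)
}
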