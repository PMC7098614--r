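#' Monte Carlo rate of ellipse-based pattern detection
#'
#' Repeats sample-trial / ordinate / detect-pattern `n_reps` times and returns
#' the fraction of replicates in which the control-group ellipse was disjoint
#' from all treatment-group ellipses. With `cohens_d = 0` in the scenario this
#' is the false-pattern rate of the ordination method; with `cohens_d > 0` it
#' is its sensitivity (true-pattern rate). Replicate-level errors (e.g.
#' degenerate ellipses) are counted as "not detected" and tallied, never
#' fatal.
#'
#' @inheritParams sample_trial
#' @param method Ordination method, see [ordinate()].
#' @param n_reps Number of replicate trials.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param ellipse_type Ellipse convention, see [confidence_ellipse_95()].
#' @return One-row tibble: scenario factors, `method`, `n_reps`, `n_detected`,
#'   `rate`, `n_failed`.
#' @export
pattern_rate_study <- function(scenario, params, method, n_reps = 1000,
                               seed = 1, ellipse_type = "chisq") {
  stopifnot(n_reps >= 1)
  n_detected <- 0L
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      trial <- sample_trial(scenario, params, seed = .rep_seed(seed, 0L, r))
      ord <- ordinate(trial, method)
      suppressWarnings(detect_pattern(ord, type = ellipse_type))$detected
    }, error = function(e) NA)
    if (is.na(res)) n_failed <- n_failed + 1L
    else if (res) n_detected <- n_detected + 1L
  }
  sc <- as.list(scenario)
  tibble::tibble(method = method, n_per_group = as.integer(sc$n_per_group),
                 cohens_d = sc$cohens_d, distribution = sc$distribution,
                 variance_ratio = sc$variance_ratio, n_reps = as.integer(n_reps),
                 n_detected = n_detected, rate = n_detected / n_reps,
                 n_failed = n_failed)
}

#' Null and sensitivity study of ordination pattern detection
#'
#' For each requested ordination method, estimates the false-pattern rate
#' (`cohens_d = 0`) and the true-pattern sensitivity (default `cohens_d = 2`)
#' from `n_reps` simulated trials per condition, applying every method to the
#' *same* simulated datasets within a condition.
#'
#' @param params A [population_params] object.
#' @param methods Ordination methods to compare.
#' @param n_per_group Subjects per group (default 5).
#' @param cohens_d Effect sizes for the study conditions (default `c(0, 2)`).
#' @param n_reps Replicates per condition.
#' @param base_seed Integer seed.
#' @param ellipse_type Ellipse convention.
#' @return Tibble with one row per method x condition (rate table).
#' @export
ordination_study <- function(params, methods = c("pca", "lda", "rda", "plsda"),
                             n_per_group = 5, cohens_d = c(0, 2),
                             n_reps = 1000, base_seed = 1,
                             ellipse_type = "chisq") {
  out <- list()
  for (di in seq_along(cohens_d)) {
    d <- cohens_d[di]
    sc <- scenario_spec(n_per_group, cohens_d = d)
    counts <- setNames(integer(length(methods)), methods)
    fails <- setNames(integer(length(methods)), methods)
    for (r in seq_len(n_reps)) {
      trial <- sample_trial(sc, params, seed = .rep_seed(base_seed, di, r))
      for (m in methods) {
        res <- tryCatch(
          suppressWarnings(detect_pattern(ordinate(trial, m),
                                          type = ellipse_type))$detected,
          error = function(e) NA)
        if (is.na(res)) fails[m] <- fails[m] + 1L
        else if (res) counts[m] <- counts[m] + 1L
      }
    }
    out[[di]] <- tibble::tibble(method = methods, cohens_d = d,
                                n_per_group = as.integer(n_per_group),
                                n_reps = as.integer(n_reps),
                                n_detected = as.integer(counts),
                                rate = counts / n_reps,
                                n_failed = as.integer(fails))
  }
  dplyr::bind_rows(out)
}
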