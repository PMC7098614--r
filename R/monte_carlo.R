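# replicate seed, kept inside 32-bit integer range so any cell of the design
# is reproducible in isolation; the base seed is spread with a multiplier so
# that nearby base seeds do not share per-replicate streams
.rep_seed <- function(base_seed, scenario_index, r) {
  as.integer((as.numeric(base_seed) * 69069 + as.numeric(scenario_index) * 1e6 +
                as.numeric(r)) %% (2^31 - 1))
}

.all_methods <- c("anova", "welch", "lmm", "pca_anova",
                  "manova_wilks", "manova_pillai", "manova_hl", "manova_roy")

.manova_method_map <- c(manova_wilks = "wilks", manova_pillai = "pillai",
                        manova_hl = "hotelling_lawley", manova_roy = "roy")

#' Apply the test battery to one simulated trial
#'
#' Runs every requested method on a trial: per-variable ANOVA and Welch's
#' ANOVA (one test per variable), a linear mixed effects treatment main-effect
#' test and a MANOVA per endpoint (one test per endpoint and criterion), and
#' ANOVA on each Kaiser-retained principal component score. A failing fit
#' yields a row with `p_value = NA` (counted downstream as non-significant)
#' rather than aborting the replicate.
#'
#' @param trial A `trial_dataset` tibble.
#' @param params The [population_params] the trial was drawn from (needed for
#'   the population correlation matrix behind the PC scores).
#' @param methods Subset of `"anova"`, `"welch"`, `"lmm"`, `"pca_anova"`,
#'   `"manova_wilks"`, `"manova_pillai"`, `"manova_hl"`, `"manova_roy"`.
#' @param lmm_engine Engine for [lmm_main_effect()]; the default `"balanced"`
#'   is the exact between-subject-stratum F (identical to the Satterthwaite
#'   mixed-model test for these balanced layouts).
#' @return Tibble of test results: `method`, `target`, `statistic`, `df1`,
#'   `df2`, `p_value`, `note`.
#' @export
evaluate_replicate <- function(trial, params, methods = .all_methods,
                               lmm_engine = "balanced") {
  stopifnot(all(methods %in% .all_methods))
  labels <- attr(trial, "labels")
  endpoints <- unique(labels$endpoint)
  out <- list()

  fail_rows <- function(method, targets, msg) {
    tibble::tibble(method = method, target = targets, statistic = NA_real_,
                   df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
                   note = paste("error:", msg))
  }
  Y <- trial_values(trial)

  if ("anova" %in% methods) {
    out$anova <- tryCatch(
      dplyr::mutate(.test_result("anova", labels$variable,
                                 .anova_cols(Y, trial$group)), note = NA_character_),
      error = function(e) fail_rows("anova", labels$variable, conditionMessage(e)))
  }
  if ("welch" %in% methods) {
    out$welch <- tryCatch(
      dplyr::mutate(.test_result("welch", labels$variable,
                                 .welch_cols(Y, trial$group)), note = NA_character_),
      error = function(e) fail_rows("welch", labels$variable, conditionMessage(e)))
  }
  if ("lmm" %in% methods) {
    if (lmm_engine == "balanced") {
      # vectorized balanced exact F: one-way ANOVA on per-endpoint subject
      # means, identical to lmm_main_effect(engine = "balanced") per endpoint
      out$lmm <- tryCatch({
        M <- vapply(endpoints, function(ep) {
          rowMeans(Y[, labels$variable[labels$endpoint == ep], drop = FALSE])
        }, numeric(nrow(Y)))
        dplyr::mutate(.test_result("lmm", endpoints,
                                   .anova_cols(M, trial$group)),
                      note = "balanced exact F")
      }, error = function(e) fail_rows("lmm", endpoints, conditionMessage(e)))
    } else {
      out$lmm <- dplyr::bind_rows(lapply(endpoints, function(ep) {
        tryCatch(lmm_main_effect(trial, ep, engine = lmm_engine),
                 error = function(e) fail_rows("lmm", ep, conditionMessage(e)))
      }))
    }
  }
  if ("pca_anova" %in% methods) {
    out$pca <- tryCatch(
      dplyr::mutate(suppressWarnings(pca_scores_anova(trial, params$R)),
                    note = NA_character_),
      error = function(e) fail_rows("pca_anova", "PC", conditionMessage(e)))
  }
  man_methods <- intersect(methods, names(.manova_method_map))
  if (length(man_methods)) {
    man <- dplyr::bind_rows(lapply(endpoints, function(ep) {
      tryCatch(manova_endpoint(trial, ep),
               error = function(e)
                 tibble::tibble(endpoint = ep,
                                criterion = unname(.manova_method_map),
                                statistic = NA_real_, f_value = NA_real_,
                                df1 = NA_real_, df2 = NA_real_, p_value = NA_real_))
    }))
    for (m in man_methods) {
      sub <- man[man$criterion == .manova_method_map[[m]], , drop = FALSE]
      out[[m]] <- tibble::tibble(method = m, target = sub$endpoint,
                                 statistic = sub$f_value, df1 = sub$df1,
                                 df2 = sub$df2, p_value = sub$p_value,
                                 note = NA_character_)
    }
  }
  dplyr::bind_rows(out)
}

#' Replicated simulation of one scenario with pooled rejection rates
#'
#' Simulates `n_reps` trials under one scenario, applies the requested test
#' battery to each, and pools significant tests across variables/endpoints
#' *and* replicates: `rate = n_significant / n_tests`, where `n_tests` counts
#' every test performed (18 per replicate for per-variable methods, 6 per
#' endpoint-level method, the Kaiser retention count for PC-score ANOVA).
#' Under `cohens_d = 0` the rate estimates empirical type I error; otherwise
#' empirical power. Failed fits count as non-rejections and are reported in
#' `n_failed`. Deterministic given `base_seed` (per-replicate seeding, so any
#' replicate is reproducible in isolation).
#'
#' @inheritParams evaluate_replicate
#' @param scenario One-row tibble from [scenario_grid()] or [scenario_spec()];
#'   an existing `scenario_id` column enters the seeding.
#' @param params A [population_params] object.
#' @param n_reps Number of replicate trials.
#' @param base_seed Integer base seed.
#' @param alpha Rejection threshold (default 0.05, two-sided omnibus p).
#' @return Tibble with one row per method: scenario factors, `method`,
#'   `n_significant`, `n_tests`, `rate`, `mc_se` (binomial standard error),
#'   `n_reps`, `n_failed`, `base_seed`.
#' @export
run_scenario <- function(scenario, params, methods = .all_methods,
                         n_reps = 1000, base_seed = 1, alpha = 0.05,
                         lmm_engine = "balanced") {
  stopifnot(n_reps >= 1)
  sc <- as.list(scenario)
  idx <- if (!is.null(sc$scenario_id)) as.integer(sc$scenario_id) else 0L
  keys <- intersect(.all_methods, methods)
  n_sig <- setNames(numeric(length(keys)), keys)
  n_tst <- n_sig
  n_fail <- n_sig
  for (r in seq_len(n_reps)) {
    trial <- sample_trial(scenario, params, seed = .rep_seed(base_seed, idx, r))
    res <- evaluate_replicate(trial, params, methods, lmm_engine = lmm_engine)
    m <- factor(res$method, levels = keys)
    n_sig <- n_sig + tabulate(m[which(res$p_value < alpha)], length(keys))
    n_tst <- n_tst + tabulate(m, length(keys))
    n_fail <- n_fail + tabulate(m[is.na(res$p_value)], length(keys))
  }
  tallies <- tibble::tibble(method = keys, n_significant = as.integer(n_sig),
                            n_tests = as.integer(n_tst),
                            n_failed = as.integer(n_fail))
  rate <- ifelse(tallies$n_tests > 0, tallies$n_significant / tallies$n_tests, NA_real_)
  dplyr::bind_cols(
    tibble::as_tibble(sc[intersect(c("scenario_id", "n_per_group", "cohens_d",
                                     "distribution", "variance_ratio"), names(sc))]),
    tibble::tibble(method = tallies$method,
                   n_significant = tallies$n_significant,
                   n_tests = tallies$n_tests,
                   rate = rate,
                   mc_se = sqrt(pmax(rate * (1 - rate), 0) / pmax(tallies$n_tests, 1)),
                   n_reps = as.integer(n_reps),
                   n_failed = tallies$n_failed,
                   base_seed = as.integer(base_seed)))
}

.grid_hash <- function(grid, methods, n_reps, base_seed) {
  rlang::hash(list(grid = as.data.frame(grid), methods = methods,
                   n_reps = n_reps, base_seed = base_seed))
}

#' Run the full factorial simulation grid
#'
#' Applies [run_scenario()] to every row of a scenario grid, optionally
#' streaming results to a TSV file after each scenario so long runs can be
#' resumed. The output file carries the grid configuration hash in a header
#' comment; resuming against a file produced under a different configuration
#' is refused.
#'
#' @inheritParams run_scenario
#' @param grid Scenario tibble from [scenario_grid()].
#' @param out_file Optional TSV path for incremental results.
#' @param resume If `TRUE`, scenarios already present in `out_file` are
#'   skipped and the remaining ones appended.
#' @param verbose Print per-scenario progress.
#' @return Tibble of pooled rejection rates, one row per scenario x method.
#' @export
run_grid <- function(params, grid = scenario_grid(), methods = .all_methods,
                     n_reps = 1000, base_seed = 1, alpha = 0.05,
                     lmm_engine = "balanced", out_file = NULL, resume = FALSE,
                     verbose = FALSE) {
  hash <- .grid_hash(grid, methods, n_reps, base_seed)
  done <- integer()
  prev <- NULL
  if (!is.null(out_file) && file.exists(out_file) && resume) {
    hdr <- readLines(out_file, n = 1)
    file_hash <- sub("^# grid_hash: ", "", hdr)
    if (!startsWith(hdr, "# grid_hash: ") || file_hash != hash)
      stop("resume file was produced under a different configuration; refusing")
    prev <- readr::read_tsv(out_file, comment = "#", show_col_types = FALSE)
    if (nrow(prev) > 0) done <- unique(prev$scenario_id) else prev <- NULL
  } else if (!is.null(out_file)) {
    writeLines(paste0("# grid_hash: ", hash), out_file)
  }

  rows_written <- length(done) > 0
  out <- if (!is.null(prev)) list(prev) else list()
  for (i in seq_len(nrow(grid))) {
    scn <- grid[i, ]
    if (scn$scenario_id %in% done) next
    t0 <- Sys.time()
    res <- run_scenario(scn, params, methods, n_reps = n_reps,
                        base_seed = base_seed, alpha = alpha,
                        lmm_engine = lmm_engine)
    out[[length(out) + 1]] <- res
    if (!is.null(out_file)) {
      readr::write_tsv(res, out_file, append = TRUE, col_names = !rows_written)
      rows_written <- TRUE
    }
    if (verbose)
      message(sprintf("scenario %d/%d (n=%d d=%.1f %s vr=%g) %.1fs",
                      scn$scenario_id, nrow(grid), scn$n_per_group,
                      scn$cohens_d, scn$distribution, scn$variance_ratio,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$scenario_id)
}

#' Pivot simulation results into type-I-error and power tables
#'
#' Splits pooled rejection rates into an empirical type I error table
#' (`cohens_d = 0`) and an empirical power table (`cohens_d > 0`), pivoted to
#' one column per method within each (distribution, variance ratio, effect
#' size, sample size) cell — the tabular equivalent of the usual 3 x 3 panel
#' figures.
#'
#' @param results Output of [run_grid()] or [run_scenario()].
#' @return List with tibbles `type_i` and `power`.
#' @export
summarize_rates <- function(results) {
  stopifnot(nrow(results) > 0)
  pivot <- function(df) {
    if (nrow(df) == 0) return(df)
    tidyr::pivot_wider(
      df[, c("distribution", "variance_ratio", "cohens_d", "n_per_group",
             "method", "rate")],
      names_from = "method", values_from = "rate")
  }
  list(type_i = pivot(results[results$cohens_d == 0, ]),
       power = pivot(results[results$cohens_d > 0, ]))
}
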