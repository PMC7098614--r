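test_that("evaluate_replicate produces the documented test counts per method", {
  pop <- test_pop()
  tr <- quick_trial(n = 8, d = 0.3, seed = 15)
  counts <- dplyr::count(evaluate_replicate(tr, pop), method)
  expect_equal(counts$n[counts$method == "anova"], 18)
  expect_equal(counts$n[counts$method == "welch"], 18)
  expect_equal(counts$n[counts$method == "lmm"], 6)
  expect_equal(counts$n[counts$method == "manova_wilks"], 6)
  expect_equal(counts$n[counts$method == "manova_roy"], 6)
  k <- length(kaiser_components(pop$R)$retained)
  expect_equal(counts$n[counts$method == "pca_anova"], k)

  # identity population correlation retains nothing
  pop_id <- block_population(rho = 0, p = 18, mu = unname(pop$mu),
                             var = unname(pop$var))
  tr_id <- sample_trial(scenario_spec(8, 0), pop_id, seed = 1)
  res <- evaluate_replicate(tr_id, pop_id, methods = "pca_anova")
  expect_equal(nrow(res), 0)

  # the vectorized lmm fast path equals the per-endpoint balanced engine
  fast <- evaluate_replicate(tr, pop, methods = "lmm", lmm_engine = "balanced")
  slow <- dplyr::bind_rows(lapply(unique(pop$labels$endpoint), function(ep)
    lmm_main_effect(tr, ep, engine = "balanced")))
  expect_equal(fast$p_value[match(slow$target, fast$target)], slow$p_value,
               tolerance = 1e-12)
})

test_that("run_scenario pools counts, is bitwise reproducible, and satisfies the rate identity", {
  pop <- test_pop()
  sc <- scenario_spec(10, 0.8)
  r1 <- run_scenario(sc, pop, methods = c("anova", "lmm"), n_reps = 20, base_seed = 5)
  r2 <- run_scenario(sc, pop, methods = c("anova", "lmm"), n_reps = 20, base_seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$rate, r1$n_significant / r1$n_tests)
  expect_equal(r1$n_tests, c(20L * 18L, 20L * 6L))

  # pooled rate equals the mean of per-replicate rates (constant tests/replicate)
  per_rep <- vapply(1:20, function(r) {
    tr <- sample_trial(sc, pop, seed = mvtrial:::.rep_seed(5, 0, r))
    res <- evaluate_replicate(tr, pop, methods = "anova")
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_equal(mean(per_rep), r1$rate[r1$method == "anova"], tolerance = 1e-12)

  # saturation under an absurd effect
  sat <- run_scenario(scenario_spec(10, 10), pop, methods = c("anova", "welch", "lmm"),
                      n_reps = 10, base_seed = 2)
  expect_true(all(sat$rate > 0.99))
})

test_that("run_grid composes run_scenario, streams to disk, and resumes losslessly", {
  pop <- test_pop()
  grid <- scenario_grid(n_per_group = c(5, 10), cohens_d = c(0, 0.8),
                        distribution = "normal", variance_ratio = 1)
  expect_equal(nrow(grid), 4)
  res <- run_grid(pop, grid, methods = c("anova", "manova_wilks"), n_reps = 5,
                  base_seed = 9)
  expect_equal(nrow(res), 8)

  # single-cell grid equals a direct run_scenario call
  direct <- run_scenario(grid[2, ], pop, methods = c("anova", "manova_wilks"),
                         n_reps = 5, base_seed = 9)
  expect_equal(as.data.frame(res[res$scenario_id == 2, ]), as.data.frame(direct))

  # interrupted run resumed -> identical table
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "partial.tsv")
  f2 <- file.path(dir, "full.tsv")
  full <- run_grid(pop, grid, methods = "anova", n_reps = 5, base_seed = 9,
                   out_file = f2)
  # simulate an interruption after the first two scenarios
  writeLines(head(readLines(f2), 1 + 1 + 2), f1)
  resumed <- run_grid(pop, grid, methods = "anova", n_reps = 5, base_seed = 9,
                      out_file = f1, resume = TRUE)
  expect_equal(as.data.frame(resumed), as.data.frame(full))
  expect_identical(readLines(f1), readLines(f2))

  # a mismatching configuration is refused on resume
  expect_error(run_grid(pop, grid, methods = "anova", n_reps = 6, base_seed = 9,
                        out_file = f1, resume = TRUE), "different configuration")
})

test_that("summarize_rates splits null from power rows without altering rates", {
  pop <- test_pop()
  grid <- scenario_grid(n_per_group = 5, cohens_d = c(0, 0.8),
                        distribution = c("normal", "gamma"), variance_ratio = c(1, 5))
  res <- run_grid(pop, grid, methods = "anova", n_reps = 3, base_seed = 4)
  tabs <- summarize_rates(res)
  expect_equal(nrow(tabs$type_i), 4) # 2 distributions x 2 variance ratios
  expect_equal(nrow(tabs$power), 4)
  joined <- dplyr::left_join(
    res, dplyr::bind_rows(tabs$type_i, tabs$power),
    by = c("distribution", "variance_ratio", "cohens_d", "n_per_group"))
  expect_equal(joined$anova, joined$rate)
  # panel count for the default grid: 3 distributions x 3 variance ratios
  expect_equal(nrow(dplyr::distinct(scenario_grid()[, c("distribution", "variance_ratio")])), 9)

  only_null <- summarize_rates(res[res$cohens_d == 0, ])
  expect_equal(nrow(only_null$power), 0)
  p <- plot_rejection_rates(res, cohens_d = 0)
  expect_s3_class(p, "ggplot")
})

test_that("failed fits are tallied as non-rejections rather than aborting the scenario", {
  pop <- block_population(p = 3, mu = c(0.4, 2, 3), var = c(1, 1, 1))
  # lognormal with a strong negative shift: some replicates error at sampling
  # level is fatal, so instead inject failure at the test level via a
  # degenerate column (zero within-group variance for welch)
  sc <- scenario_spec(5, 0)
  tr <- sample_trial(sc, pop, seed = 2)
  tr$v1 <- rep(1, nrow(tr)) # constant column
  attr(tr, "labels") <- pop$labels
  res <- evaluate_replicate(tr, pop, methods = c("anova", "welch"))
  welch_rows <- res[res$method == "welch", ]
  expect_true(all(is.na(welch_rows$p_value)))
  expect_match(welch_rows$note[1], "error")
})
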