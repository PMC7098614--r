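test_that("apply_effect implements mu1 = mu0 +/- s*d with the average-sd rule", {
  expect_equal(apply_effect(10, 2.5, 0.8, +1), 12)
  expect_equal(apply_effect(c(3, -7), c(1, 9), 0), c(3, -7)) # null identity
  expect_equal(apply_effect(0, 1, 0.5, -1), -0.5)
  # control sd 2, variance ratio 5: s = (2 + 2*sqrt(5))/2, shift = 0.5*s
  s <- effect_sd(2, 5)
  expect_equal(s, (2 + 2 * sqrt(5)) / 2)
  expect_equal(apply_effect(0, s, 0.5) - 0, (1 + sqrt(5)) / 2, tolerance = 1e-12)
  expect_error(apply_effect(1, 0, 0.5), "positive")
})

test_that("gamma_shape_rate inverts the gamma moments exactly", {
  expect_equal(gamma_shape_rate(4, 2), tibble::tibble(alpha = 8, beta = 2))
  expect_equal(gamma_shape_rate(1, 1), tibble::tibble(alpha = 1, beta = 1)) # exponential
  gp <- gamma_shape_rate(3, 0.5)
  expect_equal(gp$alpha, 18)
  expect_equal(gp$beta, 6)
  # round trip to relative error < 1e-12
  mu <- c(0.3, 7, 120); v <- c(0.01, 2, 900)
  g <- gamma_shape_rate(mu, v)
  expect_equal(g$alpha / g$beta, mu, tolerance = 1e-13)
  expect_equal(g$alpha / g$beta^2, v, tolerance = 1e-13)
  # moment check against large-sample simulation
  set.seed(1)
  x <- rgamma(1e6, shape = 18, rate = 6)
  expect_lt(abs(mean(x) - 3), 3 * sqrt(0.5 / 1e6))
  expect_lt(abs(var(x) - 0.5), 3 * sd((x - 3)^2) / sqrt(1e6))
  expect_error(gamma_shape_rate(-1, 1), "positive")
})

test_that("sample_trial injects the requested effect and variance ratio (large-sample)", {
  pop <- block_population(rho = 0.4, p = 4, mu = c(5, 8, 12, 20), var = c(1, 4, 9, 25))
  for (dist in c("normal", "lognormal", "gamma")) {
    tr <- sample_trial(scenario_spec(2e4, cohens_d = 0.8, distribution = dist,
                                     n_treatment_groups = 1), pop, seed = 7)
    X <- trial_values(tr)
    ctrl <- X[tr$group == "control", ]
    trt <- X[tr$group == "dose1", ]
    d_hat <- (colMeans(trt) - colMeans(ctrl)) / sqrt(pop$var)
    se <- sqrt(2 / 2e4) # standard error of a difference of means, d units
    expect_true(all(abs(d_hat - 0.8) < 4 * se), info = dist)
    # control moments match the population
    expect_equal(unname(colMeans(ctrl)), unname(pop$mu), tolerance = 0.03)
    expect_equal(unname(apply(ctrl, 2, var)), unname(pop$var), tolerance = 0.06)
  }
})

test_that("treatment variance inflation hits the target ratio for every distribution", {
  pop <- block_population(rho = 0.4, p = 3, mu = c(5, 9, 14), var = c(1, 4, 9))
  for (dist in c("normal", "lognormal", "gamma")) {
    tr <- sample_trial(scenario_spec(1e5, cohens_d = 0, distribution = dist,
                                     variance_ratio = 5, n_treatment_groups = 1),
                       pop, seed = 13)
    X <- trial_values(tr)
    ratio <- apply(X[tr$group == "dose1", ], 2, var) /
      apply(X[tr$group == "control", ], 2, var)
    expect_true(all(abs(ratio - 5) / 5 < 0.05), info = dist)
  }
})

test_that("lognormal and gamma margins are genuinely right-skewed", {
  pop <- block_population(rho = 0.3, p = 3, mu = c(2, 5, 9), var = c(1, 4, 16))
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  for (dist in c("lognormal", "gamma")) {
    tr <- sample_trial(scenario_spec(2e4, distribution = dist,
                                     n_treatment_groups = 1), pop, seed = 3)
    sk <- apply(trial_values(tr)[tr$group == "control", ], 2, skew)
    expect_true(all(sk > 0.2), info = dist)
  }
})

test_that("sampling is deterministic given the seed and keyed to variable identity", {
  pop <- test_pop()
  sc <- scenario_spec(8, 0.5, "gamma", 2)
  t1 <- sample_trial(sc, pop, seed = 99)
  t2 <- sample_trial(sc, pop, seed = 99)
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(trial_values(t1),
                                trial_values(sample_trial(sc, pop, seed = 100)))))

  # permuting the variables of the population permutes the sampled columns
  set.seed(42)
  perm <- sample(pop$p)
  pop_p <- population_params(pop$mu[perm], pop$var[perm], pop$R[perm, perm],
                             labels = pop$labels[perm, ])
  for (dist in c("normal", "lognormal", "gamma")) {
    a <- sample_trial(scenario_spec(5, 0.5, dist), pop, seed = 7)
    b <- sample_trial(scenario_spec(5, 0.5, dist), pop_p, seed = 7)
    for (v in pop$labels$variable) expect_equal(a[[v]], b[[v]], info = dist)
  }
})

test_that("group structure and the long view are consistent and lossless", {
  pop <- test_pop()
  tr <- quick_trial(n = 6, d = 0.2, seed = 2)
  expect_equal(as.vector(table(tr$group)), rep(6L, 4))
  expect_false(anyNA(trial_values(tr)))
  long <- trial_long(tr)
  expect_equal(nrow(long), 24 * pop$p)
  wide_back <- tidyr::pivot_wider(long[, c("subject_id", "group", "variable", "value")],
                                  names_from = "variable", values_from = "value")
  expect_equal(as.data.frame(wide_back[, names(tr)]), as.data.frame(tr),
               ignore_attr = TRUE)
})

test_that("nonpositive target means are rejected for positive-support distributions", {
  pop <- block_population(p = 3, mu = c(0.5, 2, 3), var = c(1, 1, 1))
  # a large negative effect drives the gamma/lognormal mean of v1 negative
  expect_error(sample_trial(scenario_spec(5, 3, "gamma"), pop, seed = 1,
                            effect_sign = -1),
               "positive")
  expect_error(sample_trial(scenario_spec(5, 3, "lognormal"), pop, seed = 1,
                            effect_sign = -1),
               "positive")
})

test_that("two-group comparisons have their nominal null distribution for all three distributions", {
  pop <- block_population(rho = 0.4, p = 3, mu = c(4, 7, 11), var = c(1, 2, 3))
  sc <- scenario_spec(10, 0, n_treatment_groups = 1)
  for (dist in c("normal", "lognormal", "gamma")) {
    sc$distribution <- dist
    pvals <- vapply(1:500, function(r) {
      tr <- sample_trial(sc, pop, seed = 5000 + r)
      oneway_anova(tr$v1, tr$group)$p_value
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})
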