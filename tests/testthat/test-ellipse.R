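test_that("the chi-squared 95% ellipse covers about 95% of fresh draws", {
  set.seed(50)
  P <- matrix(rnorm(2e5), ncol = 2)
  e <- confidence_ellipse_95(P)
  expect_equal(e$scale, qchisq(0.95, 2))
  fresh <- matrix(rnorm(2e5), ncol = 2)
  inside <- mvtrial:::.ellipse_maha(e, fresh) <= e$scale
  expect_lt(abs(mean(inside) - 0.95), 0.005)
})

test_that("ellipse geometry follows the covariance of the points", {
  set.seed(51)
  theta <- runif(1000, 0, 2 * pi)
  P <- cbind(2 * cos(theta), sin(theta)) # major axis along x, 2:1
  e <- confidence_ellipse_95(P)
  dec <- eigen(e$shape, symmetric = TRUE)
  expect_lt(abs(sqrt(dec$values[1] / dec$values[2]) - 2) / 2, 0.05)
  expect_gt(abs(dec$vectors[1, 1]), 0.99) # leading axis is x

  # translation equivariance
  e2 <- confidence_ellipse_95(sweep(P, 2, c(-3, 11), `+`))
  expect_equal(e2$center, e$center + c(-3, 11))
  expect_equal(e2$shape, e$shape)

  # small-sample t convention is wider than the chi-squared one
  et <- confidence_ellipse_95(P[1:10, ], type = "t")
  ec <- confidence_ellipse_95(P[1:10, ])
  expect_gt(et$scale, ec$scale)

  expect_error(confidence_ellipse_95(P[1:2, ]), "at least 3")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(confidence_ellipse_95(line), "collinear")
})

test_that("disjointness detects tangency of unit circles at centre distance 2", {
  a <- make_circle(c(0, 0))
  expect_false(ellipses_disjoint(a, a)) # identical -> overlap
  expect_true(ellipses_disjoint(a, make_circle(c(10, 0))))
  expect_false(ellipses_disjoint(a, make_circle(c(1.99, 0))))
  expect_true(ellipses_disjoint(a, make_circle(c(2.01, 0))))
  # brute-force dense-grid oracle around the tangency point
  for (dx in c(1.95, 2.05)) {
    b <- make_circle(c(dx, 0))
    grid <- as.matrix(expand.grid(x = seq(-1.2, dx + 1.2, by = 0.004),
                                  y = seq(-1.2, 1.2, by = 0.004)))
    both <- mvtrial:::.ellipse_maha(a, grid) <= a$scale &
      mvtrial:::.ellipse_maha(b, grid) <= b$scale
    expect_equal(ellipses_disjoint(a, b), !any(both))
  }
  # containment counts as overlap
  inner <- make_circle(c(0.1, 0), radius = 0.2)
  expect_false(ellipses_disjoint(a, inner))
})

test_that("detect_pattern requires the control ellipse to clear every dose group", {
  tr <- quick_trial(n = 10, d = 0, seed = 61)
  ord <- ordinate(tr, "pca")
  null_pat <- detect_pattern(ord)
  expect_false(null_pat$detected) # shared population
  expect_equal(length(null_pat$disjoint), 3)
  expect_equal(null_pat$detected, all(null_pat$disjoint)) # AND semantics

  # shift the control scores far away: pattern must be detected
  ord2 <- ord
  ctrl <- ord2$scores$group == "control"
  ord2$scores$axis1[ctrl] <- ord2$scores$axis1[ctrl] + 100
  pat2 <- detect_pattern(ord2)
  expect_true(pat2$detected)
  expect_true(all(pat2$disjoint))

  # rigid rotation of the score plane leaves the verdict unchanged
  for (ang in c(0.3, 1.2, 2.8)) {
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    for (base in list(ord, ord2)) {
      o <- base
      sc <- as.matrix(base$scores[, c("axis1", "axis2")]) %*% rot
      o$scores$axis1 <- sc[, 1]
      o$scores$axis2 <- sc[, 2]
      expect_equal(detect_pattern(o)$detected, detect_pattern(base)$detected)
    }
  }

  # a degenerate (collinear) group is counted as not-detected with a warning
  ord3 <- ord2
  d1 <- ord3$scores$group == "dose1"
  ord3$scores$axis2[d1] <- 2 * ord3$scores$axis1[d1]
  expect_warning(pat3 <- detect_pattern(ord3), "degenerate")
  expect_false(pat3$disjoint[["dose1"]])
  expect_false(pat3$detected)
})

test_that("pattern_rate_study is reproducible and near zero for PCA under the null", {
  pop <- test_pop()
  sc <- scenario_spec(5, 0)
  one <- pattern_rate_study(sc, pop, "pca", n_reps = 1, seed = 9)
  expect_true(one$rate %in% c(0, 1))
  expect_identical(one, pattern_rate_study(sc, pop, "pca", n_reps = 1, seed = 9))

  null_pca <- pattern_rate_study(sc, pop, "pca", n_reps = 200, seed = 123)
  expect_lte(null_pca$rate, 0.02)
})

test_that("tidiers expose scores, ellipses and verdicts as tibbles", {
  tr <- quick_trial(n = 5, seed = 77)
  ord <- ordinate(tr, "rda")
  expect_equal(nrow(tidy(ord)), 20)
  gl <- glance(ord)
  expect_equal(gl$method, "rda")
  expect_true(gl$explained_axis1 >= gl$explained_axis2)
  e <- make_circle(c(1, 2), radius = 3)
  path <- tidy(e, K = 90)
  expect_equal(nrow(path), 91)
  expect_equal(max(abs(sqrt((path$x - 1)^2 + (path$y - 2)^2) - 3)), 0, tolerance = 1e-9)
  pat <- tidy(suppressWarnings(detect_pattern(ord)))
  expect_equal(nrow(pat), 3)
  p <- autoplot(ord)
  expect_s3_class(p, "ggplot")
})
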