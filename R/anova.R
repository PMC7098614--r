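# Vectorized one-way fixed-effects ANOVA over the columns of Y.
# Returns a tibble with statistic, df and p per column.
.anova_cols <- function(Y, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  g <- nlevels(groups)
  N <- nrow(Y)
  if (g < 2) stop("at least 2 groups are required")
  counts <- tabulate(groups, g)
  if (any(counts < 2)) stop("every group needs at least 2 observations")
  G <- model.matrix(~ groups - 1) # N x g indicator
  gm <- crossprod(G, Y) / counts # g x p group means
  grand <- colMeans(Y)
  ss_between <- colSums(counts * sweep(gm, 2, grand)^2)
  ss_within <- colSums((Y - G %*% gm)^2)
  df1 <- g - 1
  df2 <- N - g
  if (any(ss_within <= 0))
    stop("degenerate data: zero within-group variance")
  Fstat <- unname((ss_between / df1) / (ss_within / df2))
  tibble::tibble(statistic = Fstat, df1 = df1, df2 = df2,
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE))
}

# Vectorized Welch heteroscedastic ANOVA over the columns of Y.
.welch_cols <- function(Y, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  g <- nlevels(groups)
  if (g < 2) stop("at least 2 groups are required")
  counts <- tabulate(groups, g)
  if (any(counts < 2)) stop("every group needs at least 2 observations")
  G <- model.matrix(~ groups - 1)
  gm <- crossprod(G, Y) / counts
  s2 <- crossprod(G, Y^2) / counts - gm^2
  s2 <- s2 * counts / (counts - 1) # unbiased group variances, g x p
  if (any(s2 <= 0)) stop("a group has zero variance; Welch weights are undefined")
  w <- counts / s2 # g x p weights
  sw <- colSums(w)
  mw <- colSums(w * gm) / sw # weighted grand means
  A <- colSums(w * sweep(gm, 2, mw)^2) / (g - 1)
  tmp <- colSums((1 - w / rep(sw, each = g))^2 / (counts - 1))
  B <- 1 + 2 * (g - 2) / (g^2 - 1) * tmp
  Fstat <- unname(A / B)
  df1 <- g - 1
  df2 <- unname((g^2 - 1) / (3 * tmp))
  tibble::tibble(statistic = Fstat, df1 = df1, df2 = df2,
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE))
}

.test_result <- function(method, target, tab) {
  dplyr::bind_cols(tibble::tibble(method = method, target = target), tab)
}

#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA F test: `F = MS_between / MS_within` on
#' `(g - 1, N - g)` degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param groups Group labels (coerced to factor), same length as `y`.
#' @param target Label carried into the result (the variable tested).
#' @return A one-row tibble: `method`, `target`, `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
oneway_anova <- function(y, groups, target = NA_character_) {
  .test_result("anova", target, .anova_cols(matrix(as.numeric(y), ncol = 1), groups))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch (1951) F test with group weights `n_i / s_i^2` and
#' Welch-Satterthwaite denominator degrees of freedom; does not assume equal
#' group variances.
#'
#' @inheritParams oneway_anova
#' @return A one-row tibble: `method`, `target`, `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @export
welch_anova <- function(y, groups, target = NA_character_) {
  .test_result("welch", target, .welch_cols(matrix(as.numeric(y), ncol = 1), groups))
}
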