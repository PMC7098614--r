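# Between-group (H) and within-group (E) cross-product matrices and the four
# classical MANOVA criteria with their conventional F approximations, computed
# from the eigenvalues of E^{-1} H. Matches the conventions of mainstream
# statistical software, including Roy's anticonservative upper-bound F.
.manova_stats <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  q <- ncol(Y)
  N <- nrow(Y)
  if (g < 2) stop("at least 2 groups are required")
  vh <- g - 1
  ve <- N - g
  if (ve <= q)
    stop("insufficient error degrees of freedom: need N - g > q")

  grand <- colMeans(Y)
  H <- matrix(0, q, q)
  E <- matrix(0, q, q)
  for (l in levels(groups)) {
    Yg <- Y[groups == l, , drop = FALSE]
    m <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(m - grand)
    E <- E + crossprod(sweep(Yg, 2, m))
  }
  EiH <- tryCatch(solve(E, H), error = function(e)
    stop("insufficient error degrees of freedom: error matrix is singular"))
  lam <- Re(eigen(EiH, only.values = TRUE)$values)
  lam <- sort(pmax(lam, 0), decreasing = TRUE)

  s <- min(q, vh)
  m <- (abs(q - vh) - 1) / 2
  n2 <- (ve - q - 1) / 2

  # Pillai's trace
  V <- sum(lam / (1 + lam))
  f_pillai <- ((2 * n2 + s + 1) / (2 * m + s + 1)) * V / (s - V)
  df_pillai <- c(s * (2 * m + s + 1), s * (2 * n2 + s + 1))

  # Wilks' lambda, Rao's F
  W <- prod(1 / (1 + lam))
  r <- ve - (q - vh + 1) / 2
  u <- (q * vh - 2) / 4
  tt <- if (q^2 + vh^2 - 5 > 0) sqrt((q^2 * vh^2 - 4) / (q^2 + vh^2 - 5)) else 1
  f_wilks <- (1 - W^(1 / tt)) / W^(1 / tt) * (r * tt - 2 * u) / (q * vh)
  df_wilks <- c(q * vh, r * tt - 2 * u)

  # Lawley-Hotelling trace
  TT <- sum(lam)
  f_hl <- TT * 2 * (s * n2 + 1) / (s^2 * (2 * m + s + 1))
  df_hl <- c(s * (2 * m + s + 1), 2 * (s * n2 + 1))

  # Roy's largest root, upper-bound F
  rr <- max(q, vh)
  f_roy <- lam[1] * (ve - rr + vh) / rr
  df_roy <- c(rr, ve - rr + vh)

  tibble::tibble(
    criterion = c("wilks", "pillai", "hotelling_lawley", "roy"),
    statistic = c(W, V, TT, lam[1]),
    f_value = c(f_wilks, f_pillai, f_hl, f_roy),
    df1 = c(df_wilks[1], df_pillai[1], df_hl[1], df_roy[1]),
    df2 = c(df_wilks[2], df_pillai[2], df_hl[2], df_roy[2]),
    p_value = pf(c(f_wilks, f_pillai, f_hl, f_roy),
                 c(df_wilks[1], df_pillai[1], df_hl[1], df_roy[1]),
                 c(df_wilks[2], df_pillai[2], df_hl[2], df_roy[2]),
                 lower.tail = FALSE))
}

#' Per-endpoint MANOVA with four multivariate criteria
#'
#' Treats the repeated measures of one endpoint as the dependent variables of
#' a one-way MANOVA across treatment groups and evaluates the four classical
#' criteria — Wilks' lambda, Pillai's trace, the Lawley-Hotelling trace and
#' Roy's largest root — each with the F approximation conventional in
#' mainstream statistical software. Roy's largest root deliberately uses the
#' anticonservative upper-bound F, which is what standard software reports
#' and what makes its type I error inflate under the null.
#'
#' @inheritParams lmm_main_effect
#' @return Tibble with one row per criterion: `endpoint`, `criterion`,
#'   `statistic`, `f_value`, `df1`, `df2`, `p_value`.
#' @export
manova_endpoint <- function(trial, endpoint) {
  labels <- attr(trial, "labels")
  if (is.null(labels)) stop("trial has no variable labels")
  vars <- labels$variable[labels$endpoint == endpoint]
  if (length(vars) == 0) stop("unknown endpoint: ", endpoint)
  Y <- as.matrix(trial[, vars])
  res <- .manova_stats(Y, trial$group)
  dplyr::bind_cols(tibble::tibble(endpoint = endpoint), res)
}
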