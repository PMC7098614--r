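# column standardization that tolerates zero-variance columns (mapped to 0)
.standardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  bad <- s <= 0 | !is.finite(s)
  s[bad] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, `/`)
  Xs[, bad] <- 0
  Xs
}

.safe_cor <- function(X, v) {
  out <- suppressWarnings(as.vector(cor(X, v)))
  out[!is.finite(out)] <- 0
  out
}

# two-component NIPALS partial least squares of X (standardized) on Y (centred
# one-hot group membership); returns X-scores and per-component X-variance
.nipals_pls2 <- function(X, Y, ncomp = 2, tol = 1e-10, maxit = 500) {
  ssx0 <- sum(X^2)
  scores <- matrix(0, nrow(X), ncomp)
  explained <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    p_load <- crossprod(X, tt) / sum(tt^2)
    q_load <- crossprod(Y, tt) / sum(tt^2)
    X <- X - tcrossprod(tt, p_load)
    Y <- Y - tcrossprod(tt, q_load)
    scores[, h] <- tt
    explained[h] <- sum(tt^2) * sum(p_load^2) / ssx0
  }
  list(scores = scores, explained = explained)
}

#' Two-dimensional ordination of a trial
#'
#' Projects a simulated trial onto two axes with one of four methods:
#'
#' * `"pca"` — eigendecomposition of the correlation matrix of the pooled
#'   data; unsupervised.
#' * `"lda"` — Fisher discriminant directions maximizing the between-group to
#'   within-group scatter ratio. The within-group scatter matrix is inverted
#'   with the Moore-Penrose pseudo-inverse and no shrinkage is applied, so the
#'   rank-deficient regime (more variables than error degrees of freedom)
#'   executes and deliberately exhibits its characteristic overfitting.
#' * `"rda"` — redundancy analysis of the standardized data constrained by
#'   group membership (via [vegan::rda()]); site scores on the first two
#'   constrained axes.
#' * `"plsda"` — two-component NIPALS partial least squares of the
#'   standardized data against centred one-hot group membership; X-scores.
#'
#' All methods use a deterministic sign convention: each axis is flipped so
#' that the variable with the largest absolute correlation with the axis
#' correlates positively.
#'
#' @param trial A `trial_dataset` tibble.
#' @param method One of `"pca"`, `"lda"`, `"rda"`, `"plsda"`.
#' @return An object of class `ordination2d`: list with `method`, `scores` (a
#'   tibble `subject_id`, `group`, `axis1`, `axis2`), `explained` (fraction of
#'   variance per axis) and `axis1_correlations` (named vector of Pearson
#'   correlations of each variable with axis 1).
#' @export
ordinate <- function(trial, method = c("pca", "lda", "rda", "plsda")) {
  method <- match.arg(method)
  X <- trial_values(trial)
  groups <- trial$group
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2) stop("at least 2 variables are required")
  if (n < 4 || nlevels(droplevels(as.factor(groups))) < 2)
    stop("at least 4 subjects in at least 2 groups are required")

  if (method == "pca") {
    Xs <- .standardize(X)
    e <- eigen(cor(Xs), symmetric = TRUE)
    scores <- Xs %*% e$vectors[, 1:2, drop = FALSE]
    explained <- e$values[1:2] / sum(pmax(e$values, 0))
  } else if (method == "lda") {
    grp <- droplevels(as.factor(groups))
    Xc <- sweep(X, 2, colMeans(X))
    W <- matrix(0, p, p)
    B <- matrix(0, p, p)
    for (l in levels(grp)) {
      Xg <- X[grp == l, , drop = FALSE]
      m <- colMeans(Xg) - colMeans(X)
      W <- W + crossprod(sweep(Xg, 2, colMeans(Xg)))
      B <- B + nrow(Xg) * tcrossprod(m)
    }
    e <- eigen(MASS::ginv(W) %*% B)
    ord <- order(Re(e$values), decreasing = TRUE)
    lam <- pmax(Re(e$values[ord]), 0)
    V <- Re(e$vectors[, ord[1:2], drop = FALSE])
    V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
    scores <- Xc %*% V
    explained <- if (sum(lam) > 0) lam[1:2] / sum(lam) else c(0, 0)
  } else if (method == "rda") {
    Xs <- .standardize(X)
    Ymm <- model.matrix(~ droplevels(as.factor(groups)))[, -1, drop = FALSE]
    ord <- vegan::rda(Xs, Ymm)
    sc <- vegan::scores(ord, display = "sites", choices = 1:2)
    scores <- as.matrix(sc)
    explained <- ord$CCA$eig[1:2] / ord$tot.chi
  } else {
    Xs <- .standardize(X)
    G <- model.matrix(~ droplevels(as.factor(groups)) - 1)
    Yc <- sweep(G, 2, colMeans(G))
    fit <- .nipals_pls2(Xs, Yc, ncomp = 2)
    scores <- fit$scores
    explained <- fit$explained
  }

  # deterministic orientation: largest-|correlation| variable positive per axis
  for (j in 1:2) {
    cj <- .safe_cor(X, scores[, j])
    i <- which.max(abs(cj))
    if (length(i) && cj[i] < 0) scores[, j] <- -scores[, j]
  }
  explained <- as.numeric(pmin(pmax(explained, 0), 1))

  structure(list(
    method = method,
    scores = tibble::tibble(subject_id = trial$subject_id, group = groups,
                            axis1 = scores[, 1], axis2 = scores[, 2]),
    explained = explained,
    axis1_correlations = setNames(.safe_cor(X, scores[, 1]), colnames(X)),
    n = n, p = p), class = "ordination2d")
}

#' @export
print.ordination2d <- function(x, ...) {
  cat("<ordination2d>", toupper(x$method), "-", x$n, "subjects,", x$p, "variables\n")
  cat(sprintf("  explained: axis1 %.1f%%, axis2 %.1f%%\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Correlations of original variables with an ordination axis
#'
#' Pearson correlation of each trial variable with a vector of axis scores,
#' with small correlations zeroed: entries with `|r| < threshold` are replaced
#' by exactly 0 to filter out unimportant variables, all others are returned
#' unchanged. Variables with zero variance get a 0 with a warning.
#'
#' @param trial A `trial_dataset` tibble.
#' @param axis_scores Numeric vector of scores, one per subject.
#' @param threshold Absolute-correlation cutoff below which correlations are
#'   zeroed (default 0.5; 0 disables the filter).
#' @return Tibble with columns `variable`, `correlation` (raw) and `filtered`.
#' @export
loading_correlations <- function(trial, axis_scores, threshold = 0.5) {
  X <- trial_values(trial)
  if (length(axis_scores) != nrow(X))
    stop("axis_scores must have one entry per subject")
  s <- apply(X, 2, sd)
  if (any(s <= 0)) warning("zero-variance variable(s); correlation set to 0")
  r <- .safe_cor(X, as.numeric(axis_scores))
  filtered <- ifelse(abs(r) < threshold, 0, r)
  tibble::tibble(variable = colnames(X), correlation = r, filtered = filtered)
}
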