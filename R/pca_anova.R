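#' Eigendecomposition of a population correlation matrix with Kaiser retention
#'
#' Eigenvalues are sorted in decreasing order and each eigenvector is oriented
#' so that its largest-magnitude loading is positive. Components are retained
#' when their eigenvalue is strictly greater than one (Kaiser criterion).
#'
#' @param R Correlation matrix.
#' @return List with `values`, `vectors` and `retained` (indices of the
#'   Kaiser-retained components).
#' @export
kaiser_components <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs, retained = which(vals > 1))
}

#' ANOVA on principal component scores
#'
#' Computes principal components from the *population* correlation matrix
#' (not the sample matrix), retains those whose eigenvalue exceeds one
#' (Kaiser criterion), projects the column-standardized trial data (pooled
#' mean and standard deviation across all groups) onto the retained
#' eigenvectors, and runs a one-way ANOVA across treatment groups on each
#' retained component score.
#'
#' @param trial A `trial_dataset` tibble.
#' @param R Population correlation matrix matching the trial's variables
#'   (typically `params$R`).
#' @return Tibble with one row per retained component (`method`, `target`,
#'   `statistic`, `df1`, `df2`, `p_value`); zero rows, with a warning, when no
#'   eigenvalue exceeds one.
#' @export
pca_scores_anova <- function(trial, R) {
  X <- trial_values(trial)
  R <- as.matrix(R)
  if (ncol(X) != nrow(R) || nrow(R) != ncol(R))
    stop("R must be a square matrix matching the trial dimension")
  kc <- kaiser_components(R)
  if (length(kc$retained) == 0) {
    warning("no eigenvalue exceeds 1; no components retained")
    return(tibble::tibble(method = character(), target = character(),
                          statistic = numeric(), df1 = numeric(),
                          df2 = numeric(), p_value = numeric()))
  }
  Xstd <- scale(X) # pooled mean/sd across all groups
  scores <- Xstd %*% kc$vectors[, kc$retained, drop = FALSE]
  res <- .anova_cols(scores, trial$group)
  dplyr::bind_cols(
    tibble::tibble(method = "pca_anova",
                   target = paste0("PC", kc$retained)),
    res)
}
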