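#' Population parameters for a multi-endpoint trial
#'
#' Bundles the control-population mean vector, variance vector and correlation
#' matrix that drive all data simulation, together with labels mapping each of
#' the `p` variables to an (endpoint, time) pair.
#'
#' @param mu Numeric vector of length `p`: control-group means, one per
#'   variable (endpoint units).
#' @param var Numeric vector of length `p`: strictly positive control-group
#'   variances.
#' @param R `p x p` correlation matrix; must be symmetric with unit diagonal
#'   and strictly positive eigenvalues.
#' @param labels Tibble with columns `variable`, `endpoint`, `time` (one row
#'   per variable), or `NULL` to derive labels from `names(mu)`.
#'
#' @return An object of class `population_params`: a list with elements `mu`,
#'   `var`, `R`, `labels` and `p`.
#' @seealso [default_population()], [bootstrap_population_params()],
#'   [read_population_csv()]
#' @export
population_params <- function(mu, var, R, labels = NULL) {
  p <- length(mu)
  if (p < 2) stop("at least 2 variables are required")
  if (length(var) != p) stop("`var` must have the same length as `mu`")
  if (!all(is.finite(mu)) || !all(is.finite(var))) stop("non-finite parameter values")
  if (any(var <= 0)) stop("`var` must be strictly positive")
  R <- as.matrix(R)
  if (nrow(R) != p || ncol(R) != p) stop("`R` must be ", p, " x ", p)
  if (max(abs(R - t(R))) > 1e-8) stop("`R` must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("`R` must have a unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`R` must be positive definite (min eigenvalue ", format(min(ev)), ")")

  if (is.null(labels)) {
    nm <- names(mu)
    if (is.null(nm)) nm <- paste0("v", seq_len(p))
    labels <- tibble::tibble(variable = nm, endpoint = nm, time = NA_character_)
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(nrow(labels) == p, all(c("variable", "endpoint", "time") %in% names(labels)))

  nm <- labels$variable
  names(mu) <- nm
  names(var) <- nm
  dimnames(R) <- list(nm, nm)
  structure(list(mu = mu, var = var, R = R, labels = labels, p = p),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params> p =", x$p, "variables\n")
  cat("  endpoints:", paste(unique(x$labels$endpoint), collapse = ", "), "\n")
  tms <- unique(x$labels$time)
  if (!all(is.na(tms))) cat("  times:", paste(tms, collapse = ", "), "\n")
  cat("  mean range: [", format(min(x$mu), digits = 4), ",",
      format(max(x$mu), digits = 4), "]\n")
  invisible(x)
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Symmetrizes the input and, when its smallest eigenvalue falls below the
#' floor `eps = eps_ratio * max(eigenvalue)`, replaces it by the nearest
#' positive-definite matrix (Higham's alternating projections, via
#' [Matrix::nearPD()]) with eigenvalues lifted to at least `eps`. A matrix
#' that is already positive definite is returned unchanged apart from the
#' symmetrization, which makes the operation idempotent.
#'
#' @param S Square numeric matrix (symmetrized internally as `(S + t(S))/2`).
#' @param eps_ratio Eigenvalue floor as a fraction of the largest eigenvalue.
#' @return A symmetric positive-definite matrix of the same dimension.
#' @export
nearest_positive_definite <- function(S, eps_ratio = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("input must be a square matrix")
  if (!all(is.finite(S))) stop("input contains non-finite values")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eps <- eps_ratio * max(ev, 0)
  if (eps <= 0) eps <- eps_ratio  # all-zero / negative-semidefinite input
  if (min(ev) >= eps) return(S)
  if (max(ev) <= 0) {
    # no positive part at all: lift straight to the configured floor
    out <- S + (eps - min(ev, 0)) * diag(nrow(S))
    dimnames(out) <- dimnames(S)
    return(out)
  }
  out <- as.matrix(Matrix::nearPD(S, conv.tol = 1e-11, posd.tol = 0)$mat)
  out <- (out + t(out)) / 2
  e <- eigen(out, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  out
}

#' Estimate population parameters by bootstrapping a pilot dataset
#'
#' Draws `B` bootstrap samples of whole subjects (rows, so the cross-variable
#' covariance is preserved), averages the replicate column means and sample
#' covariance matrices, repairs the averaged covariance with
#' [nearest_positive_definite()], and splits it into a variance vector and a
#' correlation matrix.
#'
#' @param pilot Matrix or data frame of pilot measurements, one row per
#'   subject, one column per variable; no missing values.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for the resampling.
#' @inheritParams population_params
#' @return A [population_params] object.
#' @export
bootstrap_population_params <- function(pilot, B = 10000, seed = 1, labels = NULL) {
  X <- as.matrix(pilot)
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("pilot too small: at least 2 subjects are required")
  if (!all(is.finite(X))) stop("pilot contains non-finite values")
  if (B < 1) stop("B must be >= 1")
  n <- nrow(X)
  p <- ncol(X)

  withr::with_seed(seed, {
    mu_acc <- numeric(p)
    cov_acc <- matrix(0, p, p)
    for (b in seq_len(B)) {
      Xb <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      mu_acc <- mu_acc + colMeans(Xb)
      cov_acc <- cov_acc + cov(Xb)
    }
  })
  mu <- mu_acc / B
  S <- nearest_positive_definite(cov_acc / B)

  v <- diag(S)
  R <- S / sqrt(tcrossprod(v))
  diag(R) <- 1
  # the rescaling can nudge eigenvalues; re-repair if needed
  R <- nearest_positive_definite(R)
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1

  if (is.null(labels) && !is.null(colnames(X))) names(mu) <- colnames(X)
  population_params(mu = mu, var = v, R = R, labels = labels)
}

#' Built-in control-population generator
#'
#' Deterministically (given `seed`) generates a plausible parameter set for a
#' preclinical trial with `n_endpoints` endpoints each measured at `n_times`
#' time points: positive means on heterogeneous scales, moderate coefficients
#' of variation, strong within-endpoint temporal correlation (about 0.7
#' between adjacent time points, decaying with lag) and moderate
#' cross-endpoint correlation (about 0.3-0.5), repaired to positive
#' definiteness. Intended as a stand-in when no pilot data or transcribed
#' population tables are available; [read_population_csv()] loads
#' user-supplied values in its place.
#'
#' @param n_endpoints Number of endpoints (default 6).
#' @param n_times Number of repeated measurements per endpoint (default 3).
#' @param seed Integer seed; the same seed always yields the same parameters.
#' @return A [population_params] object with `p = n_endpoints * n_times`.
#' @export
default_population <- function(n_endpoints = 6, n_times = 3, seed = 20200326) {
  if (n_endpoints < 1 || n_times < 1) stop("n_endpoints and n_times must be >= 1")
  ep_names <- c("neuroscore", "limb_placing", "lesion_volume",
                "edema_volume", "t2_lesion", "t2_lesion_contra")
  if (n_endpoints <= length(ep_names)) {
    ep <- ep_names[seq_len(n_endpoints)]
  } else {
    ep <- c(ep_names, paste0("endpoint", seq_len(n_endpoints - length(ep_names))))
  }
  tm <- paste0("day", c(1, 7, 14, seq_len(max(0, n_times - 3)) * 7 + 14))[seq_len(n_times)]
  labels <- tidyr::expand_grid(endpoint = ep, time = tm)
  labels$variable <- paste(labels$endpoint, labels$time, sep = ".")
  p <- nrow(labels)

  withr::with_seed(seed, {
    # heterogeneous positive scales per endpoint, mild drift over time
    base_mean <- exp(stats::runif(n_endpoints, log(2), log(300)))
    drift <- matrix(stats::runif(p, 0.8, 1.25), n_endpoints, n_times, byrow = TRUE)
    mu <- as.vector(t(base_mean * drift))
    cv <- stats::runif(p, 0.15, 0.45)
    v <- (mu * cv)^2

    # block correlation: AR-like within endpoint, moderate between endpoints
    R <- matrix(0, p, p)
    ep_idx <- rep(seq_len(n_endpoints), each = n_times)
    tm_idx <- rep(seq_len(n_times), n_endpoints)
    cross <- matrix(stats::runif(n_endpoints^2, 0.30, 0.50), n_endpoints)
    cross <- (cross + t(cross)) / 2
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j) {
          R[i, j] <- 1
        } else if (ep_idx[i] == ep_idx[j]) {
          R[i, j] <- 0.7^abs(tm_idx[i] - tm_idx[j])
        } else {
          R[i, j] <- cross[ep_idx[i], ep_idx[j]] *
            0.85^abs(tm_idx[i] - tm_idx[j])
        }
      }
    }
  })
  R <- nearest_positive_definite(R)
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  population_params(mu = mu, var = v, R = R,
                    labels = labels[, c("variable", "endpoint", "time")])
}

#' Read and write population parameters as CSV files
#'
#' The on-disk representation is a triplet of plain-text files: `means.csv`
#' (`label,mean`), `vars.csv` (`label,variance`) and `corr.csv` (a `p x p`
#' correlation matrix with variable labels as header row and first column).
#' Variable labels of the form `endpoint.time` are split into endpoint and
#' time components.
#'
#' @param means_file,vars_file,corr_file Paths to the three CSV files.
#' @return `read_population_csv()` returns a [population_params] object;
#'   `write_population_csv()` invisibly returns the three paths written.
#' @export
read_population_csv <- function(means_file, vars_file, corr_file) {
  means <- readr::read_csv(means_file, show_col_types = FALSE)
  vars <- readr::read_csv(vars_file, show_col_types = FALSE)
  if (!all(c("label", "mean") %in% names(means)))
    stop("means file must have columns label,mean")
  if (!all(c("label", "variance") %in% names(vars)))
    stop("vars file must have columns label,variance")
  if (nrow(means) != nrow(vars) || !all(means$label == vars$label))
    stop("means and vars files disagree on the variable axis")
  p <- nrow(means)
  corr <- readr::read_csv(corr_file, show_col_types = FALSE)
  if (ncol(corr) != p + 1)
    stop("correlation file has ", ncol(corr) - 1, " columns, expected ", p,
         " (column axis mismatch)")
  if (nrow(corr) != p)
    stop("correlation file has ", nrow(corr), " rows, expected ", p,
         " (row axis mismatch)")
  R <- as.matrix(corr[, -1])
  lab <- means$label
  parts <- strsplit(lab, ".", fixed = TRUE)
  ok <- lengths(parts) == 2
  labels <- tibble::tibble(
    variable = lab,
    endpoint = ifelse(ok, vapply(parts, `[`, "", 1), lab),
    time = ifelse(ok, vapply(parts, `[`, "", 2), NA_character_))
  population_params(mu = means$mean, var = vars$variance, R = R, labels = labels)
}

#' @param params A [population_params] object.
#' @param dir Directory in which to write `means.csv`, `vars.csv`, `corr.csv`.
#' @rdname read_population_csv
#' @export
write_population_csv <- function(params, dir) {
  stopifnot(inherits(params, "population_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("means.csv", "vars.csv", "corr.csv"))
  readr::write_csv(tibble::tibble(label = names(params$mu), mean = params$mu), paths[1])
  readr::write_csv(tibble::tibble(label = names(params$var), variance = params$var), paths[2])
  corr <- tibble::as_tibble(params$R)
  corr <- dplyr::bind_cols(tibble::tibble(label = rownames(params$R)), corr)
  readr::write_csv(corr, paths[3])
  invisible(paths)
}
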