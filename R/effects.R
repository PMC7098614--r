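#' Place a treatment-group mean from a standardized effect size
#'
#' Computes `mu1 = mu0 + sign * s * d`, the treatment-group population mean
#' implied by Cohen's d. Under variance heterogeneity `s` should be the
#' average of the control and treatment standard deviations (see
#' [effect_sd()]); under equal variance it is the common standard deviation.
#' Vectorized over all arguments.
#'
#' @param mu0 Control-group mean(s).
#' @param s Standard deviation(s) used to scale the effect; must be positive.
#' @param d Cohen's d (>= 0).
#' @param sign Direction of the shift per variable, +1 or -1.
#' @return The treatment-group mean(s).
#' @export
apply_effect <- function(mu0, s, d, sign = 1) {
  if (any(s <= 0)) stop("s must be strictly positive")
  if (any(d < 0)) stop("d must be >= 0")
  if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  mu0 + sign * s * d
}

#' Effect-scaling standard deviation under variance heterogeneity
#'
#' With a treatment-to-control variance ratio `v`, the treatment standard
#' deviation is `s_control * sqrt(v)` and the standardized effect is scaled by
#' the average of the two standard deviations.
#'
#' @param s_control Control-group standard deviation(s).
#' @param variance_ratio Treatment-to-control variance ratio (>= 1).
#' @return The average standard deviation `(s_control + s_control*sqrt(v))/2`.
#' @export
effect_sd <- function(s_control, variance_ratio = 1) {
  if (any(s_control <= 0)) stop("s_control must be strictly positive")
  if (any(variance_ratio < 1)) stop("variance_ratio must be >= 1")
  (s_control + s_control * sqrt(variance_ratio)) / 2
}

#' Gamma shape and rate from a target mean and variance
#'
#' Inverts the gamma moments `mu = alpha/beta`, `sigma^2 = alpha/beta^2`:
#' `alpha = mu^2/sigma^2`, `beta = mu/sigma^2`. Vectorized.
#'
#' @param mu Target mean(s); must be strictly positive (the gamma family has
#'   positive support, so gamma scenarios require positive means).
#' @param var Target variance(s); strictly positive.
#' @return A tibble with columns `alpha` (shape) and `beta` (rate).
#' @export
gamma_shape_rate <- function(mu, var) {
  if (any(mu <= 0))
    stop("gamma scenarios require strictly positive target means (mu > 0)")
  if (any(var <= 0)) stop("var must be strictly positive")
  tibble::tibble(alpha = mu^2 / var, beta = mu / var)
}
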