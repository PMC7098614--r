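#' Tidy an ordination into its score table
#'
#' @param x An `ordination2d` object.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `group`, `axis1`, `axis2`.
#' @export
tidy.ordination2d <- function(x, ...) x$scores

#' One-row summary of an ordination fit
#'
#' @inheritParams tidy.ordination2d
#' @return Tibble with `method`, `explained_axis1`, `explained_axis2`, `n`, `p`.
#' @export
glance.ordination2d <- function(x, ...) {
  tibble::tibble(method = x$method,
                 explained_axis1 = x$explained[1],
                 explained_axis2 = x$explained[2],
                 n = x$n, p = x$p)
}

#' Tidy a confidence ellipse into a boundary path
#'
#' @param x A `conf_ellipse` object.
#' @param K Number of boundary points.
#' @param ... Unused.
#' @return Tibble with `x`, `y` tracing the closed boundary.
#' @export
tidy.conf_ellipse <- function(x, K = 360, ...) {
  b <- ellipse_boundary(x, K)
  tibble::tibble(x = c(b[, 1], b[1, 1]), y = c(b[, 2], b[1, 2]))
}

#' Tidy a pattern-detection verdict
#'
#' @param x A `pattern_result` object.
#' @param ... Unused.
#' @return Tibble with one row per treatment group: `method`, `group`,
#'   `disjoint`, `detected`.
#' @export
tidy.pattern_result <- function(x, ...) {
  tibble::tibble(method = x$method, group = names(x$disjoint),
                 disjoint = unname(x$disjoint), detected = x$detected)
}
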