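#' Score plot of a 2-D ordination with per-group confidence ellipses
#'
#' Subjects in the plane of the first two ordination axes, coloured by group,
#' with the 95% confidence ellipse of each group drawn under the convention
#' used by [detect_pattern()].
#'
#' @param object An `ordination2d` object.
#' @param type Ellipse convention, see [confidence_ellipse_95()].
#' @param level Ellipse coverage level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ordination2d <- function(object, type = "chisq", level = 0.95, ...) {
  sc <- object$scores
  paths <- dplyr::bind_rows(lapply(levels(droplevels(as.factor(sc$group))), function(l) {
    P <- as.matrix(sc[sc$group == l, c("axis1", "axis2")])
    e <- tryCatch(confidence_ellipse_95(P, level = level, type = type),
                  error = function(err) NULL)
    if (is.null(e)) return(NULL)
    dplyr::mutate(tidy(e), group = l)
  }))
  gg <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                         colour = .data$group)) +
    ggplot2::geom_point(size = 2)
  if (nrow(paths) > 0)
    gg <- gg + ggplot2::geom_path(data = paths,
                                  ggplot2::aes(x = .data$x, y = .data$y,
                                               colour = .data$group),
                                  inherit.aes = FALSE)
  gg + ggplot2::labs(
    x = sprintf("Axis 1 (%.0f%%)", 100 * object$explained[1]),
    y = sprintf("Axis 2 (%.0f%%)", 100 * object$explained[2]),
    title = toupper(object$method)) +
    ggplot2::theme_minimal()
}

#' Panelled rejection-rate plot over the scenario grid
#'
#' Pooled rejection rate against per-group sample size, one line per method,
#' panelled by distribution and variance ratio (the 3 x 3 layout when the
#' full default grid was run) for a fixed effect size.
#'
#' @param results Output of [run_grid()].
#' @param cohens_d Which effect size to display (default 0, i.e. type I
#'   error).
#' @param alpha_line Nominal level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(results, cohens_d = 0, alpha_line = 0.05) {
  df <- results[results$cohens_d == cohens_d, ]
  if (nrow(df) == 0) stop("no results at cohens_d = ", cohens_d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_per_group, y = .data$rate,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = alpha_line, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(distribution ~ variance_ratio,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "subjects per group",
                  y = if (cohens_d == 0) "empirical type I error" else "empirical power",
                  title = sprintf("Pooled rejection rate, Cohen's d = %g", cohens_d)) +
    ggplot2::theme_bw()
}
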