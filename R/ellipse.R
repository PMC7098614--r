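#' 95% confidence ellipse of a 2-D point cloud
#'
#' The ellipse is centred at the sample mean with shape given by the sample
#' covariance matrix; a point `x` lies inside when its squared Mahalanobis
#' distance from the centre is at most `scale`. The default convention takes
#' `scale` as the 0.95 quantile of the chi-squared distribution with 2
#' degrees of freedom (population-coverage ellipse, 5.9915); `type = "t"`
#' selects the small-sample data-ellipse scaling
#' `2 (n - 1) / (n - 2) * qf(level, 2, n - 2)`.
#'
#' @param points Numeric matrix (or data frame) with `n >= 3` rows and 2
#'   columns.
#' @param level Coverage level (default 0.95).
#' @param type `"chisq"` (default) or `"t"`.
#' @return Object of class `conf_ellipse`: list with `center` (length 2),
#'   `shape` (2 x 2 covariance), `scale` (squared quantile radius) and `n`.
#' @export
confidence_ellipse_95 <- function(points, level = 0.95, type = c("chisq", "t")) {
  type <- match.arg(type)
  P <- as.matrix(points)
  if (ncol(P) != 2) stop("points must have exactly 2 columns")
  n <- nrow(P)
  if (n < 3) stop("degenerate ellipse: at least 3 points are required")
  if (!all(is.finite(P))) stop("points contain non-finite values")
  center <- colMeans(P)
  shape <- cov(P)
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 1e-300))
    stop("degenerate ellipse: points are (nearly) collinear")
  scale <- switch(type,
                  chisq = qchisq(level, df = 2),
                  t = 2 * (n - 1) / (n - 2) * qf(level, 2, n - 2))
  structure(list(center = center, shape = shape, scale = scale, n = n),
            class = "conf_ellipse")
}

# squared Mahalanobis distances of rows of P from the ellipse centre
.ellipse_maha <- function(e, P) {
  stats::mahalanobis(P, center = e$center, cov = e$shape)
}

#' Boundary points of a confidence ellipse
#'
#' @param e A `conf_ellipse`.
#' @param K Number of boundary points.
#' @return `K x 2` matrix tracing the boundary.
#' @export
ellipse_boundary <- function(e, K = 720) {
  dec <- eigen(e$shape, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = K + 1)[-(K + 1)]
  circ <- cbind(cos(theta), sin(theta))
  pts <- circ %*% (sqrt(pmax(dec$values, 0)) * t(dec$vectors)) * sqrt(e$scale)
  sweep(pts, 2, e$center, `+`)
}

#' Do two confidence ellipses have disjoint interiors?
#'
#' Each boundary is parameterized at `K` points; the ellipses are declared
#' disjoint when no boundary point of either lies inside the other and
#' neither centre lies inside the other (which also covers containment).
#'
#' @param e1,e2 `conf_ellipse` objects.
#' @param K Boundary resolution (default 720 points).
#' @return Logical scalar.
#' @export
ellipses_disjoint <- function(e1, e2, K = 720) {
  stopifnot(inherits(e1, "conf_ellipse"), inherits(e2, "conf_ellipse"))
  if (.ellipse_maha(e2, rbind(e1$center)) <= e2$scale) return(FALSE)
  if (.ellipse_maha(e1, rbind(e2$center)) <= e1$scale) return(FALSE)
  b1 <- ellipse_boundary(e1, K)
  b2 <- ellipse_boundary(e2, K)
  if (any(.ellipse_maha(e2, b1) <= e2$scale)) return(FALSE)
  if (any(.ellipse_maha(e1, b2) <= e1$scale)) return(FALSE)
  TRUE
}

#' Detect a treatment-effect pattern in an ordination
#'
#' Builds a 95% confidence ellipse per group from the first two ordination
#' axes and declares a treatment-effect pattern when the control-group
#' ellipse is disjoint from the ellipses of *all* treatment groups. A group
#' whose ellipse is degenerate (collinear scores) makes its flag `FALSE`
#' (pattern not detected) and is recorded in `note`.
#'
#' @param ord An [ordinate()] result.
#' @param type,level,K Passed to [confidence_ellipse_95()] /
#'   [ellipses_disjoint()].
#' @return Object of class `pattern_result`: list with `method`, `detected`
#'   (logical), `disjoint` (named logical, one per treatment group) and
#'   `note`.
#' @export
detect_pattern <- function(ord, type = c("chisq", "t"), level = 0.95, K = 720) {
  stopifnot(inherits(ord, "ordination2d"))
  type <- match.arg(type)
  sc <- ord$scores
  grp <- droplevels(as.factor(sc$group))
  lv <- levels(grp)
  ctrl_lv <- lv[1]
  notes <- character()
  mk <- function(l) {
    P <- as.matrix(sc[grp == l, c("axis1", "axis2")])
    tryCatch(confidence_ellipse_95(P, level = level, type = type),
             error = function(e) {
               notes <<- c(notes, paste0(l, ": ", conditionMessage(e)))
               NULL
             })
  }
  ctrl <- mk(ctrl_lv)
  doses <- lv[-1]
  disjoint <- setNames(logical(length(doses)), doses)
  for (l in doses) {
    el <- mk(l)
    disjoint[l] <- if (is.null(ctrl) || is.null(el)) FALSE else
      ellipses_disjoint(ctrl, el, K = K)
  }
  if (length(notes)) warning("degenerate ellipse(s): ",
                             paste(notes, collapse = "; "))
  structure(list(method = ord$method, detected = all(disjoint),
                 disjoint = disjoint,
                 note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat("<pattern_result>", toupper(x$method), "- pattern detected:", x$detected, "\n")
  cat("  control disjoint from:",
      paste(sprintf("%s=%s", names(x$disjoint), x$disjoint), collapse = ", "), "\n")
  invisible(x)
}
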