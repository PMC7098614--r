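# long data for one endpoint, with factors ready for model fitting
.endpoint_long <- function(trial, endpoint) {
  long <- trial_long(trial)
  dat <- long[long$endpoint == endpoint, , drop = FALSE]
  if (nrow(dat) == 0) stop("unknown endpoint: ", endpoint)
  tms <- unique(dat$time)
  if (length(tms) < 2)
    stop("endpoint '", endpoint, "' has a single time point; use oneway_anova()")
  dat$time <- factor(dat$time, levels = tms)
  dat$subject_id <- factor(dat$subject_id)
  dat
}

#' Linear mixed effects omnibus test for a treatment main effect
#'
#' Fits `value ~ group + time + (1 | subject)` to the repeated measures of one
#' endpoint and tests the treatment factor. Three engines are available:
#'
#' * `"satterthwaite"` (default): REML fit via [lmerTest::lmer()], F test
#'   with Satterthwaite degrees of freedom.
#' * `"balanced"`: the exact between-subject-stratum F test — a one-way ANOVA
#'   on subject means across time points. For the balanced complete layouts
#'   this package simulates it is numerically identical to the Satterthwaite
#'   mixed-model test whenever the between-subject variance estimate is
#'   positive, at a small fraction of the cost, and it remains an exact
#'   F test at the boundary.
#' * `"lrt"`: likelihood-ratio test comparing maximum-likelihood fits with
#'   and without the treatment factor (chi-squared reference).
#'
#' The engine used is recorded in the `note` column; a boundary (zero
#' between-subject variance) REML fit is flagged there as well.
#'
#' @param trial A `trial_dataset` tibble.
#' @param endpoint Endpoint label to test.
#' @param engine Degrees-of-freedom strategy, see Details.
#' @return A one-row tibble: `method`, `target`, `statistic`, `df1`, `df2`,
#'   `p_value`, `note`.
#' @export
lmm_main_effect <- function(trial, endpoint,
                            engine = c("satterthwaite", "balanced", "lrt")) {
  engine <- match.arg(engine)
  dat <- .endpoint_long(trial, endpoint)

  if (engine == "balanced") {
    means <- tapply(dat$value, dat$subject_id, mean)
    grp <- dat$group[match(names(means), dat$subject_id)]
    res <- .anova_cols(cbind(as.numeric(means)), grp)
    return(dplyr::bind_cols(
      tibble::tibble(method = "lmm", target = endpoint), res,
      tibble::tibble(note = "balanced exact F")))
  }

  if (engine == "lrt") {
    full <- lme4::lmer(value ~ group + time + (1 | subject_id), data = dat,
                       REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
    null <- lme4::lmer(value ~ time + (1 | subject_id), data = dat,
                       REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
    lrt <- anova(null, full)
    return(tibble::tibble(method = "lmm", target = endpoint,
                          statistic = lrt$Chisq[2], df1 = lrt$Df[2], df2 = Inf,
                          p_value = lrt$`Pr(>Chisq)`[2], note = "ML likelihood ratio"))
  }

  fit <- lmerTest::lmer(value ~ group + time + (1 | subject_id), data = dat,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  note <- "satterthwaite"
  if (lme4::isSingular(fit, tol = 1e-6))
    note <- "satterthwaite; boundary: zero between-subject variance"
  a <- suppressMessages(anova(fit))
  row <- a["group", ]
  tibble::tibble(method = "lmm", target = endpoint,
                 statistic = row[["F value"]], df1 = row[["NumDF"]],
                 df2 = row[["DenDF"]], p_value = row[["Pr(>F)"]], note = note)
}

#' Mixed model with treatment-by-time interaction and per-time contrasts
#'
#' Fits `value ~ group * time + (1 | subject)` to one endpoint's repeated
#' measures and compares every dose group against control separately at each
#' time point (estimated marginal means with Satterthwaite degrees of
#' freedom). The omnibus interaction test travels in the
#' `"interaction"` attribute; contrasts are reported regardless of its
#' significance so that callers can apply their own gate.
#'
#' @inheritParams lmm_main_effect
#' @param adjust Multiplicity adjustment for the per-time contrasts:
#'   `"none"` (default), `"dunnettx"` or `"bonferroni"`.
#' @return Tibble with one row per (time point, dose group): `endpoint`,
#'   `variable`, `time`, `contrast`, `estimate`, `p_value`.
#' @export
lmm_interaction_posthoc <- function(trial, endpoint,
                                    adjust = c("none", "dunnettx", "bonferroni")) {
  adjust <- match.arg(adjust)
  dat <- .endpoint_long(trial, endpoint)
  fit <- lmerTest::lmer(value ~ group * time + (1 | subject_id), data = dat,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  a <- suppressMessages(anova(fit))
  inter <- tibble::tibble(method = "lmm_interaction", target = endpoint,
                          statistic = a["group:time", "F value"],
                          df1 = a["group:time", "NumDF"],
                          df2 = a["group:time", "DenDF"],
                          p_value = a["group:time", "Pr(>F)"])
  emm <- emmeans::emmeans(fit, ~ group | time, lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1,
                                   adjust = adjust))
  out <- tibble::tibble(
    endpoint = endpoint,
    variable = paste(endpoint, as.character(ctr$time), sep = "."),
    time = as.character(ctr$time),
    contrast = paste0("control vs. ", sub(" - control", "", ctr$contrast)),
    estimate = ctr$estimate,
    p_value = ctr$p.value)
  attr(out, "interaction") <- inter
  out
}
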