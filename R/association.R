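#' Percent change from a baseline timepoint
#'
#' Re-expresses a longitudinal biomarker panel as percent change from each
#' unit's baseline observation: `100 * (value_t - value_b) / value_b`, with
#' baseline rows mapped to 0. The experimental unit is the animal for lung
#' measures and the individual limb for joint measures; the panel's `unit_id`
#' carries whichever applies.
#'
#' @param panel Long data frame with columns `unit_id`, `timepoint_months`,
#'   `measure`, `value` (extra columns are preserved).
#' @param baseline_months Baseline timepoint. Default 2 (months of age).
#' @return The panel with `value` replaced by percent change; units lacking a
#'   baseline observation are dropped with a warning.
#' @export
percent_change_from_baseline <- function(panel, baseline_months = 2) {
  needed <- c("unit_id", "timepoint_months", "measure", "value")
  if (!all(needed %in% names(panel))) {
    stop("panel must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(panel$unit_id, panel$measure, sep = "\r")
  is_base <- panel$timepoint_months == baseline_months
  base_map <- tapply(panel$value[is_base], key[is_base], `[[`, 1L)
  have <- key %in% names(base_map)
  if (!all(have)) {
    warning(sum(!have), " row(s) dropped: no baseline observation at ",
            baseline_months, " months for their unit")
  }
  out <- panel[have, , drop = FALSE]
  b <- as.numeric(base_map[key[have]])
  if (any(b == 0)) {
    stop("baseline value of 0 for unit(s): ",
         paste(unique(out$unit_id[b == 0]), collapse = ", "), call. = FALSE)
  }
  out$value <- 100 * (out$value - b) / b
  out
}

#' Log-transform a running metric
#'
#' Running metrics are right-skewed and include exact zeros after cessation,
#' so the normalizing transform is `log10(x + 1)`: order-preserving, zero
#' maps to zero, and defined on the whole observed range.
#'
#' @param values Non-negative numeric vector.
#' @return Transformed vector.
#' @examples
#' log_transform_metric(c(0, 9, 999)) # 0, 1, 3
#' @export
log_transform_metric <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("running metrics cannot be negative", call. = FALSE)
  }
  log10(values + 1)
}

#' Change since the first observation
#'
#' Within each unit's time-ordered series, subtracts the first observation:
#' the first value maps to 0 and later values to their difference from it.
#' Used to put running metrics on a within-animal change scale before
#' regression.
#'
#' @param values Numeric vector.
#' @param time Optional time of each observation (used to order within unit).
#' @param unit Optional unit identifier; when given, the delta is computed
#'   within each unit separately.
#' @return Vector of deltas, same length and order as `values`.
#' @examples
#' change_since_first(c(5, 7, 4)) # 0, 2, -1
#' @export
change_since_first <- function(values, time = NULL, unit = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (is.null(unit)) unit <- rep(1L, length(values))
  if (is.null(time)) {
    time <- stats::ave(seq_along(values), unit, FUN = seq_along)
  }
  out <- numeric(length(values))
  for (u in unique(unit)) {
    idx <- which(unit == u)
    if (!length(idx)) next
    first <- idx[order(time[idx])][1L]
    out[idx] <- values[idx] - values[first]
  }
  out
}

# Conditional residuals of a mixed model with time (categorical) as the only
# fixed effect and a random intercept per unit: obs - fixed - unit intercept.
# Falls back to fixed-effects detrending when only one unit is present.
mixed_time_detrend <- function(v, time, unit) {
  time_f <- droplevels(factor(time))
  unit_f <- droplevels(factor(unit))
  d <- data.frame(v = v, time_f = time_f, unit_f = unit_f)
  if (nlevels(unit_f) > 1L) {
    # derivative checks add nothing to the residuals and dominate runtime
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(v ~ 0 + time_f + (1 | unit_f), data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = lme4::.makeCC(action = "ignore",
                                                       tol = 1e-4)))))
    unname(stats::residuals(fit))
  } else {
    unname(stats::residuals(stats::lm(v ~ 0 + time_f, data = d)))
  }
}

fit_sum_contrast <- function(data, cols) {
  for (cl in cols) data[[cl]] <- factor(data[[cl]])
  contr <- stats::setNames(
    replicate(length(cols), "contr.sum", simplify = FALSE), cols)
  list(data = data, contrasts = contr)
}

#' Factorial (mixed-effects) analysis of a longitudinal outcome
#'
#' Fits a linear mixed model with all main effects and interactions of the
#' supplied factors (e.g. genotype, sex or activity, and time as a
#' categorical factor), a random intercept per experimental unit, and REML
#' estimation, then reports a Wald chi-square test per model term. When the
#' data carry a single timepoint (or no repeated measures), the model
#' degrades to a fixed-effects factorial ANOVA of the remaining factors.
#' Factors are coded with sum-to-zero contrasts so the per-term tests are the
#' usual type-III factorial tests.
#'
#' @param data Long data frame.
#' @param outcome Name of the outcome column.
#' @param factors Character vector of factor column names (each must have at
#'   least 2 levels after subsetting; single-level factors are dropped with a
#'   message).
#' @param unit Name of the experimental-unit column for the random intercept.
#' @return A list of class `effect_table`: `table` (one row per term:
#'   `term`, `statistic`, `df`, `p_value`), `model`, `type`
#'   (`"mixed"` or `"fixed"`), and `singular` (TRUE when the random-effect
#'   fit was singular; reported, never hidden).
#' @export
factorial_mixed_effects <- function(data, outcome, factors, unit) {
  stopifnot(outcome %in% names(data), unit %in% names(data),
            all(factors %in% names(data)))
  nlev <- vapply(factors, function(f) length(unique(data[[f]])), 0L)
  if (any(nlev < 2L)) {
    message("dropping single-level factor(s): ",
            paste(factors[nlev < 2L], collapse = ", "))
    factors <- factors[nlev >= 2L]
  }
  if (!length(factors)) stop("no factor with >= 2 levels", call. = FALSE)
  prepared <- fit_sum_contrast(data, factors)
  data <- prepared$data
  fixed <- paste(factors, collapse = " * ")
  repeated <- any(table(data[[unit]]) > 1L) && length(unique(data[[unit]])) > 1L
  singular <- FALSE
  if (repeated) {
    form <- stats::as.formula(
      paste0(outcome, " ~ ", fixed, " + (1 | ", unit, ")"))
    fit <- lme4::lmer(form, data = data, REML = TRUE,
                      contrasts = prepared$contrasts)
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("random-intercept fit is singular (unit variance ~ 0); ",
              "fixed-effect Wald tests reported, interpret with care")
    }
    an <- car::Anova(fit, type = 3, test.statistic = "Chisq")
    tab <- data.frame(term = rownames(an), statistic = an[["Chisq"]],
                      df = an[["Df"]], p_value = an[["Pr(>Chisq)"]],
                      stringsAsFactors = FALSE)
    type <- "mixed"
  } else {
    form <- stats::as.formula(paste0(outcome, " ~ ", fixed))
    fit <- stats::lm(form, data = data, contrasts = prepared$contrasts)
    an <- car::Anova(fit, type = 3)
    keep <- !(rownames(an) %in% c("Residuals"))
    tab <- data.frame(term = rownames(an)[keep],
                      statistic = an[["F value"]][keep],
                      df = an[["Df"]][keep],
                      p_value = an[["Pr(>F)"]][keep],
                      stringsAsFactors = FALSE)
    type <- "fixed"
  }
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, model = fit, type = type, singular = singular),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("<effect_table> %s-effects factorial analysis%s\n", x$type,
              if (x$singular) " [singular random-effect fit]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Longitudinal partial correlation via mixed-model detrending
#'
#' Estimates the association between a running metric and a biomarker while
#' accounting for the longitudinal design: each variable is fit with a mixed
#' model having time (categorical) as the only fixed effect and a random
#' intercept per unit; the partial correlation is the Pearson correlation of
#' the paired conditional residuals (observed minus fixed-effect prediction
#' minus unit intercept). Its p-value uses a t statistic on
#' `n_obs - 2 - (n_time - 1)` degrees of freedom, deducting the time
#' fixed-effect dimension.
#'
#' The running metric is expected on the analysis scale — log-transformed
#' and expressed as change since first observation (see
#' [log_transform_metric()], [change_since_first()]).
#'
#' An alternative estimator (`method = "rmcorr"`) computes the
#' repeated-measures correlation: both variables are detrended on time and
#' the common within-unit slope is extracted by ANCOVA on unit, pooling
#' within-unit covariance.
#'
#' @param x,y Numeric vectors of paired observations (one per unit-time).
#' @param time Time labels (coerced to factor).
#' @param unit Unit identifiers (animal or limb).
#' @param method `"residual"` (default; mixed-model conditional residuals)
#'   or `"rmcorr"`.
#' @return A list of class `partial_correlation`: `rho`, `p_value`, `df`,
#'   `n_obs`, `n_units`, `n_time`, `method`.
#' @export
partial_correlation_longitudinal <- function(x, y, time, unit,
                                             method = c("residual", "rmcorr")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(time) ||
      length(x) != length(unit)) {
    stop("x, y, time, unit must have the same length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y, time, unit)
  x <- x[ok]; y <- y[ok]
  time_f <- factor(time[ok]); unit_f <- factor(unit[ok])
  n_obs <- length(x)
  n_units <- nlevels(droplevels(unit_f))
  n_time <- nlevels(droplevels(time_f))
  if (n_obs < 3L) stop("need at least 3 paired observations", call. = FALSE)
  d <- data.frame(x = x, y = y, time_f = droplevels(time_f),
                  unit_f = droplevels(unit_f))
  if (method == "residual") {
    rx <- mixed_time_detrend(d$x, d$time_f, d$unit_f)
    ry <- mixed_time_detrend(d$y, d$time_f, d$unit_f)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
      stop("zero residual variance after detrending", call. = FALSE)
    }
    rho <- stats::cor(rx, ry)
    df <- n_obs - 2L - (n_time - 1L)
  } else {
    dx <- stats::residuals(stats::lm(x ~ 0 + time_f, data = d))
    dy <- stats::residuals(stats::lm(y ~ 0 + time_f, data = d))
    if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
      stop("zero residual variance after detrending", call. = FALSE)
    }
    fit <- stats::lm(dy ~ unit_f + dx)
    an <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate
    ss_x <- an["dx", "Sum Sq"]
    ss_err <- an["Residuals", "Sum Sq"]
    slope <- stats::coef(fit)[["dx"]]
    rho <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
    df <- n_obs - n_units - 1L - (n_time - 1L)
  }
  if (df < 1L) stop("not enough observations for inference (df < 1)",
                    call. = FALSE)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(rho = rho, p_value = p, df = df, n_obs = n_obs,
                 n_units = n_units, n_time = n_time, method = method),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf(
    "<partial_correlation> rho = %.3f (p = %.3g, df = %d, method = %s)\n",
    x$rho, x$p_value, x$df, x$method))
  cat(sprintf("  %d observations on %d units across %d timepoints\n",
              x$n_obs, x$n_units, x$n_time))
  invisible(x)
}

#' Running metric on the regression analysis scale
#'
#' Convenience composition used before [partial_correlation_longitudinal()]:
#' `log10(x + 1)` followed by change-since-first within unit.
#'
#' @param values Raw running metric values (non-negative).
#' @param time Observation times.
#' @param unit Unit identifiers.
#' @return Transformed vector.
#' @export
running_change_scale <- function(values, time, unit) {
  change_since_first(log_transform_metric(values), time = time, unit = unit)
}
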