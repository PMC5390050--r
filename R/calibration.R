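#' Fit a calibration line
#'
#' Ordinary least-squares fit of detector response against concentration for
#' one analyte (optionally one day/lab series). With `force_zero = TRUE` the
#' intercept is omitted, giving the closed-form no-intercept estimator
#' `slope = sum(x * y) / sum(x^2)`; the residual standard deviation then uses
#' n - 1 degrees of freedom instead of n - 2.
#'
#' @param data A data frame with columns `level_ug_per_ml` and `response`
#'   (extra columns such as `analyte`, `day`, `lab` are carried as labels if
#'   constant).
#' @param force_zero Force the line through the origin.
#' @return An object of class `calib_fit` with components `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `sigma` (residual SD),
#'   `se_y` (residual SD of the free fit, used in the zero-forcing
#'   comparison), `r` (Pearson correlation), `n`, `df`, `zero_forced`, and
#'   the label fields `analyte`, `day`, `lab`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @seealso [decide_zero_forcing()], [lack_of_fit_test()], [loq()]
#' @export
#' @examples
#' d <- data.frame(level_ug_per_ml = c(1, 2, 5), response = c(10, 20, 50))
#' fit_calibration(d, force_zero = TRUE)
fit_calibration <- function(data, force_zero = FALSE) {
  check_columns(data, c("level_ug_per_ml", "response"), "calibration series")
  x <- data$level_ug_per_ml
  y <- data$response
  if (anyNA(x) || anyNA(y)) abort("calibration series contains NA values.")
  if (any(x < 0)) abort("concentrations must be >= 0.")
  if (length(unique(x)) < 2) {
    abort("calibration series needs at least 2 distinct concentration levels.")
  }
  if (stats::sd(y) == 0) {
    abort("degenerate fit: responses have zero variance.")
  }

  label <- function(col) {
    v <- unique(data[[col]])
    if (length(v) == 1) as.character(v) else NA_character_
  }

  free <- lm(y ~ x)
  se_y <- muffle_perfect_fit(summary(free))$sigma
  if (force_zero) {
    m <- lm(y ~ x + 0)
    slope <- unname(coef(m)[["x"]])
    intercept <- 0
    se_intercept <- NA_real_
  } else {
    m <- free
    slope <- unname(coef(m)[["x"]])
    intercept <- unname(coef(m)[["(Intercept)"]])
    se_intercept <- muffle_perfect_fit(summary(m))$coefficients["(Intercept)", "Std. Error"]
  }
  sm <- muffle_perfect_fit(summary(m))
  structure(
    list(
      slope = slope,
      intercept = intercept,
      se_slope = sm$coefficients["x", "Std. Error"],
      se_intercept = se_intercept,
      sigma = sm$sigma,
      se_y = se_y,
      r = stats::cor(x, y),
      n = length(x),
      df = m$df.residual,
      zero_forced = force_zero,
      analyte = if ("analyte" %in% names(data)) label("analyte") else NA_character_,
      day = if ("day" %in% names(data)) label("day") else NA_character_,
      lab = if ("lab" %in% names(data)) label("lab") else NA_character_,
      data = tibble::tibble(level_ug_per_ml = x, response = y)
    ),
    class = "calib_fit"
  )
}

#' @export
print.calib_fit <- function(x, ...) {
  cat(sprintf("<calib_fit%s>%s\n",
              if (!is.na(x$analyte)) paste0(": ", x$analyte) else "",
              if (x$zero_forced) " (forced through zero)" else ""))
  cat(sprintf("  slope %.5g (se %.3g), intercept %.4g, r %.6f\n",
              x$slope, x$se_slope, x$intercept, x$r))
  cat(sprintf("  residual SD %.4g on %d df (n = %d)\n", x$sigma, x$df, x$n))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x,object A `calib_fit`.
#' @param ... Unused.
#' @export
tidy.calib_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @rdname fit_calibration
#' @export
glance.calib_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, day = x$day, lab = x$lab,
    slope = x$slope, intercept = x$intercept, r = x$r,
    sigma = x$sigma, se_y = x$se_y, zero_forced = x$zero_forced,
    n = x$n, df = x$df
  )
}

#' Fit calibration lines per group
#'
#' Convenience wrapper fitting [fit_calibration()] for every combination of
#' the grouping columns (default analyte x day x lab) and returning one
#' [glance()] row per fit.
#'
#' @param data Calibration table (`analyte`, `level_ug_per_ml`, `response`,
#'   `day`, `lab`, ...).
#' @param force_zero Passed to [fit_calibration()].
#' @param by Grouping columns present in `data`.
#' @return A tibble with one row per group: the grouping columns plus the
#'   `glance()` statistics of each fit.
#' @export
fit_calibrations <- function(data, force_zero = FALSE,
                             by = intersect(c("analyte", "day", "lab"),
                                            names(data))) {
  check_columns(data, c("level_ug_per_ml", "response"), "calibration table")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_calibration(d, force_zero = force_zero)) |>
        dplyr::select(-dplyr::any_of(by))
    }) |>
    dplyr::ungroup()
}

#' Decide whether to force the calibration through zero
#'
#' Tests the free-fit intercept against zero with a t-test at level `alpha`;
#' forcing is supported when the intercept is not statistically
#' distinguishable from zero. The simpler magnitude comparison of |b|
#' against the residual standard error of the fit (`se_y`) is also computed
#' and reported, and the verdict is logged as a message. Forcing the curve
#' through zero reduces the relative error at the low end of the working
#' range, which is where the LOQ-adjacent samples sit.
#'
#' @param fit A free (intercept) [fit_calibration()] fit.
#' @param alpha Significance level for the intercept t-test.
#' @param quiet Suppress the log message.
#' @return A one-row tibble: `force_zero`, `intercept`, `se_intercept`,
#'   `t`, `p_value`, `abs_b_below_se_y` (the magnitude comparison), `alpha`.
#' @export
decide_zero_forcing <- function(fit, alpha = 0.05, quiet = FALSE) {
  stopifnot(inherits(fit, "calib_fit"))
  if (fit$zero_forced) {
    abort("`fit` must be a free (intercept) fit; refit with force_zero = FALSE.")
  }
  t_stat <- fit$intercept / fit$se_intercept
  p <- 2 * pt(-abs(t_stat), df = fit$df)
  force <- p >= alpha
  out <- tibble::tibble(
    force_zero = force,
    intercept = fit$intercept,
    se_intercept = fit$se_intercept,
    t = t_stat,
    p_value = p,
    abs_b_below_se_y = abs(fit$intercept) < fit$se_y,
    alpha = alpha
  )
  if (!quiet) {
    rlang::inform(sprintf(
      "zero-forcing %s: intercept %.4g (se %.3g), t = %.3g, p = %.3g; |b| %s se_y (%.3g)",
      if (force) "supported" else "not supported",
      fit$intercept, fit$se_intercept, t_stat, p,
      if (abs(fit$intercept) < fit$se_y) "<" else ">=", fit$se_y))
  }
  out
}

#' Lack-of-fit test for calibration linearity
#'
#' Partitions the residual sum of squares of the calibration fit into pure
#' (replicate) error and lack-of-fit, and compares `F = MS_lof / MS_pe`
#' against the critical F at level `alpha`. Requires replicated
#' concentration levels; with only as many distinct levels as model
#' parameters the lack-of-fit degrees of freedom vanish and the test is
#' inapplicable (an explicit error, never a silent pass).
#'
#' @param data Calibration series (`level_ug_per_ml`, `response`).
#' @param force_zero Fit the line through the origin before testing.
#' @param alpha Significance level.
#' @return A one-row tibble: `F`, `F_critical`, `df_lof`, `df_pe`,
#'   `p_value`, `linear_ok` (`TRUE` iff `F < F_critical`).
#' @export
lack_of_fit_test <- function(data, force_zero = FALSE, alpha = 0.05) {
  check_columns(data, c("level_ug_per_ml", "response"), "calibration series")
  x <- data$level_ug_per_ml
  y <- data$response
  m_levels <- length(unique(x))
  n <- length(x)
  if (n == m_levels) {
    abort("lack-of-fit test inapplicable: no replicated concentration levels.")
  }
  n_par <- if (force_zero) 1L else 2L
  df_lof <- m_levels - n_par
  df_pe <- n - m_levels
  if (df_lof < 1) {
    abort(sprintf(
      "lack-of-fit test inapplicable: %d distinct level(s) leave df_lof = %d.",
      m_levels, df_lof))
  }

  fit <- fit_calibration(data, force_zero = force_zero)
  fitted <- fit$intercept + fit$slope * x
  ss_res <- sum((y - fitted)^2)
  level_means <- stats::ave(y, x, FUN = mean)
  ss_pe <- sum((y - level_means)^2)
  ss_lof <- max(ss_res - ss_pe, 0)

  ms_lof <- ss_lof / df_lof
  ms_pe <- ss_pe / df_pe
  if (ms_pe == 0) abort("pure error is zero; replicates are identical.")
  f_stat <- ms_lof / ms_pe
  f_crit <- qf(1 - alpha, df_lof, df_pe)
  tibble::tibble(
    F = f_stat,
    F_critical = f_crit,
    df_lof = df_lof,
    df_pe = df_pe,
    p_value = stats::pf(f_stat, df_lof, df_pe, lower.tail = FALSE),
    linear_ok = f_stat < f_crit
  )
}

#' Theoretical limit of quantification
#'
#' `LOQ = 10 * sigma / S`, with `sigma` the residual standard deviation of
#' the calibration fit and `S` its slope.
#'
#' @param fit A [fit_calibration()] fit (or any list with `sigma` and
#'   `slope`).
#' @return LOQ in ug/mL.
#' @seealso [clamp_loq()] for the reporting policy.
#' @export
#' @examples
#' loq(list(sigma = 0.05, slope = 1))  # 0.5 ug/mL
loq <- function(fit) {
  if (is.null(fit$slope) || is.null(fit$sigma)) {
    abort("`fit` must provide `slope` and `sigma`.")
  }
  if (fit$slope <= 0) abort("LOQ undefined: slope must be > 0.")
  10 * fit$sigma / fit$slope
}

#' Reported-LOQ clamping policy
#'
#' The reported LOQ is never below the lowest calibration level used to
#' establish the analyte's response factor: concentrations below the lowest
#' calibrant are extrapolations, so the reported LOQ is set at that level
#' whenever the theoretical estimate falls below it.
#'
#' @param loq_theoretical Theoretical LOQ(s) from [loq()] (ug/mL).
#' @param lowest_level Lowest calibration level(s) used (ug/mL).
#' @return Reported LOQ(s) in ug/mL.
#' @export
#' @examples
#' clamp_loq(0.5, 5)  # 5
clamp_loq <- function(loq_theoretical, lowest_level) {
  if (any(loq_theoretical < 0) || any(lowest_level <= 0)) {
    abort("LOQ values must be >= 0 and calibration levels > 0.")
  }
  pmax(loq_theoretical, lowest_level)
}

#' Working range of a calibration series
#'
#' The interval between the lowest and highest calibration level.
#'
#' @param data Calibration series with column `level_ug_per_ml` (a bare
#'   numeric vector of levels is also accepted).
#' @return A one-row tibble with `low` and `high` (ug/mL).
#' @export
working_range <- function(data) {
  levels <- if (is.data.frame(data)) {
    check_columns(data, "level_ug_per_ml", "calibration series")
    data$level_ug_per_ml
  } else {
    data
  }
  levels <- unique(levels)
  if (length(levels) < 2) {
    abort("working range needs at least 2 distinct levels.")
  }
  tibble::tibble(low = min(levels), high = max(levels))
}
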