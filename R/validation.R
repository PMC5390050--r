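#' Repeatability and intermediate precision by one-way ANOVA
#'
#' One-way random-effects ANOVA with day as the grouping factor.
#' Repeatability variance is the within-day mean square; the between-day
#' component is `(MS_between - MS_within) / n_bar` (harmonic-mean replicates
#' per day), truncated at zero when negative; intermediate-precision
#' variance is their sum. Both are reported as %RSD of the grand mean.
#'
#' @param data A data frame with columns `day` and `value` (mg/g); an
#'   optional `analyte` column triggers per-analyte computation.
#' @return A tibble with columns `repeatability_rsd`, `intermediate_rsd`
#'   (%), `grand_mean`, `s_r`, `s_day` (component SDs, absolute units),
#'   `day_component_truncated`, `n_days`, `n_total` (plus `analyte` when
#'   grouped).
#' @export
#' @examples
#' d <- data.frame(day = rep(1:3, each = 3), value = c(10, 11, 10, 12, 11, 12, 10, 10, 11))
#' precision_anova(d)
precision_anova <- function(data) {
  check_columns(data, c("day", "value"), "precision table")
  if ("analyte" %in% names(data)) {
    return(
      data |>
        dplyr::group_by(.data$analyte) |>
        dplyr::group_modify(~ precision_anova_one(.x)) |>
        dplyr::ungroup()
    )
  }
  precision_anova_one(data)
}

precision_anova_one <- function(data) {
  day <- factor(data$day)
  value <- data$value
  if (anyNA(value)) abort("precision values contain NA.")
  if (length(value) < 2) abort("degenerate: a single measurement.")
  if (nlevels(day) < 2) {
    abort("intermediate precision undefined with a single day.")
  }
  reps <- table(day)
  if (!any(reps >= 2)) {
    abort("at least one day needs >= 2 replicates for a within-day variance.")
  }

  a <- muffle_perfect_fit(anova(lm(value ~ day)))
  ms_between <- a$`Mean Sq`[1]
  ms_within <- a$`Mean Sq`[2]
  n_bar <- length(reps) / sum(1 / as.numeric(reps))  # harmonic mean

  s_r2 <- ms_within
  s_day2_raw <- (ms_between - ms_within) / n_bar
  truncated <- s_day2_raw < 0
  s_day2 <- max(s_day2_raw, 0)
  s_ip2 <- s_r2 + s_day2
  grand_mean <- mean(value)
  tibble::tibble(
    repeatability_rsd = 100 * sqrt(s_r2) / grand_mean,
    intermediate_rsd = 100 * sqrt(s_ip2) / grand_mean,
    grand_mean = grand_mean,
    s_r = sqrt(s_r2),
    s_day = sqrt(s_day2),
    day_component_truncated = truncated,
    n_days = nlevels(day),
    n_total = length(value)
  )
}

#' Spike recovery and its uncertainty
#'
#' Recovery from a fortification experiment: for every fortified replicate,
#' `recovery = 100 x (found - mean(unfortified)) / added`. The reported
#' recovery is the mean over all spiking levels and replicates (averaging
#' across levels is the conservative convention) and `u_rec` is the sample
#' SD of those individual recoveries. Restrict `data` to one level for the
#' single-point variant.
#'
#' @param data A data frame with columns `value` (found content, mg/g) and
#'   `added` (added content, mg/g; 0 for unfortified rows). An optional
#'   `analyte` column triggers per-analyte computation.
#' @return A tibble with columns `recovery` (%), `u_rec` (%), `n_spiked`,
#'   `n_unspiked` (plus `analyte` when grouped).
#' @export
spike_recovery <- function(data) {
  check_columns(data, c("value", "added"), "spiking table")
  if ("analyte" %in% names(data)) {
    return(
      data |>
        dplyr::group_by(.data$analyte) |>
        dplyr::group_modify(~ spike_recovery_one(.x)) |>
        dplyr::ungroup()
    )
  }
  spike_recovery_one(data)
}

spike_recovery_one <- function(data) {
  if (any(data$added < 0)) abort("`added` amounts must be >= 0.")
  base <- data$value[data$added == 0]
  spiked <- data[data$added > 0, ]
  if (length(base) < 1) abort("no unfortified (added = 0) replicates.")
  if (nrow(spiked) < 1) abort("no fortified (added > 0) replicates.")
  rec <- 100 * (spiked$value - mean(base)) / spiked$added
  tibble::tibble(
    recovery = mean(rec),
    u_rec = if (length(rec) >= 2) sd(rec) else NA_real_,
    n_spiked = length(rec),
    n_unspiked = length(base)
  )
}

#' Bias uncertainty from a control (reference) material
#'
#' Relative bias component for the uncertainty budget: the relative
#' deviation of the measured mean from the reference value combined in
#' quadrature with the reference's own relative uncertainty,
#' `u_bias = 100 x sqrt(((mean - ref)/ref)^2 + (u_ref/ref)^2)`.
#'
#' @param measured Replicate measured values (mg/g).
#' @param reference_value Certified/reference value (mg/g), on the same mass
#'   basis as the measurement (see [defatted_reference()]).
#' @param reference_uncertainty Standard uncertainty of the reference value
#'   (mg/g).
#' @return `u_bias` in %.
#' @export
#' @examples
#' bias_from_control(c(2.9, 2.9, 2.9), reference_value = 3.0)
bias_from_control <- function(measured, reference_value,
                              reference_uncertainty = 0) {
  if (length(measured) < 1 || anyNA(measured)) {
    abort("`measured` needs at least one non-NA value.")
  }
  check_number(reference_value, "reference_value", min = 0, strict_min = TRUE)
  check_number(reference_uncertainty, "reference_uncertainty", min = 0)
  rel_dev <- (mean(measured) - reference_value) / reference_value
  rel_ref <- reference_uncertainty / reference_value
  100 * sqrt(rel_dev^2 + rel_ref^2)
}

#' Convert a reference value to the defatted mass basis
#'
#' A chocolate control material is defatted before analysis, so certified
#' per-gram values must be re-expressed per gram of defatted material:
#' `ref_defatted = ref_whole / (1 - fat_fraction)`.
#'
#' @param reference_value Certified value on the whole-material basis (mg/g).
#' @param fat_fraction Mass fraction of fat removed (0 <= f < 1).
#' @return Reference value on the defatted basis (mg/g).
#' @export
#' @examples
#' defatted_reference(2.0, 0.5)  # 4.0
defatted_reference <- function(reference_value, fat_fraction) {
  check_number(reference_value, "reference_value", min = 0, strict_min = TRUE)
  check_number(fat_fraction, "fat_fraction", min = 0, max = 1 - 1e-12)
  reference_value / (1 - fat_fraction)
}

#' Expanded measurement uncertainty
#'
#' Combines the six relative standard-uncertainty components of the
#' indirect-calibration method into the expanded uncertainty
#' \deqn{U = k \sqrt{u_{rep(RRF)}^2 + u_{il(RRF)}^2 + u_r^2/n_1 +
#'   u_{ip}^2/n_2 + u_{bias}^2 + u_{rec}^2}}{
#'   U = k * sqrt(u_rep_rrf^2 + u_il_rrf^2 + u_r^2/n1 + u_ip^2/n2 +
#'   u_bias^2 + u_rec^2)}
#' where the RRF terms are the within- and between-lab RRF dispersions,
#' `u_r`/`u_ip` are repeatability and intermediate precision divided by the
#' number of analyses `n1` and days `n2`, and `u_bias`/`u_rec` come from the
#' control material and spike recovery. All components enter as percent
#' relative standard uncertainties and `U` is returned in percent; mixing in
#' absolute units is rejected at validation. `k = 2` gives ~95% coverage.
#'
#' Arguments are vectorised, so a whole per-analyte budget table can be
#' evaluated in one call.
#'
#' @param u_rep_rrf,u_il_rrf Within-/between-lab RRF dispersion (%).
#' @param u_r,u_ip Repeatability and intermediate precision (%).
#' @param n1 Total number of analyses (>= 1).
#' @param n2 Number of days measured (>= 1).
#' @param u_bias,u_rec Bias and recovery components (%).
#' @param k Coverage factor (default 2).
#' @return A tibble with the components, `k`, `u_combined` (%) and `U` (%).
#' @export
#' @examples
#' expanded_uncertainty(u_r = 6, u_ip = 2, n1 = 9, n2 = 3)$U  # 4.62
expanded_uncertainty <- function(u_rep_rrf = 0, u_il_rrf = 0,
                                 u_r = 0, u_ip = 0, n1 = 1, n2 = 1,
                                 u_bias = 0, u_rec = 0, k = 2) {
  comp <- list(u_rep_rrf = u_rep_rrf, u_il_rrf = u_il_rrf, u_r = u_r,
               u_ip = u_ip, u_bias = u_bias, u_rec = u_rec)
  for (nm in names(comp)) {
    if (!is.numeric(comp[[nm]]) || anyNA(comp[[nm]]) || any(comp[[nm]] < 0)) {
      abort(sprintf("`%s` must be a non-negative percent value.", nm))
    }
  }
  if (any(n1 < 1) || any(n2 < 1)) abort("`n1` and `n2` must be >= 1.")
  if (any(k <= 0)) abort("`k` must be > 0.")
  u_c <- sqrt(u_rep_rrf^2 + u_il_rrf^2 + u_r^2 / n1 + u_ip^2 / n2 +
                u_bias^2 + u_rec^2)
  tibble::tibble(
    u_rep_rrf = u_rep_rrf, u_il_rrf = u_il_rrf, u_r = u_r, u_ip = u_ip,
    n1 = n1, n2 = n2, u_bias = u_bias, u_rec = u_rec, k = k,
    u_combined = u_c, U = k * u_c
  )
}

#' Stability assessment
#'
#' For each analyte, computes the change from the first to the last
#' timepoint (`delta = value(t_max) - value(0)`) and an acceptance
#' half-width equal to the mean of all timepoint values times the analyte's
#' intermediate-precision fraction. The `stable` flag (`|delta| <=`
#' half-width) is advisory: a drift within the method's own
#' between-day noise cannot be distinguished from no trend, so both numbers
#' are always reported and the flag is not a formal pass/fail verdict.
#'
#' @param data Stability table with columns `analyte`, `timepoint_h`,
#'   `value` (mg/g); must include 0 h and at least one later timepoint per
#'   analyte.
#' @param ip Intermediate-precision fraction per analyte: a single number,
#'   a named vector, or a data frame with columns `analyte`, `ip` (an `ip`
#'   column already present in `data` is used by default).
#' @return A tibble per analyte: `t0`, `t_final`, `value_t0`,
#'   `value_final`, `delta`, `mean_value`, `ip`, `acceptable_halfwidth`,
#'   `stable`.
#' @export
#' @examples
#' stability_assess(stability_reference())
stability_assess <- function(data, ip = NULL) {
  check_columns(data, c("analyte", "timepoint_h", "value"), "stability table")
  if (is.null(ip)) {
    if (!"ip" %in% names(data)) {
      abort("provide `ip` (fraction) or include an `ip` column in `data`.")
    }
  } else if (is.data.frame(ip)) {
    check_columns(ip, c("analyte", "ip"), "`ip` table")
    data <- dplyr::left_join(dplyr::select(data, -dplyr::any_of("ip")),
                             ip, by = "analyte")
  } else if (!is.null(names(ip))) {
    data <- dplyr::mutate(dplyr::select(data, -dplyr::any_of("ip")),
                          ip = unname(ip[.data$analyte]))
  } else {
    check_number(ip, "ip", min = 0)
    data$ip <- ip
  }
  if (anyNA(data$ip)) abort("missing `ip` fraction for some analyte(s).")

  data |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      tp <- sort(unique(d$timepoint_h))
      if (!0 %in% tp) abort("stability series must include the 0 h timepoint.")
      if (length(tp) < 2) abort("stability series needs >= 2 timepoints.")
      v0 <- mean(d$value[d$timepoint_h == 0])
      vT <- mean(d$value[d$timepoint_h == max(tp)])
      m <- mean(d$value)
      hw <- m * d$ip[1]
      tibble::tibble(
        t0 = 0, t_final = max(tp),
        value_t0 = v0, value_final = vT,
        delta = vT - v0,
        mean_value = m, ip = d$ip[1],
        acceptable_halfwidth = hw,
        stable = abs(vT - v0) <= hw
      )
    }) |>
    dplyr::ungroup()
}
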