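#' Daily relative response factor
#'
#' RRF of an oligomer on one day: the ratio of the oligomer's calibration
#' slope to the epicatechin slope fitted on the same day and in the same
#' lab. Any sensitivity drift common to the day cancels in the ratio, which
#' is why the RRF (and not the raw slope) is the transferable quantity.
#'
#' @param dp_fit,epi_fit [fit_calibration()] fits for the oligomer and for
#'   epicatechin, from the same day/lab.
#' @return The RRF (a fraction).
#' @export
daily_rrf <- function(dp_fit, epi_fit) {
  stopifnot(inherits(dp_fit, "calib_fit"), inherits(epi_fit, "calib_fit"))
  same <- function(a, b) is.na(a) || is.na(b) || identical(a, b)
  if (!same(dp_fit$day, epi_fit$day) || !same(dp_fit$lab, epi_fit$lab)) {
    abort(sprintf("day/lab mismatch between fits: (%s, %s) vs (%s, %s).",
                  dp_fit$day, dp_fit$lab, epi_fit$day, epi_fit$lab))
  }
  if (epi_fit$slope <= 0) abort("epicatechin slope must be > 0.")
  dp_fit$slope / epi_fit$slope
}

#' Mean-of-means RRF and its RSD
#'
#' Aggregates daily RRF determinations into the reported value: the
#' arithmetic mean of the daily RRFs, with the relative standard deviation
#' `100 x sd(daily) / mean(daily)` (sample SD, n - 1).
#'
#' @param daily Numeric vector of daily RRF values (>= 1 for a mean, >= 2
#'   for an RSD).
#' @return A one-row tibble: `rrf`, `rsd_percent`, `n_days`.
#' @export
#' @examples
#' mean_of_means_rrf(c(0.58, 0.59, 0.59))
mean_of_means_rrf <- function(daily) {
  if (length(daily) < 1 || anyNA(daily)) {
    abort("`daily` needs at least one non-NA RRF value.")
  }
  m <- mean(daily)
  tibble::tibble(
    rrf = m,
    rsd_percent = if (length(daily) >= 2) 100 * sd(daily) / m else NA_real_,
    n_days = length(daily)
  )
}

#' Compute an RRF table from calibration data
#'
#' Full RRF determination: fits per-(analyte, day, lab) calibration lines,
#' forms the daily slope ratio against the same day's epicatechin fit, and
#' aggregates to the mean-of-means RRF with its across-day RSD, per lab.
#'
#' @param data Calibration table with columns `analyte`, `level_ug_per_ml`,
#'   `response`, `day`, `lab`; must include `"epicatechin"` series.
#' @param force_zero Force calibration lines through the origin.
#' @param keep_daily Also return the per-day ratios (attribute `"daily"`).
#' @return A tibble with columns `lab`, `analyte`, `rrf`, `rsd_percent`,
#'   `n_days` (epicatechin rows carry RRF 1 by construction).
#' @export
compute_rrf_table <- function(data, force_zero = TRUE, keep_daily = FALSE) {
  check_columns(data, c("analyte", "level_ug_per_ml", "response", "day", "lab"),
                "calibration table")
  if (!"epicatechin" %in% data$analyte) {
    abort("calibration table has no epicatechin series to reference against.")
  }
  slopes <- fit_calibrations(data, force_zero = force_zero) |>
    dplyr::select("analyte", "day", "lab", "slope")
  epi <- slopes |>
    dplyr::filter(.data$analyte == "epicatechin") |>
    dplyr::select("day", "lab", epi_slope = "slope")
  daily <- slopes |>
    dplyr::inner_join(epi, by = c("day", "lab")) |>
    dplyr::mutate(rrf_daily = .data$slope / .data$epi_slope)
  out <- daily |>
    dplyr::group_by(.data$lab, .data$analyte) |>
    dplyr::summarise(
      mean_of_means_rrf(.data$rrf_daily),
      .groups = "drop"
    )
  if (keep_daily) attr(out, "daily") <- daily
  out
}

#' Between-lab dispersion of RRF determinations
#'
#' Splits RRF variation into the two uncertainty-budget components: the
#' pooled within-lab (across-day) RSD, `u_rep(RRF)`, and the RSD of the lab
#' mean RRFs, `u_il(RRF)`.
#'
#' @param daily A tibble of daily RRFs with columns `lab`, `analyte`, and
#'   `rrf_daily` (as the `"daily"` attribute of [compute_rrf_table()]), or
#'   a per-lab RRF table with `lab`, `analyte`, `rrf` (then only `u_il` is
#'   computable and `u_rep` comes from `rsd_percent` if present).
#' @return A tibble with columns `analyte`, `u_rep_rrf` (%), `u_il_rrf` (%),
#'   `n_labs`.
#' @export
rrf_dispersion_across_labs <- function(daily) {
  check_columns(daily, c("lab", "analyte"), "RRF table")
  if (dplyr::n_distinct(daily$lab) < 2) {
    abort("between-lab RRF dispersion needs results from at least 2 labs.")
  }
  if ("rrf_daily" %in% names(daily)) {
    per_lab <- daily |>
      dplyr::group_by(.data$analyte, .data$lab) |>
      dplyr::summarise(
        lab_mean = mean(.data$rrf_daily),
        lab_rsd = 100 * sd(.data$rrf_daily) / mean(.data$rrf_daily),
        .groups = "drop"
      )
  } else {
    check_columns(daily, "rrf", "per-lab RRF table")
    per_lab <- daily |>
      dplyr::mutate(lab_mean = .data$rrf,
                    lab_rsd = if ("rsd_percent" %in% names(daily)) {
                      .data$rsd_percent
                    } else NA_real_) |>
      dplyr::select("analyte", "lab", "lab_mean", "lab_rsd")
  }
  per_lab |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      u_rep_rrf = sqrt(mean(.data$lab_rsd^2)),  # pooled within-lab RSD
      u_il_rrf = 100 * sd(.data$lab_mean) / mean(.data$lab_mean),
      n_labs = dplyr::n(),
      .groups = "drop"
    )
}

#' Quantify a sample peak table
#'
#' Converts integrated dp-class peak responses into concentrations and
#' contents. For each analyte,
#' `conc (ug/mL) = response / (slope_epi x RRF)` and
#' `content (mg/g) = conc x volume_mL x dilution / mass_mg`.
#' The monomer class uses RRF = 1. Results below the analyte's reported LOQ
#' are flagged (`below_loq`), retained in the output, and excluded from
#' class totals by [total_oligomers()].
#'
#' @param peaks Peak table with columns `analyte`, `response`, and (unless
#'   given as arguments) `mass_mg`, `volume_ml`, `dilution`. If responses of
#'   a dp class were integrated per isomer, pre-sum them per class; rows
#'   sharing `analyte` (within a `sample_id`/`day`/`replicate` grouping, if
#'   present) are summed here.
#' @param epi_slope Epicatechin calibration slope (response per ug/mL), or a
#'   `calib_fit`.
#' @param rrfs RRF table (`analyte`, `rrf`), e.g. [rrf_reference()] or
#'   [compute_rrf_table()] output. Every analyte in `peaks` must have an
#'   entry; `"epicatechin"` defaults to 1 if absent.
#' @param mass_mg,volume_ml,dilution Scalar overrides when not columns of
#'   `peaks`.
#' @param loqs Optional LOQ table (`analyte`, `loq_ug_per_ml`), e.g.
#'   [loq_reference()]; when `NULL` no flagging is done.
#' @return A tibble with the identifying columns of `peaks` plus `analyte`,
#'   `conc_ug_per_ml`, `content_mg_per_g`, `below_loq`, `loq_used`.
#' @export
#' @examples
#' peaks <- data.frame(analyte = "dp2", response = 200)
#' quantify_sample(peaks, epi_slope = 10, rrfs = data.frame(analyte = "dp2", rrf = 0.5),
#'                 mass_mg = 100, volume_ml = 50, dilution = 1)
quantify_sample <- function(peaks, epi_slope, rrfs,
                            mass_mg = NULL, volume_ml = NULL, dilution = NULL,
                            loqs = NULL) {
  check_columns(peaks, c("analyte", "response"), "peak table")
  if (inherits(epi_slope, "calib_fit")) epi_slope <- epi_slope$slope
  check_number(epi_slope, "epi_slope", min = 0, strict_min = TRUE)
  check_columns(rrfs, c("analyte", "rrf"), "RRF table")

  peaks <- tibble::as_tibble(peaks)
  for (col in c("mass_mg", "volume_ml", "dilution")) {
    override <- switch(col, mass_mg = mass_mg, volume_ml = volume_ml,
                       dilution = dilution)
    if (!is.null(override)) peaks[[col]] <- override
    if (!col %in% names(peaks)) {
      abort(sprintf("`%s` must be a column of `peaks` or given as an argument.",
                    col))
    }
  }
  if (any(peaks$mass_mg <= 0) || any(peaks$volume_ml <= 0)) {
    abort("`mass_mg` and `volume_ml` must be > 0.")
  }
  if (any(peaks$dilution < 1)) abort("`dilution` must be >= 1.")

  rrf_map <- rrfs |>
    dplyr::distinct(.data$analyte, .keep_all = TRUE) |>
    dplyr::select("analyte", "rrf")
  if (!"epicatechin" %in% rrf_map$analyte) {
    rrf_map <- dplyr::bind_rows(rrf_map,
                                tibble::tibble(analyte = "epicatechin", rrf = 1))
  }
  missing <- setdiff(unique(peaks$analyte), rrf_map$analyte)
  if (length(missing) > 0) {
    abort(sprintf("no RRF available for analyte(s): %s.",
                  paste(missing, collapse = ", ")))
  }

  id_cols <- intersect(c("sample_id", "day", "lab", "replicate", "condition",
                         "spike_fraction", "added_mg_per_g"), names(peaks))
  summed <- peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, "analyte",
                                                  "mass_mg", "volume_ml",
                                                  "dilution")))) |>
    dplyr::summarise(response = sum(.data$response), .groups = "drop")

  out <- summed |>
    dplyr::left_join(rrf_map, by = "analyte") |>
    dplyr::mutate(
      conc_ug_per_ml = .data$response / (epi_slope * .data$rrf),
      content_mg_per_g = .data$conc_ug_per_ml * .data$volume_ml *
        .data$dilution / .data$mass_mg
    )
  if (!is.null(loqs)) {
    check_columns(loqs, c("analyte", "loq_ug_per_ml"), "LOQ table")
    out <- out |>
      dplyr::left_join(dplyr::select(loqs, "analyte",
                                     loq_used = "loq_ug_per_ml"),
                       by = "analyte") |>
      dplyr::mutate(below_loq = !is.na(.data$loq_used) &
                      .data$conc_ug_per_ml < .data$loq_used)
  } else {
    out$loq_used <- NA_real_
    out$below_loq <- FALSE
  }
  dplyr::select(out, dplyr::all_of(id_cols), "analyte", "response",
                "conc_ug_per_ml", "content_mg_per_g", "below_loq", "loq_used")
}

#' Total oligomeric content
#'
#' Sums the dp2--dp10 contents of a quantified sample. The monomer class is
#' excluded; results flagged below the LOQ are excluded from the total and
#' reported via a message.
#'
#' @param results Output of [quantify_sample()] for one consistent sample.
#' @param quiet Suppress the below-LOQ exclusion message.
#' @return Total oligomer content in mg/g.
#' @export
total_oligomers <- function(results, quiet = FALSE) {
  check_columns(results, c("analyte", "content_mg_per_g"), "results table")
  olig <- dplyr::filter(results, is_oligomer(.data$analyte))
  below <- if ("below_loq" %in% names(olig)) olig$below_loq else FALSE
  if (any(below) && !quiet) {
    rlang::inform(sprintf("excluding below-LOQ analyte(s) from total: %s",
                          paste(unique(olig$analyte[below]), collapse = ", ")))
  }
  sum(olig$content_mg_per_g[!below])
}
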