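#' Simulation configuration for synthetic detector data
#'
#' Defines the "true" state of the measurement system the synthetic-data
#' generators emulate: the epicatechin calibration slope, the per-dp relative
#' response factors, and the variance structure (proportional detector noise,
#' between-day and between-lab slope multipliers). The defaults mirror the
#' study conditions of the validated method: an 8-level calibration over
#' 5--100 ug/mL with 3 replicates per level on 3 days, the reference RRF
#' ladder, ~2% proportional response noise, and modest day/lab effects.
#'
#' Day and lab effects are log-normal multipliers with mean 1 applied to the
#' detector sensitivity, shared by all analytes within a (day, lab). Because
#' they are common to numerator and denominator, they cancel in RRF slope
#' ratios: the RRF is the quantity that is stable across days and labs,
#' which is the premise of indirect oligomer calibration. The first lab is
#' the reference instrument (multiplier fixed at 1), so its calibration and
#' the sample generators share one detector scale.
#'
#' @param epi_slope True epicatechin calibration slope (response units per
#'   ug/mL). Arbitrary detector scale; quantification is invariant to it.
#' @param rrfs Named numeric vector of true RRFs for the oligomers (values in
#'   (0, 1]); defaults to the reference ladder of [rrf_reference()].
#' @param noise_cv Proportional (multiplicative Gaussian) response noise, as
#'   a fraction.
#' @param day_effect_cv Between-day dispersion of the log-normal sensitivity
#'   multiplier, as a fraction.
#' @param lab_effect_cv Between-lab dispersion of the log-normal sensitivity
#'   multiplier, as a fraction.
#' @param levels Calibration concentrations in ug/mL, strictly positive and
#'   strictly increasing.
#' @param replicates_per_level Replicate injections per level.
#' @param n_days Number of calibration days.
#' @param n_labs Number of laboratories.
#' @param seed Integer seed; every generator is fully deterministic given
#'   the config.
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' head(simulate_calibration(cfg))
sim_config <- function(epi_slope = 10,
                       rrfs = NULL,
                       noise_cv = 0.02,
                       day_effect_cv = 0.03,
                       lab_effect_cv = 0.05,
                       levels = c(5, 10, 20, 30, 40, 50, 75, 100),
                       replicates_per_level = 3,
                       n_days = 3,
                       n_labs = 1,
                       seed = NULL) {
  if (is.null(rrfs)) {
    ref <- rrf_reference()
    rrfs <- setNames(ref$rrf[ref$analyte != "epicatechin"],
                     ref$analyte[ref$analyte != "epicatechin"])
  }
  check_number(epi_slope, "epi_slope", min = 0, strict_min = TRUE)
  if (!is.numeric(rrfs) || is.null(names(rrfs)) || any(!nzchar(names(rrfs)))) {
    abort("`rrfs` must be a named numeric vector (names are analyte ids).")
  }
  if (any(rrfs <= 0 | rrfs > 1)) {
    abort("`rrfs` values must lie in (0, 1].")
  }
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(day_effect_cv, "day_effect_cv", min = 0)
  check_number(lab_effect_cv, "lab_effect_cv", min = 0)
  if (!is.numeric(levels) || length(levels) < 1 || any(levels <= 0)) {
    abort("`levels` must be strictly positive concentrations (ug/mL).")
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    abort("`levels` must be strictly increasing.")
  }
  check_number(replicates_per_level, "replicates_per_level", min = 1)
  check_number(n_days, "n_days", min = 1)
  check_number(n_labs, "n_labs", min = 1)
  if (is.null(seed)) abort("`seed` is required for reproducible simulation.")
  check_number(seed, "seed")

  structure(
    list(
      epi_slope = epi_slope, rrfs = rrfs, noise_cv = noise_cv,
      day_effect_cv = day_effect_cv, lab_effect_cv = lab_effect_cv,
      levels = as.numeric(levels),
      replicates_per_level = as.integer(replicates_per_level),
      n_days = as.integer(n_days), n_labs = as.integer(n_labs),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  epi slope %.3g, %d analytes, levels %s ug/mL\n",
              x$epi_slope, length(x$rrfs) + 1L,
              paste(range(x$levels), collapse = "-")))
  cat(sprintf("  %d day(s) x %d lab(s) x %d rep(s)/level; noise %.1f%%, day %.1f%%, lab %.1f%%; seed %d\n",
              x$n_days, x$n_labs, x$replicates_per_level,
              100 * x$noise_cv, 100 * x$day_effect_cv, 100 * x$lab_effect_cv,
              x$seed))
  invisible(x)
}

# log-normal multiplier with unit mean and the requested CV
rlnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# multiplicative Gaussian detector noise factor
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  1 + stats::rnorm(n, 0, cv)
}

# Draw shared (lab, day) sensitivity multipliers. The first lab is the
# reference instrument (multiplier 1): lab effects are relative to the
# detector scale that `epi_slope` defines, and sample batches (generated
# without a lab effect) are measured on that reference instrument.
draw_effects <- function(config) {
  labs <- paste0("lab", seq_len(config$n_labs))
  days <- paste0("day", seq_len(config$n_days))
  lab_mult <- setNames(rlnorm_mult(config$n_labs, config$lab_effect_cv), labs)
  lab_mult[1] <- 1
  grid <- tidyr::expand_grid(lab = labs, day = days)
  grid$day_mult <- rlnorm_mult(nrow(grid), config$day_effect_cv)
  grid$lab_mult <- lab_mult[grid$lab]
  grid
}

truncate_negative <- function(response, what) {
  n_neg <- sum(response < 0)
  if (n_neg > 0) {
    warn(sprintf("%d simulated %s response(s) were negative and truncated to zero.",
                 n_neg, what))
    response[response < 0] <- 0
  }
  response
}

#' Simulate calibration series
#'
#' Generates replicated (concentration, response) calibration points for the
#' monomer and every oligomer in the config, across days and labs. The
#' response model is
#' `response = conc x epi_slope x RRF x day_mult x lab_mult x (1 + noise)`,
#' with RRF = 1 for epicatechin. Negative responses (unreachable at
#' realistic CVs) are truncated to zero with a warning.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `analyte`, `level_ug_per_ml`, `response`,
#'   `day`, `lab`, `replicate`.
#' @export
simulate_calibration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  effects <- draw_effects(config)
  slopes <- c(epicatechin = 1, config$rrfs) * config$epi_slope

  grid <- tidyr::expand_grid(
    effects,
    analyte = names(slopes),
    level_ug_per_ml = config$levels,
    replicate = seq_len(config$replicates_per_level)
  )
  resp <- grid$level_ug_per_ml * slopes[grid$analyte] *
    grid$day_mult * grid$lab_mult * noise_factor(nrow(grid), config$noise_cv)
  grid |>
    dplyr::mutate(response = truncate_negative(unname(resp), "calibration")) |>
    dplyr::select("analyte", "level_ug_per_ml", "response",
                  "day", "lab", "replicate")
}

#' Sample design for synthetic extract batches
#'
#' Describes one dissolved solid sample: the true analyte contents, the
#' gravimetric/volumetric factors that connect content (mg/g) to measured
#' concentration (ug/mL), and an optional glass-adsorption loss. The default
#' mass/volume (100 mg into a 50 mL flask) matches the optimized dissolution
#' protocol. Adsorption loss removes a fraction
#' `loss = adsorption_loss_per_cm2 x contacted_surface_cm2` of each
#' analyte's concentration before detection; a named coefficient vector
#' restricts the loss to specific analytes (observed in practice for the
#' higher oligomers).
#'
#' @param true_contents Named numeric vector of true contents (mg/g).
#' @param sample_mass_mg Sample mass (mg).
#' @param volume_ml Dissolution volume (mL).
#' @param dilution Extra dilution factor (>= 1); the epicatechin-rich
#'   extract is measured at a 10-fold extra dilution to stay within the
#'   detector's linear range.
#' @param adsorption_loss_per_cm2 Fraction lost per cm2 of contacted glass;
#'   scalar or named per-analyte vector. Default 0.
#' @param contacted_surface_cm2 Contacted glass surface area (cm2).
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(true_contents,
                          sample_mass_mg = 100,
                          volume_ml = 50,
                          dilution = 1,
                          adsorption_loss_per_cm2 = 0,
                          contacted_surface_cm2 = 0) {
  if (!is.numeric(true_contents) || is.null(names(true_contents)) ||
      any(!nzchar(names(true_contents))) || any(true_contents < 0)) {
    abort("`true_contents` must be a named non-negative numeric vector (mg/g).")
  }
  check_number(sample_mass_mg, "sample_mass_mg", min = 0, strict_min = TRUE)
  check_number(volume_ml, "volume_ml", min = 0, strict_min = TRUE)
  check_number(dilution, "dilution", min = 1)
  check_number(contacted_surface_cm2, "contacted_surface_cm2", min = 0)
  loss <- loss_fractions(adsorption_loss_per_cm2, contacted_surface_cm2,
                         names(true_contents))
  if (any(loss < 0 | loss >= 1)) {
    abort("adsorption loss must satisfy 0 <= loss < 1 for every analyte.")
  }
  structure(
    list(true_contents = true_contents, sample_mass_mg = sample_mass_mg,
         volume_ml = volume_ml, dilution = dilution,
         adsorption_loss_per_cm2 = adsorption_loss_per_cm2,
         contacted_surface_cm2 = contacted_surface_cm2),
    class = "sample_design"
  )
}

loss_fractions <- function(coeff, surface, analytes) {
  if (is.null(names(coeff))) {
    check_number(coeff, "adsorption_loss_per_cm2", min = 0)
    setNames(rep(coeff * surface, length(analytes)), analytes)
  } else {
    full <- setNames(rep(0, length(analytes)), analytes)
    unknown <- setdiff(names(coeff), analytes)
    if (length(unknown) > 0) {
      abort(sprintf("adsorption coefficients given for unknown analyte(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    full[names(coeff)] <- coeff * surface
    full
  }
}

# content (mg/g) -> measured concentration (ug/mL) in the injected solution
content_to_conc <- function(content, design) {
  content * design$sample_mass_mg / (design$volume_ml * design$dilution)
}

#' Simulate a replicated sample batch
#'
#' Generates integrated dp-class peak responses for replicate dissolutions
#' of one sample analysed over several days, following the precision-study
#' layout (3 replicates x 3 days by default). True contents are converted
#' to solution concentrations via mass/volume/dilution, reduced by any
#' adsorption loss, and passed through the detector response model with a
#' per-day sensitivity multiplier shared across analytes.
#'
#' @param design A [sample_design()].
#' @param config A [sim_config()]; supplies slope, RRFs, noise and day
#'   effects (labs are not crossed here; a single lab is assumed).
#' @param n_reps Replicates per day.
#' @param n_days Number of analysis days.
#' @return A tibble with columns `sample_id`, `day`, `replicate`, `analyte`,
#'   `response`, `mass_mg`, `volume_ml`, `dilution`.
#' @export
simulate_sample_batch <- function(design, config, n_reps = 3, n_days = 3) {
  stopifnot(inherits(design, "sample_design"), inherits(config, "sim_config"))
  check_number(n_reps, "n_reps", min = 1)
  check_number(n_days, "n_days", min = 1)
  withr::local_seed(config$seed)

  analytes <- names(design$true_contents)
  slopes <- c(epicatechin = 1, config$rrfs) * config$epi_slope
  missing_rrf <- setdiff(analytes, names(slopes))
  if (length(missing_rrf) > 0) {
    abort(sprintf("config has no RRF for analyte(s): %s.",
                  paste(missing_rrf, collapse = ", ")))
  }
  loss <- loss_fractions(design$adsorption_loss_per_cm2,
                         design$contacted_surface_cm2, analytes)
  conc <- content_to_conc(design$true_contents, design) * (1 - loss)

  days <- paste0("day", seq_len(n_days))
  day_mult <- setNames(rlnorm_mult(n_days, config$day_effect_cv), days)
  grid <- tidyr::expand_grid(day = days, replicate = seq_len(n_reps),
                             analyte = analytes)
  resp <- conc[grid$analyte] * slopes[grid$analyte] * day_mult[grid$day] *
    noise_factor(nrow(grid), config$noise_cv)
  grid |>
    dplyr::mutate(
      sample_id = "sample1",
      response = truncate_negative(unname(resp), "sample"),
      mass_mg = design$sample_mass_mg,
      volume_ml = design$volume_ml,
      dilution = design$dilution
    ) |>
    dplyr::select("sample_id", "day", "replicate", "analyte", "response",
                  "mass_mg", "volume_ml", "dilution")
}

#' Simulate a spiking (fortification) experiment
#'
#' Emits replicate peak responses for an unfortified sample and for samples
#' fortified at the given fractions of the expected content (default 100%
#' and 200%), recording the added amount per analyte so recovery can be
#' computed after quantification. All conditions share one analysis day.
#'
#' @param design A [sample_design()] for the base (unfortified) sample.
#' @param config A [sim_config()].
#' @param spike_levels Spike fractions of the expected content; `c(1, 2)`
#'   reproduces the ~100%/200% fortification design.
#' @param n_reps Replicates per condition.
#' @return A tibble with columns `condition` (e.g. `"0%"`, `"100%"`),
#'   `spike_fraction`, `replicate`, `analyte`, `response`,
#'   `added_mg_per_g`, `mass_mg`, `volume_ml`, `dilution`.
#' @export
simulate_spiking <- function(design, config, spike_levels = c(1, 2),
                             n_reps = 3) {
  stopifnot(inherits(design, "sample_design"), inherits(config, "sim_config"))
  if (length(spike_levels) < 1 || any(spike_levels <= 0)) {
    abort("`spike_levels` must be a nonempty vector of positive fractions.")
  }
  check_number(n_reps, "n_reps", min = 1)
  withr::local_seed(config$seed)

  analytes <- names(design$true_contents)
  slopes <- c(epicatechin = 1, config$rrfs) * config$epi_slope
  loss <- loss_fractions(design$adsorption_loss_per_cm2,
                         design$contacted_surface_cm2, analytes)
  day_mult <- rlnorm_mult(1, config$day_effect_cv)

  fractions <- c(0, spike_levels)
  grid <- tidyr::expand_grid(spike_fraction = fractions,
                             replicate = seq_len(n_reps),
                             analyte = analytes)
  content <- design$true_contents[grid$analyte] * (1 + grid$spike_fraction)
  conc <- content * design$sample_mass_mg /
    (design$volume_ml * design$dilution) * (1 - loss[grid$analyte])
  resp <- conc * slopes[grid$analyte] * day_mult *
    noise_factor(nrow(grid), config$noise_cv)
  grid |>
    dplyr::mutate(
      condition = sprintf("%d%%", round(100 * .data$spike_fraction)),
      response = truncate_negative(unname(resp), "spiking"),
      added_mg_per_g = unname(design$true_contents[.data$analyte] *
                                .data$spike_fraction),
      mass_mg = design$sample_mass_mg,
      volume_ml = design$volume_ml,
      dilution = design$dilution
    ) |>
    dplyr::select("condition", "spike_fraction", "replicate", "analyte",
                  "response", "added_mg_per_g", "mass_mg", "volume_ml",
                  "dilution")
}

#' Simulate an extract stability time series
#'
#' Contents drift linearly in time,
#' `value(t) = content0 x (1 + drift x t) x (1 + noise)`,
#' and are reported directly in mg/g at the requested timepoints (the
#' default grid 0/48/96/168 h matches the one-week stability window).
#'
#' @param design A [sample_design()]; its `true_contents` are the 0 h values.
#' @param config A [sim_config()]; only `noise_cv` and `seed` are used.
#' @param timepoints_h Measurement times in hours; must include 0.
#' @param drift_per_h Fractional drift per hour; scalar or named per-analyte
#'   vector (e.g. `-4e-4` loses ~6.7% over 168 h).
#' @return A tibble with columns `analyte`, `timepoint_h`, `value` (mg/g).
#' @export
simulate_stability <- function(design, config,
                               timepoints_h = c(0, 48, 96, 168),
                               drift_per_h = 0) {
  stopifnot(inherits(design, "sample_design"), inherits(config, "sim_config"))
  if (!0 %in% timepoints_h) abort("`timepoints_h` must include 0.")
  withr::local_seed(config$seed)

  analytes <- names(design$true_contents)
  drift <- if (is.null(names(drift_per_h))) {
    setNames(rep(drift_per_h, length(analytes)), analytes)
  } else {
    full <- setNames(rep(0, length(analytes)), analytes)
    full[intersect(names(drift_per_h), analytes)] <-
      drift_per_h[intersect(names(drift_per_h), analytes)]
    full
  }
  grid <- tidyr::expand_grid(analyte = analytes,
                             timepoint_h = sort(timepoints_h))
  value <- design$true_contents[grid$analyte] *
    (1 + drift[grid$analyte] * grid$timepoint_h) *
    noise_factor(nrow(grid), config$noise_cv)
  grid |>
    dplyr::mutate(value = pmax(unname(value), 0)) |>
    dplyr::select("analyte", "timepoint_h", "value")
}

#' Simulate an inter-laboratory study
#'
#' Generates per-lab results for one material with between-lab and
#' within-lab (day, replicate) variance components, plus an optional planted
#' outlier lab whose results are shifted by a multiple of the between-lab
#' SD. Used to exercise consensus statistics, z-scores and the control-QC
#' gate.
#'
#' @param true_value True consensus value (mg/g).
#' @param n_labs Number of laboratories.
#' @param lab_cv Between-lab CV (fraction).
#' @param day_cv Between-day CV within lab (fraction).
#' @param rep_cv Replicate CV (fraction).
#' @param n_days,n_reps Days and replicates per day per lab (2 x 3 mirrors
#'   the collaborative-trial design).
#' @param outlier_lab Optional lab index to displace.
#' @param outlier_shift_sd Shift of the outlier lab's mean, in units of the
#'   between-lab SD (`true_value x lab_cv`).
#' @param seed Integer seed.
#' @return A tibble with columns `lab`, `day`, `replicate`, `value`.
#' @export
simulate_interlab <- function(true_value, n_labs = 8, lab_cv = 0.05,
                              day_cv = 0.02, rep_cv = 0.03,
                              n_days = 2, n_reps = 3,
                              outlier_lab = NULL, outlier_shift_sd = 0,
                              seed = NULL) {
  check_number(true_value, "true_value", min = 0, strict_min = TRUE)
  check_number(n_labs, "n_labs", min = 2)
  if (is.null(seed)) abort("`seed` is required.")
  withr::local_seed(as.integer(seed))

  labs <- seq_len(n_labs)
  lab_mean <- true_value * rlnorm_mult(n_labs, lab_cv)
  if (!is.null(outlier_lab)) {
    lab_mean[outlier_lab] <- lab_mean[outlier_lab] +
      outlier_shift_sd * true_value * lab_cv
  }
  grid <- tidyr::expand_grid(lab = labs, day = seq_len(n_days))
  grid$day_mult <- rlnorm_mult(nrow(grid), day_cv)
  grid <- tidyr::expand_grid(grid, replicate = seq_len(n_reps))
  grid$value <- lab_mean[grid$lab] * grid$day_mult *
    noise_factor(nrow(grid), rep_cv)
  dplyr::select(grid, "lab", "day", "replicate", "value")
}
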