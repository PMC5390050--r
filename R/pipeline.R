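#' Default extract composition for pipeline scenarios
#'
#' Realistic true contents (mg/g) of a procyanidin-rich apple extract:
#' ~1% monomers and a broad oligomer distribution peaking around dp4--dp7,
#' totalling roughly 60% procyanidins by mass.
#'
#' @return Named numeric vector of contents (mg/g).
#' @export
default_contents <- function() {
  c(epicatechin = 12.9, dp2 = 40.6, dp3 = 45.1, dp4 = 82.0, dp5 = 77.1,
    dp6 = 93.5, dp7 = 78.6, dp8 = 71.5, dp9 = 61.6, dp10 = 54.9)
}

#' Read a pipeline run configuration from YAML
#'
#' Loads a YAML file whose top-level keys mirror the arguments of
#' [run_pipeline()] (`seed`, `out_dir`, `sim`, `sample`, `n_reps`,
#' `n_days`, `spike_levels`, `k`, `loq_policy`). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A named list suitable for `do.call(run_pipeline, ...)`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "out_dir", "sim", "sample", "n_reps", "n_days",
               "spike_levels", "k", "loq_policy")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) abort("config must set `seed`.")
  if (!is.null(cfg$sample$true_contents)) {
    cfg$sample$true_contents <- unlist(cfg$sample$true_contents)
  }
  cfg
}

#' Run the quantification-and-validation pipeline end to end
#'
#' Executes the full method sequence on a simulated scenario:
#' calibrate (per-day fits, zero-forcing decision, lack-of-fit, LOQ) ->
#' determine RRFs -> quantify a replicated sample batch -> validate
#' (ANOVA precision, spike recovery, stability, per-analyte expanded
#' uncertainty). Every stage's output is returned as a tibble; with
#' `out_dir` set, each is also written as a CSV in the pipeline dialect.
#' The run is fully deterministic given `seed`.
#'
#' The uncertainty budget takes `u_rep(RRF)` from the simulated across-day
#' RRF RSDs, `u_il(RRF)` from the dispersion of the two reference-lab RRF
#' sets, `u_r`/`u_ip` from the precision stage with `n1 = n_reps x n_days`
#' and `n2 = n_days`, and `u_rec` from the spiking stage; `u_bias` is
#' evaluated for the monomer from a simulated control measurement.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param out_dir Optional output directory for per-stage CSVs.
#' @param sim Named list of [sim_config()] overrides.
#' @param sample Named list of [sample_design()] overrides.
#' @param n_reps,n_days Replicates/days of the precision batch.
#' @param spike_levels Fortification fractions for the recovery stage.
#' @param k Coverage factor for the expanded uncertainty.
#' @param loq_policy `"lowest-level"` (clamp to the lowest calibration
#'   level, the reporting default) or `"theoretical"`.
#' @param quiet Suppress stage log messages.
#' @return An object of class `rrf_pipeline`: a list of tibbles
#'   (`calibration`, `zero_forcing`, `lack_of_fit`, `loq`, `rrf`,
#'   `results`, `precision`, `recovery`, `stability`, `uncertainty`,
#'   `summary`).
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(seed = 1, quiet = TRUE)
#' run$summary
#' }
run_pipeline <- function(seed, out_dir = NULL, sim = list(), sample = list(),
                         n_reps = 3, n_days = 3, spike_levels = c(1, 2),
                         k = 2, loq_policy = c("lowest-level", "theoretical"),
                         quiet = FALSE) {
  loq_policy <- match.arg(loq_policy)
  check_number(seed, "seed")
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))

  config <- do.call(sim_config, utils::modifyList(list(seed = as.integer(seed)),
                                                  sim))
  if (is.null(sample$true_contents)) sample$true_contents <- default_contents()
  design <- do.call(sample_design, sample)

  # --- calibrate -------------------------------------------------------
  say("stage calibrate: simulating %d-day calibration (seed %d)",
      config$n_days, config$seed)
  cal <- simulate_calibration(config)
  epi_all <- dplyr::filter(cal, .data$analyte == "epicatechin",
                           .data$lab == "lab1")
  free_fit <- fit_calibration(epi_all)
  zf <- decide_zero_forcing(free_fit, quiet = quiet)
  force_zero <- zf$force_zero
  say("stage calibrate: zero-forcing %s",
      if (force_zero) "applied" else "not applied")
  lof <- lack_of_fit_test(epi_all, force_zero = force_zero)
  fits <- fit_calibrations(cal, force_zero = force_zero)

  epi_fit <- fit_calibration(epi_all, force_zero = force_zero)
  loq_theoretical <- loq(epi_fit)
  lowest <- tibble::tibble(analyte = analyte_roster(),
                           lowest_level = min(config$levels))
  loq_tbl <- lowest |>
    dplyr::mutate(
      loq_theoretical = loq_theoretical,
      loq_ug_per_ml = if (loq_policy == "lowest-level") {
        clamp_loq(loq_theoretical, .data$lowest_level)
      } else {
        loq_theoretical
      }
    )
  say("stage calibrate: theoretical LOQ %.3g ug/mL, policy %s",
      loq_theoretical, loq_policy)

  # --- RRFs ------------------------------------------------------------
  rrf <- compute_rrf_table(cal, force_zero = force_zero, keep_daily = TRUE)
  rrf_lab <- dplyr::filter(rrf, .data$lab == "lab1")
  u_il <- rrf_dispersion_across_labs(
    dplyr::bind_rows(
      dplyr::select(rrf_reference("lab2"), "analyte", "rrf", "lab"),
      dplyr::select(rrf_reference("lab1"), "analyte", "rrf", "lab")
    )
  )
  say("stage rrf: %d analytes, dp2 RRF %.3f", nrow(rrf_lab),
      rrf_lab$rrf[rrf_lab$analyte == "dp2"])

  # --- quantify --------------------------------------------------------
  batch <- simulate_sample_batch(design, config, n_reps = n_reps,
                                 n_days = n_days)
  results <- quantify_sample(batch, epi_fit, rrf_lab,
                             loqs = loq_tbl["analyte"] |>
                               dplyr::mutate(loq_ug_per_ml =
                                               loq_tbl$loq_ug_per_ml))
  say("stage quantify: %d results, %d below LOQ", nrow(results),
      sum(results$below_loq))

  # --- validate --------------------------------------------------------
  precision <- results |>
    dplyr::select("analyte", "day", value = "content_mg_per_g") |>
    precision_anova()

  spiked <- simulate_spiking(design, config, spike_levels = spike_levels)
  spiked_q <- quantify_sample(spiked, epi_fit, rrf_lab) |>
    dplyr::rename(added = "added_mg_per_g")
  recovery <- spiked_q |>
    dplyr::select("analyte", value = "content_mg_per_g", "added") |>
    spike_recovery()

  stab <- simulate_stability(design, config) |>
    dplyr::left_join(
      dplyr::select(precision, "analyte",
                    ip = "intermediate_rsd") |>
        dplyr::mutate(ip = .data$ip / 100),
      by = "analyte"
    ) |>
    stability_assess()

  # control-sample bias for the monomer (simulated CRM measurement)
  control_design <- sample_design(true_contents = c(epicatechin = 4.0),
                                  sample_mass_mg = design$sample_mass_mg,
                                  volume_ml = design$volume_ml)
  control <- simulate_sample_batch(control_design, config, n_reps = 2,
                                   n_days = 2) |>
    quantify_sample(epi_fit, rrf_lab)
  u_bias_epi <- bias_from_control(control$content_mg_per_g,
                                  reference_value = 4.0,
                                  reference_uncertainty = 0.08)

  budget_in <- precision |>
    dplyr::left_join(dplyr::select(rrf_lab, "analyte",
                                   u_rep_rrf = "rsd_percent"),
                     by = "analyte") |>
    dplyr::left_join(dplyr::select(u_il, "analyte", "u_il_rrf"),
                     by = "analyte") |>
    dplyr::left_join(dplyr::select(recovery, "analyte", "u_rec"),
                     by = "analyte") |>
    dplyr::mutate(
      u_rep_rrf = dplyr::coalesce(.data$u_rep_rrf, 0),
      u_il_rrf = dplyr::coalesce(.data$u_il_rrf, 0),
      u_rec = dplyr::coalesce(.data$u_rec, 0),
      u_bias = ifelse(.data$analyte == "epicatechin", u_bias_epi, 0)
    )
  uncertainty <- budget_in |>
    dplyr::mutate(expanded_uncertainty(
      u_rep_rrf = .data$u_rep_rrf, u_il_rrf = .data$u_il_rrf,
      u_r = .data$repeatability_rsd, u_ip = .data$intermediate_rsd,
      n1 = n_reps * n_days, n2 = n_days,
      u_bias = .data$u_bias, u_rec = .data$u_rec, k = k
    )[c("u_combined", "U")]) |>
    dplyr::select("analyte", "u_rep_rrf", "u_il_rrf",
                  u_r = "repeatability_rsd", u_ip = "intermediate_rsd",
                  "u_bias", "u_rec", "u_combined", "U")

  summary <- results |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(content_mg_per_g = mean(.data$content_mg_per_g),
                     below_loq = any(.data$below_loq), .groups = "drop") |>
    dplyr::left_join(dplyr::select(rrf_lab, "analyte", "rrf"), by = "analyte") |>
    dplyr::left_join(dplyr::select(loq_tbl, "analyte", "loq_ug_per_ml"),
                     by = "analyte") |>
    dplyr::left_join(dplyr::select(precision, "analyte",
                                   u_r = "repeatability_rsd",
                                   u_ip = "intermediate_rsd"),
                     by = "analyte") |>
    dplyr::left_join(dplyr::select(recovery, "analyte", "recovery"),
                     by = "analyte") |>
    dplyr::left_join(dplyr::select(uncertainty, "analyte", "U"),
                     by = "analyte")

  out <- structure(
    list(
      calibration = fits, zero_forcing = zf, lack_of_fit = lof,
      loq = loq_tbl, rrf = rrf_lab, results = results,
      precision = precision, recovery = recovery, stability = stab,
      uncertainty = uncertainty, summary = summary,
      seed = as.integer(seed)
    ),
    class = "rrf_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("calibration", "zero_forcing", "lack_of_fit", "loq", "rrf",
                 "results", "precision", "recovery", "stability",
                 "uncertainty", "summary")) {
      write_table(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    say("report bundle written to %s", out_dir)
  }
  out
}

#' @export
print.rrf_pipeline <- function(x, ...) {
  cat(sprintf("<rrf_pipeline> seed %d\n", x$seed))
  cat(sprintf("  %d analytes quantified; zero-forcing %s; linear_ok %s\n",
              nrow(x$summary),
              ifelse(x$zero_forcing$force_zero, "applied", "not applied"),
              x$lack_of_fit$linear_ok))
  print(x$summary)
  invisible(x)
}
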