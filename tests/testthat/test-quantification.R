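test_that("daily RRF is the slope ratio and rejects mismatched series", {
  dp <- fit_calibration(exact_series(slope = 5), force_zero = TRUE)
  epi <- fit_calibration(exact_series(slope = 10), force_zero = TRUE)
  expect_equal(daily_rrf(dp, epi), 0.5)

  d1 <- exact_series(); d1$day <- "day1"
  d2 <- exact_series(); d2$day <- "day2"
  expect_error(daily_rrf(fit_calibration(d1), fit_calibration(d2)), "mismatch")
})

test_that("mean-of-means RRF is the arithmetic mean with n-1 RSD", {
  mm <- mean_of_means_rrf(c(0.5, 0.5, 0.5))
  expect_equal(mm$rrf, 0.5)
  expect_equal(mm$rsd_percent, 0)

  mm2 <- mean_of_means_rrf(c(0.58, 0.59, 0.59))
  expect_equal(round(mm2$rrf, 3), 0.587)
  expect_equal(mm2$rsd_percent, 100 * sd(c(0.58, 0.59, 0.59)) / mean(c(0.58, 0.59, 0.59)))
  expect_true(is.na(mean_of_means_rrf(0.5)$rsd_percent))
})

test_that("RRF table equals brute-force daily slope ratios", {
  cfg <- sim_config(seed = 61, n_days = 3)
  cal <- simulate_calibration(cfg)
  tbl <- compute_rrf_table(cal, force_zero = TRUE)

  # brute force: per-day no-intercept slopes, ratio, plain mean
  brute <- sapply(paste0("dp", 2:10), function(a) {
    mean(sapply(paste0("day", 1:3), function(d) {
      sub <- function(an) cal[cal$analyte == an & cal$day == d, ]
      s <- function(df) sum(df$level_ug_per_ml * df$response) /
        sum(df$level_ug_per_ml^2)
      s(sub(a)) / s(sub("epicatechin"))
    }))
  })
  got <- setNames(tbl$rrf, tbl$analyte)[names(brute)]
  expect_equal(unname(got), unname(brute), tolerance = 1e-10)
})

test_that("simulated RRF determination recovers the reference ladder", {
  truth <- setNames(rrf_reference()$rrf, rrf_reference()$analyte)
  cfg <- sim_config(noise_cv = 0.02, seed = 71)
  tbl <- compute_rrf_table(simulate_calibration(cfg), force_zero = TRUE)
  rel_err <- abs(tbl$rrf - truth[tbl$analyte]) / truth[tbl$analyte]
  # slope-ratio noise at 2% point noise is well under 2% relative
  expect_true(all(rel_err < 0.02))
})

test_that("across-lab RRF dispersion splits within- and between-lab spread", {
  # identical labs: between-lab component vanishes
  same <- data.frame(lab = rep(c("a", "b"), each = 2),
                     analyte = "dp2", rrf_daily = rep(c(0.5, 0.52), 2))
  disp <- rrf_dispersion_across_labs(same)
  expect_equal(disp$u_il_rrf, 0, tolerance = 1e-12)

  # the two reference labs for dp2: u_il = 100 * sd / mean
  two <- dplyr::bind_rows(rrf_reference("lab1"), rrf_reference("lab2"))
  disp2 <- rrf_dispersion_across_labs(two[c("lab", "analyte", "rrf")])
  dp2 <- disp2[disp2$analyte == "dp2", ]
  expect_equal(dp2$u_il_rrf, 100 * sd(c(0.489, 0.587)) / mean(c(0.489, 0.587)))
  expect_equal(round(dp2$u_il_rrf, 1), 12.9)

  expect_error(rrf_dispersion_across_labs(rrf_reference()[c("lab", "analyte", "rrf")]),
               "2 labs")
})

test_that("between-lab effect size is recovered from multi-lab simulation", {
  # lab multipliers at 5% CV; u_il across 6 labs should estimate ~5%
  ests <- vapply(1:20, function(i) {
    cfg <- sim_config(lab_effect_cv = 0.05, n_labs = 6, n_days = 2,
                      noise_cv = 0.01, rrfs = c(dp2 = 0.587), seed = 100 + i)
    cal <- simulate_calibration(cfg)
    slopes <- fit_calibrations(cal, force_zero = TRUE)
    epi <- slopes[slopes$analyte == "epicatechin",
                  c("day", "lab", "slope")]
    names(epi)[3] <- "epi_slope"
    daily <- merge(slopes[slopes$analyte == "dp2", ], epi,
                   by = c("day", "lab"))
    daily$rrf_daily <- daily$slope / daily$epi_slope
    # lab effects cancel in the ratio, so measure dispersion on epi slopes
    lab_means <- tapply(daily$epi_slope, daily$lab, mean)
    100 * sd(lab_means) / mean(lab_means)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 5), 1.5)
})

test_that("quantification follows the unit arithmetic of the dilution chain", {
  peaks <- data.frame(analyte = "dp2", response = 200)
  res <- quantify_sample(peaks, epi_slope = 10,
                         rrfs = data.frame(analyte = "dp2", rrf = 0.5),
                         mass_mg = 100, volume_ml = 50, dilution = 1)
  expect_equal(res$conc_ug_per_ml, 40)
  expect_equal(res$content_mg_per_g, 20)

  res10 <- quantify_sample(peaks, epi_slope = 10,
                           rrfs = data.frame(analyte = "dp2", rrf = 0.5),
                           mass_mg = 100, volume_ml = 50, dilution = 10)
  expect_equal(res10$content_mg_per_g, 200)
})

test_that("quantification is invariant to rescaling the detector", {
  cfg <- sim_config(seed = 8, n_days = 1)
  des <- sample_design(default_contents())
  b <- simulate_sample_batch(des, cfg, n_reps = 2, n_days = 1)
  q1 <- quantify_sample(b, epi_slope = 10, rrfs = rrf_reference())
  b2 <- b; b2$response <- b2$response * 3.7
  q2 <- quantify_sample(b2, epi_slope = 37, rrfs = rrf_reference())
  expect_equal(q1$content_mg_per_g, q2$content_mg_per_g, tolerance = 1e-12)
})

test_that("per-isomer rows within a dp class are summed before quantification", {
  peaks <- data.frame(analyte = c("dp2", "dp2"), response = c(120, 80))
  res <- quantify_sample(peaks, epi_slope = 10,
                         rrfs = data.frame(analyte = "dp2", rrf = 0.5),
                         mass_mg = 100, volume_ml = 50, dilution = 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$conc_ug_per_ml, 40)
})

test_that("missing RRFs and invalid factors are rejected", {
  peaks <- data.frame(analyte = "dp9", response = 10)
  expect_error(quantify_sample(peaks, 10, data.frame(analyte = "dp2", rrf = 0.5),
                               mass_mg = 100, volume_ml = 50, dilution = 1),
               "dp9")
  expect_error(quantify_sample(data.frame(analyte = "dp2", response = 1), 10,
                               rrf_reference(), mass_mg = 0, volume_ml = 50,
                               dilution = 1),
               "mass_mg")
})

test_that("LOQ flagging marks, retains and excludes from totals", {
  peaks <- data.frame(analyte = c("epicatechin", "dp2", "dp10"),
                      response = c(1000, 500, 1))
  res <- quantify_sample(peaks, epi_slope = 10, rrfs = rrf_reference(),
                         mass_mg = 100, volume_ml = 50, dilution = 1,
                         loqs = loq_reference())
  expect_true(res$below_loq[res$analyte == "dp10"])
  expect_false(any(res$below_loq[res$analyte != "dp10"]))
  expect_equal(nrow(res), 3)  # flagged, not dropped

  tot <- suppressMessages(total_oligomers(res))
  dp2_only <- res$content_mg_per_g[res$analyte == "dp2"]
  expect_equal(tot, dp2_only)  # monomer and below-LOQ dp10 excluded
  expect_message(total_oligomers(res), "dp10")
})

test_that("total oligomers sums dp2..dp10 and excludes the monomer", {
  res <- data.frame(analyte = analyte_roster(), content_mg_per_g = 1,
                    below_loq = FALSE)
  expect_equal(total_oligomers(res), 9)
})
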