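test_that("identical measurements give zero precision RSDs", {
  d <- data.frame(day = rep(1:3, each = 3), value = 5)
  p <- precision_anova(d)
  expect_equal(p$repeatability_rsd, 0, tolerance = 1e-12)
  expect_equal(p$intermediate_rsd, 0, tolerance = 1e-12)
})

test_that("precision ANOVA matches a hand-worked variance partition", {
  d <- data.frame(day = rep(1:3, each = 3),
                  value = c(10.1, 10.3, 10.2, 10.8, 10.9, 11.0, 9.9, 9.8, 10.0))
  p <- precision_anova(d)

  # manual one-way ANOVA, 3 days x 3 reps
  day_means <- tapply(d$value, d$day, mean)
  grand <- mean(d$value)
  ss_between <- 3 * sum((day_means - grand)^2)
  ss_within <- sum((d$value - rep(day_means, each = 3))^2)
  ms_between <- ss_between / 2
  ms_within <- ss_within / 6
  s_r2 <- ms_within
  s_d2 <- max(0, (ms_between - ms_within) / 3)
  expect_equal(p$s_r, sqrt(s_r2), tolerance = 1e-10)
  expect_equal(p$s_day, sqrt(s_d2), tolerance = 1e-10)
  expect_equal(p$repeatability_rsd, 100 * sqrt(s_r2) / grand, tolerance = 1e-10)
  expect_equal(p$intermediate_rsd, 100 * sqrt(s_r2 + s_d2) / grand,
               tolerance = 1e-10)
})

test_that("negative between-day components truncate to zero", {
  # days identical in mean, large replicate spread: MS_between < MS_within
  withr::local_seed(9)
  d <- data.frame(day = rep(1:3, each = 20),
                  value = rep(c(10, 10, 10), each = 20) + rnorm(60, 0, 2))
  p <- precision_anova(d)
  if (p$day_component_truncated) {
    expect_equal(p$s_day, 0)
    expect_equal(p$intermediate_rsd, p$repeatability_rsd)
  }
  expect_gte(p$intermediate_rsd, p$repeatability_rsd)
})

test_that("precision ANOVA recovers planted variance components", {
  withr::local_seed(33)
  n_days <- 50; n_reps <- 10
  day_eff <- rnorm(n_days, 0, 0.04)
  d <- data.frame(day = rep(seq_len(n_days), each = n_reps))
  d$value <- 10 * (1 + day_eff[d$day]) * (1 + rnorm(nrow(d), 0, 0.03))
  p <- precision_anova(d)
  expect_lt(abs(p$repeatability_rsd - 3) / 3, 0.2)
  expect_lt(abs(sqrt(p$intermediate_rsd^2 - p$repeatability_rsd^2) - 4) / 4, 0.2)
})

test_that("precision edge cases error out explicitly", {
  expect_error(precision_anova(data.frame(day = 1, value = 1)), "single")
  expect_error(precision_anova(data.frame(day = c(1, 1, 1), value = c(1, 2, 3))),
               "single day")
  expect_error(precision_anova(data.frame(day = 1:3, value = c(1, 2, 3))),
               "replicates")
})

test_that("recovery is exact when found minus base equals added", {
  d <- data.frame(value = c(10, 10, 10, 15, 15, 20, 20),
                  added = c(0, 0, 0, 5, 5, 10, 10))
  r <- spike_recovery(d)
  expect_equal(r$recovery, 100)
  expect_equal(r$u_rec, 0)
})

test_that("a systematic 20% loss yields ~80% recovery", {
  withr::local_seed(15)
  added <- rep(c(10, 20), each = 3)
  found <- 10 + 0.8 * added + rnorm(6, 0, 0.05)
  d <- data.frame(value = c(rep(10, 3), found),
                  added = c(rep(0, 3), added))
  r <- spike_recovery(d)
  expect_lt(abs(r$recovery - 80), 2)
})

test_that("recovery is invariant to adding a constant to all values", {
  withr::local_seed(25)
  d <- data.frame(value = c(10.1, 9.9, 10.0, 15.2, 14.8, 19.9, 20.3),
                  added = c(0, 0, 0, 5, 5, 10, 10))
  d2 <- d; d2$value <- d2$value + 100
  expect_equal(spike_recovery(d)$recovery, spike_recovery(d2)$recovery,
               tolerance = 1e-10)
  expect_equal(spike_recovery(d)$u_rec, spike_recovery(d2)$u_rec,
               tolerance = 1e-10)
})

test_that("single-point recovery variant works on one spike level", {
  d <- data.frame(value = c(10, 10, 19.0, 19.2, 18.8), added = c(0, 0, 10, 10, 10))
  r <- spike_recovery(d)
  expect_equal(r$n_spiked, 3)
  expect_equal(r$recovery, mean(100 * (c(19.0, 19.2, 18.8) - 10) / 10))
})

test_that("bias from a control material combines deviation and reference u", {
  expect_equal(bias_from_control(c(3, 3, 3), 3, 0), 0)
  expect_equal(bias_from_control(c(2.9, 2.9), 3.0, 0), 100 * 0.1 / 3)
  u <- bias_from_control(c(2.9, 2.9), 3.0, 0.06)
  expect_equal(u, 100 * sqrt((0.1 / 3)^2 + (0.06 / 3)^2))
  expect_error(bias_from_control(c(3, 3), 0), "reference_value")
})

test_that("defatting rescales the reference value by the residual mass", {
  expect_equal(defatted_reference(2.0, 0.5), 4.0)
  expect_equal(defatted_reference(3.0, 0), 3.0)
  expect_error(defatted_reference(2.0, 1), "fat_fraction")
})

test_that("expanded uncertainty matches the closed form", {
  expect_equal(expanded_uncertainty()$U, 0)
  u <- expanded_uncertainty(u_r = 6, u_ip = 2, n1 = 9, n2 = 3)
  expect_equal(u$U, 2 * sqrt(36 / 9 + 4 / 3), tolerance = 1e-12)
  expect_equal(round(u$U, 2), 4.62)
})

test_that("expanded uncertainty is strictly monotone in every component", {
  base <- list(u_rep_rrf = 3, u_il_rrf = 4, u_r = 5, u_ip = 6, n1 = 9, n2 = 3,
               u_bias = 2, u_rec = 7, k = 2)
  u0 <- do.call(expanded_uncertainty, base)$U
  for (comp in c("u_rep_rrf", "u_il_rrf", "u_r", "u_ip", "u_bias", "u_rec")) {
    bumped <- base
    bumped[[comp]] <- bumped[[comp]] + 1
    expect_gt(do.call(expanded_uncertainty, bumped)$U, u0)
  }
})

test_that("invalid uncertainty inputs are rejected", {
  expect_error(expanded_uncertainty(u_r = -1), "u_r")
  expect_error(expanded_uncertainty(n1 = 0), "n1")
  expect_error(expanded_uncertainty(k = 0), "k")
})

test_that("stability reference rows reproduce delta and half-width", {
  v <- stability_assess(stability_reference())
  dp7 <- v[v$analyte == "dp7", ]
  expect_equal(dp7$delta, -5.3, tolerance = 1e-9)
  expect_equal(round(dp7$acceptable_halfwidth, 2), 1.56)
  dp4 <- v[v$analyte == "dp4", ]
  expect_equal(round(dp4$acceptable_halfwidth, 2), 4.02)
})

test_that("constant stability series is stable with zero delta", {
  d <- data.frame(analyte = "dp2", timepoint_h = c(0, 48, 96, 168), value = 40)
  v <- stability_assess(d, ip = 0.05)
  expect_equal(v$delta, 0)
  expect_true(v$stable)
})

test_that("stability requires the 0 h anchor and an ip fraction", {
  d <- data.frame(analyte = "dp2", timepoint_h = c(48, 96), value = c(40, 41))
  expect_error(stability_assess(d, ip = 0.05), "0 h")
  d2 <- data.frame(analyte = "dp2", timepoint_h = c(0, 96), value = c(40, 41))
  expect_error(stability_assess(d2), "ip")
})
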