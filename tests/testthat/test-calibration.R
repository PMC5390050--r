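test_that("an exact line through the origin is fitted exactly", {
  fit <- fit_calibration(exact_series(slope = 10), force_zero = TRUE)
  expect_equal(fit$slope, 10)
  expect_equal(fit$sigma, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_identical(fit$intercept, 0)
  expect_true(fit$zero_forced)
})

test_that("forced-zero slope equals the closed form sum(xy)/sum(x^2)", {
  withr::local_seed(7)
  for (i in 1:20) {
    d <- noisy_series(slope = runif(1, 1, 20), intercept = rnorm(1, 0, 5),
                      sd = runif(1, 0.1, 3))
    fit <- fit_calibration(d, force_zero = TRUE)
    expect_equal(fit$slope,
                 sum(d$level_ug_per_ml * d$response) / sum(d$level_ug_per_ml^2),
                 tolerance = 1e-10)
  }
})

test_that("noisy fits agree with the textbook least-squares oracle", {
  withr::local_seed(21)
  d <- noisy_series(slope = 10, intercept = 2, levels = c(5, 10, 20, 30, 40, 50, 75),
                    reps = 3, sd = 1)
  fit <- fit_calibration(d)
  x <- d$level_ug_per_ml; y <- d$response; n <- length(x)
  # independent closed-form OLS
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - b0 - b1 * x
  s <- sqrt(sum(resid^2) / (n - 2))
  expect_equal(fit$slope, b1, tolerance = 1e-10)
  expect_equal(fit$intercept, b0, tolerance = 1e-10)
  expect_equal(fit$sigma, s, tolerance = 1e-10)
  # slope lands within 3 standard errors of truth
  expect_lt(abs(fit$slope - 10), 3 * fit$se_slope)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(level_ug_per_ml = c(5, 5, 5),
                                          response = c(50, 51, 49))),
               "distinct")
  expect_error(fit_calibration(data.frame(level_ug_per_ml = c(1, 2, 3),
                                          response = c(7, 7, 7))),
               "degenerate")
})

test_that("simulated epicatechin day-series achieves r > 0.999 at method-scale noise", {
  cfg <- sim_config(seed = 31)
  cal <- simulate_calibration(cfg)
  day1 <- cal[cal$analyte == "epicatechin" & cal$day == "day1", ]
  fit <- fit_calibration(day1)
  expect_gt(fit$r, 0.999)
})

test_that("zero-forcing decision follows the intercept t-test", {
  # perfect line through the origin: no evidence against b = 0
  withr::local_seed(3)
  d <- noisy_series(slope = 10, intercept = 0, sd = 0.5)
  fit <- fit_calibration(d)
  expect_true(decide_zero_forcing(fit, quiet = TRUE)$force_zero)

  # intercept 50x its standard error: forcing must be refused
  d2 <- noisy_series(slope = 10, intercept = 0, sd = 0.5)
  fit2 <- fit_calibration(d2)
  d2$response <- d2$response + 50 * fit2$se_intercept
  verdict <- decide_zero_forcing(fit_calibration(d2), quiet = TRUE)
  expect_false(verdict$force_zero)

  expect_error(decide_zero_forcing(fit_calibration(d, force_zero = TRUE)),
               "free")
})

test_that("zero-forcing has ~95% acceptance on true zero-intercept data", {
  withr::local_seed(17)
  reps <- 400
  forced <- vapply(seq_len(reps), function(i) {
    d <- noisy_series(slope = 10, intercept = 0, levels = c(5, 10, 20, 50, 100),
                      reps = 3, sd = 2)
    decide_zero_forcing(fit_calibration(d), quiet = TRUE)$force_zero
  }, logical(1))
  # binomial(400, 0.95): mean(forced) should sit within ~3 SE of 0.95
  expect_gt(mean(forced), 0.91)
  expect_lt(mean(forced), 0.985)
})

test_that("lack-of-fit test matches an independent model-comparison oracle", {
  withr::local_seed(13)
  for (i in 1:10) {
    d <- noisy_series(slope = 5, intercept = 1, levels = c(2, 5, 10, 20, 30),
                      reps = 3, sd = 0.5)
    res <- lack_of_fit_test(d)
    # oracle: F from comparing the line against the per-level means model
    cmp <- anova(lm(response ~ level_ug_per_ml, d),
                 lm(response ~ factor(level_ug_per_ml), d))
    expect_equal(res$F, cmp$F[2], tolerance = 1e-10)
    expect_equal(res$df_lof, cmp$Df[2])
    expect_equal(res$p_value, cmp$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("lack-of-fit detects gross curvature and passes linear data", {
  withr::local_seed(5)
  x <- rep(c(1, 2, 3, 4, 5), each = 3)
  quad <- data.frame(level_ug_per_ml = x,
                     response = x^2 + rnorm(length(x), 0, 0.01))
  expect_false(lack_of_fit_test(quad)$linear_ok)

  lin <- data.frame(level_ug_per_ml = x,
                    response = 10 * x + rnorm(length(x), 0, 0.5))
  expect_true(lack_of_fit_test(lin)$linear_ok)
})

test_that("lack-of-fit F is ~1 on-null for large replicated designs", {
  withr::local_seed(29)
  f_vals <- vapply(1:50, function(i) {
    d <- noisy_series(slope = 10, intercept = 0,
                      levels = seq(5, 100, length.out = 10), reps = 5, sd = 1)
    lack_of_fit_test(d)$F
  }, numeric(1))
  # under H0, E[F] = df_pe/(df_pe-2) ~ 1.05
  expect_lt(abs(mean(f_vals) - 1), 0.25)
  expect_gt(mean(vapply(1:50, function(i) {
    d <- noisy_series(slope = 10, intercept = 0,
                      levels = seq(5, 100, length.out = 10), reps = 5, sd = 1)
    lack_of_fit_test(d)$linear_ok
  }, logical(1))), 0.85)
})

test_that("lack-of-fit is an explicit error when degrees of freedom vanish", {
  two_levels <- data.frame(level_ug_per_ml = rep(c(5, 10), each = 3),
                           response = rep(c(50, 100), each = 3) + 1:6 * 0.01)
  expect_error(lack_of_fit_test(two_levels), "inapplicable")
  no_reps <- exact_series()
  expect_error(lack_of_fit_test(no_reps), "replicated")
})

test_that("LOQ follows 10 sigma / S and is scale invariant", {
  expect_equal(loq(list(sigma = 0.05, slope = 1)), 0.5)
  expect_equal(loq(list(sigma = 0, slope = 2)), 0)
  expect_error(loq(list(sigma = 0.1, slope = 0)), "slope")

  # homogeneity: rescaling the detector leaves the LOQ unchanged
  withr::local_seed(41)
  d <- noisy_series()
  f1 <- fit_calibration(d)
  d2 <- d; d2$response <- d2$response * 37.5
  f2 <- fit_calibration(d2)
  expect_equal(loq(f1), loq(f2), tolerance = 1e-10)
})

test_that("LOQ reporting clamps to the lowest calibration level", {
  expect_equal(clamp_loq(0.5, 5), 5)
  expect_equal(clamp_loq(12, 5), 12)
  expect_equal(clamp_loq(rep(0.5, 4), c(5, 10, 25, 50)), c(5, 10, 25, 50))
})

test_that("working range is the level interval, order-invariant", {
  expect_equal(working_range(data.frame(level_ug_per_ml = c(5, 20, 100, 50))),
               working_range(data.frame(level_ug_per_ml = c(100, 5, 50, 20))))
  wr <- working_range(c(5, 10, 100))
  expect_equal(c(wr$low, wr$high), c(5, 100))
  expect_error(working_range(c(5, 5, 5)), "2 distinct")
})

test_that("tidy/glance expose the fit in broom shape", {
  fit <- fit_calibration(exact_series(), force_zero = TRUE)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  g <- glance(fit)
  expect_true(g$zero_forced)
  expect_equal(g$slope, 10)
})
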