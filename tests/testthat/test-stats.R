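# Subject-paired resampled Wilcoxon inference, relative risks, baseline
# comparison and correlation.

test_that("identical groups collapse to the degenerate p = 1 case", {
  g <- list(S1 = c(1.2), S2 = c(0.8), S3 = c(1.5))
  res <- iterated_wilcoxon(g, g, n_iter = 20, seed = 1)
  expect_equal(res$median_p, 1)
  expect_equal(res$n_degenerate, 20)
})

test_that("one-pairing-per-subject reduces to the standard signed-rank test", {
  withr::local_seed(2)
  a <- setNames(as.list(rnorm(15, 0.5)), paste0("S", 1:15))
  b <- setNames(as.list(rnorm(15)), paste0("S", 1:15))
  res <- iterated_wilcoxon(a, b, n_iter = 50, alternative = "greater", seed = 3)
  direct <- wilcox.test(unlist(a) - unlist(b), alternative = "greater")$p.value
  expect_equal(res$median_p, direct)
  expect_true(all(res$p_values == direct))
  expect_equal(res$n_pairs, 15)
})

test_that("a planted one-sd shift in a 40-subject cohort is detected", {
  withr::local_seed(4)
  a <- list(); b <- list()
  for (s in 1:40) {
    sid <- paste0("S", s)
    a[[sid]] <- rnorm(3, mean = 1)
    b[[sid]] <- rnorm(3, mean = 0)
  }
  res <- iterated_wilcoxon(a, b, n_iter = 200, alternative = "greater", seed = 5)
  expect_lt(res$median_p, 0.01)
})

test_that("disjoint subject sets raise the no-paired-support error", {
  expect_error(iterated_wilcoxon(list(S1 = 1:3), list(S2 = 1:3)),
               "no paired support")
})

test_that("fixed seeds reproduce the median p exactly", {
  withr::local_seed(6)
  a <- lapply(setNames(1:10, paste0("S", 1:10)), function(i) rnorm(4, 0.3))
  b <- lapply(setNames(1:10, paste0("S", 1:10)), function(i) rnorm(2))
  r1 <- iterated_wilcoxon(a, b, n_iter = 100, seed = 7)
  r2 <- iterated_wilcoxon(a, b, n_iter = 100, seed = 7)
  expect_identical(r1$median_p, r2$median_p)
  expect_identical(r1$p_values, r2$p_values)
})

test_that("relative risk matches the closed form and handles zeros", {
  # equal risks
  rr <- relative_risk(10, 50, 20, 100)
  expect_equal(rr$rr, 1)
  expect_false(rr$significant)
  expect_true(rr$ci[1] < 1 && rr$ci[2] > 1)
  # hand computation with z = qnorm(0.995)
  rr2 <- relative_risk(20, 100, 10, 100)
  expect_equal(rr2$rr, 2)
  z <- qnorm(0.995)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100)
  expect_equal(rr2$ci, exp(log(2) + c(-1, 1) * z * se))
  # self-comparison is exactly 1
  expect_equal(relative_risk(7, 31, 7, 31)$rr, 1)
  # zero count: continuity-corrected and flagged
  rr3 <- relative_risk(5, 40, 0, 40)
  expect_true(rr3$corrected)
  expect_true(is.finite(rr3$rr))
})

test_that("power is monotone in the planted effect size", {
  withr::local_seed(8)
  reject_rate <- function(shift, reps = 50) {
    mean(replicate(reps, {
      a <- lapply(setNames(1:12, paste0("S", 1:12)),
                  function(i) rnorm(2, shift))
      b <- lapply(setNames(1:12, paste0("S", 1:12)), function(i) rnorm(2))
      iterated_wilcoxon(a, b, n_iter = 40, alternative = "greater")$median_p < 0.01
    }))
  }
  rates <- vapply(c(0, 0.75, 1.5), reject_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.05)
  expect_gt(rates[3], rates[1])
})

test_that("baseline comparison detects shifts and degenerate equality", {
  stable <- data.frame(subject_id = rep(paste0("S", 1:10), each = 2),
                       value = rep(2.0, 20))
  # all levels equal the baseline: degenerate p = 1
  lv_eq <- lapply(setNames(1:10, paste0("S", 1:10)), function(i) c(2.0, 2.0))
  r_eq <- baseline_compare(lv_eq, stable, n_iter = 10, seed = 9)
  expect_equal(r_eq$median_p, 1)
  expect_equal(attr(r_eq, "baseline"), 2.0)
  # small positive offset on every level: one-sided p below 0.01
  lv_up <- lapply(lv_eq, function(v) v + 0.1)
  r_up <- baseline_compare(lv_up, stable, n_iter = 10,
                           alternative = "greater", seed = 9)
  expect_lt(r_up$median_p, 0.01)
  # the non-iterated variant agrees with a direct signed-rank test
  r_plain <- baseline_compare(lv_up, stable, iterate = FALSE,
                              alternative = "greater")
  direct <- suppressWarnings(
    wilcox.test(unlist(lv_up) - 2.0, alternative = "greater")$p.value)
  expect_equal(r_plain$median_p, direct)
})

test_that("planted pre-response bradycardia is detected against baseline", {
  # respiratory arousals get a pulse-rate dip before the rise; the fitted
  # window-start level should sit below the stable-sleep baseline
  eff <- default_effect_table()
  eff$freq_mag_sd[] <- 0; eff$amp_drop_sd[] <- 0
  eff$freq_delay_sd[] <- 0; eff$amp_delay_sd[] <- 0
  cfg <- default_run_config(
    synth = cohort_config(n_subjects = 4, arousals_per_subject = 3,
                          effects = eff, bradycardia_drop = 0.12,
                          cause_probs = c("spontaneous" = 0, "apnea+des" = 1,
                                          "apnea-des" = 0, "hypopnea+des" = 0,
                                          "hypopnea-des" = 0),
                          noise_sd = 0.02, seed = 10),
    stats = stats_control(n_iterations = 50, seed = 10))
  out <- run_pipeline(cfg)
  fr <- out$calls[out$calls$kind == "frequency" & out$calls$response_present, ]
  baseline <- median(out$stable$mean_frequency)
  expect_lt(median(fr$level_before), baseline)
})

test_that("correlation handles linear, anti-correlated and degenerate input", {
  expect_equal(magnitude_delay_correlation(1:10, 2 * (1:10) + 3)$rho, 1)
  expect_lt(magnitude_delay_correlation(1:10, -(1:10) + rnorm(10, 0, 0.1))$rho, 0)
  expect_error(magnitude_delay_correlation(1:2, 1:2), "at least 3")
  expect_error(magnitude_delay_correlation(1:10, rep(1, 10)), "zero variance")
  # independence: no spurious correlation at n = 1000
  withr::local_seed(11)
  r <- magnitude_delay_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(r$rho), 0.1)
})
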