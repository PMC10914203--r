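# Step-model fitting and response categorization.

test_that("fit_once is a fixed point on exactly generated series", {
  par <- c(a = 1.5, b1 = 0.3, b2_rel = 1.2, b3_rel = 0.9,
           c1 = -2, c2_rel = 0.4, c3_rel = 0.7)
  s <- make_tl_series(par, duration_s = 10)
  f <- fit_once(s, guess = par)
  expect_lt(f$ssr, 1e-12)
  for (nm in names(par)) {
    expect_equal(f[[nm]], unname(par[nm]), tolerance = 1e-4)
  }
})

test_that("analytic jacobian agrees with finite differences", {
  t <- seq(-8, 18, by = 0.25)
  fj <- ppgarousal:::.tl_resid_jac(t, 18, 5)
  p <- c(1.5, 0.3, 1.2, 0.9, -2, 0.4, 0.7)
  y <- rep(0, length(t))
  J <- fj$jac(p, y)
  h <- 1e-6
  for (k in seq_along(p)) {
    pp <- p; pp[k] <- pp[k] + h
    pm <- p; pm[k] <- pm[k] - h
    num <- (fj$resid(pp, y) - fj$resid(pm, y)) / (2 * h)
    expect_equal(J[, k], num, tolerance = 1e-5)
  }
})

test_that("a constant series fits to a flat model", {
  t <- seq(-8, 18 - 1 / 64, by = 1 / 64)
  s <- characteristic_series(t, rep(1.4, length(t)), "frequency", 10,
                             smoothed = TRUE)
  f <- multistart_fit(s)
  expect_equal(f$a, 1.4, tolerance = 1e-3)
  expect_lt(abs(f$b1), 1e-3)
  cl <- categorize(f, "frequency")
  expect_false(cl$response_present)
})

test_that("multistart finds a late response and satisfies the argmin property", {
  withr::local_seed(21)
  # single late rise near 0.9 * t_max
  par <- c(a = 1, b1 = 0.8, b2_rel = 0, b3_rel = 0, c1 = 14,
           c2_rel = 0.5, c3_rel = 0.8)
  s <- make_tl_series(par, duration_s = 10, noise_sd = 0.02)
  best <- multistart_fit(s)
  single <- fit_once(s, guess = c(a = median(s$values[s$times < 0]), b1 = 0,
                                  b2_rel = 1, b3_rel = 1, c1 = 0,
                                  c2_rel = 0.5, c3_rel = 0.8))
  expect_lte(best$ssr, single$ssr)
  cl <- categorize(best, "frequency")
  expect_true(cl$response_present)
  expect_equal(cl$magnitude, 0.8, tolerance = 0.1)
  expect_equal(cl$delay, 14, tolerance = 0.5)

  # argmin property: the returned ssr is minimal over every grid start
  ctrl <- respmodel_control()
  grid <- expand.grid(c1 = ctrl$c1_starts, c2_rel = ctrl$c2_rel_starts,
                      c3_rel = ctrl$c3_rel_starts)
  a0 <- median(s$values[s$times < 0])
  ssrs <- vapply(seq_len(nrow(grid)), function(i) {
    fit_once(s, guess = c(a = a0, b1 = 0, b2_rel = 1, b3_rel = 1,
                          c1 = grid$c1[i], c2_rel = grid$c2_rel[i],
                          c3_rel = grid$c3_rel[i]))$ssr
  }, numeric(1))
  expect_lte(best$ssr, min(ssrs) + 1e-9)
})

test_that("noisy planted steps are recovered across replicates", {
  withr::local_seed(31)
  n_ok <- 0L
  reps <- 30
  for (r in seq_len(reps)) {
    par <- random_tl_par()
    s <- make_tl_series(par, noise_sd = 0.05 * par[["a"]])
    truth <- logistic_fit(par[["a"]], par[["b1"]], par[["b2_rel"]],
                          par[["b3_rel"]], par[["c1"]], par[["c2_rel"]],
                          par[["c3_rel"]], -8, 18)
    f <- multistart_fit(s)
    mags_t <- c(truth$b1, truth$b1 * truth$b2_rel, truth$b1 * truth$b3_rel)
    mags_f <- c(f$b1, f$b1 * f$b2_rel, f$b1 * f$b3_rel)
    ok_mag <- all(abs(mags_f - mags_t) <= 0.15 * abs(mags_t))
    ok_t <- all(abs(c(f$c1, f$c2, f$c3) -
                      c(truth$c1, truth$c2, truth$c3)) <= 0.5)
    if (ok_mag && ok_t) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, round(0.9 * reps))
})

test_that("categorization is scale- and time-shift-equivariant", {
  withr::local_seed(41)
  par <- random_tl_par()
  s <- make_tl_series(par, noise_sd = 0.02)
  f1 <- multistart_fit(s)
  c1 <- categorize(f1, "frequency", eval_times = s$times)

  # scaling the series scales levels and magnitude, keeps category and delay
  k <- 3.2
  s2 <- characteristic_series(s$times, k * s$values, s$kind,
                              s$arousal_duration_s, smoothed = TRUE)
  f2 <- multistart_fit(s2)
  c2 <- categorize(f2, "frequency", eval_times = s2$times)
  expect_equal(f2$a, k * f1$a, tolerance = 1e-2)
  expect_equal(f2$b1, k * f1$b1, tolerance = 1e-2)
  expect_equal(c2$category_id, c1$category_id)
  if (c1$response_present) {
    expect_equal(c2$magnitude, k * c1$magnitude, tolerance = 1e-2)
    expect_equal(c2$delay, c1$delay, tolerance = 0.05)
  }

  # shifting times and window shifts the fitted transition times
  dlt <- 2.5
  s3 <- characteristic_series(s$times + dlt, s$values, s$kind,
                              s$arousal_duration_s, smoothed = TRUE)
  w3 <- list(t_min = -8 + dlt, t_max = 18 + dlt, y_max = max(s3$values))
  ctrl <- respmodel_control(c1_starts = respmodel_control()$c1_starts + dlt)
  f3 <- multistart_fit(s3, window = w3, control = ctrl)
  expect_equal(c(f3$c1, f3$c2, f3$c3) - dlt, c(f1$c1, f1$c2, f1$c3),
               tolerance = 0.05)
})

test_that("categorize reproduces planted considerability patterns", {
  withr::local_seed(51)
  reps <- 60
  n_match <- 0L
  pattern_of <- function(fit) {
    cl <- categorize(fit, "frequency")
    cl$category_id
  }
  for (r in seq_len(reps)) {
    par <- random_tl_par(duration_s = 4, b2_range = c(0, 2),
                         b3_range = c(0, 2))
    truth <- logistic_fit(par[["a"]], par[["b1"]], par[["b2_rel"]],
                          par[["b3_rel"]], par[["c1"]], par[["c2_rel"]],
                          par[["c3_rel"]], -8, 12)
    s <- make_tl_series(par, duration_s = 4)
    f <- multistart_fit(s)
    if (pattern_of(f) == pattern_of(truth)) n_match <- n_match + 1L
  }
  expect_gte(n_match / reps, 0.95)
})

test_that("detect_responses reflects the planted truth on synthetic arousals", {
  # null arousal: zero planted magnitudes, zero noise -> neither response
  eff <- default_effect_table()
  eff$freq_mag_mean[] <- 0; eff$freq_mag_sd[] <- 0
  eff$amp_drop_mean[] <- 0; eff$amp_drop_sd[] <- 0
  cfg0 <- cohort_config(
    n_subjects = 1, arousals_per_subject = 1, noise_sd = 0, effects = eff,
    recovery_prob = c(frequency = 0, amplitude = 0), bradycardia_drop = 0,
    seed = 61)
  s0 <- generate_subject(cfg0, 1)
  tr0 <- s0$truth$arousals[1, ]
  ch0 <- arousal_characteristics(s0$record, tr0$start_s, tr0$duration_s)
  res0 <- detect_responses(ch0$frequency, ch0$amplitude)
  expect_false(res0$frequency$response_present)
  expect_false(res0$amplitude$response_present)

  # sustained 0.3 Hz rise at 4 s delay: magnitude recovered within 20%,
  # delay within 1 s, against the generator truth
  eff$freq_mag_mean[] <- 0.3; eff$freq_delay_mean[] <- 4
  eff$freq_delay_sd[] <- 0
  cfg1 <- cohort_config(
    n_subjects = 1, arousals_per_subject = 1, noise_sd = 0.01, effects = eff,
    duration_range = c(10, 10),
    recovery_prob = c(frequency = 0, amplitude = 0), bradycardia_drop = 0,
    seed = 62)
  s1 <- generate_subject(cfg1, 1)
  tr1 <- s1$truth$arousals[1, ]
  ch1 <- arousal_characteristics(s1$record, tr1$start_s, tr1$duration_s)
  res1 <- detect_responses(ch1$frequency, ch1$amplitude)
  expect_true(res1$frequency$response_present)
  expect_lt(abs(res1$frequency$magnitude - 0.3), 0.2 * 0.3)
  expect_lt(abs(res1$frequency$delay - 4), 1)
  expect_false(res1$amplitude$response_present)

  # rise followed by a planted recovery: recovery detected; the truncated
  # plateau attenuates the fitted magnitude, allow 25%
  eff$freq_mag_mean[] <- 0.4; eff$freq_delay_mean[] <- 3
  cfg2 <- cohort_config(
    n_subjects = 1, arousals_per_subject = 1, noise_sd = 0.01, effects = eff,
    duration_range = c(12, 12), recovery_lag_range = c(7, 7),
    recovery_prob = c(frequency = 1, amplitude = 0), bradycardia_drop = 0,
    seed = 62)
  s2 <- generate_subject(cfg2, 1)
  tr2 <- s2$truth$arousals[1, ]
  ch2 <- arousal_characteristics(s2$record, tr2$start_s, tr2$duration_s)
  res2 <- detect_responses(ch2$frequency, ch2$amplitude)
  expect_true(res2$frequency$response_present)
  expect_true(res2$frequency$recovery_present)
  expect_lt(abs(res2$frequency$magnitude - 0.4), 0.25 * 0.4)
  expect_false(res2$amplitude$response_present)
})
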