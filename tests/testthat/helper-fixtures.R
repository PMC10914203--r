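# Shared fixtures: step-model series generators and annotation builders.

# A characteristic series generated exactly from the triple-logistic model.
make_tl_series <- function(par, duration_s = 10, noise_sd = 0, kind = "frequency") {
  t <- seq(-8, duration_s + 8 - 1 / 64, by = 1 / 64)
  y <- triple_logistic(t, par, t_max = duration_s + 8)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  characteristic_series(t, y, kind, duration_s, smoothed = TRUE)
}

# Random step-model parameters with well-separated transitions, all within
# the fitting bounds. Used for parameter-recovery and categorization checks.
random_tl_par <- function(duration_s = 10, min_gap = 2.5,
                          b2_range = c(0.8, 1.6), b3_range = c(0.6, 1.4)) {
  t_max <- duration_s + 8
  repeat {
    a <- runif(1, 1, 2)
    b1 <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.4) * a
    par <- c(a = a, b1 = b1,
             b2_rel = runif(1, b2_range[1], b2_range[2]),
             b3_rel = runif(1, b3_range[1], b3_range[2]),
             c1 = runif(1, -4, 2),
             c2_rel = runif(1, 0.2, 0.6),
             c3_rel = runif(1, 0.5, 0.9))
    f <- logistic_fit(par[["a"]], par[["b1"]], par[["b2_rel"]], par[["b3_rel"]],
                      par[["c1"]], par[["c2_rel"]], par[["c3_rel"]],
                      t_min = -8, t_max = t_max)
    if (f$c2 - f$c1 >= min_gap && f$c3 - f$c2 >= min_gap &&
        f$c3 <= t_max - 1 && min(triple_logistic(seq(-8, t_max, 0.25),
                                                 par, t_max)) > 0) {
      return(par)
    }
  }
}

# Annotation builder with N2 epochs covering [0, total_s) by default.
make_ann <- function(arousals = NULL, resp_events = NULL,
                     desaturations = NULL, total_s = 900,
                     unscored_epochs = integer(), subject_id = "T01") {
  n_ep <- ceiling(total_s / 30)
  stage <- rep("N2", n_ep)
  stage[unscored_epochs] <- "unscored"
  annotation_set(
    arousals = arousals, resp_events = resp_events,
    desaturations = desaturations,
    stage_epochs = data.frame(epoch_start_s = (seq_len(n_ep) - 1) * 30,
                              stage = stage),
    subject_id = subject_id
  )
}

# Constant-value characteristics provider for stable-sleep sampling tests.
const_provider <- function(freq = 1.5, amp = 6.0, lo = 0, hi = Inf) {
  f <- function(start_s) list(mean_frequency = freq, mean_amplitude = amp)
  attr(f, "bounds") <- c(lo, hi)
  f
}

# Tiny synthetic record: pure tone, for feature tests.
tone_record <- function(freqs, amps = 1, fs = 64, dur_s = 20, phase = 0) {
  t <- (seq_len(fs * dur_s) - 1) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t + phase),
                      freqs, rep_len(amps, length(freqs))))
  ppg_record(x, fs, "tone")
}
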