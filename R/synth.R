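# Synthetic polysomnography cohort generator. Produces pulse-train PPG
# waveforms with planted logistic frequency and amplitude responses around
# scored arousals, annotation tracks that satisfy (or deliberately violate)
# the inclusion rules, and a ground-truth table for every planted response.
#
# The clinical cohort behind the analysis is not public; all distributional
# choices here are stand-ins that emulate the reported effect structure
# (baseline levels, per-cause magnitude and delay medians) and are clearly
# labelled as synthetic.

# Fixed pulse shape: unit-energy sum of the first three harmonics. The higher
# harmonics spread spectral power above the fundamental so that the
# power-weighted mean frequency exceeds the pulse rate by a fixed factor.
PULSE_HARMONICS <- c(1.0, 0.4, 0.15) / sqrt(sum(c(1.0, 0.4, 0.15)^2))

#' Pulse shape constants
#'
#' The periodic pulse waveform is \eqn{w(\phi) = \sum_k h_k \sin(k\phi)} with
#' unit-energy harmonic coefficients \eqn{h}. `harmonic_factor` is the ratio
#' between the power-weighted mean frequency of the pulse train and the pulse
#' rate, \eqn{\sum h_k^2 k / \sum h_k^2}; `pp_range` is
#' \eqn{\max w - \min w}, the peak-to-peak range of the unit pulse shape.
#'
#' @return A list with `harmonics`, `harmonic_factor` and `pp_range`.
#' @export
pulse_shape <- function() {
  h <- PULSE_HARMONICS
  k <- seq_along(h)
  phi <- seq(0, 2 * pi, length.out = 4096L)
  w <- colSums(h * sin(outer(k, phi)))
  list(harmonics = h,
       harmonic_factor = sum(h^2 * k) / sum(h^2),
       pp_range = max(w) - min(w))
}

#' Per-cause effect-size table for the synthetic cohort
#'
#' Mean frequency-response magnitudes (Hz, on the mean-instantaneous-frequency
#' scale), amplitude drops (a.u., on the instantaneous-amplitude scale) and
#' response delays (s) per arousal cause, chosen to emulate the per-cause
#' medians reported for the clinical cohort this generator stands in for.
#' Standard deviations default to 25% of the magnitude means and 0.8 s for
#' delays.
#'
#' @return data.frame with one row per cause.
#' @export
default_effect_table <- function() {
  data.frame(
    cause = c("spontaneous", "hypopnea-des", "hypopnea+des",
              "apnea-des", "apnea+des"),
    freq_mag_mean = c(0.15, 0.18, 0.18, 0.25, 0.25),
    freq_mag_sd = c(0.15, 0.18, 0.18, 0.25, 0.25) * 0.25,
    freq_delay_mean = c(3.8, 3.8, 4.7, 4.7, 4.7),
    freq_delay_sd = 0.8,
    amp_drop_mean = c(1.29, 1.37, 1.50, 1.37, 1.50),
    amp_drop_sd = c(1.29, 1.37, 1.50, 1.37, 1.50) * 0.25,
    amp_delay_mean = c(3.8, 3.8, 4.1, 4.4, 4.4),
    amp_delay_sd = 0.8
  )
}

#' Configuration of a synthetic cohort
#'
#' Identical seed and settings produce a byte-identical cohort; each subject
#' draws from its own stream derived from `(seed, subject_index)`.
#'
#' @param n_subjects Number of subjects.
#' @param arousals_per_subject Arousals planted per subject (scalar, or range
#'   `c(min, max)` sampled per subject).
#' @param cause_probs Named probabilities over the five causes, summing to 1.
#' @param effects Effect-size table, see [default_effect_table()].
#' @param baseline_freq_range Range of per-subject baseline mean instantaneous
#'   frequency in Hz (characteristic scale; the underlying pulse rate is this
#'   divided by the harmonic factor).
#' @param baseline_amp_range Range of per-subject baseline instantaneous
#'   amplitude in a.u. (characteristic scale).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param fs Output sampling rate in Hz (>= 64).
#' @param arousal_gap_s Spacing between consecutive planted arousals.
#' @param duration_range Arousal duration range in seconds.
#' @param delay_range Allowed response delay range in seconds.
#' @param recovery_prob Named probabilities of a planted recovery for
#'   `frequency` and `amplitude` responses.
#' @param recovery_lag_range Lag from response to recovery midpoint, seconds.
#' @param bradycardia_drop Pre-response pulse-rate depression (Hz,
#'   characteristic scale) planted during the causal respiratory event of
#'   respiratory arousals; 0 disables it.
#' @param n_excludable Deliberately excludable arousals planted per subject
#'   (flagged in the truth table; they violate the duration or proximity
#'   rules).
#' @param transition Transition kernel for planted responses: `"logistic"`
#'   (growth rate 5, matching the fitted model) or `"raised_cosine"` (smooth
#'   non-logistic transitions for robustness checks).
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40,
                          arousals_per_subject = 5,
                          cause_probs = c("spontaneous" = 0.2,
                                          "apnea+des" = 0.2,
                                          "apnea-des" = 0.2,
                                          "hypopnea+des" = 0.2,
                                          "hypopnea-des" = 0.2),
                          effects = default_effect_table(),
                          baseline_freq_range = c(1.45, 1.75),
                          baseline_amp_range = c(5.6, 7.0),
                          noise_sd = 0.05,
                          fs = 64,
                          arousal_gap_s = 75,
                          duration_range = c(5, 12),
                          delay_range = c(-2, 10),
                          recovery_prob = c(frequency = 0.66, amplitude = 0.5),
                          recovery_lag_range = c(4, 7),
                          bradycardia_drop = 0.05,
                          n_excludable = 0,
                          transition = c("logistic", "raised_cosine"),
                          seed = 1L) {
  transition <- match.arg(transition)
  stopifnot(n_subjects >= 0, fs >= 64,
            abs(sum(cause_probs) - 1) < 1e-8,
            all(names(cause_probs) %in% AROUSAL_CAUSES),
            diff(range(duration_range)) >= 0,
            duration_range[1] >= 3, duration_range[2] <= 15)
  if (arousal_gap_s < duration_range[2] + 44) {
    stop("arousal_gap_s too small: events cannot satisfy the 10 s clearance ",
         "rules with arousals up to ", duration_range[2],
         " s and causal events up to 24 s (need >= ",
         duration_range[2] + 44, " s)")
  }
  structure(
    list(n_subjects = n_subjects, arousals_per_subject = arousals_per_subject,
         cause_probs = cause_probs, effects = effects,
         baseline_freq_range = baseline_freq_range,
         baseline_amp_range = baseline_amp_range,
         noise_sd = noise_sd, fs = fs, arousal_gap_s = arousal_gap_s,
         duration_range = duration_range, delay_range = delay_range,
         recovery_prob = recovery_prob,
         recovery_lag_range = recovery_lag_range,
         bradycardia_drop = bradycardia_drop,
         n_excludable = n_excludable, transition = transition,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

.subject_seed <- function(seed, subject_index) {
  (as.numeric(seed) * 48271 + as.numeric(subject_index) * 9973) %% 2147483629
}

.transition_kernel <- function(t, c, transition) {
  if (transition == "logistic") {
    stats::plogis(5 * (t - c))
  } else {
    # raised cosine over [c - 0.5, c + 0.5]
    x <- pmin(pmax(t - c + 0.5, 0), 1)
    0.5 * (1 - cos(pi * x))
  }
}

.runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate one synthetic subject
#'
#' Synthesizes an amplitude-modulated pulse-train PPG with planted logistic
#' frequency rises and amplitude dips around each arousal, plus annotation
#' tracks (arousals, obstructive respiratory events, desaturations, 30-s
#' stage epochs) laid out to satisfy the inclusion rules, and the
#' ground-truth parameters of every planted response.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index (`<= n_subjects`).
#' @return A list with `record` ([ppg_record()]), `annotations`
#'   ([annotation_set()]) and `truth` (list: `subject_id`,
#'   `baseline_pulse_rate` in Hz, `baseline_pulse_amplitude` in a.u.,
#'   `baseline_freq_char`, `baseline_amp_char` on the characteristic scales,
#'   and `arousals`, a data.frame of planted per-arousal parameters with an
#'   `includable` flag).
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"),
            subject_index >= 1, subject_index <= max(config$n_subjects, 1))
  shape <- pulse_shape()
  hf <- shape$harmonic_factor
  sid <- sprintf("S%03d", subject_index)

  with_local_seed(.subject_seed(config$seed, subject_index), {
    n_ar <- if (length(config$arousals_per_subject) > 1) {
      sample(config$arousals_per_subject[1]:config$arousals_per_subject[2], 1)
    } else as.integer(config$arousals_per_subject)
    causes <- sample(names(config$cause_probs), n_ar, replace = TRUE,
                     prob = config$cause_probs)
    durations <- .runif_range(n_ar, config$duration_range)
    gap <- config$arousal_gap_s
    starts <- 120 + (seq_len(n_ar) - 1) * gap + stats::runif(n_ar, -3, 3)

    eff <- config$effects
    rows <- match(causes, eff$cause)
    truth <- data.frame(
      subject_id = sid, arousal_id = seq_len(n_ar),
      start_s = starts, duration_s = durations, cause = causes,
      includable = TRUE,
      true_freq_magnitude = pmax(
        stats::rnorm(n_ar, eff$freq_mag_mean[rows], eff$freq_mag_sd[rows]), 0.02),
      true_freq_delay_s = pmin(pmax(
        stats::rnorm(n_ar, eff$freq_delay_mean[rows], eff$freq_delay_sd[rows]),
        config$delay_range[1]), config$delay_range[2]),
      true_amp_drop = pmax(
        stats::rnorm(n_ar, eff$amp_drop_mean[rows], eff$amp_drop_sd[rows]), 0.1),
      true_amp_delay_s = pmin(pmax(
        stats::rnorm(n_ar, eff$amp_delay_mean[rows], eff$amp_delay_sd[rows]),
        config$delay_range[1]), config$delay_range[2])
    )
    truth$freq_recovery <- stats::rbinom(n_ar, 1, config$recovery_prob[["frequency"]]) == 1
    truth$amp_recovery <- stats::rbinom(n_ar, 1, config$recovery_prob[["amplitude"]]) == 1
    truth$freq_recovery_lag_s <- .runif_range(n_ar, config$recovery_lag_range)
    truth$amp_recovery_lag_s <- .runif_range(n_ar, config$recovery_lag_range)
    # a recovery only counts as planted when its midpoint fits the analysis
    # window [-8, duration + 8] with ~2 s of settling room
    fits <- function(delay, lag) delay + lag + 2 <= truth$duration_s + 8
    truth$freq_recovery <- truth$freq_recovery &
      fits(truth$true_freq_delay_s, truth$freq_recovery_lag_s)
    truth$amp_recovery <- truth$amp_recovery &
      fits(truth$true_amp_delay_s, truth$amp_recovery_lag_s)

    # respiratory events and desaturations
    resp <- list(); desat <- list()
    truth$event_start_s <- NA_real_; truth$event_duration_s <- NA_real_
    for (i in seq_len(n_ar)) {
      if (causes[i] == "spontaneous") next
      e_dur <- stats::runif(1, 14, 24)
      e_end <- starts[i] + stats::runif(1, -4, min(durations[i], 4))
      e_start <- e_end - e_dur
      type <- if (grepl("^apnea", causes[i])) "obstructive_apnea" else "hypopnea"
      resp[[length(resp) + 1L]] <- data.frame(
        start_s = e_start, duration_s = e_dur, type = type)
      truth$event_start_s[i] <- e_start
      truth$event_duration_s[i] <- e_dur
      if (grepl("\\+des$", causes[i])) {
        d_start <- e_end - stats::runif(1, 2, 6)
        desat[[length(desat) + 1L]] <- data.frame(
          start_s = d_start, duration_s = stats::runif(1, 10, 20))
      }
    }

    # deliberately excludable arousals (annotation-only, no planted response)
    excl <- list()
    t_base <- if (n_ar > 0) max(starts + durations) + 60 else 120
    for (j in seq_len(config$n_excludable)) {
      t0 <- t_base + (j - 1) * 50
      if (j %% 2L == 1L) {
        # proximity violation: two arousals 8 s apart
        excl[[length(excl) + 1L]] <- data.frame(
          start_s = c(t0, t0 + 8 + 5), duration_s = c(5, 5),
          scored_cause = "spontaneous")
      } else {
        # duration violation
        excl[[length(excl) + 1L]] <- data.frame(
          start_s = t0, duration_s = 2.5, scored_cause = "spontaneous")
      }
    }
    excl_df <- if (length(excl)) do.call(rbind, excl) else NULL

    total_s <- 30 * ceiling((t_base + config$n_excludable * 50 + 60) / 30)
    fs <- config$fs
    n <- total_s * fs
    tt <- (seq_len(n) - 1) / fs

    base_freq <- .runif_range(1, config$baseline_freq_range)   # char scale
    base_amp <- .runif_range(1, config$baseline_amp_range)     # char scale
    base_rate <- base_freq / hf                                # pulse rate, Hz
    carrier <- base_amp / shape$pp_range                       # pulse amplitude

    rate <- rep(base_rate, n)
    amod <- rep(1, n)   # relative amplitude modulation
    K <- function(c) .transition_kernel(tt, c, config$transition)
    for (i in seq_len(n_ar)) {
      t_resp <- starts[i] + truth$true_freq_delay_s[i]
      mag_r <- truth$true_freq_magnitude[i] / hf
      if (causes[i] != "spontaneous" && config$bradycardia_drop > 0) {
        b <- config$bradycardia_drop / hf
        rate <- rate - b * K(truth$event_start_s[i] + 2) +
          (mag_r + b) * K(t_resp)
      } else {
        rate <- rate + mag_r * K(t_resp)
      }
      # the response always decays back to baseline; when no recovery is
      # planted the return is placed 6 s past the analysis window end so the
      # fitted window sees a sustained response
      t_freq_rec <- if (truth$freq_recovery[i]) {
        t_resp + truth$freq_recovery_lag_s[i]
      } else starts[i] + durations[i] + 14
      rate <- rate - mag_r * K(t_freq_rec)
      t_amp <- starts[i] + truth$true_amp_delay_s[i]
      dfrac <- truth$true_amp_drop[i] / base_amp
      amod <- amod - dfrac * K(t_amp)
      t_amp_rec <- if (truth$amp_recovery[i]) {
        t_amp + truth$amp_recovery_lag_s[i]
      } else starts[i] + durations[i] + 14
      amod <- amod + dfrac * K(t_amp_rec)
    }
    truth$true_amp_drop_fraction <- truth$true_amp_drop / base_amp

    phi <- stats::runif(1, 0, 2 * pi) + 2 * pi * cumsum(rate) / fs
    h <- shape$harmonics
    w <- h[1] * sin(phi) + h[2] * sin(2 * phi) + h[3] * sin(3 * phi)
    x <- carrier * amod * w
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)

    # stage epochs: 2 epochs of wake, then a repeating sleep-stage cycle
    n_ep <- total_s / 30
    cycle <- c(rep("N2", 20), rep("N3", 6), rep("N2", 10), rep("R", 8))
    stages <- c("W", "W", rep(cycle, length.out = max(n_ep - 2, 0)))
    stage_df <- data.frame(epoch_start_s = (seq_len(n_ep) - 1) * 30,
                           stage = stages[seq_len(n_ep)])

    ar_df <- data.frame(
      start_s = starts, duration_s = durations,
      scored_cause = ifelse(causes == "spontaneous", "spontaneous", "respiratory"))
    if (!is.null(excl_df)) {
      truth_excl <- data.frame(
        subject_id = sid,
        arousal_id = n_ar + seq_len(nrow(excl_df)),
        start_s = excl_df$start_s, duration_s = excl_df$duration_s,
        cause = "spontaneous", includable = FALSE)
      for (cn in setdiff(names(truth), names(truth_excl))) truth_excl[[cn]] <- NA
      truth <- rbind(truth, truth_excl[names(truth)])
      ar_df <- rbind(ar_df, excl_df)
    }

    list(
      record = ppg_record(x, fs, sid),
      annotations = annotation_set(
        arousals = ar_df,
        resp_events = if (length(resp)) do.call(rbind, resp) else NULL,
        desaturations = if (length(desat)) do.call(rbind, desat) else NULL,
        stage_epochs = stage_df,
        subject_id = sid),
      truth = list(subject_id = sid,
                   baseline_pulse_rate = base_rate,
                   baseline_pulse_amplitude = carrier,
                   baseline_freq_char = base_freq,
                   baseline_amp_char = base_amp,
                   arousals = truth)
    )
  })
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A list of subjects as returned by [generate_subject()]
#'   (empty when `n_subjects = 0`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}

#' Cohort ground-truth table
#'
#' Binds the per-arousal truth records of a cohort into one data.frame
#' suitable for CSV export.
#'
#' @param cohort A list from [generate_cohort()].
#' @return data.frame of planted per-arousal parameters across subjects.
#' @export
cohort_truth_table <- function(cohort) {
  if (length(cohort) == 0L) {
    return(data.frame(subject_id = character(), arousal_id = integer()))
  }
  do.call(rbind, lapply(cohort, function(s) s$truth$arousals))
}
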