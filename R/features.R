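# PPG signal characteristics: power-weighted mean instantaneous frequency and
# sliding-window instantaneous amplitude, both derived at 64 Hz on a 2-s
# (128-sample) window advanced one sample at a time.

# Fixed analysis constants. All characteristic derivation happens at 64 Hz;
# the spectrogram window is 2 s (128 samples) zero-padded to 16 * 64 = 1024
# points, giving frequency bins 0..32 Hz in steps of 1/16 Hz.
CHAR_FS <- 64L
CHAR_WIN <- 128L
CHAR_NFFT <- 1024L

#' Construct a PPG record
#'
#' A `ppg_record` is a uniformly sampled photoplethysmogram waveform with its
#' sampling rate and a subject identifier.
#'
#' @param samples Numeric vector of PPG samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#' @param start_s Time of the first sample in seconds (default 0).
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, subject_id = "subject", start_s = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0L, is.numeric(fs), fs > 0)
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.character(subject_id), start_s = start_s),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Decimate a PPG record to the analysis sampling rate
#'
#' Anti-alias filters and downsamples the waveform to `target_hz` (64 Hz by
#' default). Integer decimation factors use an IIR anti-aliasing decimator;
#' non-integer factors fall back to polyphase resampling.
#'
#' @param record A [ppg_record()].
#' @param target_hz Target sampling rate in Hz, default 64.
#' @return A [ppg_record()] at `target_hz`.
#' @export
ppg_decimate <- function(record, target_hz = 64) {
  stopifnot(inherits(record, "ppg_record"))
  if (record$fs < target_hz) {
    stop("insufficient sampling rate: ", record$fs, " Hz < ", target_hz, " Hz")
  }
  if (record$fs == target_hz) return(record)
  q <- record$fs / target_hz
  if (abs(q - round(q)) < 1e-9) {
    q <- round(q)
    # zero-phase windowed-sinc lowpass at 0.8 of the target Nyquist: flat
    # passband (well under 1% ripple) and > 50 dB stopband attenuation
    h <- as.numeric(signal::fir1(128, 0.8 / q))
    y <- signal::filtfilt(h, 1, record$samples)
    y <- y[seq(1, length(y), by = q)]
  } else {
    # rational approximation of the resampling ratio
    fr <- .rational_ratio(target_hz / record$fs)
    y <- signal::resample(record$samples, fr[1], fr[2])
  }
  ppg_record(y, target_hz, record$subject_id, record$start_s)
}

.rational_ratio <- function(x, max_den = 4096L) {
  # continued-fraction approximation p/q of x
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- as.integer(a * p1 + p0); q2 <- as.integer(a * q1 + q0)
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p2 / q2 - x) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p1, q1)
}

#' Extract the analysis segment around one arousal
#'
#' Slices the waveform from 10 s before the arousal start to 10 s after its
#' end. Segment times are kept relative to the EEG arousal start.
#'
#' @param record A [ppg_record()] at 64 Hz.
#' @param start_s Arousal start in seconds on the record's time axis.
#' @param duration_s Arousal duration in seconds.
#' @return A `ppg_segment`: samples, fs, relative start time (-10 s) and
#'   `arousal_duration_s`.
#' @export
extract_segment <- function(record, start_s, duration_s) {
  stopifnot(inherits(record, "ppg_record"))
  if (record$fs != CHAR_FS) {
    stop("segment extraction requires a 64 Hz record; call ppg_decimate() first")
  }
  fs <- record$fs
  i0 <- round((start_s - 10 - record$start_s) * fs) + 1L
  n <- round((duration_s + 20) * fs)
  if (i0 < 1L || i0 + n - 1L > length(record$samples)) {
    stop("segment out of record bounds for arousal at ", start_s, " s",
         call. = FALSE)
  }
  structure(
    list(samples = record$samples[i0:(i0 + n - 1L)], fs = fs,
         t0 = -10, arousal_duration_s = duration_s,
         subject_id = record$subject_id),
    class = "ppg_segment"
  )
}

#' Construct a characteristic series
#'
#' A time series of one PPG characteristic (mean instantaneous frequency in Hz
#' or instantaneous amplitude in a.u.) on a 1/64 s grid, with times relative to
#' the EEG arousal start.
#'
#' @param times Numeric time axis in seconds.
#' @param values Numeric characteristic values.
#' @param kind `"frequency"` or `"amplitude"`.
#' @param arousal_duration_s Arousal duration in seconds (optional).
#' @param smoothed Logical, whether the 2-s moving average has been applied.
#' @return An object of class `characteristic_series`.
#' @export
characteristic_series <- function(times, values, kind,
                                  arousal_duration_s = NA_real_,
                                  smoothed = FALSE) {
  kind <- match.arg(kind, c("frequency", "amplitude"))
  stopifnot(length(times) == length(values))
  structure(
    list(times = times, values = values, kind = kind,
         arousal_duration_s = arousal_duration_s, smoothed = smoothed),
    class = "characteristic_series"
  )
}

#' @export
print.characteristic_series <- function(x, ...) {
  cat(sprintf("<characteristic_series> %s%s: %d samples, t in [%.3f, %.3f] s\n",
              x$kind, if (isTRUE(x$smoothed)) " (smoothed)" else "",
              length(x$values), min(x$times), max(x$times)))
  invisible(x)
}

# Raw frequency characteristic over all positions where the 128-sample window
# fits entirely. Value j corresponds to the window x[j .. j+127], anchored at
# the sample 64 positions in (the window covers [t - 1 s, t + 63/64 s]).
# Each window is mean-removed before the zero-padded transform; otherwise the
# DC component of the boxcar window leaks into nearby bins and biases the
# weighted mean.
.char_freq_values <- function(x) {
  n <- length(x)
  if (n < CHAR_WIN) stop("signal shorter than the 2-s analysis window")
  nwin <- n - CHAR_WIN + 1L
  idx <- outer(seq_len(CHAR_WIN) - 1L, seq_len(nwin) - 1L, `+`) + 1L
  W <- matrix(x[idx], CHAR_WIN, nwin)
  W <- sweep(W, 2, colMeans(W))
  X <- matrix(0, CHAR_NFFT, nwin)
  X[seq_len(CHAR_WIN), ] <- W
  P <- abs(stats::mvfft(X))^2
  P <- P[seq_len(CHAR_NFFT / 2L + 1L), , drop = FALSE]   # 0 .. 32 Hz
  f <- (seq_len(nrow(P)) - 1L) / 16                      # 1/16 Hz bins
  tot <- colSums(P)
  v <- colSums(f * P)
  out <- numeric(nwin)
  nz <- tot > 0
  out[nz] <- v[nz] / tot[nz]
  out
}

# Raw amplitude characteristic: max - min over the same 128-sample windows.
.char_amp_values <- function(x) {
  n <- length(x)
  if (n < CHAR_WIN) stop("signal shorter than the 2-s analysis window")
  hi <- zoo::rollmax(x, CHAR_WIN, align = "left")
  lo <- -zoo::rollmax(-x, CHAR_WIN, align = "left")
  hi - lo
}

# Centered 2-s moving average keeping only positions where the averaging
# window fits entirely; returns length(v) - 127 values aligned with v[65 ...].
.movavg_valid <- function(v) {
  n <- length(v)
  if (n < CHAR_WIN) stop("series shorter than the 2-s smoothing window")
  cs <- cumsum(v)
  j <- seq_len(n - CHAR_WIN + 1L)
  (cs[j + CHAR_WIN - 1L] - c(0, cs)[j]) / CHAR_WIN
}

.char_times <- function(segment, nwin) {
  # value j is anchored at sample j + 64 of the segment
  segment$t0 + (63 + seq_len(nwin)) / CHAR_FS
}

#' Mean instantaneous frequency characteristic
#'
#' Power-weighted mean frequency of the PPG short-time spectrum: for each
#' position of a 2-s boxcar window (advanced one sample at a time) the window
#' is mean-removed and zero-padded to 1024 points, and the value is
#' \eqn{\sum_f f P_f / \sum_f P_f} over bins 0..32 Hz in 1/16 Hz steps, with
#' \eqn{P_f} the squared transform magnitude. A constant (after mean removal,
#' all-zero) window yields 0.
#'
#' @param segment A `ppg_segment` (or `ppg_record`) at 64 Hz.
#' @return An unsmoothed [characteristic_series()] of kind `"frequency"`,
#'   trimmed to positions where the window fits entirely.
#' @export
mean_instantaneous_frequency <- function(segment) {
  v <- .char_freq_values(segment$samples)
  characteristic_series(.char_times(segment, length(v)), v, "frequency",
                        segment$arousal_duration_s %||% NA_real_)
}

#' Instantaneous amplitude characteristic
#'
#' Maximum minus minimum PPG value within the 2-s moving window
#' \eqn{[t - 1\,s, t + 1\,s)}, advanced one sample at a time.
#'
#' @inheritParams mean_instantaneous_frequency
#' @return An unsmoothed [characteristic_series()] of kind `"amplitude"`.
#' @export
instantaneous_amplitude <- function(segment) {
  v <- .char_amp_values(segment$samples)
  characteristic_series(.char_times(segment, length(v)), v, "amplitude",
                        segment$arousal_duration_s %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth a characteristic series
#'
#' Applies a centered 2-s moving average and trims the trace so that, for an
#' arousal segment, the final series covers the analysis window from 8 s
#' before the arousal start to 8 s after its end (length
#' `(arousal_duration_s + 16) * 64` samples, t = 0 at the EEG arousal start).
#'
#' @param series An unsmoothed [characteristic_series()].
#' @return A smoothed, trimmed [characteristic_series()].
#' @export
smooth_characteristic <- function(series) {
  stopifnot(inherits(series, "characteristic_series"))
  v <- .movavg_valid(series$values)
  t <- series$times[64L + seq_along(v)]
  d <- series$arousal_duration_s
  if (!is.na(d)) {
    target <- round((d + 16) * CHAR_FS)
    k <- which.min(abs(t - (-8)))
    if (k + target - 1L > length(v)) {
      stop("smoothed series too short for the analysis window")
    }
    v <- v[k:(k + target - 1L)]
    t <- -8 + (seq_len(target) - 1L) / CHAR_FS   # snap the grid
  }
  characteristic_series(t, v, series$kind, d, smoothed = TRUE)
}

#' Derive both smoothed characteristics for one arousal
#'
#' Convenience wrapper: extracts the segment and returns the smoothed
#' frequency and amplitude characteristic series.
#'
#' @param record A 64 Hz [ppg_record()].
#' @param start_s,duration_s Arousal start and duration in seconds.
#' @return A list with elements `frequency` and `amplitude`.
#' @export
arousal_characteristics <- function(record, start_s, duration_s) {
  seg <- extract_segment(record, start_s, duration_s)
  list(
    frequency = smooth_characteristic(mean_instantaneous_frequency(seg)),
    amplitude = smooth_characteristic(instantaneous_amplitude(seg))
  )
}

#' Characteristic provider for arbitrary 10-s windows
#'
#' Returns a function `f(start_s)` giving the mean of the smoothed frequency
#' and amplitude characteristics over `[start_s, start_s + 10)`, used for
#' stable-sleep baseline sampling. The attribute `"bounds"` gives the valid
#' range of `start_s`.
#'
#' @param record A 64 Hz [ppg_record()].
#' @return A function of `start_s` returning
#'   `list(mean_frequency, mean_amplitude)`.
#' @export
make_characteristics_provider <- function(record) {
  stopifnot(inherits(record, "ppg_record"), record$fs == CHAR_FS)
  n <- length(record$samples)
  margin <- 3  # 2 s of window losses plus slack
  f <- function(start_s) {
    i0 <- round((start_s - margin - record$start_s) * CHAR_FS) + 1L
    len <- round((10 + 2 * margin) * CHAR_FS)
    if (i0 < 1L || i0 + len - 1L > n) stop("window out of record bounds")
    x <- record$samples[i0:(i0 + len - 1L)]
    fv <- .movavg_valid(.char_freq_values(x))
    av <- .movavg_valid(.char_amp_values(x))
    # values align with x[128 + seq_along(fv)] anchors; times of the valid
    # region start margin - 2 s after the slice start
    t <- (start_s - margin + 2) + (seq_along(fv) - 1L) / CHAR_FS
    keep <- t >= start_s & t < start_s + 10
    list(mean_frequency = mean(fv[keep]), mean_amplitude = mean(av[keep]))
  }
  attr(f, "bounds") <- c(record$start_s + margin,
                         record$start_s + n / CHAR_FS - 10 - margin)
  f
}
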