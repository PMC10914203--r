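# Triple-logistic step model for arousal responses: three consecutive logistic
# transitions with alternating signs are fit to each smoothed characteristic by
# bounded least squares from a grid of starting points, and the fitted steps
# are classified into response / delay / recovery calls.

#' Evaluate the triple-logistic step model
#'
#' The model is
#' \deqn{f(t) = a + \frac{b_1}{1+e^{-g(t-c_1)}}
#'              - \frac{b_1 b_{2}}{1+e^{-g(t-c_2)}}
#'              + \frac{b_1 b_{3}}{1+e^{-g(t-c_3)}}}
#' with fixed growth rate \eqn{g = 5} and the second and third transition
#' times parameterized relative to the window end \eqn{t_{max}}:
#' \eqn{c_2 = c_1 + 1 + c_{2,rel} (t_{max} - c_1 - 3)} and
#' \eqn{c_3 = c_2 + 1 + c_{3,rel} (t_{max} - c_2 - 2)}, which enforces
#' \eqn{c_1 < c_2 < c_3} with at least 1 s between transitions.
#'
#' @param t Time points in seconds relative to the EEG arousal start.
#' @param par Named list or vector with elements `a`, `b1`, `b2_rel`,
#'   `b3_rel`, `c1`, `c2_rel`, `c3_rel`.
#' @param t_max End of the fitting window in seconds.
#' @param growth Logistic growth rate (default 5).
#' @return Numeric vector of model values at `t`.
#' @export
triple_logistic <- function(t, par, t_max, growth = 5) {
  p <- as.numeric(par[c("a", "b1", "b2_rel", "b3_rel", "c1", "c2_rel", "c3_rel")])
  cs <- .logistic_times(p[5], p[6], p[7], t_max)
  p[1] + p[2] * stats::plogis(growth * (t - cs[1])) -
    p[2] * p[3] * stats::plogis(growth * (t - cs[2])) +
    p[2] * p[4] * stats::plogis(growth * (t - cs[3]))
}

.logistic_times <- function(c1, c2_rel, c3_rel, t_max) {
  c2 <- c1 + 1 + c2_rel * (t_max - c1 - 3)
  c3 <- c2 + 1 + c3_rel * (t_max - c2 - 2)
  c(c1, c2, c3)
}

#' Fitting window of a characteristic series
#'
#' @param series A smoothed [characteristic_series()].
#' @return A list with `t_min`, `t_max` (window end, i.e. one sample step past
#'   the last time point) and `y_max`, the largest value in the window.
#' @export
fit_window <- function(series) {
  stopifnot(inherits(series, "characteristic_series"))
  list(t_min = series$times[1],
       t_max = series$times[length(series$times)] + 1 / 64,
       y_max = max(series$values))
}

#' Default fitting control settings
#'
#' Bounds and multistart grids for the triple-logistic fit. `b_rel_max` bounds
#' the relative step sizes, `c1_starts` are start guesses centered on the EEG
#' arousal start, `c2_rel_starts` sit around the halfway point of the
#' remaining window and `c3_rel_starts` are large to catch very late changes.
#'
#' @param growth Logistic growth rate.
#' @param b_rel_max Upper bound for `b2_rel` and `b3_rel`.
#' @param c1_starts,c2_rel_starts,c3_rel_starts Multistart grids.
#' @param threshold Considerability threshold as a fraction of the mean fitted
#'   value (default 0.05).
#' @param ftol Least-squares convergence tolerance.
#' @param maxfev Maximum residual evaluations per start.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of control settings.
#' @export
respmodel_control <- function(growth = 5, b_rel_max = 20,
                              c1_starts = c(-4, -2, 0, 2, 4),
                              c2_rel_starts = c(0.25, 0.5, 0.75),
                              c3_rel_starts = c(0.6, 0.8, 0.95),
                              threshold = 0.05,
                              ftol = 1e-8, maxfev = 2000, maxiter = 200) {
  list(growth = growth, b_rel_max = b_rel_max, c1_starts = c1_starts,
       c2_rel_starts = c2_rel_starts, c3_rel_starts = c3_rel_starts,
       threshold = threshold, ftol = ftol, maxfev = maxfev,
       maxiter = maxiter)
}

#' Construct a logistic fit object
#'
#' Normally produced by [fit_once()] / [multistart_fit()]; constructing one
#' directly is useful to categorize published fit parameters.
#'
#' @param a,b1,b2_rel,b3_rel,c1,c2_rel,c3_rel Model parameters.
#' @param t_min,t_max Fitting window in seconds relative to arousal start.
#' @param ssr Sum of squared residuals (NA when not fitted to data).
#' @param growth Logistic growth rate.
#' @param converged Logical.
#' @return An object of class `logistic_fit` with derived `c2`, `c3`.
#' @export
logistic_fit <- function(a, b1, b2_rel, b3_rel, c1, c2_rel, c3_rel,
                         t_min, t_max, ssr = NA_real_, growth = 5,
                         converged = TRUE) {
  cs <- .logistic_times(c1, c2_rel, c3_rel, t_max)
  structure(
    list(a = a, b1 = b1, b2_rel = b2_rel, b3_rel = b3_rel,
         c1 = cs[1], c2 = cs[2], c3 = cs[3],
         c2_rel = c2_rel, c3_rel = c3_rel,
         t_min = t_min, t_max = t_max, ssr = ssr, growth = growth,
         converged = converged),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(paste0("<logistic_fit> a=%.4g b1=%.4g b2_rel=%.4g b3_rel=%.4g\n",
                     "  c1=%.3f c2=%.3f c3=%.3f  ssr=%.4g  window [%.2f, %.2f]\n"),
              x$a, x$b1, x$b2_rel, x$b3_rel, x$c1, x$c2, x$c3, x$ssr,
              x$t_min, x$t_max))
  invisible(x)
}

# Analytic Jacobian of the residuals (y - f) with respect to the seven
# parameters, used to speed up and stabilize the Levenberg-Marquardt fit.
.tl_resid_jac <- function(t, t_max, growth) {
  list(
    resid = function(p, y) y - {
      cs <- .logistic_times(p[5], p[6], p[7], t_max)
      p[1] + p[2] * stats::plogis(growth * (t - cs[1])) -
        p[2] * p[3] * stats::plogis(growth * (t - cs[2])) +
        p[2] * p[4] * stats::plogis(growth * (t - cs[3]))
    },
    jac = function(p, y) {
      cs <- .logistic_times(p[5], p[6], p[7], t_max)
      S1 <- stats::plogis(growth * (t - cs[1]))
      S2 <- stats::plogis(growth * (t - cs[2]))
      S3 <- stats::plogis(growth * (t - cs[3]))
      dS1 <- -growth * S1 * (1 - S1)   # dS/dc
      dS2 <- -growth * S2 * (1 - S2)
      dS3 <- -growth * S3 * (1 - S3)
      dc2_dc1 <- 1 - p[6]
      dc3_dc1 <- (1 - p[6]) * (1 - p[7])
      dc2_dc2r <- t_max - p[5] - 3
      dc3_dc2r <- (1 - p[7]) * dc2_dc2r
      dc3_dc3r <- t_max - cs[2] - 2
      J <- cbind(
        1,
        S1 - p[3] * S2 + p[4] * S3,
        -p[2] * S2,
        p[2] * S3,
        p[2] * dS1 - p[2] * p[3] * dS2 * dc2_dc1 + p[2] * p[4] * dS3 * dc3_dc1,
        -p[2] * p[3] * dS2 * dc2_dc2r + p[2] * p[4] * dS3 * dc3_dc2r,
        p[2] * p[4] * dS3 * dc3_dc3r
      )
      -J
    }
  )
}

#' Single bounded least-squares fit of the step model
#'
#' Runs a Levenberg-Marquardt fit from one starting point, with bounds
#' `a` in `[0, y_max]`, `b1` in `[-y_max, y_max]`, `b2_rel`, `b3_rel` in
#' `[0, b_rel_max]`, `c1` in `[t_min, t_max - 3]` and `c2_rel`, `c3_rel` in
#' `[0, 1]`.
#'
#' @param series A smoothed [characteristic_series()].
#' @param window Fitting window from [fit_window()] (computed if `NULL`).
#' @param guess Named numeric start vector with elements `a`, `b1`, `b2_rel`,
#'   `b3_rel`, `c1`, `c2_rel`, `c3_rel`.
#' @param control See [respmodel_control()].
#' @return A `logistic_fit`; non-convergence is flagged with infinite `ssr`.
#' @export
fit_once <- function(series, window = NULL, guess, control = respmodel_control()) {
  if (is.null(window)) window <- fit_window(series)
  t <- series$times
  y <- series$values
  pnames <- c("a", "b1", "b2_rel", "b3_rel", "c1", "c2_rel", "c3_rel")
  p0 <- as.numeric(guess[pnames])
  lower <- c(0, -window$y_max, 0, 0, window$t_min, 0, 0)
  upper <- c(window$y_max, window$y_max, control$b_rel_max, control$b_rel_max,
             window$t_max - 3, 1, 1)
  p0 <- pmin(pmax(p0, lower), upper)
  fj <- .tl_resid_jac(t, window$t_max, control$growth)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = fj$resid, jac = fj$jac, y = y,
      control = minpack.lm::nls.lm.control(
        ftol = control$ftol, maxfev = control$maxfev,
        maxiter = control$maxiter)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(sum(fit$fvec^2))) {
    return(logistic_fit(p0[1], p0[2], p0[3], p0[4], p0[5], p0[6], p0[7],
                        window$t_min, window$t_max, ssr = Inf,
                        growth = control$growth, converged = FALSE))
  }
  p <- fit$par
  logistic_fit(p[1], p[2], p[3], p[4], p[5], p[6], p[7],
               window$t_min, window$t_max, ssr = sum(fit$fvec^2),
               growth = control$growth, converged = TRUE)
}

#' Multistart fit of the step model
#'
#' Repeats [fit_once()] from every combination of the start grids for `c1`,
#' `c2_rel` and `c3_rel` (with `a` started at the median value before the
#' arousal start, `b1` at 0 and `b2_rel = b3_rel = 1`) and returns the fit
#' with the smallest sum of squared residuals, ties broken by grid order.
#'
#' @inheritParams fit_once
#' @return The minimum-SSR `logistic_fit`; when every start fails the returned
#'   fit has infinite `ssr` and `converged = FALSE` and should be discarded.
#' @export
multistart_fit <- function(series, window = NULL, control = respmodel_control()) {
  if (is.null(window)) window <- fit_window(series)
  a0 <- stats::median(series$values[series$times < 0])
  if (!is.finite(a0)) a0 <- stats::median(series$values)
  grid <- expand.grid(c1 = control$c1_starts,
                      c2_rel = control$c2_rel_starts,
                      c3_rel = control$c3_rel_starts,
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- c(a = a0, b1 = 0, b2_rel = 1, b3_rel = 1,
           c1 = grid$c1[i], c2_rel = grid$c2_rel[i], c3_rel = grid$c3_rel[i])
    f <- fit_once(series, window, g, control)
    if (is.null(best) || f$ssr < best$ssr) best <- f
  }
  best
}

#' Categorize a fitted step model into a response call
#'
#' The three fitted steps have signed magnitudes `b1`, `-b1 * b2_rel` and
#' `b1 * b3_rel`. A step is considerable when its absolute magnitude exceeds
#' `threshold` (default 5%) of the mean fitted value over the window. The 16
#' categories encode the considerability pattern of the three steps (bit 4 =
#' step 1, bit 2 = step 2, bit 1 = step 3, as `category_id - 1` modulo 8) and
#' the sign of `b1` (`category_id > 8` for a decreasing first step). The
#' response is the considerable step in the response direction (frequency
#' increase, amplitude decrease) whose post-step level differs most from the
#' window-start level `a`; its magnitude is that level difference, its delay
#' the step time, and a recovery is a considerable opposite-direction step
#' occurring later.
#'
#' @param fit A `logistic_fit`.
#' @param kind `"frequency"` or `"amplitude"`.
#' @param threshold Considerability threshold (fraction of mean fitted value).
#' @param eval_times Optional time grid for the mean fitted value; defaults to
#'   the 1/64 s grid over `[t_min, t_max)`.
#' @return An object of class `response_call`.
#' @export
categorize <- function(fit, kind, threshold = 0.05, eval_times = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  kind <- match.arg(kind, c("frequency", "amplitude"))
  if (is.null(eval_times)) {
    eval_times <- seq(fit$t_min, fit$t_max - 1 / 64, by = 1 / 64)
  }
  par <- c(a = fit$a, b1 = fit$b1, b2_rel = fit$b2_rel, b3_rel = fit$b3_rel,
           c1 = fit$c1, c2_rel = fit$c2_rel, c3_rel = fit$c3_rel)
  mean_fitted <- mean(triple_logistic(eval_times, par, fit$t_max, fit$growth))
  steps <- c(fit$b1, -fit$b1 * fit$b2_rel, fit$b1 * fit$b3_rel)
  times <- c(fit$c1, fit$c2, fit$c3)
  considerable <- abs(steps) > threshold * abs(mean_fitted)
  cum <- cumsum(steps)

  dir <- if (kind == "frequency") 1 else -1
  cand <- which(considerable & sign(steps) == dir)
  pattern <- sum(considerable * c(4L, 2L, 1L))
  category_id <- 1L + pattern + 8L * (fit$b1 < 0)

  if (length(cand) == 0L) {
    call <- list(kind = kind, category_id = category_id,
                 response_present = FALSE, response_step = NA_integer_,
                 magnitude = NA_real_, delay = NA_real_,
                 recovery_present = FALSE, recovery_delay = NA_real_,
                 level_before = fit$a, level_after = NA_real_,
                 mean_fitted = mean_fitted, ssr = fit$ssr)
    return(structure(call, class = "response_call"))
  }
  k <- cand[which.max(abs(cum[cand]))]
  later_opposite <- which(considerable & sign(steps) == -dir & seq_along(steps) > k)
  recovery <- length(later_opposite) > 0L
  call <- list(
    kind = kind, category_id = category_id, response_present = TRUE,
    response_step = k, magnitude = abs(cum[k]), delay = times[k],
    recovery_present = recovery,
    recovery_delay = if (recovery) times[min(later_opposite)] else NA_real_,
    level_before = fit$a, level_after = fit$a + cum[k],
    mean_fitted = mean_fitted, ssr = fit$ssr
  )
  structure(call, class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  if (x$response_present) {
    cat(sprintf(paste0("<response_call> %s: response at step %d, magnitude ",
                       "%.4g, delay %.2f s, recovery %s (category %d)\n"),
                x$kind, x$response_step, x$magnitude, x$delay,
                if (x$recovery_present) "yes" else "no", x$category_id))
  } else {
    cat(sprintf("<response_call> %s: no response (category %d)\n",
                x$kind, x$category_id))
  }
  invisible(x)
}

#' Detect frequency and amplitude responses for one arousal
#'
#' Applies [multistart_fit()] and [categorize()] to both smoothed
#' characteristic series of an arousal.
#'
#' @param freq_series,amp_series Smoothed [characteristic_series()] objects.
#' @param control See [respmodel_control()].
#' @return A list with elements `frequency` and `amplitude`, each either a
#'   `response_call` or `NULL` when the fit was discarded (all starts failed).
#' @export
detect_responses <- function(freq_series, amp_series,
                             control = respmodel_control()) {
  out <- list(frequency = NULL, amplitude = NULL)
  for (kind in c("frequency", "amplitude")) {
    series <- if (kind == "frequency") freq_series else amp_series
    fit <- multistart_fit(series, control = control)
    if (is.finite(fit$ssr)) {
      out[[kind]] <- categorize(fit, kind, control$threshold,
                                eval_times = series$times)
    }
  }
  out
}
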