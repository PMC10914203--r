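# Statistical inference for grouped arousal measures: subject-paired
# resampled (iterated) Wilcoxon signed-rank tests, relative risks with
# confidence intervals, stable-sleep baseline comparisons and
# magnitude-delay correlations.

#' Normalize grouped measures
#'
#' Accepts either a data.frame with `subject_id` and `value` columns or a
#' named list of numeric vectors (one per subject) and returns the latter.
#'
#' @param x Grouped measurements.
#' @return Named list mapping subject id to a numeric vector.
#' @export
as_grouped <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject_id", "value") %in% names(x)))
    x <- split(x$value, x$subject_id)
  }
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(v) v[is.finite(v)])
  x[vapply(x, length, integer(1)) > 0L]
}

# Wilcoxon signed-rank p-value of a difference vector. Zeros are dropped
# (Wilcoxon's method, as in stats::wilcox.test); an all-zero vector is the
# degenerate no-evidence case and yields p = 1.
signed_rank_p <- function(diffs, alternative = "two.sided") {
  diffs <- diffs[is.finite(diffs)]
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    return(structure(1, degenerate = TRUE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(nz, alternative = alternative)$p.value)
  structure(unname(p), degenerate = FALSE)
}

#' Iterated subject-paired Wilcoxon signed-rank test
#'
#' For two groups of measurements sharing subjects: in each iteration, for
#' every shared subject the larger side is sampled without replacement down
#' to the smaller side's count and the values are randomly paired within the
#' subject; the pairs are pooled across subjects and a Wilcoxon signed-rank
#' test of the differences (A minus B) is run. The median p-value over the
#' iterations is the reported measure of significance.
#'
#' @param groupA,groupB Grouped measures (see [as_grouped()]).
#' @param n_iter Number of iterations (default 1000).
#' @param alternative `"two.sided"`, `"greater"` (A tends larger) or
#'   `"less"`.
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `iterated_test_result`: `median_p`,
#'   `p_values`, `n_iterations`, `alternative`, `n_subjects`, `n_pairs`,
#'   `n_degenerate`.
#' @export
iterated_wilcoxon <- function(groupA, groupB, n_iter = 1000,
                              alternative = c("two.sided", "greater", "less"),
                              seed = NULL) {
  alternative <- match.arg(alternative)
  a <- as_grouped(groupA); b <- as_grouped(groupB)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) stop("no paired support: no shared subjects")
  a <- a[shared]; b <- b[shared]
  na <- vapply(a, length, integer(1)); nb <- vapply(b, length, integer(1))
  m <- pmin(na, nb)

  run <- function() {
    ps <- numeric(n_iter); ndeg <- 0L
    for (it in seq_len(n_iter)) {
      diffs <- unlist(lapply(seq_along(shared), function(s) {
        a[[s]][sample.int(na[s], m[s])] - b[[s]][sample.int(nb[s], m[s])]
      }), use.names = FALSE)
      p <- signed_rank_p(diffs, alternative)
      if (isTRUE(attr(p, "degenerate"))) ndeg <- ndeg + 1L
      ps[it] <- p
    }
    list(ps = ps, ndeg = ndeg)
  }
  res <- if (is.null(seed)) run() else with_local_seed(seed, run())
  structure(
    list(median_p = stats::median(res$ps), p_values = res$ps,
         n_iterations = n_iter, alternative = alternative,
         n_subjects = length(shared), n_pairs = sum(m),
         n_degenerate = res$ndeg),
    class = "iterated_test_result"
  )
}

#' @export
print.iterated_test_result <- function(x, ...) {
  cat(sprintf(paste0("<iterated_test_result> median p = %.4g (%s, %d ",
                     "iterations, %d subjects, %d pairs)\n"),
              x$median_p, x$alternative, x$n_iterations, x$n_subjects,
              x$n_pairs))
  invisible(x)
}

#' Relative risk with confidence interval
#'
#' Computes `rr = (x1/n1) / (x2/n2)` with a log-normal confidence interval
#' `exp(log rr +/- z * sqrt(1/x1 - 1/n1 + 1/x2 - 1/n2))` at `ci_level`
#' (99% by default). Zero counts trigger a 0.5 continuity correction, which
#' is flagged in the result.
#'
#' @param x1,n1 Events and trials in the first group.
#' @param x2,n2 Events and trials in the second group.
#' @param ci_level Confidence level (default 0.99).
#' @return An object of class `relative_risk_result`: `rr`, `ci` (low,
#'   high), `significant` (CI excludes 1), `corrected`, and the counts.
#' @export
relative_risk <- function(x1, n1, x2, n2, ci_level = 0.99) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  corrected <- (x1 == 0 || x2 == 0)
  if (corrected) {
    x1 <- x1 + 0.5; x2 <- x2 + 0.5; n1 <- n1 + 0.5; n2 <- n2 + 0.5
  }
  rr <- (x1 / n1) / (x2 / n2)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  structure(
    list(rr = rr, ci = ci, significant = ci[1] > 1 || ci[2] < 1,
         corrected = corrected, ci_level = ci_level,
         counts = c(x1 = x1, n1 = n1, x2 = x2, n2 = n2)),
    class = "relative_risk_result"
  )
}

#' @export
print.relative_risk_result <- function(x, ...) {
  cat(sprintf("<relative_risk_result> RR = %.3f, %g%% CI [%.3f, %.3f]%s%s\n",
              x$rr, 100 * x$ci_level, x$ci[1], x$ci[2],
              if (x$significant) " *" else "",
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Compare characteristic levels with the stable-sleep baseline
#'
#' The baseline is the median of the stable-sleep sample means (pooled over
#' subjects). With `iterate = TRUE` the comparison mirrors the paired design:
#' in each iteration, each subject's levels are subsampled down to that
#' subject's stable-sample count (the baseline acting as the constant pair
#' member) before the pooled one-sample signed-rank test of
#' `level - baseline`. With `iterate = FALSE` a single one-sample test over
#' all levels is run.
#'
#' @param levels Grouped measures of fitted levels (see [as_grouped()]).
#' @param stable data.frame of stable-sleep samples with `subject_id` and the
#'   value column named by `value_col`, or grouped measures.
#' @param value_col Column of `stable` holding the characteristic mean.
#' @param n_iter,alternative,seed As in [iterated_wilcoxon()].
#' @param iterate Use the subject-subsampled iterated variant (default) or a
#'   plain one-sample test.
#' @return An `iterated_test_result` (with `n_iterations = 1` when
#'   `iterate = FALSE`); the baseline is attached as attribute `"baseline"`.
#' @export
baseline_compare <- function(levels, stable, value_col = "value",
                             n_iter = 1000,
                             alternative = c("two.sided", "greater", "less"),
                             seed = NULL, iterate = TRUE) {
  alternative <- match.arg(alternative)
  lv <- as_grouped(levels)
  st <- if (is.data.frame(stable) && value_col %in% names(stable)) {
    as_grouped(data.frame(subject_id = stable$subject_id,
                          value = stable[[value_col]]))
  } else as_grouped(stable)
  if (length(st) == 0L) stop("no stable-sleep samples")
  baseline <- stats::median(unlist(st, use.names = FALSE))

  if (!iterate) {
    d <- unlist(lv, use.names = FALSE) - baseline
    p <- signed_rank_p(d, alternative)
    res <- structure(
      list(median_p = as.numeric(p), p_values = as.numeric(p),
           n_iterations = 1L, alternative = alternative,
           n_subjects = length(lv), n_pairs = length(d),
           n_degenerate = as.integer(isTRUE(attr(p, "degenerate")))),
      class = "iterated_test_result")
    attr(res, "baseline") <- baseline
    return(res)
  }
  shared <- intersect(names(lv), names(st))
  if (length(shared) == 0L) stop("no paired support: no shared subjects")
  lv <- lv[shared]
  nl <- vapply(lv, length, integer(1))
  ns <- vapply(st[shared], length, integer(1))
  m <- pmin(nl, ns)
  run <- function() {
    ps <- numeric(n_iter); ndeg <- 0L
    for (it in seq_len(n_iter)) {
      d <- unlist(lapply(seq_along(shared), function(s) {
        lv[[s]][sample.int(nl[s], m[s])]
      }), use.names = FALSE) - baseline
      p <- signed_rank_p(d, alternative)
      if (isTRUE(attr(p, "degenerate"))) ndeg <- ndeg + 1L
      ps[it] <- p
    }
    list(ps = ps, ndeg = ndeg)
  }
  res <- if (is.null(seed)) run() else with_local_seed(seed, run())
  out <- structure(
    list(median_p = stats::median(res$ps), p_values = res$ps,
         n_iterations = n_iter, alternative = alternative,
         n_subjects = length(shared), n_pairs = sum(m),
         n_degenerate = res$ndeg),
    class = "iterated_test_result")
  attr(out, "baseline") <- baseline
  out
}

#' Pearson correlation between response delays and magnitudes
#'
#' @param delay,magnitude Numeric vectors over responding arousals.
#' @return A list with `rho`, `p` and `n`.
#' @export
magnitude_delay_correlation <- function(delay, magnitude) {
  keep <- is.finite(delay) & is.finite(magnitude)
  delay <- delay[keep]; magnitude <- magnitude[keep]
  if (length(delay) < 3L) stop("need at least 3 responding arousals")
  if (stats::sd(delay) == 0 || stats::sd(magnitude) == 0) {
    stop("zero variance in delay or magnitude")
  }
  ct <- stats::cor.test(delay, magnitude, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(delay))
}

#' Default statistics settings
#'
#' @param n_iterations Iterations of the resampled Wilcoxon test.
#' @param alpha Significance threshold (default 0.01).
#' @param ci_level Confidence level for relative risks (default 0.99).
#' @param seed Integer seed for all resampling.
#' @return A list of settings.
#' @export
stats_control <- function(n_iterations = 1000, alpha = 0.01, ci_level = 0.99,
                          seed = 1L) {
  list(n_iterations = n_iterations, alpha = alpha, ci_level = ci_level,
       seed = as.integer(seed))
}

#' Build the cohort report
#'
#' Produces, per characteristic kind: (i) per-cause response and recovery
#' proportions with pairwise relative risks of NOT detecting a response or
#' recovery; (ii) per-cause magnitude and delay medians with pairwise
#' one-sided iterated Wilcoxon median p-values (direction taken from the sign
#' of the median difference and recorded); (iii) median levels before and
#' after the response relative to the stable-sleep baseline with iterated
#' signed-rank p-values.
#'
#' @param calls data.frame of per-arousal response calls with columns
#'   `subject_id`, `cause`, `kind`, `response_present`, `magnitude`,
#'   `delay_s`, `recovery_present`, `level_before`, `level_after`.
#' @param stable data.frame of stable-sleep samples (see
#'   [sample_stable_sleep()]).
#' @param control See [stats_control()].
#' @return An object of class `cohort_report`: lists `proportions`,
#'   `rr_response`, `rr_recovery`, `magnitude`, `delay`, `levels` keyed by
#'   kind, plus `meta`.
#' @export
build_report <- function(calls, stable, control = stats_control()) {
  stopifnot(is.data.frame(calls))
  report <- list(proportions = list(), rr_response = list(),
                 rr_recovery = list(), magnitude = list(), delay = list(),
                 levels = list())

  pair_matrix <- function(values_by_cause, n_iter, seed_base) {
    causes <- names(values_by_cause)
    k <- length(causes)
    p <- matrix(NA_real_, k, k, dimnames = list(causes, causes))
    direction <- matrix(NA_integer_, k, k, dimnames = list(causes, causes))
    if (k < 2) return(list(p = p, direction = direction))
    idx <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      gi <- values_by_cause[[i]]; gj <- values_by_cause[[j]]
      med_i <- stats::median(unlist(gi, use.names = FALSE))
      med_j <- stats::median(unlist(gj, use.names = FALSE))
      alt <- if (med_i >= med_j) "greater" else "less"
      res <- tryCatch(
        iterated_wilcoxon(gi, gj, n_iter, alt, seed = seed_base + idx),
        error = function(e) NULL)
      if (!is.null(res)) {
        p[i, j] <- p[j, i] <- res$median_p
        direction[i, j] <- if (med_i >= med_j) 1L else -1L
        direction[j, i] <- -direction[i, j]
      }
    }
    list(p = p, direction = direction)
  }

  for (kd in c("frequency", "amplitude")) {
    sub <- calls[calls$kind == kd & !is.na(calls$response_present), , drop = FALSE]
    if (nrow(sub) == 0L) next
    causes <- intersect(AROUSAL_CAUSES, unique(sub$cause))

    # (i) proportions and relative risks
    prop <- do.call(rbind, lapply(causes, function(cz) {
      g <- sub[sub$cause == cz, ]
      r <- g[g$response_present, ]
      data.frame(cause = cz, n = nrow(g), n_response = nrow(r),
                 prop_response = nrow(r) / nrow(g),
                 n_recovery = sum(r$recovery_present),
                 prop_recovery = if (nrow(r)) sum(r$recovery_present) / nrow(r)
                                 else NA_real_)
    }))
    report$proportions[[kd]] <- prop

    rr_tab <- function(x_col, n_col) {
      k <- length(causes)
      m <- matrix(NA_real_, k, k, dimnames = list(causes, causes))
      sig <- matrix(NA, k, k, dimnames = list(causes, causes))
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (prop[[n_col]][i] == 0 || prop[[n_col]][j] == 0) next
        rr <- relative_risk(prop[[n_col]][i] - prop[[x_col]][i], prop[[n_col]][i],
                            prop[[n_col]][j] - prop[[x_col]][j], prop[[n_col]][j],
                            control$ci_level)
        m[i, j] <- rr$rr; sig[i, j] <- rr$significant
      }
      list(rr = m, significant = sig)
    }
    report$rr_response[[kd]] <- rr_tab("n_response", "n")
    report$rr_recovery[[kd]] <- rr_tab("n_recovery", "n_response")

    # (ii) magnitudes and delays among responders
    resp <- sub[sub$response_present, , drop = FALSE]
    by_cause <- function(col) {
      g <- lapply(causes, function(cz) {
        r <- resp[resp$cause == cz, ]
        as_grouped(data.frame(subject_id = r$subject_id, value = r[[col]]))
      })
      stats::setNames(g, causes)
    }
    mag <- by_cause("magnitude")
    del <- by_cause("delay_s")
    med <- function(vbc) vapply(vbc, function(g)
      stats::median(unlist(g, use.names = FALSE)), numeric(1))
    report$magnitude[[kd]] <- c(
      list(median = med(mag)),
      pair_matrix(mag, control$n_iterations, control$seed + 1000L))
    report$delay[[kd]] <- c(
      list(median = med(del)),
      pair_matrix(del, control$n_iterations, control$seed + 2000L))

    # (iii) levels vs stable-sleep baseline
    if (!is.null(stable) && nrow(stable) > 0L) {
      value_col <- if (kd == "frequency") "mean_frequency" else "mean_amplitude"
      baseline <- stats::median(stable[[value_col]])
      lev <- do.call(rbind, lapply(causes, function(cz) {
        r <- resp[resp$cause == cz, ]
        row <- data.frame(cause = cz,
                          median_before_rel = stats::median(r$level_before) - baseline,
                          median_after_rel = stats::median(r$level_after) - baseline,
                          p_before = NA_real_, p_after = NA_real_)
        for (side in c("before", "after")) {
          g <- as_grouped(data.frame(subject_id = r$subject_id,
                                     value = r[[paste0("level_", side)]]))
          res <- tryCatch(
            baseline_compare(g, stable, value_col = value_col,
                             n_iter = control$n_iterations,
                             seed = control$seed + 3000L),
            error = function(e) NULL)
          if (!is.null(res)) row[[paste0("p_", side)]] <- res$median_p
        }
        row
      }))
      attr(lev, "baseline") <- baseline
      report$levels[[kd]] <- lev
    }
  }
  report$meta <- list(alpha = control$alpha, ci_level = control$ci_level,
                      n_iterations = control$n_iterations,
                      seed = control$seed)
  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  for (kd in names(x$proportions)) {
    cat(sprintf("-- %s --\n", kd))
    print(x$proportions[[kd]], row.names = FALSE)
    cat("medians: magnitude ",
        paste(sprintf("%s=%.3g", names(x$magnitude[[kd]]$median),
                      x$magnitude[[kd]]$median), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
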