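# Arousal inclusion/exclusion rules, cause classification and stable-sleep
# reference sampling. Time convention: seconds from recording start, events as
# half-open intervals [start, start + duration).

AROUSAL_CAUSES <- c("spontaneous", "apnea+des", "apnea-des",
                    "hypopnea+des", "hypopnea-des")
OBSTRUCTIVE_TYPES <- c("obstructive_apnea", "hypopnea")
SLEEP_STAGES <- c("N1", "N2", "N3", "R")

#' Construct an annotation set
#'
#' Per-subject event tracks on one time axis: arousals, respiratory events,
#' oxygen desaturations (>= 3 percentage points) and 30-s sleep-stage epochs.
#'
#' @param arousals data.frame with `start_s`, `duration_s` and optionally
#'   `scored_cause`.
#' @param resp_events data.frame with `start_s`, `duration_s`, `type` (one of
#'   `"obstructive_apnea"`, `"hypopnea"`, `"central_apnea"`, `"mixed_apnea"`).
#' @param desaturations data.frame with `start_s`, `duration_s`.
#' @param stage_epochs data.frame with `epoch_start_s`, `stage` (one of
#'   `"W"`, `"N1"`, `"N2"`, `"N3"`, `"R"`, `"unscored"`).
#' @param subject_id Subject identifier.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(arousals = NULL, resp_events = NULL,
                           desaturations = NULL, stage_epochs = NULL,
                           subject_id = "subject") {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(lapply(cols, function(cl) vector(cl, 0L)),
                  col.names = names(cols))
  }
  if (is.null(arousals))
    arousals <- empty(start_s = "numeric", duration_s = "numeric",
                      scored_cause = "character")
  if (is.null(arousals$scored_cause)) arousals$scored_cause <- "unspecified"
  if (is.null(resp_events))
    resp_events <- empty(start_s = "numeric", duration_s = "numeric",
                         type = "character")
  if (is.null(desaturations))
    desaturations <- empty(start_s = "numeric", duration_s = "numeric")
  if (is.null(stage_epochs))
    stage_epochs <- empty(epoch_start_s = "numeric", stage = "character")
  stopifnot(all(arousals$duration_s > 0), all(resp_events$duration_s > 0),
            all(arousals$start_s >= 0), all(resp_events$start_s >= 0))
  structure(
    list(arousals = arousals, resp_events = resp_events,
         desaturations = desaturations, stage_epochs = stage_epochs,
         subject_id = as.character(subject_id)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(paste0("<annotation_set> subject %s: %d arousals, %d resp ",
                     "events, %d desaturations, %d epochs\n"),
              x$subject_id, nrow(x$arousals), nrow(x$resp_events),
              nrow(x$desaturations), nrow(x$stage_epochs)))
  invisible(x)
}

#' Default event-selection settings
#'
#' @param proximity_s Exclusion radius around an arousal for other scored
#'   arousals and non-causal respiratory events (default 10 s).
#' @param assoc_lookback_s How long before the arousal start the causal
#'   respiratory event may have ended (default 5 s).
#' @param min_event_s Minimum duration of a causal respiratory event
#'   (default 10 s).
#' @param desat_window_s Window after the respiratory event end within which
#'   an overlapping desaturation counts as accompanying it (default 20 s).
#' @param min_arousal_s,max_arousal_s Allowed arousal duration range
#'   (default 3 and 15 s).
#' @return A list of settings.
#' @export
events_control <- function(proximity_s = 10, assoc_lookback_s = 5,
                           min_event_s = 10, desat_window_s = 20,
                           min_arousal_s = 3, max_arousal_s = 15) {
  list(proximity_s = proximity_s, assoc_lookback_s = assoc_lookback_s,
       min_event_s = min_event_s, desat_window_s = desat_window_s,
       min_arousal_s = min_arousal_s, max_arousal_s = max_arousal_s)
}

.overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

.epoch_stage <- function(stage_epochs, time_s) {
  i <- which(stage_epochs$epoch_start_s <= time_s &
               time_s < stage_epochs$epoch_start_s + 30)
  if (length(i) == 0L) "unscored" else stage_epochs$stage[i[1]]
}

#' Associate an arousal with its causal obstructive respiratory event
#'
#' A candidate is an obstructive apnea or hypopnea of duration at least
#' `min_event_s` that ended no earlier than `assoc_lookback_s` before the
#' arousal start and at the latest at the arousal end. The association must
#' be unique: zero or two or more candidates yield no association.
#'
#' @param start_s,duration_s Arousal start and duration in seconds.
#' @param resp_events Respiratory event data.frame (see [annotation_set()]).
#' @param control See [events_control()].
#' @return A one-row data.frame (the associated event) or `NULL`.
#' @export
associate_respiratory_event <- function(start_s, duration_s, resp_events,
                                        control = events_control()) {
  if (nrow(resp_events) == 0L) return(NULL)
  ends <- resp_events$start_s + resp_events$duration_s
  cand <- resp_events$type %in% OBSTRUCTIVE_TYPES &
    resp_events$duration_s >= control$min_event_s &
    ends >= start_s - control$assoc_lookback_s &
    ends <= start_s + duration_s
  if (sum(cand) != 1L) return(NULL)
  resp_events[cand, , drop = FALSE]
}

#' Flag whether a respiratory event is accompanied by a desaturation
#'
#' `TRUE` when any desaturation overlaps the window from the event start to
#' `desat_window_s` seconds after the event end.
#'
#' @param event_start_s,event_duration_s The associated respiratory event.
#' @param desaturations Desaturation data.frame with `start_s`, `duration_s`.
#' @param control See [events_control()].
#' @return Logical scalar.
#' @export
flag_desaturation <- function(event_start_s, event_duration_s, desaturations,
                              control = events_control()) {
  if (nrow(desaturations) == 0L) return(FALSE)
  lo <- event_start_s
  hi <- event_start_s + event_duration_s + control$desat_window_s
  any(.overlaps(desaturations$start_s,
                desaturations$start_s + desaturations$duration_s, lo, hi))
}

#' Apply the arousal inclusion rules and classify causes
#'
#' Rules are evaluated in a fixed order and only the first failure is logged:
#' \enumerate{
#'   \item duration: arousal shorter than 3 s or longer than 15 s;
#'   \item stage: neither the arousal's 30-s epoch nor the previous one has a
#'     scored sleep stage;
#'   \item proximity: another scored arousal, or a respiratory event other
#'     than the assumed cause, within 10 s of the arousal start or end;
#'   \item association: the assumed causal obstructive event lasted less than
#'     10 s;
#'   \item uniqueness: more than one obstructive event qualifies as the cause.
#' }
#' Arousals with no nearby obstructive cause are classified spontaneous;
#' associated arousals are classified by event type and desaturation presence
#' (`"apnea+des"`, `"apnea-des"`, `"hypopnea+des"`, `"hypopnea-des"`).
#' Central and mixed apneas are never causes; their proximity excludes the
#' arousal.
#'
#' @param ann An [annotation_set()].
#' @param control See [events_control()].
#' @return A list with `cases` (data.frame of included arousals: `arousal_id`,
#'   `start_s`, `duration_s`, `cause`, `stage`, associated event columns) and
#'   `exclusions` (data.frame: `arousal_id`, `start_s`, `duration_s`, `rule`,
#'   `details`).
#' @export
filter_and_classify <- function(ann, control = events_control()) {
  stopifnot(inherits(ann, "annotation_set"))
  ar <- ann$arousals
  n <- nrow(ar)
  cases <- list(); excl <- list()
  re <- ann$resp_events
  re_end <- if (nrow(re)) re$start_s + re$duration_s else numeric()

  for (i in seq_len(n)) {
    s <- ar$start_s[i]; d <- ar$duration_s[i]; e <- s + d
    id <- if (!is.null(ar$arousal_id)) ar$arousal_id[i] else i
    fail <- function(rule, details = "") {
      data.frame(arousal_id = id, start_s = s, duration_s = d,
                 rule = rule, details = details)
    }

    # 1. duration
    if (d < control$min_arousal_s || d > control$max_arousal_s) {
      excl[[length(excl) + 1L]] <- fail("duration", sprintf("%.2f s", d))
      next
    }

    # 2. stage: own epoch, else previous
    own <- .epoch_stage(ann$stage_epochs, s)
    prev <- .epoch_stage(ann$stage_epochs, s - 30)
    stage <- if (own != "unscored") own else prev
    if (stage == "unscored") {
      excl[[length(excl) + 1L]] <- fail("stage", "no scored stage in own or previous epoch")
      next
    }

    # assumed cause: obstructive events ending in the association window
    # (any duration at this point; the length gate is the association rule)
    assumed <- if (nrow(re)) {
      which(re$type %in% OBSTRUCTIVE_TYPES &
              re_end >= s - control$assoc_lookback_s & re_end <= e)
    } else integer()

    # 3. proximity: other arousals, and respiratory events other than the
    # assumed cause, within proximity_s of the arousal start or end
    other_ar <- setdiff(seq_len(n), i)
    near_ar <- any(.overlaps(ar$start_s[other_ar],
                             ar$start_s[other_ar] + ar$duration_s[other_ar],
                             s - control$proximity_s, e + control$proximity_s))
    other_re <- setdiff(seq_len(nrow(re)), assumed)
    near_re <- length(other_re) > 0 &&
      any(.overlaps(re$start_s[other_re], re_end[other_re],
                    s - control$proximity_s, e + control$proximity_s))
    if (near_ar || near_re) {
      excl[[length(excl) + 1L]] <- fail(
        "proximity", if (near_ar) "another arousal within 10 s"
                     else "non-causal respiratory event within 10 s")
      next
    }

    # 4./5. association and uniqueness
    if (length(assumed) == 0L) {
      cause <- "spontaneous"
      ev <- NULL
    } else if (length(assumed) > 1L) {
      excl[[length(excl) + 1L]] <- fail(
        "uniqueness", sprintf("%d candidate events", length(assumed)))
      next
    } else if (re$duration_s[assumed] < control$min_event_s) {
      excl[[length(excl) + 1L]] <- fail(
        "association", sprintf("causal event lasted %.2f s", re$duration_s[assumed]))
      next
    } else {
      ev <- re[assumed, , drop = FALSE]
      des <- flag_desaturation(ev$start_s, ev$duration_s, ann$desaturations,
                               control)
      base <- if (ev$type == "obstructive_apnea") "apnea" else "hypopnea"
      cause <- paste0(base, if (des) "+des" else "-des")
    }

    cases[[length(cases) + 1L]] <- data.frame(
      subject_id = ann$subject_id, arousal_id = id,
      start_s = s, duration_s = d, cause = cause, stage = stage,
      event_start_s = if (is.null(ev)) NA_real_ else ev$start_s,
      event_duration_s = if (is.null(ev)) NA_real_ else ev$duration_s,
      event_type = if (is.null(ev)) NA_character_ else ev$type
    )
  }
  list(
    cases = if (length(cases)) do.call(rbind, cases) else
      data.frame(subject_id = character(), arousal_id = integer(),
                 start_s = numeric(), duration_s = numeric(),
                 cause = character(), stage = character(),
                 event_start_s = numeric(), event_duration_s = numeric(),
                 event_type = character()),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(arousal_id = integer(), start_s = numeric(),
                 duration_s = numeric(), rule = character(),
                 details = character())
  )
}

#' Sample stable-sleep reference periods
#'
#' Enumerates event-free, transition-free 10-s candidate periods on a 1-s
#' grid, thins them greedily to be non-overlapping, groups them by sleep
#' stage, randomly permutes each group and takes up to as many samples as the
#' subject has included respiratory arousals in that stage (all candidates
#' when fewer exist). Each sample carries the mean of both characteristics
#' over its 10 s.
#'
#' @param ann An [annotation_set()].
#' @param cases Included arousal cases from [filter_and_classify()]; only
#'   respiratory (non-spontaneous) cases set the per-stage quota.
#' @param provider A characteristics provider from
#'   [make_characteristics_provider()] (or any function of `start_s`
#'   returning `list(mean_frequency, mean_amplitude)`, optionally with a
#'   `"bounds"` attribute).
#' @param seed Integer seed for the permutation.
#' @return data.frame with `subject_id`, `start_s`, `duration_s`, `stage`,
#'   `mean_frequency`, `mean_amplitude` (zero rows when no candidates exist).
#' @export
sample_stable_sleep <- function(ann, cases, provider, seed = 1L) {
  stopifnot(inherits(ann, "annotation_set"))
  resp <- cases[cases$cause != "spontaneous", , drop = FALSE]
  out <- list()
  bounds <- attr(provider, "bounds") %||% c(-Inf, Inf)

  ev_start <- c(ann$arousals$start_s, ann$resp_events$start_s,
                ann$desaturations$start_s)
  ev_end <- c(ann$arousals$start_s + ann$arousals$duration_s,
              ann$resp_events$start_s + ann$resp_events$duration_s,
              ann$desaturations$start_s + ann$desaturations$duration_s)

  se <- ann$stage_epochs
  with_local_seed(seed, {
    for (stg in SLEEP_STAGES) {
      need <- sum(resp$stage == stg)
      if (need == 0L) next
      ep <- se$epoch_start_s[se$stage == stg]
      if (length(ep) == 0L) next
      starts <- sort(unlist(lapply(ep, function(t0) t0 + 0:29)))
      ok <- vapply(starts, function(t0) {
        if (t0 < bounds[1] || t0 > bounds[2]) return(FALSE)
        # stage constant over [t0, t0 + 10): both covering epochs match
        if (.epoch_stage(se, t0) != stg) return(FALSE)
        if (.epoch_stage(se, t0 + 10 - 1e-9) != stg) return(FALSE)
        !any(.overlaps(ev_start, ev_end, t0, t0 + 10))
      }, logical(1))
      starts <- starts[ok]
      # greedy thinning to non-overlapping periods
      kept <- numeric()
      last <- -Inf
      for (t0 in starts) {
        if (t0 >= last + 10) { kept <- c(kept, t0); last <- t0 }
      }
      if (length(kept) == 0L) next
      kept <- kept[sample.int(length(kept))]
      take <- utils::head(kept, need)
      for (t0 in take) {
        ch <- provider(t0)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = ann$subject_id, start_s = t0, duration_s = 10,
          stage = stg, mean_frequency = ch$mean_frequency,
          mean_amplitude = ch$mean_amplitude)
      }
    }
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), start_s = numeric(),
               duration_s = numeric(), stage = character(),
               mean_frequency = numeric(), mean_amplitude = numeric())
}

# Run code with a local RNG state, restoring the caller's stream afterwards.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
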