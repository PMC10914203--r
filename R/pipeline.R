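# End-to-end orchestration: configuration, validation, per-subject analysis
# and report/artifact writing.

#' Default run configuration
#'
#' Bundles the settings of every stage: the synthetic-cohort generator (or
#' input paths for user-supplied data), event selection, characteristic
#' derivation, step-model fitting and statistics.
#'
#' @param synth A [cohort_config()] (ignored when `input` is given).
#' @param input Optional list of subjects with elements `ppg_csv` and
#'   `annotations_csv` (paths) for user-supplied data.
#' @param events See [events_control()].
#' @param respmodel See [respmodel_control()].
#' @param stats See [stats_control()].
#' @param seed Integer master seed (propagated to stages lacking their own).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(synth = cohort_config(), input = NULL,
                               events = events_control(),
                               respmodel = respmodel_control(),
                               stats = stats_control(),
                               seed = 1L) {
  structure(
    list(synth = synth, input = input, events = events,
         respmodel = respmodel, stats = stats, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Schema and range checks for every parameter; an empty return means the
#' configuration is runnable. Problems are returned, not raised.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return Character vector of problems (empty when valid).
#' @export
validate_run_config <- function(config) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  ev <- config$events
  if (!is.numeric(ev$proximity_s) || ev$proximity_s < 0)
    add("events$proximity_s must be >= 0")
  if (!is.numeric(ev$assoc_lookback_s) || ev$assoc_lookback_s < 0)
    add("events$assoc_lookback_s must be >= 0")
  if (!is.numeric(ev$min_event_s) || ev$min_event_s <= 0)
    add("events$min_event_s must be > 0")
  if (!is.numeric(ev$desat_window_s) || ev$desat_window_s < 0)
    add("events$desat_window_s must be >= 0")
  if (ev$min_arousal_s >= ev$max_arousal_s)
    add("events$min_arousal_s must be below events$max_arousal_s")

  rm_ <- config$respmodel
  if (rm_$growth <= 0) add("respmodel$growth must be > 0")
  if (rm_$b_rel_max <= 0) add("respmodel$b_rel_max must be > 0")
  if (rm_$threshold < 0 || rm_$threshold >= 1)
    add("respmodel$threshold must be in [0, 1)")
  # the analysis window is [-8, duration + 8]; c1 starts must be inside
  # [t_min, t_max - 3] for the shortest admissible arousal
  t_min <- -8; t_max_min <- ev$min_arousal_s + 8
  if (any(rm_$c1_starts < t_min | rm_$c1_starts > t_max_min - 3))
    add(sprintf("respmodel$c1_starts outside fit window [%g, %g]",
                t_min, t_max_min - 3))
  if (any(rm_$c2_rel_starts < 0 | rm_$c2_rel_starts > 1))
    add("respmodel$c2_rel_starts must be in [0, 1]")
  if (any(rm_$c3_rel_starts < 0 | rm_$c3_rel_starts > 1))
    add("respmodel$c3_rel_starts must be in [0, 1]")

  st <- config$stats
  if (st$n_iterations < 1) add("stats$n_iterations must be >= 1")
  if (st$alpha <= 0 || st$alpha >= 1) add("stats$alpha must be in (0, 1)")
  if (st$ci_level <= 0 || st$ci_level >= 1)
    add("stats$ci_level must be in (0, 1)")

  if (is.null(config$input) && !inherits(config$synth, "cohort_config"))
    add("synth must be a cohort_config when no input paths are given")
  problems
}

#' Analyze one subject
#'
#' Applies the full per-subject chain: decimation to 64 Hz, arousal
#' filtering and classification, characteristic derivation, multistart
#' step-model fitting and categorization, and stable-sleep sampling.
#'
#' @param record A [ppg_record()].
#' @param ann An [annotation_set()].
#' @param config A `run_config`.
#' @return A list with `calls` (per-arousal, per-kind data.frame),
#'   `stable` (stable-sleep samples), `exclusions` and `dropped`
#'   (arousals lost to segment bounds or failed fits).
#' @export
analyze_subject <- function(record, ann, config = default_run_config()) {
  rec <- ppg_decimate(record, 64)
  flt <- filter_and_classify(ann, config$events)
  cases <- flt$cases
  calls <- list(); dropped <- list()

  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ch <- tryCatch(arousal_characteristics(rec, cs$start_s, cs$duration_s),
                   error = function(e) NULL)
    if (is.null(ch)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        arousal_id = cs$arousal_id, reason = "segment out of bounds")
      next
    }
    res <- detect_responses(ch$frequency, ch$amplitude, config$respmodel)
    for (kd in c("frequency", "amplitude")) {
      cl <- res[[kd]]
      if (is.null(cl)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          arousal_id = cs$arousal_id, reason = paste("unsuccessful", kd, "fit"))
        next
      }
      calls[[length(calls) + 1L]] <- data.frame(
        subject_id = cs$subject_id, arousal_id = cs$arousal_id,
        start_s = cs$start_s, duration_s = cs$duration_s,
        cause = cs$cause, stage = cs$stage, kind = kd,
        category_id = cl$category_id,
        response_present = cl$response_present,
        response_step = cl$response_step,
        magnitude = cl$magnitude, delay_s = cl$delay,
        recovery_present = cl$recovery_present,
        level_before = cl$level_before, level_after = cl$level_after,
        ssr = cl$ssr)
    }
  }
  provider <- make_characteristics_provider(rec)
  stable <- sample_stable_sleep(ann, cases, provider,
                                seed = config$seed + 17L)
  list(
    calls = if (length(calls)) do.call(rbind, calls) else NULL,
    stable = stable,
    exclusions = flt$exclusions,
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL
  )
}

#' Run the full pipeline
#'
#' Generates (or loads) the cohort, analyzes every subject, builds the
#' report and, when `out_dir` is given, writes the artifact set: per-arousal
#' calls, stable-sleep samples, exclusion log, report tables, the synthetic
#' truth table and a run manifest (configuration hash, seed, package
#' version). Reruns with the same configuration produce identical artifacts.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `calls`, `stable`, `exclusions`,
#'   `dropped`, `report`, `truth` and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  problems <- validate_run_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }

  if (is.null(config$input)) {
    cohort <- generate_cohort(config$synth)
    subjects <- lapply(cohort, function(s)
      list(record = s$record, annotations = s$annotations))
    truth <- cohort_truth_table(cohort)
  } else {
    subjects <- lapply(seq_along(config$input), function(i) {
      inp <- config$input[[i]]
      sid <- inp$subject_id %||% sprintf("S%03d", i)
      list(record = read_ppg_csv(inp$ppg_csv, sid),
           annotations = read_annotations_csv(inp$annotations_csv, sid))
    })
    truth <- NULL
  }

  res <- lapply(subjects, function(s)
    analyze_subject(s$record, s$annotations, config))
  bind <- function(el) {
    parts <- Filter(Negate(is.null), lapply(res, `[[`, el))
    if (length(parts)) do.call(rbind, parts) else NULL
  }
  calls <- bind("calls")
  stable <- bind("stable")
  exclusions <- bind("exclusions")
  dropped <- bind("dropped")

  report <- if (!is.null(calls)) build_report(calls, stable, config$stats)
            else NULL

  manifest <- list(
    package = "ppgarousal",
    version = as.character(utils::packageVersion("ppgarousal")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_subjects = length(subjects),
    n_calls = if (is.null(calls)) 0L else nrow(calls)
  )

  out <- list(calls = calls, stable = stable, exclusions = exclusions,
              dropped = dropped, report = report, truth = truth,
              manifest = manifest)
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  invisible(out)
}

#' Hash a configuration
#'
#' MD5 digest of the serialized configuration, recorded in the run manifest
#' so that a run is reproducible from its manifest alone.
#'
#' @param config Any R object.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

write_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(out$calls, "arousal_calls.csv")
  wr(out$stable, "stable_samples.csv")
  wr(out$exclusions, "exclusion_log.csv")
  wr(out$dropped, "dropped.csv")
  wr(out$truth, "truth.csv")
  rp <- out$report
  if (!is.null(rp)) {
    for (kd in names(rp$proportions)) {
      wr(rp$proportions[[kd]], paste0("proportions_", kd, ".csv"))
      wr(as.data.frame(rp$magnitude[[kd]]$p), paste0("magnitude_p_", kd, ".csv"))
      wr(as.data.frame(rp$delay[[kd]]$p), paste0("delay_p_", kd, ".csv"))
      wr(rp$levels[[kd]], paste0("levels_", kd, ".csv"))
      wr(as.data.frame(rp$rr_response[[kd]]$rr), paste0("rr_response_", kd, ".csv"))
      wr(as.data.frame(rp$rr_recovery[[kd]]$rr), paste0("rr_recovery_", kd, ".csv"))
    }
    summary <- list(
      medians = list(magnitude = lapply(rp$magnitude, `[[`, "median"),
                     delay = lapply(rp$delay, `[[`, "median")),
      meta = rp$meta)
    jsonlite::write_json(summary, file.path(out_dir, "report_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
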