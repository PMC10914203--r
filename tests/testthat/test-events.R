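# Arousal inclusion rules, cause classification, desaturation flagging and
# stable-sleep sampling.

test_that("duration and stage gates exclude with the right reasons", {
  ann <- make_ann(
    arousals = data.frame(start_s = c(100, 150, 200, 335),
                          duration_s = c(2.5, 16, 10, 5),
                          scored_cause = "spontaneous"),
    unscored_epochs = c(11, 12))   # epochs [300, 330) and [330, 360)
  out <- filter_and_classify(ann)
  expect_equal(nrow(out$cases), 1)
  expect_equal(out$cases$start_s, 200)
  expect_equal(out$cases$cause, "spontaneous")
  expect_equal(out$cases$stage, "N2")
  ex <- out$exclusions[order(out$exclusions$start_s), ]
  expect_equal(ex$rule, c("duration", "duration", "stage"))
})

test_that("nearby arousals exclude each other, matching a brute-force oracle", {
  starts <- c(200, 250, 263, 400)   # 250 ends 255; 263 starts 8 s later
  ann <- make_ann(arousals = data.frame(start_s = starts, duration_s = 5,
                                        scored_cause = "spontaneous"))
  out <- filter_and_classify(ann)
  # oracle: pairwise interval-distance check over all arousals
  gap <- function(i, j) {
    max(starts[j] - (starts[i] + 5), starts[i] - (starts[j] + 5))
  }
  keep_oracle <- vapply(seq_along(starts), function(i) {
    all(vapply(setdiff(seq_along(starts), i),
               function(j) gap(i, j) >= 10, logical(1)))
  }, logical(1))
  expect_setequal(out$cases$start_s, starts[keep_oracle])
  expect_true(all(c(250, 263) %in% out$exclusions$start_s))
  expect_equal(out$exclusions$rule, c("proximity", "proximity"))
})

test_that("overlapping duplicate arousals are both excluded", {
  ann <- make_ann(arousals = data.frame(start_s = c(100, 102), duration_s = 6,
                                        scored_cause = "spontaneous"))
  out <- filter_and_classify(ann)
  expect_equal(nrow(out$cases), 0)
  expect_equal(out$exclusions$rule, c("proximity", "proximity"))
})

test_that("respiratory association follows the lookback, length and uniqueness rules", {
  re <- function(end, dur, type = "obstructive_apnea") {
    data.frame(start_s = end - dur, duration_s = dur, type = type)
  }
  # 12-s event ending 3 s before the arousal start: associated
  ev <- associate_respiratory_event(100, 8, re(97, 12))
  expect_equal(ev$duration_s, 12)
  # event ending 6 s before the start: outside the 5-s lookback
  expect_null(associate_respiratory_event(100, 8, re(94, 12)))
  # event ending during the arousal: associated
  expect_false(is.null(associate_respiratory_event(100, 8, re(104, 15))))
  # 9-s event ending at the arousal start: too short
  expect_null(associate_respiratory_event(100, 8, re(100, 9)))
  # two qualifying events: not uniquely associated (oracle: candidate count)
  two <- rbind(re(98, 12), re(103, 14, "hypopnea"))
  ends <- two$start_s + two$duration_s
  n_cand <- sum(two$duration_s >= 10 & ends >= 95 & ends <= 108)
  expect_equal(n_cand, 2)
  expect_null(associate_respiratory_event(100, 8, two))
  # central apnea is never a candidate
  expect_null(associate_respiratory_event(100, 8, re(97, 12, "central_apnea")))
})

test_that("filter_and_classify assigns causes and association exclusions", {
  ann <- make_ann(
    arousals = data.frame(
      start_s = c(400, 450, 500, 550, 600, 650),
      duration_s = 8,
      scored_cause = c("respiratory", "respiratory", "respiratory",
                       "spontaneous", "respiratory", "spontaneous")),
    resp_events = data.frame(
      start_s = c(386, 440, 486, 489, 534, 587, 631),
      duration_s = c(12, 9, 12, 14, 15, 15, 12),
      type = c("obstructive_apnea", "obstructive_apnea", "hypopnea",
               "obstructive_apnea", "central_apnea", "hypopnea",
               "obstructive_apnea")),
    desaturations = data.frame(start_s = 600, duration_s = 15))
  out <- filter_and_classify(ann)
  # 400: apnea ending 398, no desat -> apnea-des
  # 450: 9-s event -> association exclusion
  # 500: two candidates -> uniqueness
  # 550: central apnea ending 549 -> proximity (non-causal event)
  # 600: hypopnea ending 602 with desat at 600 -> hypopnea+des
  # 650: apnea ending 643, before the 5-s lookback -> proximity
  cs <- out$cases[order(out$cases$start_s), ]
  expect_equal(cs$start_s, c(400, 600))
  expect_equal(cs$cause, c("apnea-des", "hypopnea+des"))
  ex <- out$exclusions[order(out$exclusions$start_s), ]
  expect_equal(ex$start_s, c(450, 500, 550, 650))
  expect_equal(ex$rule, c("association", "uniqueness", "proximity", "proximity"))
})

test_that("every arousal is partitioned into one case or one logged exclusion", {
  cfg <- cohort_config(n_subjects = 3, arousals_per_subject = 4,
                       n_excludable = 2, seed = 17)
  for (s in generate_cohort(cfg)) {
    out <- filter_and_classify(s$annotations)
    n_in <- nrow(out$cases)
    n_ex <- nrow(out$exclusions)
    expect_equal(n_in + n_ex, nrow(s$annotations$arousals))
    # includable arousals per the generator truth pass the filters, planted
    # excludable ones fail them
    tr <- s$truth$arousals
    expect_setequal(round(out$cases$start_s, 6),
                    round(tr$start_s[tr$includable], 6))
  }
})

test_that("filtering is idempotent on an already-filtered case list", {
  cfg <- cohort_config(n_subjects = 2, arousals_per_subject = 4,
                       n_excludable = 1, seed = 19)
  for (s in generate_cohort(cfg)) {
    out1 <- filter_and_classify(s$annotations)
    ann2 <- s$annotations
    keep <- round(ann2$arousals$start_s, 9) %in% round(out1$cases$start_s, 9)
    ann2$arousals <- ann2$arousals[keep, , drop = FALSE]
    out2 <- filter_and_classify(ann2)
    expect_equal(nrow(out2$exclusions), 0)
    expect_equal(out2$cases$start_s, out1$cases$start_s)
    expect_equal(out2$cases$cause, out1$cases$cause)
  }
})

test_that("desaturation flagging uses the event window plus the lag", {
  desat <- data.frame(start_s = 110, duration_s = 10)
  # fully inside the event
  expect_true(flag_desaturation(100, 30, desat))
  # no desaturations at all
  expect_false(flag_desaturation(100, 30, desat[0, ]))
  # oracle: brute-force overlap with [start, end + 20]
  ctrl <- events_control()
  ev_end <- 100 + 15
  d_late <- data.frame(start_s = ev_end + ctrl$desat_window_s + 1,
                       duration_s = 10)
  expect_false(flag_desaturation(100, 15, d_late))
  d_edge <- data.frame(start_s = ev_end + ctrl$desat_window_s - 1,
                       duration_s = 10)
  expect_true(flag_desaturation(100, 15, d_edge))
})

test_that("stable-sleep sampling takes up to the per-stage arousal count", {
  ann <- make_ann(total_s = 600)   # 20 N2 epochs, no events
  cases3 <- data.frame(subject_id = "T01", cause = "apnea+des", stage = "N2")[rep(1, 3), ]
  out <- sample_stable_sleep(ann, cases3, const_provider(), seed = 5)
  expect_equal(nrow(out), 3)
  expect_true(all(out$stage == "N2"))
  expect_equal(out$mean_frequency, rep(1.5, 3))

  # only one candidate but five arousals: all (one) candidates are taken
  ann1 <- make_ann(
    total_s = 60,
    resp_events = data.frame(start_s = 12, duration_s = 60,
                             type = "obstructive_apnea"))
  cases5 <- cases3[rep(1, 5), ]
  out1 <- sample_stable_sleep(ann1, cases5, const_provider(), seed = 5)
  expect_equal(nrow(out1), 1)

  # zero arousals: zero samples
  out0 <- sample_stable_sleep(ann, cases3[0, ], const_provider(), seed = 5)
  expect_equal(nrow(out0), 0)
})

test_that("stable samples are non-overlapping, event-free and stage-dominated", {
  cfg <- cohort_config(n_subjects = 3, arousals_per_subject = 5, seed = 23)
  for (s in generate_cohort(cfg)) {
    out <- filter_and_classify(s$annotations)
    st <- sample_stable_sleep(s$annotations, out$cases,
                              const_provider(), seed = 7)
    if (nrow(st) < 2) next
    o <- st[order(st$start_s), ]
    expect_true(all(diff(o$start_s) >= 10))
    ann <- s$annotations
    for (i in seq_len(nrow(st))) {
      expect_false(any(ann$arousals$start_s < st$start_s[i] + 10 &
                         ann$arousals$start_s + ann$arousals$duration_s >
                           st$start_s[i]))
    }
    # per-stage sample counts never exceed respiratory-arousal counts
    resp <- out$cases[out$cases$cause != "spontaneous", ]
    for (stg in unique(st$stage)) {
      expect_lte(sum(st$stage == stg), sum(resp$stage == stg))
    }
  }
})
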