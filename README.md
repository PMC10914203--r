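# ppgarousal

Arousals from sleep — whether caused by obstructive apneas, hypopneas, or
occurring spontaneously — trigger autonomic responses that are visible in the
photoplethysmogram (PPG): the pulse rate rises and peripheral
vasoconstriction lowers the pulsation amplitude. `ppgarousal` is an R
package for sleep researchers and biomedical-signal engineers that detects
and quantifies these responses per arousal and compares their magnitude and
timing across arousal causes (spontaneous vs. obstructive apnea/hypopnea,
with or without ≥3% oxygen desaturation).

## Method

Per subject, the PPG is decimated to 64 Hz and two characteristics are
derived around each scored arousal (10 s of lead-in and lead-out, smoothed
with a 2-s moving average, t = 0 at the EEG arousal onset):

* the **mean instantaneous frequency**
  $\bar f_{inst}(t) = \sum_f f\,P_f / \sum_f P_f$, the power-weighted mean
  of the short-time spectrum (2-s boxcar window, hop 1 sample, zero-padded
  transform of length 16·64, bins 0–32 Hz in 1/16 Hz steps);
* the **instantaneous amplitude**, max − min of the PPG in the same 2-s
  sliding window.

Each trace is fit by bounded multistart least squares with a sum of three
logistic steps with alternating signs and fixed growth rate 5,

$$f(t) = a + \frac{b_1}{1+e^{-5(t-c_1)}} - \frac{b_1 b_2}{1+e^{-5(t-c_2)}}
  + \frac{b_1 b_3}{1+e^{-5(t-c_3)}},$$

and the fitted steps are classified: a step is considerable when it exceeds
5% of the mean fitted value; the response is the considerable step in the
response direction (frequency increase, amplitude decrease) with the
largest level change from the window-start level $a$; its magnitude is that
level difference, its delay the step time, and a later considerable
opposite step is a recovery. Groups of arousals are compared with iterated
subject-paired Wilcoxon signed-rank tests (median p over 1000 within-subject
resamplings), relative risks with 99% CIs, and baseline comparisons against
stable-sleep medians.

A synthetic polysomnography generator (`generate_cohort()`) produces
pulse-train PPG with planted, ground-truthed responses and rule-consistent
annotations, so the whole pipeline is testable without clinical recordings.

## Worked example

Classify the fitted step model of a frequency trace (parameters of a real
fit: window start level 1.44 Hz, steps +0.120, −0.136, +0.263 Hz at
−4.45 s, −2.53 s and 4.23 s):

```r
library(ppgarousal)
fit <- logistic_fit(a = 1.44, b1 = 0.120, b2_rel = 0.136/0.120,
                    b3_rel = 0.263/0.120, c1 = -4.45,
                    c2_rel = 0.0459, c3_rel = 0.301,
                    t_min = -8, t_max = 18.6)
categorize(fit, "frequency")
#> <response_call> frequency: response at step 3, magnitude 0.247, delay 4.23 s, recovery no (category 8)
```

The call reads: the pulse-frequency rise attributable to this arousal is the
third fitted step, the level settles 0.247 Hz above the pre-arousal level,
the response midpoint lags the EEG arousal onset by 4.23 s, and no recovery
occurs within the analysis window.

End-to-end on a synthetic cohort:

```r
cfg <- default_run_config(
  synth = cohort_config(n_subjects = 3, arousals_per_subject = 3, seed = 5),
  stats = stats_control(n_iterations = 200, seed = 5))
out <- run_pipeline(cfg, out_dir = "run1")
out$report$magnitude$frequency$median
#>  spontaneous    apnea+des    apnea-des hypopnea+des hypopnea-des
#>    0.1356088    0.2505733    0.3535091    0.1769320    0.2611835
```

`run1/` then contains the per-arousal calls, the stable-sleep samples, the
exclusion log, the report tables (proportions, relative risks, pairwise
median-p matrices, baseline-relative levels) and a manifest with the
configuration hash; reruns of the same configuration are byte-identical.

## Documentation

The methods vignette (`vignettes/ppg-arousal-responses.Rmd`) describes the
estimators, the step model and its categorization, the selection rules, the
inference, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
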