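---
title: "Detecting PPG frequency and amplitude responses to arousals from sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PPG frequency and amplitude responses to arousals from sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgarousal)
```

## The problem

Arousals from sleep trigger sympathetic responses: the heart rate rises and
peripheral vasoconstriction sets in. Both are visible in the
photoplethysmogram (PPG): its dominant frequency tracks the pulse rate and
its pulsation amplitude falls under vasoconstriction. In obstructive sleep
apnea (OSA), arousals are caused by airway obstructions (apneas and
hypopneas) of varying severity, with or without accompanying blood-oxygen
desaturations, and also occur spontaneously. `ppgarousal` quantifies the PPG
response to each scored arousal — its presence, direction, magnitude, delay
relative to the EEG arousal onset, and whether it recovers within the
analysis window — and compares these quantities across arousal causes with
subject-paired resampled inference.

## Signal characteristics

Each subject's PPG is decimated to 64 Hz (zero-phase windowed-sinc
anti-aliasing at 0.8 of the target Nyquist; polyphase resampling for
non-integer factors). For each arousal a segment from 10 s before the
arousal start to 10 s after its end is extracted, and two characteristics
are derived on a 1/64 s grid:

* **Mean instantaneous frequency** (Hz): for every position of a 2-s boxcar
  window advanced one sample at a time, the window is zero-padded to
  16 × 64 = 1024 points and the power-weighted mean frequency
  $\bar f_{inst}(t) = \sum_f f\,P_f / \sum_f P_f$ is computed over bins 0 to
  32 Hz in 1/16 Hz steps.
* **Instantaneous amplitude** (a.u.): the maximum minus the minimum PPG
  value in the same 2-s sliding window.

Both traces are smoothed with a centered 2-s moving average. The windowing
losses are trimmed so that each final trace spans exactly the arousal
duration plus 16 s — from 8 s before the arousal start to 8 s after its end —
with t = 0 at the EEG arousal onset.

Two numerical choices deserve note. First, each spectrogram window is
mean-removed before the transform. With a raw boxcar window the DC
component leaks into the nearby 1/16 Hz bins and biases the weighted mean;
mean removal makes a constant segment map to exactly 0 Hz and matches the
default behaviour of the standard Python spectrogram implementations this
estimator mirrors. Second, the estimator has a known upward bias of
roughly +0.1 Hz on narrowband input, because the rectangular window's
leakage tails extend much further above the pulse fundamental (up to the
32 Hz bin edge) than below it, and the higher pulse harmonics contribute to
the weighted mean. The bias is close to constant in time, so response
*magnitudes* — differences of levels — are essentially unaffected; the test
suite verifies that planted changes are recovered to within a few percent.

## The step model

A sum of three consecutive logistic transitions with alternating signs is
fit to each characteristic trace:

$$f(t) = a + \frac{b_1}{1+e^{-5(t-c_1)}} - \frac{b_1 b_{2}}{1+e^{-5(t-c_2)}}
  + \frac{b_1 b_{3}}{1+e^{-5(t-c_3)}}$$

with $c_2 = c_1 + 1 + c_{2,rel}(t_{max}-c_1-3)$ and
$c_3 = c_2 + 1 + c_{3,rel}(t_{max}-c_2-2)$, which keeps the transitions
ordered with at least 1 s between them. The growth rate is fixed at 5; the
seven free parameters are $a$, $b_1$, $b_{2}$, $b_{3}$ (relative to $b_1$),
$c_1$, $c_{2,rel}$, $c_{3,rel}$. Fitting is bounded Levenberg-Marquardt
least squares (an analytic Jacobian is supplied) with bounds
$a \in [0, y_{max}]$, $b_1 \in [-y_{max}, y_{max}]$, relative magnitudes in
$[0, 20]$, $c_1 \in [t_{min}, t_{max}-3]$ and relative times in $[0, 1]$,
where $y_{max}$ is the largest value in the window. Because the least
squares surface is multimodal, the fit is restarted from a grid of initial
guesses — $c_1 \in \{-4,-2,0,2,4\}$ s around the arousal start,
$c_{2,rel} \in \{0.25, 0.5, 0.75\}$ around the halfway point, and
$c_{3,rel} \in \{0.6, 0.8, 0.95\}$ biased late to catch very late changes —
with $a$ started at the pre-arousal median, $b_1$ at 0 and the relative
magnitudes at 1. The minimum-SSR fit wins; ties break by grid order and
arousals where every start fails are discarded and logged.

## Categorization into response calls

The three fitted steps have signed magnitudes $b_1$, $-b_1 b_2$ and
$+b_1 b_3$. A step is *considerable* when its absolute magnitude exceeds 5%
of the mean fitted value over the window (the threshold is deliberately
relative, so calls are invariant to rescaling the input; it is exposed in
`respmodel_control()` because its value is a convention, not a measurement).
Sixteen categories encode the considerability pattern of the three steps
together with the sign of $b_1$. The *response* is the considerable step in
the response direction — frequency increase, amplitude decrease — whose
post-step level differs most from the window-start level $a$; its magnitude
is that level difference, its delay is the step's logistic midpoint
(negative delays are allowed, as the cardiovascular response can precede
the EEG arousal), and a *recovery* is any considerable opposite-direction
step occurring after the response. These semantics reproduce both published
worked examples of the fit exactly: a late third-step frequency rise of
0.247 Hz without recovery, and a second-step amplitude drop of 3.77 a.u.
with recovery at the third step. One borderline note: in the amplitude
example the small first step sits within 2% of the 5% considerability
threshold; whichever way it is classified, the detected response, its
magnitude and the recovery call are unchanged.

The exact published table of the 16 classes is not recoverable from the
article text, so the encoding here (considerability bits plus the sign of
$b_1$) is this package's own, validated against the two worked examples.

## Event selection

Arousal inclusion follows fixed rules evaluated in a fixed order (only the
first failure is logged): duration within 3–15 s; a scored sleep stage in
the arousal's 30-s epoch or the previous one; no other scored arousal and no
non-causal respiratory event within 10 s of the arousal start or end; and,
for respiratory arousals, a *unique* obstructive apnea or hypopnea of at
least 10 s ending no earlier than 5 s before the arousal start and no later
than the arousal end. Central and mixed apneas are never causes and exclude
the arousal by proximity. An associated event counts as desaturating when a
≥3% desaturation overlaps the window from the event start to 20 s past the
event end; the 20 s lag (`desat_window_s`) is a circulatory-delay
convention, config-exposed because no published overlap rule exists. Causes
are labelled `spontaneous`, `apnea±des`, `hypopnea±des`.

Stable-sleep reference periods — 10-s stretches free of any scored event or
stage transition — are enumerated on a 1-s grid (the enumeration grid is
unspecified in the source method; 1 s is this package's choice), greedily
thinned to be non-overlapping, permuted, and sampled per stage up to the
subject's count of included respiratory arousals in that stage. The medians
of their characteristic means define the baseline levels.

## Inference

Because arousals from the same subject are not independent, two groups are
compared with an *iterated* subject-paired Wilcoxon signed-rank test: per
iteration, each shared subject's larger side is sampled without replacement
down to the smaller side's count and paired randomly within subject; the
pooled differences are tested and the median p over 1000 iterations is
reported, with p = 0.01 as the significance threshold (no further
multiplicity correction, mirroring the source method's convention). The
signed-rank p-values come from `stats::wilcox.test` (exact for small
tie-free samples, normal approximation otherwise; an all-zero difference
vector is treated as p = 1). Proportions of missing responses/recoveries
are compared by relative risks with 99% log-normal confidence intervals
(0.5 continuity correction on zero counts, flagged); arousals are treated
as independent across subjects in these proportions, a simplification of
the cohort-level reporting. Levels before/after the response are compared
to the stable-sleep baseline with a one-sample variant of the iterated test
(a plain one-sample test is available via `iterate = FALSE`, since the
source method does not state whether the baseline comparison was
subsampled). Magnitude–delay relationships use the Pearson correlation.

## The synthetic cohort generator

The clinical dataset behind the method (876 suspected-OSA patients) is not
public, so `cohort_config()` / `generate_cohort()` synthesize subjects with
known ground truth. The PPG is an amplitude-modulated pulse train
$A(t)\,w(\phi(t))$ with $\phi'(t) = 2\pi r(t)$: the pulse shape $w$ is a
fixed unit-energy sum of the first three harmonics (coefficients 1, 0.4,
0.15 before normalization), so the power-weighted mean frequency sits a
fixed factor $\sum h_k^2 k / \sum h_k^2 \approx 1.17$ above the pulse rate,
as it does for real PPG with harmonic content. Planted responses use the
same logistic kernel (growth 5) as the fitted model so parameter recovery
is well-posed; a raised-cosine transition is available for robustness
checks. Per-cause effect sizes default to the medians reported for the
clinical cohort (frequency magnitudes 0.15–0.25 Hz, amplitude drops
1.29–1.50 a.u., delays 3.8–4.7 s; baselines around 1.6 Hz and 6.3 a.u.),
with 25% relative spread — a stand-in distributional choice, not an
estimate. Respiratory arousals can carry a planted pre-response bradycardia
dip starting during the causal event. Every planted response decays back to
baseline; when no recovery is planted the return is placed 6 s past the
analysis window so the fit sees a sustained response while the night-long
baseline stays stationary. Event geometry (arousal durations 3–15 s, causal
events of 14–24 s ending within the association window, desaturations
overlapping them, 30-s stage epochs, wide clearances) is laid out to
satisfy the selection rules, and deliberately excludable arousals can be
planted and are flagged in the truth table. Identical seeds give
byte-identical cohorts; each subject has its own stream derived from
`(seed, subject_index)`.

What the generator does *not* emulate: motion artefacts beyond additive
Gaussian noise, respiratory modulation of the baseline, inter-beat-interval
variability, non-stationary sleep architecture, or any physiologic coupling
between frequency and amplitude responses. Passing tests on this cohort
therefore demonstrate that the pipeline recovers the effect structure it
assumes, not that the clinical numbers would reproduce.

## Problem sizes and numerical conventions

The shipped tests exercise: single-arousal recovery checks at zero or small
noise; a seeded end-to-end cohort of 40 subjects with 6 arousals each
(three causes) for the ordering and inference checks; 100 step-model series
with 5% noise for parameter recovery; and 100 measurement-level null
cohorts (20 subjects, reduced 200 iterations) for calibration of the
iterated test. These sizes were chosen as the smallest that make the
checked properties statistically stable. Other conventions: times are
seconds from recording start with half-open event intervals; the
least-squares tolerance is `ftol = 1e-8` with at most 2000 residual
evaluations and 200 iterations per start; CSV is the supported waveform
interchange format (columns `time_s, ppg`).

## Limitations

Fitted delays on real (blurred) transitions are the logistic midpoints of a
sharp model fitted to smoothed data; on synthetic data they run a few
tenths of a second late of the planted midpoint, and magnitudes of
responses that recover quickly (plateau shorter than about the 4-s total
smoothing span) are attenuated. The frequency metric is not a heart-rate
estimator — it deliberately mixes in harmonic content — and no artefact
rejection is performed, mirroring the source method. The 16-class encoding
and the stable-period grid are reconstructions validated only against the
published worked examples.
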