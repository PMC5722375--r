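---
title: "Accelerometer-based spontaneous pulse detection: model and methods"
author: "ccpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerometer-based spontaneous pulse detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpulse)
```

## The problem

During cardiopulmonary resuscitation (CPR) a rescuer must decide, with as
little interruption of chest compressions as possible, whether an organized
ECG rhythm is actually pumping blood (a *perfusing rhythm*, PR) or is
*pulseless electrical activity* (PEA). Manual pulse palpation is slow and
unreliable; invasive arterial pressure is the gold standard but rarely
available. The accelerometer already present in CPR feedback sensors placed
on the chest offers an alternative: a contracting heart shakes the chest
wall a little, and those pulse-synchronous micro-oscillations (on the order
of 2 m/s^2) are visible in the acceleration (ACC) channel during
compression pauses, buried in background noise and dwarfed by the
compression oscillations themselves (tens of m/s^2).

`ccpulse` implements the full chain: find compression-free windows from the
ACC envelope, band-pass ECG and ACC, quantify their coupling with the peak
of the normalized cross-correlation (CCp), classify PR vs. PEA by
thresholding CCp, and evaluate the classifier the way a method study would
(ROC/AUC, sensitivity/specificity/accuracy, paired AUC comparisons against
mean arterial pressure and heart rate). A seeded waveform generator
provides study-scale synthetic data so that every stage is testable without
animal recordings.

## The detection statistic

For one 3-s window, let $x(n)$ be the filtered ECG and $y(n)$ the filtered
acceleration, both of length $N$ (900 samples at 300 Hz). The package
computes the zero-padded (non-circular) normalized cross-correlation

$$
r_{xy}(l) \;=\; \frac{\sum_n x(n)\, y(n-l)}
      {\sqrt{\sum_n x(n)^2 \;\sum_n y(n)^2}},
\qquad l = 0, \pm 1, \ldots, \pm(N-1),
$$

and the statistic $\mathrm{CCp} = \max_l r_{xy}(l)$ (the signed maximum,
not the maximum modulus). Under this normalization $|r_{xy}(l)| \le 1$ by
Cauchy–Schwarz and CCp is invariant to positive rescaling of either
channel — essential because ECG gain and accelerometer sensitivity are
arbitrary. A variant that divides by the plain product
$\sum x^2 \sum y^2$ is provided as `normalization = "energy_product"`; it
is not scale-invariant and does not bound the sequence in $[-1, 1]$, and
is kept only so the two conventions can be compared explicitly.

A pulse is declared present when CCp strictly exceeds a threshold fitted
on a training split. With the defining sum, an acceleration waveform that
is a copy of the ECG delayed by $d$ samples peaks at lag $-d$: negative
peak lags mean ACC lags ECG, which is the physiological direction
(electromechanical delay). `normalized_xcorr()` is FFT-accelerated and is
tested to agree with the direct $O(N^2)$ evaluation of the sum to 1e-10.

## Preprocessing

* ECG: 4th-order Butterworth band-pass, 0.2–45 Hz.
* ACC: 4th-order Butterworth band-pass, 0.5–7.5 Hz. The order of this
  narrow filter is a package choice (matching the ECG filter); it is a
  configurable parameter.
* Both filters are applied forward–backward (zero-phase) by default.
  Phase distortion would shift the ECG-to-ACC lag structure that CCp
  measures, so a causal single pass, although selectable
  (`zero_phase = FALSE`) for real-time emulation, is not the default.
  Zero-phase application squares the magnitude response; the tests verify
  the end-to-end gain against the closed-form Butterworth response of the
  bilinear-transformed prototype (prewarped), at probe tones in and around
  both bands, to 2 %.
* Edges are handled by odd reflection over a pad of three filter state
  lengths. The 0.2 Hz edge has a multi-second time constant, so the first
  and last fraction of a second of any short window retains some
  transient; steady-state properties are therefore asserted on the
  interior of long signals in the tests. Near-unit-circle poles also set a
  practical floor (~1e-5 on unit-scale signals) on how exactly numerical
  superposition holds, which the linearity tests acknowledge with a 1e-4
  tolerance.

## Segmentation

Compression episodes are separated from hands-off pauses by a moving-RMS
envelope of the mean-removed ACC signal. The two regimes the envelope must
separate are far apart — compressions oscillate around 46 m/s^2 while
pause-time pulse transients stay near 2 m/s^2 — so the default threshold of
10 m/s^2 sits comfortably between them. The envelope window default is
0.1 s: long enough that background noise rarely crosses threshold, short
enough to resolve pause boundaries to better than ±0.2 s (a longer window
erodes each pause edge by about half the window length; with 3-s minimum
pauses and 3-s segments, edge erosion directly costs segments, which is why
the window is kept short). Runs below threshold lasting at least
`min_pause_s` (default 3 s) become pauses; each pause yields one segment of
`round(duration_s * fs)` samples anchored at the pause start (rhythm
analysis happens at the start of a pause, before compressions resume), optionally after
a guard offset (default 0 s). Pauses shorter than the segment length are
skipped and counted. A consequence of envelope-based detection is that a
pause of exactly 3.0 s is detected slightly shorter and yields no segment;
pauses of 3.2 s and above survive comfortably.

## Annotation

The reference labels follow the standard experimental definitions: a window is *organized*
if it contains at least one QRS complex; an organized window is *PR* if
systolic arterial pressure exceeds 60 mmHg **and** pulse pressure exceeds
10 mmHg (strict inequalities), else *PEA*;
disorganized windows are not hemodynamically classified. Systolic/diastolic
pressure are the window extrema of the raw ABP slice, and MAP is its
arithmetic mean over the window (in experimental practice MAP comes from a
patient monitor whose averaging rule is opaque; the `dap + pp/3` estimator
is deliberately not the default). Heart
rate is 60 divided by the *median* RR interval — robust to one missed or
spurious beat in a 3-s window; it is undefined with fewer than two beats.

QRS detection is an energy-based detector in the Pan–Tompkins spirit
(band-pass, derivative, squaring, moving-window integration, refractory
0.2 s) with two guards that together stand in for a physician's judgement:

* a spectral gate requiring an appreciable share (>10 %) of the 3–30 Hz
  energy to lie above 10 Hz — sharp QRS deflections have it, VF-like
  band-limited oscillation does not, so disorganized windows yield zero
  detections and flow to the `disorganized` label downstream;
* an energy-peak rule (fraction of window maximum and multiple of the
  window median) that rejects temporally continuous energy.

The detection band is 8–20 Hz, above the spectrum of even tall post-arrest
T waves. Fiducials are placed at the midpoint of the positive and negative
extrema of the filtered deflection, i.e. the centre of the biphasic
complex, and land within a few milliseconds of the generator's ground
truth. Because automatic detection is a stand-in, `annotate_segments()`
accepts manual QRS marks that override the detector, and exclusion flags
(rhythm transitions, defibrillation shocks) are metadata supplied by the
user or generator — automatic shock detection is out of scope.

## Threshold training and evaluation

`optimize_threshold()` scans all midpoints between consecutive distinct
feature values (plus one candidate below the minimum and one above the
maximum) under the rule "positive iff value > threshold" and keeps the
candidate with the highest training accuracy; accuracy ties break toward
higher sensitivity, then toward the smaller threshold. This data-driven
grid is resolution-free; a fixed-step grid would give the same accuracy up
to grid resolution but a slightly different numerical threshold.

Evaluation reproduces a method study's toolkit:

* AUC by the rank-sum (pair-counting) form with ties counted one half,
  which is exactly the trapezoidal area under the empirical ROC;
* sensitivity (PR detection rate), specificity (PEA rejection rate) and
  accuracy from the thresholded decisions;
* pooled-variance two-tailed Student's t for group comparisons (Welch via
  flag);
* Pearson correlation between CCp and MAP with the usual t-based test;
* paired AUC comparison by DeLong's variance estimate on the placement
  values of both features — the features are computed on the *same*
  windows, so the paired estimator is the right default; Hanley–McNeil is
  available as an unpaired alternative;
* 2×2 Pearson chi-square without continuity correction for comparing
  sensitivities/specificities/accuracies between features (Yates via
  flag), with a flag in the output when an expected cell drops below 1.

## The synthetic generator

The generator draws per-segment conditions from the study-scale
distributions: heart rate 159 ± 51 (PR) vs. 86 ± 45 (PEA) beats/min, MAP
115.3 ± 36.3 vs. 15.2 ± 9.5 mmHg, compression oscillation amplitude
46.35 ± 15.95 m/s^2, pulse transient amplitude 1.83 ± 0.96 m/s^2, pauses
of 3–5 s. Draws are Gaussian with those moments, clipped to physiological
ranges; PR MAP is clipped to [80, 250] mmHg and PEA MAP to [2, 40] mmHg so
that generated classes stay away from the 60/10 mmHg label boundaries
(label determinism on clean data is a design requirement, not an empirical
accident). The electromechanical ECG-to-ACC delay is uniform on
50–200 ms — a physiological range for electromechanical delay; it is a
parameter, not a claim about any particular heart.

Waveform shapes are deliberately simple and fully parameterized:

* **ECG (organized)**: a train of beat complexes at the drawn rate with
  5 % RR jitter — a sharp biphasic QRS (derivative-of-Gaussian, width
  parameter 10 ms) plus a broad biphasic ST-T wave (width 50 ms, 180 ms
  after the R wave), over 0.3 Hz baseline wander and white noise. The tall
  discordant T wave (amplitude 0.8 of the R wave for PR, 0.1 for PEA)
  carries the low-frequency energy that falls inside the 0.5–7.5 Hz
  analysis band; the sharp R wave carries the high-frequency signature the
  QRS detector and the VF gate rely on. The two amplitudes are calibrated
  so that the synthetic CCp class distributions land near the study-scale
  group statistics (PR means within two reference SDs of 0.440, PEA within
  two reference SDs of 0.067).
* **ECG (disorganized)**: band-limited 3–8 Hz Gaussian process, no
  repeating template.
* **ABP (PR)**: one pressure pulse per beat (fast half-sine upstroke,
  exponential diastolic decay) delayed 100–200 ms after the QRS, scaled so
  SAP > 60 and PP > 10 with the drawn MAP; **ABP (PEA)**: slow drift
  around the drawn low MAP with PP held below 10 mmHg.
* **ACC**: white background noise (default SD 3.5 m/s^2) everywhere; a
  2 Hz oscillation at the drawn compression amplitude inside compression
  intervals; and, for PR only, a pulse transient after each QRS at the
  drawn delay — the beat complex band-limited to 0.5–7.5 Hz, i.e. a damped
  oscillation, at the drawn amplitude. Driving the mechanical transient
  with the band-limited QRS-T complex reflects the physics (systole spans
  QRS to T and the chest responds only in the low-frequency band) and
  makes the noise-free CCp of a PR window approach the in-band energy
  fraction of the ECG (≈ 0.83 with the defaults).

Segments are grouped into synthetic "animals" — many PR animals with ~1.5
segments each, few PEA animals with ~10 each, mirroring the skew of arrest
experiments — so the animal-level split rule (all of an animal's segments
in one split) is exercised by `split_dataset()`.

**What the generator does not emulate**, and hence what passing tests do
*not* establish about real recordings: real compression artifacts (the
synthetic burst is a clean sinusoid), sensor-coupling and placement
effects, morphology diversity of real porcine rhythms, rhythm transitions
within a window, and any dependence between MAP and CCp beyond class
membership. Synthetic class separation (AUC typically ≥ 0.99) is
consequently cleaner than the real-data figure; the end-to-end tests
assert a sanity floor (median AUC ≥ 0.9 across seeds), not a reproduction
of the animal-study operating point.

## Numerical and design choices

* Cross-correlation via FFT on a zero-padded power-of-two length;
  exact-tie peaks resolve toward the smallest |lag|, then toward the
  negative lag, making results deterministic.
* A correlation normalization by the plain product of energies (without
  the square root) is sometimes written down but cannot produce values on
  a unit scale for signals of arbitrary units; the square-root form is the
  default and the product form remains available as `energy_product`.
* Strict `>` at every decision boundary (pressure criteria, pulse
  threshold), matching the strict-inequality style of the label
  definitions.
* Delay recovery from the correlation peak is meaningful when beats are
  separated by more than the transient length; at fast rates the ±1-beat
  alias (peaks recur every RR interval) bounds what any peak-picking
  estimator can do. The lag-recovery test therefore runs at 80 beats/min,
  with in-band noise at half the pulse amplitude (SNR 2).
* Test problem sizes: the acceptance-style checks use 100 random pairs up
  to N = 900 for the correlation oracle, 200 seeded trials for lag
  recovery, 1000 clean segments for label determinism, 1000 permutations
  for the DeLong null, and 20 study-scale datasets (63 PR / 153 PEA) for
  end-to-end separation; the whole suite runs in about a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(n_pr = 10, n_pea = 20, seed = 7)
res <- run_pipeline(cfg, quiet = TRUE)
res$study$performance[, c("feature", "auc", "sensitivity", "specificity")]

ds <- generate_dataset(2, 1, seed = 1)
cc <- normalized_xcorr(preprocess_ecg(ds$ecg[[1]], 300),
                       preprocess_acc(ds$acc[[1]], 300))
autoplot(cc, sample_rate_hz = 300)
```

## Known limitations

* Pulse detection during ongoing compressions is out of scope (the method
  operates only in hands-off intervals).
* Pauses barely longer than the segment length can be lost to envelope
  edge erosion (see Segmentation).
* The QRS stand-in is tuned to the generator's waveform families; on real
  ECG a curated annotation (via `manual_qrs`) is the intended path.
* Only CSV interchange is supported; spreadsheets must be exported to CSV
  before `read_feature_table()`.
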