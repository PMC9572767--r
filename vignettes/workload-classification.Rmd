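---
title: "Classifying driver mental workload from facial thermography and HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver mental workload from facial thermography and HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwload)
```

## The problem

Sustained cognitive load leaves physiological fingerprints that can be read
without asking the driver anything: peripheral vasoconstriction cools the
nose tip, autonomic balance shifts the spectral content of both skin
temperature and heart rhythm, and the inter-beat (RR) series becomes shorter
and more LF-dominated under sympathetic drive. `mwload` implements a
complete analysis chain for experiments in which drivers perform graded
cognitive tests while facial infrared video (10 Hz) and single-lead ECG
(256 Hz) are recorded: a two-class working-memory task (digit span, Forward
vs Backward) and a three-class verbal-learning task (immediate recall,
delayed recall, recognition). The goal is to classify which sub-task —
i.e. which workload level — a subject was performing, from per-phase
physiological features alone.

Because raw recordings of this kind are typically private, the package
ships a synthetic cohort generator with the statistical structure the
analysis assumes, so every stage is testable end to end without any
external data.

## Signal models and preprocessing

**Thermal ROI traces.** Each region of interest (nose tip, glabella) is
reduced to the mean of its masked pixels per frame (`roi_mean_series()`).
Motion and tracking glitches appear as spikes; they are removed with a
Hampel filter: for every sample, the median and the robust dispersion
$1.4826\cdot\mathrm{MAD}$ are computed over a centered window, and samples
deviating by more than $n_{SD}$ dispersions are replaced by the local
median. Defaults are a 15 s total window and $n_{SD} = 2$. Two semantics
had to be fixed where conventions differ: the window length is the *total*
span (150 samples at 10 Hz), truncated — not reflected — at the series
edges, and the dispersion is the scaled MAD rather than the standard
deviation (the MAD is what makes the filter robust in the first place).
Decisions are made against the original samples, which renders the filter
idempotent in practice. Each trace is then expressed relative to the
subject's resting level by subtracting the mean of the final 60 s of
baseline driving before the first cognitive task; the same baseline window
serves every phase. Hampel runs before the subtraction (they commute up to
the constant shift).

**Per-phase thermal features.** Nine descriptors per ROI per phase:
mean, sample SD, kurtosis, skewness, 90th percentile, sample entropy, and
the mean LF and HF band power densities with their ratio. Conventions
worth stating because ecosystems differ: skewness and kurtosis are the
biased moment ratios $m_3/m_2^{3/2}$ and $m_4/m_2^2$ with kurtosis
*non-excess* (Gaussian → 3); the percentile interpolates linearly between
order statistics; zero-variance inputs flag skewness/kurtosis as missing
rather than silently zero.

**Sample entropy** is $-\ln(A/B)$ where $B$ counts pairs of length-$m$
templates within Chebyshev distance $r$ and $A$ the same for length
$m+1$; self-matches are excluded. We use the field-standard $m = 2$,
$r = 0.2\,\mathrm{sd}$. A constant series returns 0 by convention; $B = 0$
yields a missing value. The implementation is compiled; the test suite
checks it exactly against a brute-force template-enumeration oracle.

**Spectra.** Band powers use a Welch averaged periodogram (Hamming taper,
segments of min(N, 60 s), 50% overlap, per-segment linear detrend), scaled
so the one-sided density integrates to the detrended variance. The LF band
is 0.04–0.15 Hz, HF 0.15–0.4 Hz; band power density is the trapezoidal
integral over the band divided by its width, with edge interpolation so the
integration range is exact. A zero HF power flags the LF/HF ratio missing.

**ECG and HRV.** Raw ECG is mean-removed, band-passed (first-order
high-pass at 0.05 Hz, fourth-order low-pass at min(150, 0.45·fs) Hz — the
nominal 150 Hz cap exceeds Nyquist at 256 Hz sampling) and notch-filtered
±2 Hz around 50 Hz, all zero-phase. R peaks are local maxima above the
whole-phase mean + 2 SD with a 250 ms refractory period (amplitude-priority
conflict resolution, positive polarity assumed; the threshold is relative,
so detection is scale-invariant). One implementation detail matters at the
stated noise level: the argmax of a noisy R wave wanders by a few samples,
so the detector smooths with a 10 ms Gaussian kernel — an approximate
matched filter, zero-phase, displacement-free for symmetric peaks — before
peak picking. Without it about 10% of beats localize more than one sample
off; with it fewer than 0.1% do. Six HRV features per phase: RRmean, SDNN,
RMSSD (ms), and LF/HF band densities and ratio computed on the tachogram
cubic-splined to an even 4 Hz grid. Each feature is divided by its value
during baseline driving, so models see within-subject ratios.

## Feature tables, models, validation

Rows are (subject, phase) pairs; the class label is the phase (Forward = 0
/ Backward = 1; ImmR = 0 / DelR = 1 / Rec = 2), so a complete cohort is
balanced by construction. Three views: thermal only (18 features), HRV
only (6), multimodal (24). Rows with any missing value are dropped, never
imputed.

Sixteen classifier presets span six families. Where the preset names come
from a point-and-click tradition, hyperparameters had to be fixed here:
trees simple/medium/complex prune to at most 4/20/100 splits; kNN
coarse/medium/fine use k = 100/10/1 (capped at the training size);
SVMs are polynomial of degree 1/2/3 at box constraint 1, multiclass by
one-vs-one with scores summed from signed pair margins; discriminant
analysis is LDA and a regularized QDA (class covariances shrunk 10% toward
a scaled identity, since 24 features against ~21 rows per class is
otherwise singular); ensembles use 30 learners — bagging over all features,
random-subspace LDA and 1-NN on half-size feature subsets, and a
SAMME-style booster with per-round under-sampling to the minority class
count. Scale-sensitive families are z-scored *inside* the fit on training
rows only; tree ensembles are left unscaled. Whether the original analysis
standardized its inputs is unknown; we document it as an assumption.

Validation is subject-grouped 5-fold CV: subjects are shuffled and dealt
into test sets differing in size by at most one (26 subjects → 6,5,5,5,5),
and every row of a subject lies entirely in train or test. Accuracy is
pooled over folds; repeated CV over independently shuffled plans (default
20 repetitions) smooths the fold lottery. The wrapper selector draws 50
distinct random feature subsets (size uniform, then uniform within size),
scores each by grouped-CV accuracy, and returns the best, breaking ties
toward smaller subsets then lexicographically. The selector reuses the
same flat CV criterion the original procedure implies; this risks
selection bias, so the honest generalization estimate for a *selected*
subset should come from an outer loop — the package keeps flat selection
as the default to mirror the reference procedure and leaves nesting to the
caller (run selection inside each outer fold).

Evaluation: confusion matrices, per-class one-vs-rest sensitivity /
specificity / precision / F1 with unweighted macro averages, step-exact
ROC curves (thresholds at the distinct scores plus infinite endpoints) and
AUC as the tie-aware Mann–Whitney statistic. Multiclass tasks get one ROC
per class against the union of the others. Per-feature phase contrasts use
paired t-tests across subjects with raw two-level significance marks
(p < 0.05, p < 0.01), plus a separately labeled Holm-adjusted column —
the raw marks mirror the reporting convention of this literature, the
Holm column is there because 24 features × phase pairs is a real
multiplicity.

## What the synthetic generator emulates

Per subject and phase, thermal traces are: resting level + subject offset
+ phase mean shift + sinusoids at 0.10 and 0.25 Hz (the LF/HF band
centers, so band-power recovery is analytically checkable) + AR(1) noise
(coefficient 0.9 — skin temperature is slow, which also keeps spikes
distinguishable) + Poisson-placed positive spike artifacts. ECG is built
from unit Gaussian R waves (20 ms SD) on a beat train whose instantaneous
RR is the phase mean plus the same two-band modulation plus per-beat
jitter, over white noise of SD 0.05. One master seed spawns per-subject
substreams, so enlarging a cohort never perturbs existing subjects.

Default study conditions: 26 subjects; baseline 900 s, task sub-phases
120 s (long enough for several LF cycles in every analysis window; the
original protocol does not publish per-sub-phase durations, so these are
configurable); nose-tip cooling grows with load (−0.3 to −0.7 °C across
sub-phases against AR(1) noise of marginal SD 0.1 °C), glabella warms
slightly; RR shortens (850 → 780 ms) and LF modulation deepens with load;
between-subject offsets 0.3 °C and 50 ms; 2 artifacts/min of +2 °C.
`null_mode = TRUE` forces all per-phase parameters to their baseline
values, which is the package's device for type-I-error and chance-level
checks. Cognitive-test scores are drawn jointly Gaussian with a common
within-subject correlation (default 0.5) around published-cohort-typical
means.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: tracking dropouts and registration drift beyond
point spikes, ectopic beats and non-Gaussian QRS morphology, circadian
and ambient-temperature drifts, or any true coupling between a subject's
thermal and cardiac responses beyond sharing phase labels. Synthetic
separability is also far cleaner than the modest accuracies reachable on
real cohorts; the generator validates the machinery, not the effect size.

## Numerical choices and degenerate inputs

Missing values propagate (never silent zeros): zero-variance
skewness/kurtosis, zero-HF ratios, zero-baseline HRV ratios. Flat signals
return zero band power with an undefined ratio. Peak detection on a flat
record warns and returns an empty beat list; fewer than two beats is an
error. Ties in predicted scores resolve to the lowest class index; ties in
wrapper selection to the smaller, lexicographically first subset. Fold
sizes differ by at most one. All randomness flows from explicit seeds; two
identical invocations are bit-identical.

## Problem sizes used by the automated checks

The test-suite and acceptance script keep simulation sizes at desk scale,
as the package's own choices: oracle equivalence on 50 seeded series;
beat-recovery on 20 seeds × 3 subjects at the default generative
parameters; chance-level on 20 seeds × 26-subject null cohorts with a
180 s baseline (a null cohort carries no phase effect at any duration);
effect recovery on one full default cohort; wrapper recovery on 20 seeded
runs of a 10-feature table whose two planted features are jointly (not
marginally) separating — under the smaller-subset tie-break, a single
marginally-sufficient feature would legitimately displace its partner.

## Known limitations

The flat wrapper criterion reuses the CV estimate it maximizes; nose-tip
temperature in real recordings responds with a latency the generator does
not model; the regularized QDA's shrinkage weight (0.1) is a fixed
convention, not tuned; logistic regression is binary-only by design and
is reported as "not applicable" for the three-class task; no ectopic-beat
correction or nonlinear HRV indices beyond sample entropy on the thermal
side.
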