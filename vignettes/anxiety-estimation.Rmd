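---
title: "Estimating anxiety from electrodermal and heart-rate signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating anxiety from electrodermal and heart-rate signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxsig)
```

## The problem

During virtual-reality exposure therapy a therapist wants a running, objective
estimate of the patient's anxiety so the intensity of the phobic stimulus can
be adapted in real time. Two peripheral signals carry most of the usable
information and are practical to record under a head-mounted display: skin
conductance (electrodermal activity, EDA/GSR, in microsiemens) driven purely
by sympathetic sudomotor activity, and heart rate (bpm) reflecting the
sympathetic/parasympathetic balance. The package implements the full chain
from raw samples to a class label:

1. **Conditioning** — aliasing-aware FIR low-pass filtering and decimation to
   a 51.2 Hz analysis rate, normalization utilities, and a sensor quality
   check (a deep breath must produce a conductance spike within 2–3 s).
2. **Decomposition** — splitting skin conductance into a slow tonic level
   (SCL), a phasic component (SCR) and the non-negative driver generating
   it, with detection of individual response events (amplitude, onset).
3. **Windowing** — a 5-s pre-stimulus window per rated event; the subject's
   self-reported Subjective Units of Distress (SUD, 0–10) labels the window.
4. **Features** — 32 per window: six time-domain statistics for each of
   GSR/SCL/SCR, three event-related features, spectral median and mean for
   each electrodermal channel, and heart-rate level, variability and LF/HF
   band intensities.
5. **Estimation** — a second-order polynomial in a subset of features,
   identified by least squares and selected by exhaustive subset search on a
   distribution-matched identification set.
6. **Classification** — thresholding the raw estimate into 2 classes
   (low `[0,5]`, high `(5,10]`) or 3 classes (low `[0,3]`, mild `(3,7]`,
   high `(7,10]`), reported through confusion matrices.

Because no recorded cohort is distributed with the package, a seeded
synthetic-session generator stands in for the data and doubles as the ground
truth for validation.

## Why the sampling arithmetic matters

Mains interference dominates raw EDA recordings. A 50.032 Hz fundamental
sampled at 51.2 Hz folds to

```{r}
alias_frequency(50.032, 51.2)
```

1.168 Hz — inside the electrodermal band and with a period close to a real
skin-conductance response, where no filter can remove it afterwards. The
recommended chain therefore acquires fast (512 Hz by default), low-pass
filters at 25 Hz with a 257-tap linear-phase FIR (Hamming design, >40 dB at
50 Hz), and only then decimates by 10 to 51.2 Hz. Data that arrive already
sampled at 51.2 Hz bypass this with a warning. The final rate is kept at
51.2 Hz because a 1024-point transform then produces exactly the 0–25.6 Hz,
0.05 Hz-step grid used by the spectral features.

## The decomposition model

A single sudomotor burst produces a conductance response shaped like the
two-compartment (Bateman) impulse response
$k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$, scaled here to unit peak; the
defaults $\tau_r = 1$ s, $\tau_d = 3.75$ s give a ~1.8 s rise, consistent
with the physiological 1–3 s rise and 2–10 s half-recovery. The measured
trace is modeled as `tonic + driver * kernel` with a non-negative, sparse
driver.

The implementation estimates the tonic level as a sliding 10th-percentile
baseline (20-s window, evaluated on a 0.25-s grid, smoothed over 4 s),
deconvolves the remainder in the frequency domain with Tikhonov
regularization, clips the driver at zero, re-convolves to obtain the phasic
component, and folds the slow part of any residual back into the tonic
estimate.

Numerical choices worth recording:

* **Regularization weight.** `lambda = 1e-4 * max|K|^2`. Heavier weights
  visibly bias the recovered response amplitudes downward (about 25% at
  `0.1 * max|K|^2`) and leave reconstruction residuals of 1.5–2% of the
  signal range; at `1e-4` forward-simulated traces reconstruct to within 1%
  of range while high-frequency noise far outside the kernel band is still
  suppressed. The deconvolution gain is compensated so the driver has unit
  gain in the kernel's dominant band.
* **Event onset.** The regularized driver spreads each impulse symmetrically
  around its true position, so the onset is taken as the driver-mass
  centroid of an impulse cluster; on forward simulations this recovers true
  onsets to within one sample, whereas a threshold-crossing rule reads
  systematically early (≈0.9 s at a 10%-of-peak threshold).
* **Event amplitude.** The kernel has unit peak, so an isolated response of
  amplitude $a$ corresponds to a driver impulse of mass $a$; the amplitude
  is therefore the cluster's total driver mass. A trough-to-peak read-off of
  the summed phasic trace fails for a small response riding the decay tail
  of a large one (the summed trace never rises locally), while the mass is
  superposition-proof. Forward-simulation RMSE is 4–8%.
* **Cluster floor and merging.** Driver clusters are seeded above
  `min_amplitude / 20` and clusters closer than 1 s are merged; events below
  the conventional 0.05 µS significance threshold are dropped. Dense trains
  (inter-onset gaps under ~3 s) merge by design; the event-count contracts
  hold for isolated responses.
* **Degenerate input.** An exactly constant trace returns itself as tonic
  with an empty event list rather than an error.

## Windows, features, and their conventions

Windows are half-open `[t - 5, t)`: the rating panel appears at the pickup,
so the window is strictly pre-stimulus and the pickup sample is excluded.
At 51.2 Hz a window holds exactly 256 samples. Windows may overlap when
events are closer than 5 s; SCR events belong to the window containing their
onset.

Feature conventions that depart from the obvious, kept deliberately:

* Waveform length is the sum of *squared* successive differences, as the
  source formula prints it; `wl_absolute = TRUE` switches to the
  conventional `sum(|dx|)`.
* The Willison amplitude threshold is 0.5 µS and the slope-sign-change
  guard band 0.001 µS.
* Heart-rate MAV/STD are normalized by the window's own sample count (the
  printed formulas carry an `N` that can only mean the HR vector length).
* With no detected events, AVRA and MAXRA are 0 — "no response" is minimal
  response, keeping feature vectors finite.
* The high/low frequency ratio follows the printed formula HFI/LFI.
* The spectral median minimizes `|sum(P below) - sum(P at/above)|`; among
  tied split points the largest one whose lower mass does not exceed half
  the total is taken, so a spectrum concentrated in a single bin reports
  that bin.
* Baseline statistics (MAR denominators) are the mean absolute values of
  GSR/SCL/SCR over the 60-s rest recording, floored at 0.01 µS: a fully
  relaxed baseline can contain no phasic activity at all, and the ratio
  needs a positive denominator.
* The LF band (0.04–0.15 Hz) has a period up to 25 s, which a 5-s window
  cannot resolve properly; the band features are still computed as
  specified (single-pass causal 3rd-order Butterworth filters, first sample
  subtracted to shorten the step transient), and this limitation is
  inherited knowingly — real-time response was preferred over spectral
  resolution.

## The estimator

With features $x_1 \dots x_P$ the anxiety estimate is

$$\hat{y} = \sum_{i \le j} \alpha_{ij} x_i x_j + \sum_i \beta_i x_i + \gamma,$$

a second-order Taylor approximation about the origin with
$P(P+1)/2 + P + 1$ coefficients (171 at $P = 17$, which is why the screening
stage alone cannot define the model). Coefficients minimize the sum of
squared residuals on the identification set; rank-deficient designs get the
minimum-norm solution so that enumeration never aborts mid-search.

The identification/validation split preserves the rating distribution: at
each level, `round(6/7 * N)` windows (half away from zero — a fixed,
platform-independent convention) enter the identification set. Applied to
the occurrence totals 41, 16, 12, 9, 7, 4, 4, 2, 5, 2, 3 this yields the
90/15 split with per-level identification counts
35, 14, 10, 8, 6, 3, 3, 2, 4, 2, 3.

The subset search enumerates all `choose(32, p)` subsets in lexicographic
order, fits each on the identification set only, and keeps the minimum-SSR
subset (first one on ties, for determinism). `choose(32, 7) = 3,365,856` is
the practical ceiling; `choose(32, 8)` exceeds ten million and is out of
desk-scale reach. The default pipeline stops at `max_p = 3` (5,488 fits,
seconds of work); the seven-feature search is a documented long-running
mode.

Raw estimates are not clamped — values like 7.37 are informative — and the
class intervals extend to infinity at both ends, so classification is total
and order-preserving.

## What the generator emulates, and what it does not

Each synthetic subject gets a piecewise-constant latent anxiety trajectory
(one plateau per "floor" episode), and from it:

* tonic conductance as a slow random walk around 6 µS (clipped to the
  physiological 2–20 µS), rising 0.15 µS per anxiety unit;
* phasic responses from an inhomogeneous Poisson process, 2/min at rest to
  20/min at anxiety 10, with amplitudes growing with anxiety inside
  0.1–3 µS, convolved with the Bateman kernel — thinning shares one uniform
  stream so raising anxiety under a fixed seed only ever adds events;
* mains interference at 50.032 Hz (+1 harmonic, 0.05 µS) which, at the
  51.2 Hz device rate, appears as the 1.168 Hz alias;
* heart rate 65 bpm + 3 bpm per anxiety unit, an LF (0.1 Hz) and an HF
  (0.25 Hz) sinusoid whose HF amplitude shrinks with anxiety (vagal
  withdrawal), plus white measurement noise;
* ratings as the latent anxiety at each event with uniform(−0.5, 0.5)
  reporting noise, rounded and clamped to the 11-point SUD scale. A
  requested rating histogram (e.g. the published occurrence totals) is
  reproduced exactly by pinning the trajectory plateaus to a shuffled
  rating multiset.

Session defaults are 7 subjects × 15 rated events of 360 s each — the
cohort shape of the study being emulated — giving the 105-window dataset.

The generator does **not** simulate motion artifacts, electrode drift or
detachment, a realistic pulse waveform (heart rate is generated directly),
or inter-subject differences in response shape. Passing tests therefore
demonstrate the correctness of the machinery and its recovery properties
under clean physiology, not robustness to the artifacts of real recordings.

### Identifiability of planted subsets

Validation plants a known quadratic in three *measured* features and checks
that the exhaustive search finds it. The planted subset must be
identifiable: since GSR = SCL + SCR sample by sample, amplitude-level
features of the three electrodermal channels (MAV, MAR, STD, WL) are
near-collinear (pairwise correlations above 0.99 on synthetic cohorts), and
a subset using them has rivals spanning nearly the same function space —
exact recovery would be ill-posed for any search procedure. The default
planted triple uses one feature per independent axis: `SCL_fmn` (tonic
spectral content), `HR_mav` (cardiac level), `HR_std` (variability). With
noise of 0.2 rating units the search recovers it in 20/20 seeded
replicates; at zero noise the fit is exact and the 2-class confusion matrix
is the identity.

There is no circularity in this check: anxiety generates physiology, the
features are computed from the signals alone, and the estimator learns the
inverse map.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run the signal chain at its native
51.2 Hz on full 360-s sessions (7 × 15 windows), the subset search up to
`p = 3` over all 32 features (5,488 fits) or `p = 4` over reduced pools,
and 20 seeded cohorts for the recovery property. These sizes keep a full
run in the low minutes on a single core while exercising every stage at the
study's own cohort shape; the `choose(32, 7)` search is the only part of
the published analysis not re-run routinely.

## Known limitations

* The decomposition is windowed-batch, not strictly causal; the streaming
  estimator re-decomposes the available record per update and is suitable
  for session-scale latencies, not hard real-time guarantees.
* Event features on mains-contaminated 51.2 Hz recordings are noisy because
  the 1.168 Hz alias partially survives deconvolution; the estimator's
  preferred subsets avoid event-derived features, consistent with the
  published selection.
* Ratings are ordinal but treated as numeric by the regression; the
  threshold classifier absorbs most of the resulting distortion.
* With 105 windows, models beyond a few features overfit; validation SSR
  tracking identification SSR is the guard, not a substitute for more
  subjects.
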