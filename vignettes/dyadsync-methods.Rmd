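---
title: "Methods: dyadic EEG asymmetry and lagged concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic EEG asymmetry and lagged concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the processing
model, the choices made where the procedure was genuinely open, and what
the synthetic-data checks do and do not establish about real recordings.

## The pipeline

Two partners are recorded simultaneously (250 Hz, 128-channel geodesic
montage in the reference design) across a schedule of conditions. Per
recording, the stages run in a fixed order:

1. **Zero-phase bandpass, 0.1–40 Hz.** The magnitude response of a
   two-pass Butterworth cascade (order-2 high-pass, order-6 low-pass) is
   applied in the frequency domain. This is exactly zero-phase, has no
   forward–backward edge transients, and attenuates ≈ −72 dB one octave
   above the passband and ≈ −25 dB one octave below.
2. **Bad-channel detection, threshold 0.9.** A channel is flagged when the
   median across 1 s windows of its correlation with an
   inverse-distance-weighted prediction from its `k = 8` nearest
   neighbors falls below 0.9; flat channels are always flagged. Two
   passes are made, with first-pass flags excluded from every predictor
   set, so one corrupt channel cannot drag its neighbors below threshold.
   This is a documented correlation-based reading of the published 0.9
   rejection criterion, not a re-implementation of any toolbox's
   internals.
3. **Spectral-threshold segment rejection, 20–40 Hz / 10 dB.** Sliding
   0.5 s windows with 50% overlap (matching the downstream epoch length);
   a window is rejected when its channel-averaged 20–40 Hz power exceeds
   the median window power by ≥ 10 dB. The median is computed per
   condition by default (`segment_scope` toggles recording-wide), flagged
   bad channels are excluded, and windows already rejected are excluded
   from the median on re-runs, making the operation idempotent.
4. **Interpolation and average reference.** Bad channels are replaced by
   the inverse-distance-weighted mean of nearest good neighbors on an
   idealized quasi-uniform hemispheric layout, then all channels are
   re-referenced to the per-sample channel mean. Spherical-spline
   interpolation was deliberately not used: for cluster-averaged band
   power the difference is immaterial, and the simple scheme is exactly
   testable (a bad channel amid identical neighbors is reconstructed
   exactly). The layout is synthetic — a Fibonacci hemisphere, not the
   vendor's digitized coordinates — and is used only for neighbor
   geometry.

Epochs are non-overlapping 500 ms windows from each condition's start
(trailing partial windows dropped; epochs touching any rejected sample are
invalid). Per epoch and channel, a Hann-tapered periodogram evaluated on a
zero-padded 0.5 Hz grid gives absolute alpha (mean power in 8–12 Hz,
inclusive) and relative alpha (summed 8–12 Hz power over summed 1–40 Hz
power). The 500 ms window's native resolution is 2 Hz; zero-padding only
interpolates the spectrum, which keeps the estimator transparent and
Parseval-testable. The relative-power denominator band (1–40 Hz) is a
convention, exposed as `total_band_hz`. Cluster power is the mean of the
chosen measure over the cluster's channels, and FAA = ln(right) − ln(left),
taken after cluster averaging. Relative alpha is the default mode, as in
the asymmetry literature.

FAA epochs are averaged into 2 s bins of 4 epochs; a bin's value is the
mean of its valid epochs and a bin is missing only when all four epochs
are. Concordance uses Lin's coefficient with population (1/n) moments —
the variant is a documented toggle (`moment = "sample"`), since published
formulations differ only in the relative weight of the mean-shift term.
Lag k pairs a reference person's bin t with the partner's bin t − k
("predicted by the partner's previous values"); both perspectives are
emitted, and at lag 0 they coincide by symmetry.

## Group-level summaries: pooled versus averaged

Two group-level summaries are computed per condition and lag: the CCC of
bin pairs pooled across participants (`ccc_pooled`), and the mean of
per-subject CCCs (`ccc_dyad_mean`). They answer different questions.
Pooling mixes between-subject FAA offsets into the moments: two partners
with stable offsets of opposite sign contribute a large, lag-independent
negative covariance that can dominate the pooled value (ecological-fallacy
territory — and plausibly part of why weakly negative group concordance is
observed at most lags in real dyadic data). The subject-mean summary is
immune to stable offsets, because each person's own moments standardize
their series; per-subject offsets only attenuate each CCC by a positive
factor, which preserves the location of the lag peak. For this reason the
package's lag-recovery checks (and the recommended group figure) use the
subject-mean profile, while the pooled value is retained alongside.

## The statistical models

Epoch-level FAA: `faa ~ condition * (epoch_s + epoch_s^2) + (1 | person)`,
REML with the Nelder–Mead optimizer. The epoch index is scaled to a
centered unit range per condition (`epoch_s` ∈ [−0.5, 0.5]) so the
polynomial terms stay well conditioned; the scaling is recorded in every
fit. F tests use the naive residual denominator df (n − rank), the
convention that matches epoch-level reports with df² in the tens of
thousands; Satterthwaite df via `lmerTest` is a toggle. Estimated marginal
means are evaluated at mid-condition; linear and quadratic trends are
extracted every 60 epochs (30 s) per condition with confidence intervals.

Subject-level CCC: `ccc ~ condition * lag + (1 | person)` with lag
categorical, followed by pairwise condition contrasts within each lag,
FDR-adjusted (Benjamini–Hochberg) within the lag family.

A calibration caveat, verified by construction: with a random intercept as
the only grouping term, the naive-df epoch-level F test assumes
exchangeable residuals within person. If FAA is autocorrelated across
epochs — as it is whenever a slow latent process drives it — the test is
anticonservative. The package's calibration checks therefore run under a
generator with the latent driver frozen (innovation s.d. 0), where
residuals really are independent; that verifies the model implementation,
not the robustness of the naive-df convention to autocorrelated data,
which no epoch-level model of this form possesses.

## The synthetic generator

`generate_dyad()` emulates the statistical structure the analysis assumes:

* **Latent asymmetry driver.** Per person, AR(1) on the 2 s bin grid,
  held constant within a bin, restarted at each condition around that
  condition's mean. Defaults: coefficient 0.7, stationary s.d. 0.2,
  condition means 0.058–0.092 (half the FAA scale of the condition
  profile the reference design reports). The coefficient was chosen from
  a driver-level identifiability analysis: the expected lag profile of
  pooled two-direction concordance separates neighboring lags by a factor
  proportional to the spacing of AR autocorrelations, and at coefficient
  0.9 neighboring lags differ by under 2 % — unrecoverable at realistic
  data volumes — while 0.7 separates them cleanly and still gives
  smoothly autocorrelated bins. The innovation s.d. may be set to 0 to
  freeze the driver (used in calibration checks).
* **Coupling.** Partner 2's driver is
  `c · d1(t − delay) + (1 − c) · independent AR(1)`; the delay must be a
  sample multiple and shorter than every condition. The default delay of
  4 s mirrors the lag at which dyadic FAA concordance peaks in the
  reference design.
* **Signals.** Cluster channels carry an alpha oscillation with amplitude
  `alpha_amp · exp(∓d/2)` (left/right), so that on the raw cluster
  signals ln(right power) − ln(left power) = 2d exactly — the closed form
  the recovery tests use. The oscillation is a constant-amplitude
  oscillator whose phase performs a random walk (Lorentzian linewidth,
  default 1 Hz FWHM): per-epoch power is stable, while phase decoherence
  makes estimation biases decorrelate across epochs. A deterministic
  sinusoid was rejected deliberately — at 10 Hz a 500 ms epoch contains
  exactly five cycles, so a fixed-phase sinusoid presents the identical
  phase in every epoch and its interference with the common-mode
  reference term produces large, stable per-channel power biases that
  masquerade as between-subject FAA offsets. Channels share a slow AR(1)
  background (s.d. 40 µV) with mild per-channel gain variation, plus an
  independent slow component per channel (s.d. 10 µV) that survives
  average referencing and keeps relative alpha realistic (~0.4–0.6)
  without stable between-channel power differences, plus white sensor
  noise (5 µV).
* **Artifacts and bad channels.** Bursts are narrowband 20–40 Hz
  segments whose band power sits a configured number of dB (default 15)
  above the recording's *measured* band power — measured, because the
  slow background's spectral tail, not the white noise floor, sets the
  20–40 Hz floor. Burst intervals are kept as ground truth. Listed bad
  channels are replaced by flat or high-variance traces.
* **Determinism.** One global seed drives a fixed per-stream sequence
  (driver p1, independent driver p2, signal p1, signal p2, artifacts p1,
  artifacts p2, bad channels p1, bad channels p2); within a signal
  stream the draw order is gains, background, then per channel its alpha
  phase walk, local slow component, and white noise.

Covariate tables mirror the individual-difference constructs of such
studies (survey constructs on 1–10, times in hours), with dyad-level
variables shared within a pair.

### What the generator does not emulate

No volume-conduction forward model (channel correlations come from shared
components, not head geometry); no eye-blink or EMG morphology (artifacts
are exactly the band the rejection rule inspects, which is the point — it
makes rejection testable end to end); no 1/f spectral shaping beyond the
AR backgrounds; no event-related structure. Passing recovery tests on
this generator demonstrates that the pipeline's bookkeeping, estimators
and inference behave as specified under the assumed data model — not that
the preprocessing would fully clean arbitrary real-world artifacts.

## Numerical and testing choices

* Problem sizes: recovery and calibration checks use 2 conditions of
  60–120 s, montages of 12–34 channels containing the full clusters, and
  1–3 dyads per replicate; these sizes were chosen so the full suite
  completes in a few minutes while leaving the tested effects far from
  their detection floor.
* FAA-recovery checks run in absolute alpha mode, where the generator's
  log-ratio mapping is closed-form; at default noise the bin-level
  correlation with the latent driver is ≈ 0.9. Relative mode tracks the
  same driver with slope (1 − relative alpha) and saturates near 0.75–0.85
  because broadband-power fluctuations enter through the denominator;
  this attenuation is a property of relative normalization itself and is
  why the relative-mode check asserts proportional recovery, not the
  closed form.
* The epoch-synchronous subtlety above also fixes a convention: lag
  direction. The receiver (the partner whose driver is delayed) is the
  reference person whose concordance peaks at the true lag; the test
  suite pins the alignment against a brute-force index oracle.
* Degenerate inputs: all-zero epochs, nonpositive cluster power and
  under-length conditions are marked invalid or warned about rather than
  propagated; CCC on fewer than 3 jointly valid pairs or a zero
  denominator is reported missing with a reason.
* EDF interchange uses classic 16-bit EDF with 1 s records; recordings
  whose length is not a whole second store the true sample count in the
  reserved header field and are trimmed on read. Quantization error is
  bounded by the per-channel physical range over 2¹⁶.

## Known limitations

Inference at the epoch level inherits the naive-df caveat above. The
montage geometry is idealized, so interpolation fidelity claims are about
neighbor-weighted averaging, not spline accuracy on a real head. Group
pooled CCC is reported but is sensitive to between-subject offsets, as
discussed. Surrogate-dyad (shuffled-pair) null distributions are a
natural extension hook and are not implemented.
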