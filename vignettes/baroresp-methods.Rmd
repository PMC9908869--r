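---
title: "Cardiorespiratory variability and baroreflex analysis with baroresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory variability and baroreflex analysis with baroresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroresp)
```

## The analysis problem

Spontaneous fluctuations of heart period (the R–R interval, RRI),
systolic blood pressure (SBP) and respiratory volume (RSP) carry
information about autonomic cardiovascular control. Three quantities are
of particular interest in patients with heart failure studied under
different breathing patterns (spontaneous, fast-paced at 12–15
breaths/min, slow-paced at 6 breaths/min):

* **band powers** of each signal in the very-low (0.005–0.04 Hz), low
  (0.04–0.15 Hz) and high (0.15–0.40 Hz) frequency bands;
* **squared coherence** between signal pairs, summarized by the 10-s
  index (mean over 0.08–0.12 Hz, the Mayer-wave peak of SBP–RRI
  coupling) and the 25-s index (mean over 0.03–0.05 Hz, its
  characteristic trough);
* **baroreflex sensitivity (BRS)** in ms/mmHg, estimated as the SBP→RRI
  transfer-function modulus averaged over low-frequency lines that are
  coherent (coherency modulus > 0.5) and show negative phase (RRI
  lagging SBP — the reflex direction).

`baroresp` implements the full chain from raw 200-Hz recordings (ECG,
finger pressure, uncalibrated respiratory volume) to these indices,
together with the surrogate-data significance test for coherence and
the group/condition comparison layer. Because clinical recordings of
this kind are access-restricted, the package also ships a seeded
synthetic-data generator that emulates the statistical structure the
analysis assumes, so that every stage can be verified against known
ground truth.

## From waveforms to beat and breath series

**R-peak detection.** A derivative-and-threshold detector: the ECG is
band-passed at 5–20 Hz (zero-phase), the squared derivative is smoothed
over 50 ms and compared against an adaptive threshold equal to
`threshold_factor` (default 0.4) times the running 2-s maximum of the
detection energy; a 250-ms refractory period suppresses double firings.
Each fiducial point is refined to sub-sample precision by fitting a
parabola through the three samples around the local maximum — on the
synthetic ECG at 20 dB SNR this keeps timing errors below 0.5 ms, well
under the 2.5-ms acceptance bound. The constants live in
`default_config()$detector` and are logged with every run.

**Series extraction and cleaning.** RRI is the distance between
consecutive R peaks in ms, stamped at the *later* beat (an interval is
only known once its closing beat occurs; the choice shifts the series
by less than one beat, immaterial after 5-Hz resampling). SBP is the
maximum of the pressure channel within each beat interval. Values
deviating more than 30% from an 11-beat running median (or RRI outside
300–2000 ms) are treated as artifacts/ectopic beats and replaced by
linear interpolation at their own timestamps, which preserves series
continuity for spectral analysis; edits are counted and more than 10%
edits raises a low-quality warning. The cleaning rule is a documented
stand-in: source studies typically state *that* artifacts were removed
but not *how*.

**Breath decomposition.** Breath starts are upward zero crossings of
the centered respiratory signal. Two numerical choices matter here:

* the signal is centered by subtracting a 30-s moving average, so
  very-low-frequency baseline wander cannot destroy segmentation, while
  raw (uncentered) values are kept for the volume series — the slow
  modulation of end-inspiratory (EI) and end-expiratory (EE) levels is
  precisely the phenomenon of interest;
* crossing detection runs on a 0.3-s-smoothed copy with a hysteresis of
  2% of the running tidal amplitude. Without the short smoothing,
  sample-level sensor noise can re-arm the hysteresis mid-upstroke and
  double the breath count; with it, segmentation recovers the generator's
  breath count to ±1.

Per breath *b*: EI(b) is the maximum volume within the breath, EE(b) the
minimum between EI(b) and EI(b+1), the inspired volume
I(b) = EI(b) − EE(b−1), the expired volume E(b) = EI(b) − EE(b), and the
breathing interval BI(b) the time between consecutive EI events. These
definitions imply the exact identity
`E(b) − I(b+1) = EI(b) − EI(b+1)`, which the test suite asserts to
machine precision on every processed record.

## Spectral estimation

Beat-by-beat and breath-by-breath series are cubic-spline resampled at
5 Hz (linear interpolation is available via `method` for sensitivity
checks); the respiratory waveform is decimated from 200 to 5 Hz after
zero-phase Butterworth anti-alias filtering (cutoff 2 Hz, stopband
leakage < 1% in power).

Power spectra use the Welch periodogram: 180-s Hann windows, 50%
overlap, per-segment linear detrending (protecting the VLF estimates
from ramps), scaled so the spectral integral approximates the variance
of the detrended series. Two details are deliberate:

* **running-window coverage** — when fixed stepping leaves a tail of
  the record uncovered, one flush-right segment is added (a 300-s
  record gives 3 segments; a 240-s slow-paced record gives the expected
  2);
* **broadband smoothing** — the averaged periodogram is smoothed in
  frequency with a moving average whose half-width is 10% of the center
  frequency (minimum one spectral line), i.e. a constant *relative*
  bandwidth. The exact smoothing law used by legacy implementations is
  not recoverable; the relative-bandwidth law reproduces its broadband
  character and the parameter is exposed in the configuration.

With 180-s windows the frequency resolution is 1/180 Hz, so the VLF
integral effectively starts at the first grid line ≥ 0.005 Hz. Band
integration is trapezoidal over the half-open band `[f_lo, f_hi)`, so
the shared edges at 0.04 and 0.15 Hz are never double-counted.
Respiratory spectra are normalized to unit total power, since induction
plethysmography volumes are uncalibrated; band *fractions* are
unaffected.

## Coherence, phase convention and BRS

Cross-spectra are estimated with exactly the same segmentation,
windowing, detrending and smoothing as the autospectra; squared
coherence is `k2 = |S_xy|^2 / (S_xx S_yy)` on the smoothed estimates.
Because segment averaging and frequency smoothing apply identical
non-negative weights to all three spectra, `0 ≤ k2 ≤ 1` holds by the
Cauchy–Schwarz inequality and is asserted at run time.

The cross-spectrum is defined as `mean(Conj(X) * Y)`, so a pure delay
of y behind x yields phase `−2πfτ`. With x = SBP and y = RRI the
baroreflex lag therefore produces *negative* phase in the LF band; the
test suite machine-checks this convention with a delayed-copy test
rather than relying on prose. The transfer gain is the standard
open-loop estimator `|S_xy| / S_xx`; no closed-loop correction is
attempted (feed-forward contamination is a known limitation of
transfer-function BRS).

BRS averages the gain, unweighted, over LF lines passing both gates.
"Coherency modulus greater than 0.5" is read as `sqrt(k2) > 0.5`
(equivalently k2 > 0.25); the stricter squared-modulus gate
(`k2 > 0.5`) is available via `gate = "squared"`. When no line
qualifies the estimate is *undefined* — a valid, logged outcome, not an
error. The 10-s/25-s indices average k2 over closed bands (whether
legacy implementations included band endpoints is unknowable; the
closed choice is fixed and documented here).

## Surrogate significance testing

To test where coherence exceeds its finite-sample null level, each
channel is replaced by an iterative amplitude-adjusted Fourier
transform (IAAFT) surrogate: the iteration alternates imposing the
original amplitude spectrum with rank-remapping onto the original value
distribution, ending on the remap so the amplitude distribution is
preserved *exactly* (multiset equality). Spectrum preservation is
within the logged mismatch (relative L2 typically ~3×10⁻³ after 100
iterations; non-convergence returns the best iterate with its
mismatch). Independent seeds per channel destroy cross-coupling. At
each frequency a one-sided paired t-test across subjects compares
original versus surrogate k2; zero paired differences give t = 0 and
p = 0.5 by convention.

The comparison is confined to 0–0.5 Hz, the physiological range of
beat-to-beat variability. This is not cosmetic: above the intrinsic
beat-sampling Nyquist (~0.5 Hz at normal heart rates) the 5-Hz
interpolated series contain only deterministic spline roll-off, whose
inter-line structure surrogates destroy; including those frequencies
inflates the empirical type-I rate from ~0.05 to ~0.18. Within the
physiological band the test calibrates at 0.049 on 200 uncoupled
replicate cohorts.

## Group and condition statistics

Power spectra and band powers are compared after log-transformation
(multiplicative scatter becomes additive; group summaries are geometric
mean and geometric SEM, the latter computed as `exp(sem of log
values))`; coherency values after Fisher z-transformation
(`atanh` of the coherency modulus). Per-frequency group t statistics
are exploratory — no multiplicity correction across frequencies, with
the 0.05/0.01 two-sided thresholds returned as reference lines, which
mirrors how such comparisons are conventionally displayed.

Index-level comparisons use two-way repeated-measures ANOVA (within:
condition; between: group) on complete cases for one condition pair at
a time — spontaneous vs fast-paced and slow- vs fast-paced, never free
vs slow, matching the two table designs of this study family. When any
factor shows a trend (p < 0.10), unadjusted pairwise contrasts are
emitted in the Least-Significant-Difference style. Normality is judged
by Shapiro–Wilk on the residuals of the cell-means model at p = 0.05;
on rejection the whole analysis is rerun on ranks (rank-transform
two-way ANOVA, the specific "ANOVA on ranks" flavor chosen here) and
the method is recorded in the output. Zero-variance inputs return NA
factor p-values and run no pairwise tests. Demographics use
Mann–Whitney (numeric columns) and Fisher's exact test (two-level
categorical columns).

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions (durations 900/300/240 s for free/fast/slow; 200-Hz
channels) and its only obligations are the assumed statistical
structure and recoverability of its own ground truth.

**Respiration.** `rsp(t) = A_vlf sin(2π f_vlf t + ψ) + a(t) sin(φ(t)) +
noise`. The tidal phase advances at 0.22 Hz (free; randomly modulated
±10%), a fixed rate in 12–15 breaths/min (fast) or 0.1 Hz (slow). The
tidal amplitude carries slow depth variability (CV 15% free, 3% paced —
resting tidal-volume variability of this order is physiologically
realistic, and it makes the inspired/expired volume series carry
common-mode variance in both profiles). The VLF baseline
(`f_vlf = 0.012 Hz`) shifts EI and EE *together*, leaving tidal volume
essentially unchanged: the HF-like profile uses `A_vlf = 0.25` au
versus 0.05 au for the CNT-like profile. The residual VLF leak into the
inspired volume (the baseline increment over roughly half a breath) is
kept below ~10% of the common tidal variance by these choices.

**Hemodynamics.** Beat times accumulate as
`t_{k+1} = t_k + RRI_k/1000` (integral-pulse-style accumulation chosen
for transparency), starting at a random 0.2–1.0-s offset so the first
R-wave is never clipped at the record edge. Per beat:
`SBP_k = S0 + mayer(t_k) + g_mech·rsp(t_k) + ε_S` and
`RRI_k = R0 + G·(SBP(t_k − δ) − S0) + c_RSA·rsp(t_k) + ε_R`,
with the delayed SBP linearly interpolated from the emitted beats
(G = baroreflex gain, δ = 1.5 s delay). Two modeling points deserve
emphasis:

* the **Mayer wave is a phase-diffusing sinusoid** (Lorentzian
  linewidth 0.02 Hz around 0.1 Hz), not a deterministic sine.
  Spontaneous pressure oscillations drift in phase; a deterministic
  sine would concentrate all SBP–RRI coupling in a single spectral
  line, leaving the rest of the LF band as pure noise where
  chance-coherent lines bias the gated transfer average. The
  narrowband model spreads genuine coupling across the LF band, which
  is what the transfer-function method assumes of real data;
* the autonomic and mechanical arms are driven by the **noise-free
  respiratory component** — sensor noise belongs to the recording
  channel, not to the physiology (driving both arms with measurement
  noise would manufacture a spurious zero-lag SBP–RRI coupling).

Parameter sets driving RRI outside 300–2000 ms are rejected as
non-physiologic. Default amplitudes (Mayer 3 mmHg, RSA gain 30 ms/au,
mechanical gain 2 mmHg/au, beat noises 1 mmHg and 8 ms) place the
resulting band powers and coherency indices in the range reported for
resting adults.

**Waveform rendering** closes the loop for the detection chain: Gaussian
R bumps (10-ms width) at the beat times plus white noise at 20 dB SNR,
and per-beat raised pressure pulses whose maximum equals the beat's
systolic value. BRS recovery is validated in the *fast-paced*
condition, where respiratory sinus arrhythmia stays in the HF band; at
slow pacing RSA enters the LF band and the measured BRS intentionally
exceeds the programmed gain — a feature mirroring the physiology of
slow breathing, asserted as such in the tests.

**What the generator does not emulate:** closed-loop
cardiovascular-autonomic feedback (SBP does not respond to RRI),
chemoreflex dynamics, periodic breathing, arrhythmias and ectopy
(cleaning is tested with injected spikes instead), and calibrated
respiratory volumes. Passing tests therefore demonstrate correctness of
the estimators under the assumed signal structure, not clinical
validity on real recordings.

## Problem sizes and reproducibility

The verification suite uses 20 subjects per gain level for BRS recovery
(gains 3/5/10 ms/mmHg), 200 replicate 8-subject cohorts for the
surrogate-test calibration, 6 subjects per profile for the respiratory
contrast, and 10 subjects for the coherency-structure checks — sizes at
which the Monte-Carlo error is comfortably below the asserted
tolerances. All randomness flows from explicit integer seeds through a
deterministic child-seed derivation; `simulate_cohort()` emits a seed
manifest, and identical seeds reproduce recordings bit for bit.

## Known limitations

* Transfer-function BRS is an open-loop estimator; feed-forward
  RRI→SBP coupling and cardiopulmonary reflexes bias it on real data.
* The broadband smoothing law is a configurable stand-in for legacy
  implementations whose exact law is not recoverable.
* The surrogate test uses one surrogate per subject (paired design);
  the calibration suite regenerates cohorts rather than drawing many
  surrogates per subject.
* Free-breathing analyses use all available samples; no sub-segment
  selection is attempted.
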