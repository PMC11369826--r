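---
title: "Methods: ambulatory fNIRS processing and hierarchical modelling of freezing of gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ambulatory fNIRS processing and hierarchical modelling of freezing of gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`gaitfnirs`: the forward model the synthetic generator implements, each
processing stage and its parameters, the hierarchical models, and what the
package's validation does and does not establish about real data.

## 1. Measurement model and units

Continuous-wave fNIRS measures light attenuation at two wavelengths
(760 and 850 nm here). We work in optical density changes
$\Delta OD_\lambda(t) = -\log_{10} I_\lambda(t)/\bar I_\lambda$, related to
chromophore concentration changes by the modified Beer–Lambert law

$$\Delta OD_\lambda = d \cdot DPF(\lambda, A) \cdot
  \big(\varepsilon_{HbO}(\lambda)\,\Delta HbO +
       \varepsilon_{HbR}(\lambda)\,\Delta HbR\big),$$

with interoptode distance $d$ (3 cm long channels, 1 cm short channels),
a differential pathlength factor from the general wavelength/age
polynomial (`dpf()`; about 6.3 at 760 nm for a 66-year-old), and molar
extinction coefficients from the standard compiled haemoglobin spectra
(`inst/extdata/hb_extinction.tsv`). Solving the 2×2 system per channel
gives $\Delta$HbO/$\Delta$HbR in µM. The map is linear and exactly
invertible (`hbToOd()` / `odToHb()`), which the tests exploit as a
round-trip oracle.

A noteworthy consequence of the extinction spectra: at 760 nm a typical
neural response (HbR $\approx -\tfrac13$ HbO) nearly cancels in OD, so
single-wavelength sanity checks should use the 850 nm row or the
reconstructed HbO.

## 2. The synthetic session generator

The generator (`generateSession()`) is a first-class, tested component:
it defines the conditions under which the pipeline is validated.

**Protocol.** Four runs of ~390 s by default: 60 s quiet standing, then
walking legs of 20 s between arrivals that alternate doorway (corridor
midpoint) and 180° turns (corridor ends), an instructed 30 s stop every
fifth arrival (2.5 corridor lengths, in front of the door or in the
square, with the mid-stop 180° turn in the square), turn directions
alternating and switching after each stop. Freezing episodes attach to
triggers (turn 0.35, doorway 0.25, start 0.12, destination 0.12,
walking 0.04 per opportunity, scaled by a per-participant severity) with
log-normal durations (median 3.8 s, `sdlog` 1, truncated to
0.4–45 s, matching the reported distribution shape of freeze durations).

**Forward signal.** Per channel, in µM:

* *neural*: per-ROI amplitudes (z-unit scale, default pattern: stopping
  activates SMA/PFC and deactivates M1; starting deactivates M1/PMC;
  turning/doorways activate premotor areas; freezing reduces PFC)
  × boxcar ⊛ canonical double-gamma HRF (peak 6 s, undershoot 16 s,
  ratio 1/6; kernel normalized so a 5 s event peaks at its nominal
  amplitude) × 0.3 µM per z-unit. Long channels only.
* *systemic*: a rank-8 component set shared by all channels — slow
  drift, very-low-frequency (0.04 Hz), Mayer waves (~0.1 Hz),
  respiration (~0.25 Hz), cardiac (~1.2 Hz, amplitude-modulated) and
  three band-limited noise components — with per-channel positive
  loadings (amplitudes 0.4/0.2/0.15/0.1/0.08/0.08/0.08/0.08 µM; short
  channels ×1.2). Total OD fluctuation ≈ 0.02 sd, matching the size of
  slow OD fluctuations seen in walking fNIRS; the cardiac amplitude
  (0.08 µM) keeps cardiac OD excursions well below the 0.05 motion
  threshold, as in real recordings.
* *freeze-locked surge*: a heart-rate-like gamma transient (peak ~4 s)
  at each freeze onset, 0.5 µM, expressed through the loading pattern of
  the blood-pressure-like component — i.e. inside the systemic loading
  space, which is what makes it removable by short-channel regression
  and what produces the spurious "global PFC activation during freezing"
  when regression is ablated.
* *indirect movement*: per-channel gain (0.02 ± 0.006 µM/deg) on the
  head-pitch series; participants look down around stops, turns, doors
  and freezes (bumps of 6–15°).
* *direct artifacts*: with probability 0.15/0.10 per turn or freeze, a
  spike (0.3–1 s, 0.1–0.4 OD) or a transient baseline-shift plateau
  (2–5 s, 0.05–0.15 OD) on a random long channel. Shifts are finite
  plateaus (a decoupled optode re-seating); their whole plateau is what
  the mask-extended spline flagging targets.
* white OD measurement noise, sd 0.0015; per-row reference intensities
  0.5–2; $I = I_0 10^{-OD}$.

Short channels receive systemic + surge + scalp-share of the movement
coupling but no neural term (tested by regressing them on the event
design).

**Kinematics** (60 Hz) are built from the same schedule: cruise speeds
(PD 0.95, HC 1.09 m/s), slower pre-stop deceleration and post-start
acceleration for PD, turn durations (PD 3.07 s, HC 1.89 s), yaw
trajectories with trapezoidal rate profiles, corridor positions anchored
to the event schedule and advanced by normalized cumulative velocity (so
halts freeze the position), and head-pitch bumps that drive the indirect
artifact. Velocity noise is smaller while standing so that zero-clipping
does not make a standing walker creep.

**What the generator does not emulate:** biomechanically realistic gait,
photon transport, optode-position uncertainty, non-instantaneous
(lagged) indirect artifacts, heart-rate variability coupling between
systemic components, or rater disagreement beyond onset/duration jitter.
Passing recovery tests therefore shows the pipeline implements its
stated transformations correctly and removes confounds *of the simulated
classes*; it does not certify performance on real cohort data.

## 3. Processing stages and parameters

| Stage | Parameters (defaults) |
|---|---|
| Resampling | 50 → 60 Hz, polyphase with mirror padding; mean-preserving |
| Channel pruning | SQI < 2 for > 50% of standing; 10 s windows |
| Spline correction | stdv 65 × sd(diff), amplitude 0.05 OD, tMotion 0.5 s, tMask 1 s |
| Wavelet correction | db2, IQR fence 0.8, full depth (≥ 32 approx coefficients) |
| MBLL | DPF(λ, age), compiled extinction spectra |
| Pre-regression filter | 0.5 Hz low-pass, order 3, zero-phase |
| Confound regression | 8 short-channel PCs + 9 head regressors, per run |
| Band filter | 0.01 Hz HP (order 2), 0.1 Hz LP (order 6), zero-phase |
| Normalization | per-channel, per-run z-transform |
| Merging | tolerance 2 s, union (include) |
| Selection | 10 s freeze-proximity exclusion; trigger within 5 s |
| Epochs | 0–3 s; 7–10 s for stop/start; baseline −10…−5 s; `[a,b)` |

Numerical notes:

* **Zero-phase filtering** uses forward–backward application with
  steady-state initial conditions (`.zfilt`), because a plain
  zero-state `filtfilt` leaves a transient that does not settle within a
  run for a 0.01 Hz high-pass. Single-pass magnitudes are quoted; the
  zero-phase gain is their square.
* **SQI scorer.** The cited index has no published closed form, so the
  scorer is pluggable; the default rates each window by the cardiac-band
  (0.8–2.4 Hz) power over the high-frequency noise floor, mapped as
  `1 + 1.5 log10(SNR)` into [1, 4]. A channel without a cardiac
  component (e.g. a detached optode recording ambient noise) scores ~1.
* **Spline correction** detects windows whose excursion exceeds either
  threshold, extends flags by tMask, fits a smoothing spline (20 df per
  second of artifact — flexible enough to track sub-second spikes, as in
  the published artifact-removal algorithm), subtracts it and re-levels
  the segment to the adjoining clean second. Unflagged samples are
  returned bit-identical; consequently only transient shifts whose whole
  plateau is flagged can be removed, which is why the generator's shifts
  are finite plateaus.
* **Wavelet correction** uses a periodized Daubechies-2 transform
  implemented in the package with exact reconstruction; only detail
  coefficients outside the 0.8·IQR fences are zeroed. Full decomposition
  depth is needed because unipolar spike pulses carry energy down to
  near-DC; at the deep levels the fences adapt to the systemic
  oscillations, so the shared long/short structure survives (verified:
  post-wavelet confound regression still attains R² ≈ 0.98).
* **Epoching** drops events lacking the full baseline-to-window margin
  and reports the count; ROI values are unweighted means over unmasked
  channels.

Open choices resolved: spline/wavelet operate on OD before conversion;
the regression is fitted per run with the dependent variable in
concentration units (only regressors are z-transformed); short-channel
PCA pools HbO and HbR rows within the run; freeze epochs use the same
−10…−5 s baseline as all other events for cross-condition comparability.

## 4. Hierarchical models

All models are Gaussian linear mixed models fitted by MCMC (JAGS),
written as `y = X\beta + Z u + \varepsilon` with
`u_j ~ N(0, diag(\sigma_u^2))` per participant:

* **group**: intercept + sum-contrast group (PD = +1, HC = −1; the
  coefficient is the PD deviation from the grand mean, the PD−HC
  difference is twice it) + participant intercepts;
* **condition**: intercept + two sum-contrast columns over
  freeze/stop/successful + random intercept *and* independent random
  slopes on the contrast columns. Independent (diagonal) random effects
  are used deliberately: with ~20 participants the slope–intercept
  correlations are not identifiable, and a diagonal prior avoids
  fragile covariance estimation while preserving the "slope varying
  over participants" structure. Condition contrasts are computed on the
  posterior draws, never by refitting.
* **severity**: intercept + % time frozen + motor score (both centred
  and standardized internally) + participant intercepts, PD group only.

Priors are effectively flat normals (`N(0, 10^6)`) on fixed effects and
half-normal(1) on every standard deviation — a flat prior alone is not
samplable for variances, and on the per-run z scale of the response a
half-normal(1) is weakly informative. Defaults are 4 chains × 2000
draws after 1000 warmup (configurable); convergence is checked by
split-chain R-hat (warning above 1.01) and effective sample size.
Credibility intervals are posterior quantiles; channels whose 95% (99%)
CrI excludes zero get a small (large) star in the channel maps.

Shrinkage is a tested property: a participant contributing 2 events with
the same raw mean as one contributing 50 has a posterior random effect
pulled further toward the group mean.

## 5. Validation design and simulation sizes

The study's empirical group results cannot be reproduced without its
participants, so validation is property- and recovery-based:

* exact oracles: MBLL round trip (10⁻¹⁰), analytic Butterworth gains,
  hand-counted agreement tables, hand-applied exclusion rules;
* injection oracles: spikes reduced ≥ 80% (wavelet), transient shifts
  ≥ 90% (spline) with unflagged samples bit-identical;
* recovery: on cohorts of 3 participants × 2 runs, confound regression
  at least halves the epoch RMSE against ground truth and removes
  ≥ 75% of the spurious global freeze response that the freeze-locked
  surge induces in the ablated pipeline;
* calibration: over 50 replicates of 20 participants × 30 events
  (group effect 0.2, participant sd 0.3, residual sd 1), the 95% CrI
  covers the truth 85–100% of the time with posterior-mean bias < 0.05;
  under a 120-channel null simulation ~5% of channels reach the
  95-star level.

These sizes (3 × 2 sessions, 50 replicates, 120 channels) are the
package's chosen simulation scales: large enough that each quantity's
Monte-Carlo error is small against its acceptance margin, small enough
to keep the whole validation reproducible in minutes on a laptop.

For the RMSE benchmark, estimate and truth are compared in
concentration-equivalent amplitude units (`recoveryComparison()`): the
channel-level epoch estimates are multiplied back by the per-channel
standard deviations recorded by the z-transform and divided by the
generator's µM-per-amplitude calibration, and the truth is the
band-filtered noiseless ROI time course, epoched identically. This is
the only scale on which the corrected and the ablated pipeline are in
the *same* units: a per-run z-scale depends on the residual variance of
the arm that produced it, so z-unit comparisons mix confound leakage
with arm-dependent scale factors.

## 6. Known limitations

* The SQI is a stand-in scorer reproducing the decision rule, not the
  cited proprietary index.
* Gait-event definitions (velocity threshold 0.1 m/s sustained 2 s;
  yaw rate 30°/s reconstructed from head angular acceleration by leaky
  integration; door-plane crossing with 0.3 m margin) are explicit
  package definitions; the original study deferred details to its
  supplement.
* The wavelet stage assumes artifact coefficients are distributional
  outliers; dense artifact bursts would shift the fences themselves.
* Per-participant filter cut-off tuning (done by spectrum inspection in
  practice) is intentionally not automated; cut-offs are fixed,
  configurable parameters.
* HbR is carried through every stage but not modelled statistically.
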