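---
title: "Motor-network state and TMS-evoked responses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-network state and TMS-evoked responses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnstate)
```

## The scientific question

Corticospinal excitability, indexed by the peak-to-peak amplitude of the
motor-evoked potential (MEP) that a TMS pulse over primary motor cortex
elicits in a hand muscle, fluctuates strongly from pulse to pulse. Part of
that fluctuation tracks the *state* of the sensorimotor system in the
second before the pulse. Beyond local descriptors (power and phase of the
9–13 Hz mu rhythm under the coil), the pre-stimulus *phase coupling* of
left M1 with the rest of the motor network — left supplementary motor area
(lSMA) and right M1 — carries additional information: pulses arriving in a
high-connectivity state evoke larger MEPs.

`mnstate` implements the full analysis chain needed to measure that
relationship in source space, together with a synthetic session generator
that provides ground truth for every stage:

1. epoching/decimation, bad channel/trial detection, ICA-based mu-component
   selection (`epoch_and_downsample()`, `detect_bad()`, `run_ica()`,
   `select_mu_components()`, `reconstruct_clean()`);
2. EMG processing to per-trial MEP scores (`extract_mep()`, `mep_pc1()`);
3. orientation reduction and the eLORETA spatial filter
   (`reduce_orientation()`, `eloreta_filter()`, `project_sources()`);
4. seed-based iPLV connectivity maps and cROI extraction
   (`narrowband_analytic()`, `iplv_trial()`, `seed_map()`, `group_map()`,
   `extract_crois()`, `croi_trial_iplv()`);
5. median-split state analysis of MEP modulation and its controls
   (`median_split()`, `network_trials()`, `mep_modulation()`,
   `control_splits()`, `control_split_test()`);
6. directed coupling by the multivariate phase slope index with jackknife
   pseudo-Z scores (`select_voxel_patch()`, `cross_spectra()`, `mpsi()`,
   `jackknife_pseudo_z()`, `group_z()`);
7. pre-pulse phase prediction and five-model robust-regression comparison
   by AIC (`estimate_phase_at_pulse()`, `fit_mep_models()`, `aic_rss()`,
   `classify_models()`).

## Connectivity metric

For seed phase $\phi_S(t)$ and target phase $\phi_T(t)$ (analytic phases of
the narrowband source signals), the per-trial imaginary phase-locking value
is

$$\mathrm{iPLV} = \left| \,\mathrm{Im}\; \tfrac{1}{T}\sum_t
  e^{i(\phi_S(t)-\phi_T(t))} \right| .$$

Taking only the imaginary part makes the metric blind to zero-lag coupling:
any instantaneous mixture of the same signal (volume conduction, source
leakage) has a real-valued mean phasor and contributes exactly zero. This is
the property that makes seed maps in source space interpretable at all; it
is asserted exactly in the tests.

The published formulation takes the expectation "across data epochs",
whereas the median-split state analysis needs one value per trial. We
resolve this by defining the per-trial iPLV as the within-trial time
average (formula above) and the subject-level map as the across-trial mean
of per-trial values; a pooled (coherent) variant is available via
`seed_map(average = "coherent")`.

Narrowband phases come from a two-pass fourth-order Butterworth band-pass
(2 Hz bandwidth) followed by Hilbert transform, with 64 ms of
autoregressive padding (Yule–Walker, order 30) at both ends before the
transform. Two numerical points deserve note:

* a 2 Hz-wide IIR filter rings for hundreds of milliseconds; the plain
  two-pass implementation in `signal::filtfilt()` leaves large transients
  inside a 1 s epoch. `narrowband_analytic()` therefore extends each epoch
  by 2.5 s on each side with an AR extrapolation of the raw signal (odd
  reflection as fallback) before the two passes, keeping the transient in
  the padding;
* AR padding for the Hilbert step outperforms zero padding at the window
  edges; this is verified as a paired comparison in the tests.

## Synthetic sessions: what the generator emulates

One synthetic subject is one session (`simulate_session()`): a lead field
mixes mu-band oscillators at lM1, lSMA and rM1 plus 1/f background sources
into sensor EEG (default 32 sensors, 50-source grid, 1000 pre-pulse samples
at 1 kHz per trial), and a two-muscle EMG stream carries a stimulus
artifact plus biphasic MEPs.

The oscillator model is a set of detuned phase-diffusion (Kuramoto-style)
oscillators: the seed phase follows $2\pi f_\mu t$ plus a Wiener process
(default 2.5 rad/\(\sqrt{s}\), i.e. a ~0.5 Hz linewidth), each target runs
at its own natural frequency ($f_\mu \pm 0.7$ Hz by default) and is pulled
toward the (lagged, offset) seed phase with per-trial convex weight
$\kappa_k \in [0,1]$ drawn from a Beta distribution. The defaults were
fixed on physical grounds before any acceptance run:

* **Detuning** is what makes per-trial iPLV informative through a 2 Hz
  analysis band: with identical natural frequencies the uncoupled phase
  difference barely moves within one second (a 1 s window at 2 Hz
  bandwidth holds only ~2 independent phase samples) and the per-trial
  null level rises to $\langle|\sin U|\rangle = 2/\pi$, almost
  indistinguishable from full coupling.
* **Band-limited coupling**: the oscillator waveform is band-passed around
  $f_\mu$ at generation and each coupled source carries its own broadband
  1/f floor. A pure quadrature copy would be coherent at *every*
  frequency (its Lorentzian tails included), which would produce spurious
  theta- and beta-band coupling; real inter-areal mu coupling is band
  specific, and the generator mirrors that.
* **Phase offsets** are chosen so that the effective seed–target phase
  difference sits near quadrature ($\pi/2$), where the imaginary part of
  the mean phasor — and hence the iPLV readout — is most sensitive. The
  lSMA node *leads* the seed by 10 ms, giving the directed
  SMA-to-M1 chain that the MPSI analysis should detect; lM1–rM1 coupling
  is lag-free (no direction).
* **MEP model**: $\log A_k = \beta_0 + \beta_{SMA}\kappa_k^{SMA} +
  \beta_{M1}\kappa_k^{rM1} + \beta_\phi \cos(\phi_k - \phi^*) +
  \varepsilon_k$, with $\beta = (0.4, 0.25, 0.15)$, trial noise SD 0.45
  log units and a small independent per-muscle jitter (so that PC1 of the
  two log amplitudes explains ~99% of the variance, as observed in real
  recordings). These effect sizes put the recovered network-level HC–LC
  modulation in the 20–30% range reported for real cohorts and are
  detectable — not saturated — at 800 trials.

`simulate_trial_table()` is the generator's fast path (a compiled
per-trial phase simulation): identical ground-truth structure, with
per-trial iPLV computed from the source phases directly instead of the
sensor→eLORETA→filter→Hilbert chain. Large calibration studies (hundreds
of cohorts) use this path; the full sensor-level path is validated
separately by round-trip tests (per-trial coupling recovery through the
complete pipeline reaches Spearman $\rho \approx 0.7-0.8$).

What the generator does *not* emulate: realistic head geometry (the
forward model is a smooth dipole-in-homogeneous-conductor map on a
desk-scale grid, not a boundary-element model), TMS pulse artifacts in the
EEG (the analysis uses strictly pre-pulse data), eye/muscle artifacts, or
non-stationarities across the session. Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not the physiology of
real recordings.

## Inverse model

`eloreta_filter()` implements the iterative eLORETA scheme: voxel weights
$w_j \leftarrow \sqrt{l_j^{\top} M l_j}$ with
$M = (L W^{-1} L^{\top} + \alpha H)^{+}$, $W = \mathrm{diag}(w_j)$, $H$ the
average-reference projector, and final filter $W^{-1} L^{\top} M$. Two
stabilizations make the fixed point attainable on lead fields with a large
dynamic range: weights are rescaled to unit mean each iteration (the
filter is invariant to the overall scale of $W$) and the regularization is
$\alpha$ times the *current* kernel's mean eigenvalue. Defaults
($\alpha = 0.05$, tolerance $10^{-6}$, 100 iterations) are documented
choices; the defining property — exact zero localization bias for every
noiseless lead-field column, including the underdetermined 32-sensor /
50-source case — is asserted for 100% of voxels across ten random lead
fields.

## State splits, modulation and controls

Trials are median-split per cROI into high/low connectivity halves (ties
at the median are assigned deterministically to the smaller set);
HC_network/LC_network are the intersections across cROIs. Subset
modulation is measured relative to each subject's own mean amplitude,
$\mathrm{mod}(S) = 100\,(\overline{A}_S - \overline{A})/\overline{A}$,
using the geometric mean of the two muscles' linear amplitudes; the group
test is a one-tailed paired t-test (HC > LC, the directional hypothesis).
Control splits (first/second half; even/odd trials) use per-subject
*median* amplitudes and two-tailed tests, as in the source protocol; on
stationary synthetic MEPs both calibrate at the nominal 5% false-positive
rate, and an injected slow drift is caught by the half-split but not the
parity split.

## Directionality

The multivariate phase slope index between voxel patches $X$ (dimension
$n$) and $Y$ (dimension $m$) uses whitened cross-spectra
$C(f) = S_{XX}^{-1/2} S_{XY} S_{YY}^{-1/2}$ over 1 Hz-spaced frequencies in
$f_\mu \pm 2$ Hz, $\psi = \sum_f \mathrm{Im}\,\mathrm{tr}\,
C(f)^{H} C(f+1)$. Positive $\psi$ means the first argument leads — the
convention is pinned by tests on constructed 10 ms delays. For $n = m = 1$
this reduces exactly (to $10^{-10}$) to the classic bivariate phase slope
index, which the tests compute with an independent direct implementation.
Whitening uses a $10^{-8}$-relative diagonal ridge (small patches can be
rank deficient). Significance uses the jackknife across 1 s segments
(pseudo-Z), and group-level aggregation is
$Z = \sqrt{N}\,\overline{z}$. The exact normalization of the published
multivariate estimator is not fully specified; the whitened-trace form
here is a documented choice pinned at the bivariate limit.

## Phase prediction

`estimate_phase_at_pulse()` band-passes the last 500 ms of pre-pulse seed
signal ($f_\mu \pm 1$ Hz, order-64 FIR, forward–backward), trims 64 ms per
side, fits an AR(30) model and predicts forward across the pulse; the
Hilbert phase of the predicted −64..+64 ms segment at $t = 0$ is the
estimate (cosine convention: 0 at a peak). The AR fit uses the Burg
recursion: Yule–Walker's autocorrelation bias produces visibly damped,
frequency-shifted extrapolations on near-deterministic segments (0.17 RMS
waveform error on a noiseless sinusoid, versus $10^{-4}$ for Burg), which
alone would exceed the 0.05 rad noiseless error budget. Unstable fits
(poles clearly inside the unit circle, or exploding predictions) fall back
to a deterministic phase advance from the last clean Hilbert sample and
are flagged.

## Model comparison

Five linear models of the per-trial response (PC1 of log MEPs by default)
are fitted by iteratively reweighted least squares with bisquare weights
(tuning 4.685): constant; single-cROI; network; phase
($a + c\cos\phi + d\sin\phi$); network + phase. Models are ranked by
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k+1)$. The RSS entering the AIC
is the *unweighted* residual sum of squares of the robust fit: the
bisquare-weighted RSS shrinks faster with model size than a Gaussian
likelihood allows and mis-ranks nested models under the null (null
constant-model recovery drops from ~0.7 to ~0.36 with the weighted form).

"Preferred" is the AIC argmin (exact ties go to the fewer-coefficient
model); models within $\Delta \le 7$ of the winner are "plausible", and a
winning margin below 2 is annotated as mild. A caveat worth stating
plainly: with five candidate models, argmin-AIC selection recovers a true
constant model in only about two thirds of null datasets (the chance that
no spurious nested extension gains more than $2\Delta k$ in fit is
$\approx 0.67$; a brute-force OLS oracle reproduces this). That ceiling is
a property of AIC itself, not of the implementation, and the corresponding
calibration check in the acceptance suite documents the measured rate.

Published per-subject AIC tables for these five models
(`published_aic_table()`) give a worked classification example: argmin
reproduces the reported preference counts (4/8 network + phase, 2/8
network) exactly. The published plausibility labels are not perfectly
consistent at margins near $\Delta \approx 4.5$, so the per-cell labels are
not a contract; the threshold is configurable.

## Problem sizes

Defaults used by the tests and the acceptance script: sessions of 32
sensors and 50 sources; 40–120 trials for full sensor-level round trips;
800 trials per subject and 8 subjects per cohort for power, null
calibration and model-recovery studies (hundreds of cohorts via the fast
generator path); 100-segment constructions for directionality. These are
the package's chosen desk-scale study conditions.

## Known limitations

* The forward model is synthetic and smooth; localization results say
  nothing about real BEM accuracy.
* Per-trial iPLV through a 2 Hz band over 1 s is intrinsically noisy
  (~2 effective samples); the generator's detuning makes it informative,
  but with real data the single-trial split will be noisier than the
  ground-truth coupling.
* MEP peak-to-peak estimates below ~0.1 mV are dominated by the noise
  floor of the max–min statistic (~25 µV at 10 µV EMG noise); relative
  error bounds apply only above ~0.5 mV.
* ICA cleaning on a 50-voxel grid reduces desk-scale data to the rank of
  the few kept mu components and degenerates whole-grid maps; it is
  therefore off by default in `analyze_session()` and validated on its
  own.
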