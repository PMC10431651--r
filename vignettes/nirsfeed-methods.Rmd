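---
title: "Models and methods behind nirsfeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirsfeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsfeed)
```

# The measurement and the question

Continuous-wave fNIRS measures light attenuation between source--detector
pairs at two wavelengths (here 760 and 850 nm, sampled at 7.8125 Hz).
Changes in attenuation reflect changes in oxy- and deoxy-hemoglobin
concentration in the tissue the light traverses -- cortex, but also scalp
and skull. In a neurofeedback (NF) session the participant watches a gauge
driven by the HbO2 signal of four channels over the bilateral dorsolateral
prefrontal cortex (DL-PFC) and tries to push it up through 15 trials of
30 s task / 30 s rest after a 2-minute baseline.

The scientific problem the package addresses is *specificity*: the online
signal is contaminated by superficial (scalp) hemodynamics -- slow
vascular fluctuations, Mayer waves (0.09--0.1 Hz), respiration
(0.2--0.5 Hz), cardiac pulsation (1--1.3 Hz) -- which can mimic cortical
activation. An 8 mm short channel (SC) per source sees only the
superficial layer; adding it as a nuisance regressor in the offline GLM
separates genuine DL-PFC activation from superficial false positives.
Every stage of that argument is implemented and testable here against a
generator with known ground truth.

# Montage, paradigm, containers

`default_layout()` encodes the probe: 8 sources, detectors D1--D7 forming
17 long channels (4 NF channels `S1-D1, S1-D2, S7-D5, S7-D7`, 12 other
frontal, 1 motor control) at 30 mm separation, and detector D8 collecting
an 8 mm short channel from every source. The published montage gives a
30--42 mm range but not per-channel separations; all long channels use
30 mm, which only rescales concentrations per channel and cancels in
t-statistics. Channel identity is the ordered (source, detector) pair and
array rows follow the layout's declaration order, so ROI indexing is
unambiguous.

Recordings are strictly positive intensity arrays `[channel, wavelength,
time]` with the layout and paradigm attached. On disk the package uses a
plain-text pair (`*_intensities.csv` at full double precision plus a JSON
sidecar with layout, rate and paradigm); the HDF5-based SNIRF container is
deliberately not written by this package, and the functions raise an
informative error if asked for it.

# Preprocessing

The offline chain is fixed: optical density against the whole-recording
mean intensity, `OD = -log10(I / Ibar)`; an order-3 Butterworth band-pass
under one of the two study settings (0.01--0.09 Hz, which excludes all
three physiological bands, or 0.01--0.2 Hz, which admits Mayer-wave
energy); polyphase resampling to 4 Hz; then the modified Beer--Lambert law
(MBLL)

$$\Delta OD_\lambda = \left(\varepsilon_{HbO_2,\lambda}\,\Delta HbO_2 +
\varepsilon_{HbR,\lambda}\,\Delta HbR\right) d \cdot DPF_\lambda,$$

inverted per channel as a 2x2 system. Extinction coefficients are pinned
to the Cope (1991) tabulation as distributed with the HOMER suite
(760 nm: 1486.6 / 3843.7; 850 nm: 2526.4 / 1798.6 cm^-1 per mole/L);
DPF = 6.0 at both wavelengths, a standard adult continuous-wave default.
Since MBLL is linear it commutes with the filtering, which the test suite
verifies (to 1e-6 uM: the narrow-band recursion amplifies last-bit
rounding by ~1e8, so exact-arithmetic identities hold only to that level
in doubles).

Numerical choices worth stating:

* **Zero-phase filtering** (forward--backward, effective order 6) for the
  offline path; the online path is causal single-pass, as a real-time
  system must be. Edge transients of the 0.01 Hz edge are long (~100 s),
  so the zero-phase pass uses odd-reflection padding of three slowest
  time constants.
* **Resampling** is bandlimited interpolation with a Kaiser-windowed sinc
  at the exact 64/125 rational phase grid, per-phase normalized to unit
  DC. This was written in-package because the general-purpose resampler
  available to us overshoots a 0.05 Hz sinusoid by ~2%, violating the 1%
  in-band amplitude contract the analysis relies on.
* **OD reference**: the whole-recording mean. Any reference choice only
  shifts OD by a constant per channel, which the band-pass removes.

# The GLM

The hemodynamic response function is a difference of unit-rate gamma
densities constrained to the canonical continuous-wave parameterization:
positive lobe peaking at 4 s, undershoot at 16 s, support 32 s, and the
undershoot weight solved numerically so the realized min/max amplitude
ratio is exactly 1/6; the kernel is normalized to unit peak. Task
regressors convolve per-trial 30 s boxcars with this kernel and are scaled
so one isolated trial peaks at 1 -- a beta of `a` therefore means a peak
response of `a` uM. Designs contain per-trial task columns (trialwise
mode) or a selected/unselected task pair (pooled mode), an HRF-convolved
rest column, the short-channel nuisance column, and an intercept; the
2-minute baseline is left as implicit baseline. Paradigm-derived columns
are filtered with the same band as the data, so filtering does not bias
the betas.

`fit_ar_irls()` iterates: least-squares fit, AR modelling of the
residuals (Yule--Walker, order chosen by BIC up to 16 = 4 s of lags at
4 Hz), prewhitening of response and design, and Tukey bisquare
reweighting (c = 4.685) of the whitened residuals, to convergence at
1e-6 on the betas. With the AR order forced to zero and reweighting off
it reduces exactly to OLS, which the tests assert against the closed
form.

## Why inference is filter-aware

A process band-limited to 0.01--0.09 Hz but sampled at 4 Hz has spectrum
~0 over ~95% of its band. Such a process is (asymptotically)
perfectly predictable, so *no finite AR model can whiten it*: in our
experiments AR orders 16--80 left whitened-residual lag-1 autocorrelation
at 0.74--0.98 and inflated the channel-wise type-I error to ~0.6 at a
nominal 0.05. Periodogram-based corrections fail for a subtler reason:
at these record lengths the Fourier bins around the task frequency are
strongly correlated, and even with the *true* spectrum the
diagonal-in-frequency variance formula overestimated Var(beta) by ~70%.

The package therefore exploits what is actually known: the preprocessing
is a fixed linear operator `L` (zero-phase band-pass at the device rate
followed by polyphase resampling). Writing the fitted coefficient as
`beta_j = u_j' y` with `u_j = W X (X'WX)^{-1} e_j` (W the IRLS weights),
its variance under white input-rate noise of scale sigma^2 is

$$\mathrm{Var}(\hat\beta_j) = \sigma^2 \lVert L^\top u_j \rVert^2,$$

computed with the exact adjoint of `L` (including the reflection padding
and the resampler's boundary handling). sigma^2 is matched from the OLS
residual power via `E[r'r] = sigma^2 tr((I-P) L L')`, with traces
estimated once per band by seeded Hutchinson probes, and the t reference
uses a Satterthwaite effective dof for that quadratic form (the `dof`
column of the results; it is an effective in-band sample count, two
orders of magnitude below the raw sample count). Because prewhitening is
degenerate exactly when this covariance applies, the AR step is skipped
for responses carrying preprocessing provenance and retained for
unfiltered responses. Under the full null simulation (scalp physiology,
oscillations, SC regression) the measured channel-wise type-I error is
0.065 at alpha = 0.05 over 510 fits.

The white-input assumption covers the measurement noise exactly and the
in-band physiological remainder only approximately; the SC regressor
removes most of the shared superficial power before it matters. This is
the main modelling assumption a user should keep in mind for real data
with strong uncorrected in-band structure.

# Activation, trial selection, group statistics

A channel is *activated* when its task beta is positive and its two-sided
p passes the Bonferroni threshold `0.05/m` with `m` the ROI size (4, 12
or 1) -- the correction is per ROI. A *responder* has at least one
activated NF channel. Trial selection ranks the 15 trials by the mean of
the four NF-channel t-values from a trialwise fit and refits a pooled GLM
with the k best trials as the regressor of interest; unselected trials
stay in the model as a nuisance column rather than being dropped, so the
residual is not contaminated by unmodelled responses (k = 15 degenerates
to the single all-trials regressor). Ties rank the earlier trial first.

Concordance between responder sets with and without SC regression is
exact set arithmetic (both / lost-by-correction / gained-by-correction /
neither), and group comparisons use Pearson's 2x2 chi-square without
continuity correction, df = 1. Block averages extract (-5, +60) s epochs
around task onsets, baseline-correct each epoch to its 5 s pre-onset
mean, and average over the 15 trials.

# The synthetic generator

`simulate_subject()` is the forward model the whole pipeline is validated
against. Per channel it sums, in concentration units:

* **neural**: amplitude x (boxcar over active trials convolved with the
  canonical HRF, unit single-trial peak) on the active long channels;
  HbR = -0.25 x HbO2;
* **scalp**: one shared superficial process -- a random walk smoothed
  below 0.05 Hz and scaled to 0.5 uM sd, plus Mayer (0.2 uM),
  respiratory (0.1 uM) and cardiac (0.1 uM) sinusoids with per-subject
  random phase, log-normal amplitude jitter (sdlog 0.2) and frequencies
  drawn inside their physiological bands -- entering long channels with
  gain 1.0 and short channels directly, and moving HbR scaled by -0.25;
* optional linear drift and, in the `scalp_false_positive` scenario, a
  task-locked superficial ingredient whose peak equals the cohort's
  neural amplitude (0.5 uM by default). Making the mimic exactly as
  strong as the effect it mimics is the scenario's point: an uncorrected
  analysis has no information to distinguish the two, so its responder
  calls are driven by superficial physiology, while the short-channel
  regressor removes the superficial copy whatever its size.

Concentrations map through the forward MBLL to OD, receive white Gaussian
OD noise (sd 0.002), and exponentiate to intensities around 1000 a.u.
Defaults follow magnitudes typical of continuous-wave fNIRS: cortical
responses of a few tenths of a uM, superficial fluctuations of comparable
or larger size (which is precisely why SC correction matters), and the
published physiological bands. They were fixed once, before any
end-to-end evaluation, and are all overridable in `sim_config()`.

What the generator does **not** emulate: motion artifacts (the robust
weights are exercised with synthetic spikes instead), spatially
heterogeneous scalp coupling, wavelength-dependent DPF error, optode
drift, and inter-channel neural heterogeneity. Passing tests therefore
demonstrate correctness of the computations and calibration under this
noise family, not performance on arbitrary real recordings.

# The online path

The streaming chain mirrors the acquisition software sample by sample:
OD against the first received sample, MBLL inversion, causal order-3
Butterworth 0.01--0.2 Hz, 2 s moving average, mean over the four NF
channels, and subtraction of the 5 s pre-task baseline frozen at each
onset. The gauge maps the feedback through
`height = 0.5 + 0.5 tanh(v / v0)` with `v0 = 1` uM -- the simplest
smooth, symmetric, saturating map consistent with half-height-at-zero
and nonlinear ends; the real device's nonlinearity is not published, so
only this qualitative contract is implemented. Streaming state is
explicit, so chunked and whole-recording replays are bit-identical, and
an independent vectorized batch implementation agrees to 1e-10.

One behavior worth knowing: the causal 0.01 Hz high-pass edge makes a
sustained 30 s response sag toward (and past) zero late in each block, so
the gauge rewards the rise, not the plateau. This is a property of the
published online chain, visible in the replay logs, and the reason the
online-tracking tests assert positivity on the 3--15 s rising window and
on per-trial maxima rather than on late-block means. No SC correction is
applied online by default, matching practice; `sc_online = TRUE` enables
source-matched subtraction as a forward-looking extension.

# Problem sizes and reproducibility

The validation suite uses the full session geometry (1020 s at 7.8125 Hz,
4080 samples at 4 Hz) throughout. Monte-Carlo sizes -- 30 null subjects
(510 channel fits) for calibration, 50 seeds for amplitude recovery, a
15 + 15 mixed cohort for the SC phenomenon -- were chosen as the smallest
sizes at which the binomial/Monte-Carlo error of each check is comfortably
below its acceptance band. `scripts/acceptance.R` recomputes all headline
quantities from scratch under a caller-supplied seed; every random draw in
the package flows through R's RNG seeded explicitly, and the Hutchinson
trace probes use locally scoped seeds so package internals never perturb a
caller's RNG stream.

# Known limitations

* The filter-aware covariance conditions on the estimated IRLS weights
  and the short-channel regressor (standard conditional-GLM practice);
  heavy outliers shift its scale estimate slightly.
* The white-input-noise model is an approximation for real data with
  strong in-band systemic physiology not shared with the short channels.
* With 1 motor channel, the per-ROI Bonferroni rule makes the motor ROI
  an uncorrected single test, exactly as the ROI definition implies.
* The CSV dialect stores full-precision text and is therefore bulky for
  long recordings; it is an interchange and fixture format, not an
  archival one.
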