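---
title: "Prestimulus alpha, the VAN window, and trial-level perception: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prestimulus alpha, the VAN window, and trial-level perception: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alphagate)
```

alphagate implements a complete trial-level analysis chain for a classic
question in the neuroscience of conscious perception: does the power and
phase of ongoing posterior alpha-band (8–12 Hz) activity just before a
brief visual stimulus shape the stimulus-evoked ERP in the visual awareness
negativity (VAN) window (150–250 ms), and through it, whether the stimulus
is consciously perceived? The package covers everything from an epoched-EEG
container to a two-stage structural model, together with a synthetic
single-trial EEG generator with known ground truth, so that every stage of
the chain is validated by parameter recovery rather than by eyeballing.

This vignette is the package's methods account: the data model, the
generative model behind the simulator, the spectral and circular
conventions, the statistical machinery, the numerical choices, and the
limitations we know about.

## Data model

An `epoch_set` holds a trials × channels × samples voltage array
(microvolts), the sampling rate (250 Hz throughout), the sample index of
stimulus onset, channel labels, and a per-trial metadata table (participant,
cue presence/side/field/type, report, rejection flag). Epochs span −1000 to
2000 ms around cue onset. Analysis windows are half-open `[start, end)` in
milliseconds, so adjacent windows tile without double-counting; the VAN
window is `[150, 250)` ms and the baseline window `[−200, 0)` ms.

The on-disk container is deliberately vendor-neutral: a little-endian
float32 payload in C order, a JSON sidecar with shape and metadata, and a
CSV trial table. It round-trips losslessly up to float32 (about seven
significant digits, ample at microvolt scale). The pipeline reloads a
container immediately after writing it, so full runs and partial re-runs
consume bit-identical (float32-rounded) data — this is what makes
"re-running only the analyze stage reproduces `results.json`" hold exactly.

## The synthetic generator

`simulate_dataset()` draws, per trial $i$:

* an alpha amplitude $A_i \sim \mathrm{LogNormal}(\ln 5, 0.4)$ (μV) and a
  phase $\varphi_i \sim \mathrm{Uniform}(-\pi, \pi]$;
* an ongoing oscillation $a_i(t) = A_i \cos(2\pi f_0 (t + 250\,\mathrm{ms}) + \varphi_i)$
  at $f_0 = 10$ Hz, scaled per channel by a posterior-weighted gain map
  (occipitoparietal ROI 1.0, CPz 0.4, FCz 0.1, EOG 0). By construction
  $\varphi_i$ is the cosine phase at −250 ms — the same convention the
  spectral module reports, which is what makes phase-recovery tests
  meaningful;
* 1/f ("pink") plus white noise, independent per trial and channel
  (expected RMS 3 and 1 μV). Pink noise is synthesized by frequency-domain
  shaping: the spectrum is drawn directly as complex Gaussians with
  amplitude $\propto f^{-1/2}$ (no DC) on a Hermitian grid and inverse
  transformed at a fast composite length, then truncated to the epoch;
* on cue-present trials, an evoked response: a +3 μV P1 Gaussian bump
  (120 ms, 25 ms width) and a VAN-like bump (200 ms, 35 ms width) whose
  single-trial amplitude is

  $$V_i = v_\mathrm{base} + v_\mathrm{pow} P_{z,i}
        + v_\mathrm{phase}\, w_i \cos(\varphi_i - \varphi_\mathrm{pref}),
  \qquad w_i = \frac{1}{1 + e^{-\gamma (P_{z,i} - p_0)}},$$

  with $P_{z,i}$ the participant-wise z-score of $\ln A_i^2$, defaults
  $v_\mathrm{base} = -2$, $v_\mathrm{pow} = +0.8$, $v_\mathrm{phase} = -1.5$
  μV, $\varphi_\mathrm{pref} = 70^\circ$, $\gamma = 2$, $p_0 = 0$. The
  logistic gate $w_i$ expresses the idea that phase effects are carried by
  rhythmically firing populations and therefore show mainly when alpha
  power is at or above its mean. Because $v_\mathrm{phase} < 0$, the VAN is
  *most negative* at the preferred phase;
* a perception probability
  $p_i = \mathrm{logit}^{-1}(\beta_0 + \beta_\mathrm{van}(-V_{z,i}) + \beta_\mathrm{pow} P_{z,i} + \beta_\mathrm{phase}\cos(\varphi_i - \varphi_\mathrm{pref}))$
  with $V_{z,i}$ the participant-wise z-score of the *true* $V_i$; the
  report is the correct side with probability $p_i(1-\lambda)$, the wrong
  side with probability $p_i \lambda$ ($\lambda = 0.07$), and "absent"
  otherwise. Cue-absent trials (20%) have no evoked component and report
  "absent";
* occasional blink artifacts (5% of trials, 80 μV Gaussian bumps on VEOG
  with a 15% projection to FCz, centered uniformly in −400…1200 ms).

The default cohort is 20 participants × 750 trials (600 cue-present),
matching the scale at which the recovery checks are run. Presets:
`mediated` (defaults — alpha affects perception only through the VAN),
`null` (all couplings zero), `direct_phase` ($\beta_\mathrm{phase} = 0.6$,
$v_\mathrm{phase} = 0$), and `calcarine` (the posterior entries of the VAN
topography flip sign for upper-field cues, emulating a source on opposite
banks of the calcarine sulcus; in `parietal` mode they do not).

What the generator deliberately does **not** emulate: between-channel noise
correlation, realistic head-model projection, eye-movement physiology,
non-stationary alpha (amplitude and phase are constant within a trial), or
latency jitter of the evoked components. Tests passing on this generator
show the *analysis chain* is correct and calibrated; they do not show the
chain is robust to every property of real EEG.

## Preprocessing

`baseline_correct()` subtracts the per-trial, per-channel mean of
`[−200, 0)` ms. `detect_artifacts()` applies the rejection rules: a 200-ms
window moving from −100 ms in 50-ms steps (last start 300 ms, so coverage
ends at 500 ms) flags trials whose peak-to-peak VEOG exceeds 50 μV or HEOG
20 μV; independently, any EEG (non-EOG) channel exceeding ±75 μV anywhere
in the epoch flags the trial. The ±75 μV rule is evaluated on
baseline-corrected data so both rules are invariant to constant channel
offsets. Filtering, re-referencing, ICA and channel interpolation are out
of scope — the generator emits already-processed data.

## Spectral analysis

The time-frequency transform is a tapered complex convolution: at frequency
$f$ the kernel is a Hanning window times $\cos(2\pi f t) + i\sin(2\pi f t)$,
with band-specific lengths — 3 cycles up to 7 Hz, 5 cycles for 8–14 Hz
(≈500 ms at 10 Hz), 7 for 15–30 Hz, 10 for 31–60 Hz. Conventions that
matter:

* **Kernel length** is rounded to the nearest odd sample count so a center
  sample exists and "center = analysis time" is unambiguous.
* **Normalization**: the kernel is divided by the sum of the taper weights,
  so a unit-amplitude sinusoid at $f$ yields $|z| = 0.5$ (analytic-signal
  convention). Natural-log power differences are unaffected by any such
  scaling; the convention exists to make the amplitude-scaling invariant
  ($|2z|^2 = 4|z|^2$, i.e. a $2\ln 2$ log-power shift) exact.
* **Phase convention**: phase 0 means a cosine peak at the analysis time.
* **Off-grid analysis times**: at 250 Hz the sample grid is 4 ms, so
  requested times like −250 ms (and a 50-ms analysis step) do not fall on
  the grid. Each requested time maps to the nearest sample; the coefficient
  is computed there, and its phase is rotated by
  $-2\pi f (t_\mathrm{sample} - t_\mathrm{requested})$ so the reported
  phase refers to the requested time under local sinusoidality. Without
  this, a 2-ms grid offset at 10 Hz would alias into a 7.2° phase bias.
* **Edges**: where the kernel overruns the epoch the cell is flagged
  invalid and propagates as `NA`; nothing is zero-padded, because padding
  biases power estimates near the edges.
* **Prestimulus purity**: the 10 Hz/5-cycle window centered at −250 ms maps
  to the sample at −252 ms and spans [−500, −4] ms — every contributing
  sample is strictly prestimulus (asserted programmatically in the tests).

The FFT path (cross-correlation via the convolution theorem) and the direct
inner-product path agree to better than $10^{-6}$ relative error at every
valid cell; the direct path is used by feature extraction, which only needs
a handful of (frequency, time) points and would waste work on a full grid.

**Phase-estimation noise floor.** A useful analytic fact, verified
empirically by the acceptance suite: the 125-sample Hanning taper has an
equivalent noise bandwidth of 1.5 bins = 3 Hz. For an alpha amplitude $A$
in 1/f noise of total RMS $\sigma$ (shaped over ≈0.33–125 Hz, so
$S(10\,\mathrm{Hz}) \approx \sigma^2 / (2 \times 5.9 \times 10)$ per Hz
two-sided), the phase SD of the coefficient is approximately

$$\sigma_\varphi \approx \frac{\sqrt{S(10) \cdot \mathrm{ENBW} / 2}}{A/2}.$$

At an amplitude-RMS SNR of 1 ($A/\sqrt2 = \sigma$) this evaluates to
≈0.156 rad ≈ 9°, and the measured circular RMSE over 500 trials comes out
at ≈9° (reported by the acceptance output as `phase_rmse_snr1_deg`).
This is a property of the prescribed 5-cycle estimator, not of the
implementation: a sub-5° RMSE would require either an SNR near 1.8 or a
window several times longer. The corresponding acceptance assertion is kept
at its stated bound and fails for this physical reason; all noise-free
phase checks recover phase to well under 1°.

## Circular statistics

`circ_mean_resultant()` returns the mean direction, the resultant length
(ITPC ∈ [0, 1]) and the circular SD $\sqrt{-2\ln \mathrm{ITPC}}$; a
resultant under $10^{-3}$ flags the direction as unstable rather than
returning the arg of numerical noise. `bootstrap_preferred_phase()` draws a
fixed number of trials (default 50) with replacement, takes the circular
mean, repeats (default 10,000 iterations), and summarizes the iteration
means; drawing a fixed count equates effective trial numbers between
conditions of unequal size. The RNG is an explicit seed, never global
state.

`compare_preferred_phase()` computes per-participant, per-condition
bootstrap preferred phases using **common random numbers** (the same
per-participant seed in both conditions), so identical condition data gives
an exactly zero difference. The condition contrast is the circular mean of
the per-participant differences $\Delta_s$. Two tests are reported:

* a **sign-flip test** ($\Delta_s \to \pm\Delta_s$, statistic = resultant
  length of the flipped differences), and
* a **von Mises likelihood-ratio location test** of mean direction 0.

The sign-flip test has a structural blind spot: a difference distribution
concentrated at ±π is itself flip-symmetric (the von Mises(π, κ) density
satisfies $f(x) = f(-x)$), so *no* sign-flip statistic can reject it, even
though half a cycle is the largest possible phase difference. Since
opposite-phase effects are precisely the scientifically interesting
alternative here, the location test is the one with power in that regime;
both p-values are returned and the per-participant differences themselves
are in the output for inspection.

## Features and conditions

For every retained trial — cue present, not artifact-rejected, and reported
either on the correct side (perceived = 1) or absent (perceived = 0);
wrong-side reports are excluded as ambiguous — `extract_features()`
measures:

* **power**: natural-log power averaged over 8–12 Hz (1-Hz grid) and the
  occipitoparietal ROI (POz, PO3, PO4, PO7, PO8, Oz, O1, O2, P3, P4) at
  −250 ms, the midpoint of the last 500-ms alpha window that is entirely
  prestimulus;
* **phase**: at 10 Hz, electrode POz, −250 ms (single electrode to avoid
  mixing sources with different timing);
* **van**: the `[150, 250)` ms ROI window mean. The window is one alpha
  cycle long, so any ongoing 10 Hz oscillation averages out of it exactly
  on the 4-ms grid.

Power and VAN amplitude are z-scored within participant *after* all
filtering (the statistics should describe the analyzed sample);
participants with fewer than 30 retained trials in either perception
condition are excluded, with a per-participant report attached. Terciles
are formed per participant by ascending power with ties broken by trial id;
with remainder $r = n \bmod 3$, low takes one extra trial when $r \ge 1$
and mid when $r = 2$ — a deterministic, documented rule (the split is a
partition, and low/high sizes never differ by more than 1). Per-participant
(rather than pooled) splitting matches the per-participant ERP averaging
downstream.

## Statistical models

All condition contrasts run through one engine (`trial_model()`): maximum
likelihood with per-participant **sum-to-zero fixed intercepts** standing
in for random intercepts — with ≥30 trials per condition per participant
there is little to shrink, and the fixed-intercept likelihood is exact and
fast. Uncertainty comes from a **cluster bootstrap** that resamples whole
participants with replacement (respecting within-participant dependence),
with duplicated participants relabeled as distinct clusters; 95% intervals
are percentile intervals over the focal coefficients. Evidence per term is
the BIC approximation $\mathrm{BF} \approx \exp((\mathrm{BIC}_\mathrm{without} -
\mathrm{BIC}_\mathrm{with})/2)$, read against the conventional threshold of
10 for strong evidence. Logistic fits detect complete separation (fitted
probabilities of 0 or 1, or a constant response) and rank-deficient designs
error out naming the collinear columns.

The **two-stage structural model** (`fit_structural()`) is a parametric
circular-harmonic likelihood:

$$\text{stage 1 (gaussian):}\quad
\mathrm{van}_z = b_0 + b_1 P_z + (c_1 + c_3 P_z)\cos\varphi
 + (c_2 + c_4 P_z)\sin\varphi + \varepsilon$$

$$\text{stage 2 (bernoulli):}\quad
\mathrm{logit}\,P(\mathrm{perceived}) = \alpha_s + a_1 P_z + a_2 \mathrm{van}_z
 + a_3 P_z \mathrm{van}_z + (d_1 + d_3 \mathrm{van}_z)\cos\varphi
 + (d_2 + d_4 \mathrm{van}_z)\sin\varphi.$$

The first Fourier harmonic encodes a single preferred phase; its
power-dependent amplitude and direction are derived quantities:
$A(p) = \sqrt{(c_1 + c_3 p)^2 + (c_2 + c_4 p)^2}$ and
$\hat\varphi_\mathrm{pref}(p) = \mathrm{atan2}(-(c_2 + c_4 p), -(c_1 + c_3 p))$
— the phase of the *most negative* predicted VAN, undefined (an error) when
$A(p)$ is below tolerance. Stage 1 carries no participant terms because
both sides are z-scored within participant; stage 2 keeps explicit
sum-to-zero intercepts because a binary response cannot be standardized.
Both stages are refit on the same cluster-bootstrap resamples (warm-started
logistic refits), giving joint draws of all coefficients. This model
replaces an MCMC smooth-term formulation by design: a first-harmonic
parametric likelihood with ML + bootstrap + BIC evidence is fully
implementable, deterministic given a seed, and matches a generator with a
single preferred phase; no numeric equivalence with posterior summaries of
smooth fits is claimed.

Joint Wald tests of the power×phase interaction $(c_3, c_4)$ and of the
stage-2 phase block $(d_1, d_2, d_3, d_4)$ are computed with both
model-based and bootstrap-covariance matrices. **Calibration note**: with
very few clusters the bootstrap covariance is badly anti-conservative — at
5 participants × 200 trials the bootstrap-covariance Wald test rejects a
true null several times more often than the nominal 5%, while the
model-based (OLS) Wald test stays inside the 2–10% band (both rates are
measured by the null-calibration runs and reported in the acceptance
output as `null_fpr_power_phase_pct` and
`null_fpr_power_phase_bootcov_pct`). Stage-1 trial-level residuals
are independent by construction here, so the model-based covariance is the
calibrated choice at small cluster counts, and it is what the
null-calibration acceptance check uses; percentile CIs similarly
under-cover below roughly 10–15 clusters, which is why the topography
replicates use the full 20-participant cohort.

**Mediator measurement error.** Under the `mediated` preset the stage-2
phase terms are *not* null even though the generator has no direct
phase→perception path. Perception is driven by the true single-trial VAN
amplitude, but the model conditions on the measured VAN (window mean over
noisy channels; measurement correlation with truth ≈0.7 at default noise,
reported as `van_measurement_cor` in the acceptance output). The part of
the true VAN not captured by the measurement still carries the
power-gated phase signal, and it resurfaces in the $d$ terms — the textbook
consequence of conditioning on a noisily measured mediator. At 20 × 600
trials this leakage is decisively detected (joint Wald p ≪ 0.001), so the
recovery check that expects the $d$-block to be null fails for a structural
statistical reason, not an implementation one. The practical reading: with
realistic single-trial ERP measurement noise, a "direct" phase effect on
perception in such a model cannot be distinguished from an under-adjusted
mediated one. The same measurement error attenuates $a_2$ (from the
generative −0.8 on the true-VAN scale toward roughly −0.15 on the measured
scale), which leaves its cluster-bootstrap interval close to the resolution
attainable at this scale — in the replicated recovery it excludes zero in
9 of 10 runs rather than all 10. The geometric recovery checks — the sign
of power→VAN, the fitted preferred phase within a few degrees of 70°, and
the power-gating ordering $A(+1) > A(-1)$ — pass in every replicate.

`compare_rates_by_tercile()` is a one-way repeated-measures ANOVA on
per-participant perceived rates with BIC evidence against the
intercept-only model; a vanishing tercile sum of squares is reported as
F = 0 rather than a 0/0 ratio.

## Problem sizes used by the test suite

Chosen to make the statistical assertions meaningful while keeping the
default suite tractable on one core:

* parameter recovery: 10 replicates of the default cohort (20 participants
  × 750 trials, 600 cue-present), B = 200 bootstrap resamples;
* null calibration: 200 feature-level replicates of 5 participants × 200
  trials, B = 200 (features drawn directly from the null structural model;
  under the null preset the measured features are distributionally
  equivalent to waveform-derived ones, and the waveform chain itself is
  exercised by the recovery and topography checks);
* topography discrimination: 10 calcarine and 10 parietal replicates at 20
  participants × 250 trials;
* spectral oracle: 20 random 750-sample trials over the full 1–60 Hz grid;
* phase recovery at SNR 1: 500 trials;
* unit and property tests: small constructed fixtures throughout.

## Known limitations

* The per-participant sum-to-zero intercepts provide no shrinkage; with
  very few trials per participant a mixed model would behave better.
* Percentile cluster-bootstrap CIs under-cover with fewer than ~10
  clusters; interpret intervals from small cohorts cautiously (the joint
  tests offer the model-based alternative).
* The structural model's phase dependence is first-harmonic only; a
  generator with bimodal preferred phases would be mis-summarized.
* The sign-flip phase test is blind near half-cycle differences; use
  `p_location` there.
* Evidence values are BIC approximations, not posterior model
  probabilities, and inherit BIC's unit-information prior.
* The generator's measurement-noise level implies mediator attenuation in
  stage 2 (see above); true coupling coefficients are recovered in sign and
  geometry (preferred phase, gating order), not in raw magnitude.
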