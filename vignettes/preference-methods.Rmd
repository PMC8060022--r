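---
title: "Quantifying preferred prosthetic ankle alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying preferred prosthetic ankle alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anklepref)
library(dplyr)
```

`anklepref` implements a complete workflow for measuring how a person with a
transtibial prosthesis prefers their ankle to be aligned, and for processing
the gait sensor data used to understand *why* those preferences arise. This
vignette explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The decision model

Each trial of the forced-choice protocol presents one stimulus — a static
ankle angle $x$ (degrees, dorsiflexion positive) — and asks the walker
whether they would prefer the ankle more dorsiflexed ("toes up",
`PREFER_DF`) or more plantarflexed ("toes down", `PREFER_PF`). We assume the
walker compares $x$ with an internal preferred angle $\alpha$ and answers
accordingly, with Gaussian trial-to-trial noise and occasional attention
lapses. The probability of a toes-down response is the cumulative-normal
psychometric function

$$\psi(x) = \tfrac{\lambda}{2} + (1 - \lambda)\,\Phi\!\big(s\,(x - \alpha)\big)$$

with three parameters:

* $\alpha$ — the **point of subjective equality (PSE)**, the preferred
  angle: at $x = \alpha$ both responses are equally likely.
* $s$ — the **slope** (1/degrees). Its reciprocal $\sigma = 1/s$ is reported
  as the **Reliability Index (RI)**: the deviation from preference at which,
  absent lapses, $\Phi(1) \approx 84\%$ of responses favor a change back
  toward the preference.
* $\lambda$ — the **lapse rate**, the fraction of trials answered at random.

The lapse mass is split symmetrically ($\lambda/2$ on each asymptote). This
is a deliberate choice: it preserves $\psi(\alpha) = 0.5$ exactly for any
lapse rate, so the PSE keeps its definitional meaning as the 50/50 point.

```{r psi}
psych_prob(c(-3, 0, 1.5, 3), pse = 0, slope = 1 / 1.5, lapse = 0.02)
```

## Fitting

`fit_psychometric()` estimates $(\alpha, s)$ by maximum likelihood with the
lapse rate fixed at 0.02, a standard compromise: freeing the lapse on
35-trial sessions is hopeless, and ignoring it biases the slope. Slope
bounds default to $[0.05, 10]$ per degree — much wider than the adaptive
prior below, because the prior's job is stimulus selection, not constraining
the final estimate.

Numerics: the objective is optimized in $(\alpha, \log s)$; a coarse
deterministic grid seeds a bounded quasi-Newton refinement from several
well-separated starting cells, because binomial likelihoods on small trial
sets can carry near-tied optima along flat ridges. There is no random
restart, so a fit is a pure function of its data. The PSE standard error is
an observed-information (curvature) estimate. Degenerate data are flagged,
never fatal: perfectly separated responses clamp the slope at its upper
bound with `boundary = TRUE`; one-sided response sets report a PSE outside
the tested range, also flagged. We deliberately leave the PSE unconstrained
rather than clipping it to the tested range, so out-of-range preferences are
visible instead of silently censored.

When individual sessions are too short for stable slopes, the group-level
consistency is summarized by `pool_centered_fit()`: each session's stimuli
are centered by that session's PSE, the centered trials are concatenated,
and one function is fit to the pool. The pooled PSE is left free (it should
land near zero) rather than pinned at zero; this costs one degree of freedom
and avoids forcing the centering to be perfect.

## The adaptive session

A session has 35 trials. The first 14 present each of seven equally spaced
block angles twice in seeded random order (level walking −4.5…4.5°, ramp
ascent 0…9°, ramp descent −9…0°, step 1.5°). The remaining 21 stimuli are
chosen adaptively from a 0.75°-step candidate grid spanning the tested
range, by minimizing the expected entropy of a grid posterior over
$(\alpha, \log s)$ — the classic psi-method criterion, which concentrates
trials near the preference where they are most informative.

Priors and grid: the PSE prior is uniform over the tested range, the slope
prior log-uniform over $[0.3, 3]$ per degree. The PSE grid uses 0.25° steps
and pads the tested range by 3° on each side so preferences near the range
edge remain representable; 41 log-spaced slope points make discretization
error far smaller than any reported RI. The assumed lapse rate during
selection is a conservative 5%: slope estimates (and hence stimulus
placement) degrade badly when the lapse is under-assumed but only mildly
when over-assumed, as `lapse_sensitivity()` demonstrates.

Two choices the protocol leaves open were resolved as follows. The posterior
is updated during the block phase too, so the adaptive phase starts from all
available information rather than a cold prior. Entropy ties (within
$10^{-9}$ nats, which occur when the posterior is nearly degenerate) break
toward the candidate nearest the posterior PSE mean, then by a seeded
uniform draw; one RNG stream per session makes whole sessions bit-for-bit
reproducible from their seed.

`run_session()` also supports a mid-session shift of the candidate range
(for walkers whose preference sits at or beyond the default range) and
appended manual trials; both update the posterior like ordinary trials. The
shift moves only the candidate set — the padded posterior grid stays fixed,
so no accumulated information is discarded. `run_preference_study()`
automates the shift: if the fitted preference lands within 1.5° of the range
edge, the session is re-run with the range re-centered on the estimate (up
to three enlargements), mirroring how such protocols are adapted in
practice.

```{r session}
ses <- run_session(make_responder(pse = 1, slope = 0.667, lapse = 0.02),
                   session_config("LW", seed = 7))
glance(fit_psychometric(ses$trials))
```

## Monte-Carlo design evaluation

`evaluate_design()` replays the full session + fit pipeline against
simulated responders and tabulates bias and RMSE of $\hat\alpha$ and
$\hat s$. Two named designs are built in: `hybrid_14_21` (the default
protocol) and `full_adaptive_35` (all 35 trials adaptive). Defaults used by
the package's own studies, chosen once as representative of the prior
ranges: truth $\alpha = 1.0°$, $s = 0.667/°$ (RI 1.5°), $\lambda = 0.02$;
500 replicates per design.

A finding worth knowing when interpreting slope RMSE on its natural scale:
about 1% of hybrid sessions produce perfectly separated trial logs (the 14
block trials far from the preference respond deterministically, and the 21
adaptive trials cluster within roughly ±1 RI), and the degenerate-data
policy clamps those slopes at the upper fitting bound. A handful of clamped
fits dominates a squared-error summary — with them the hybrid/full-adaptive
slope-RMSE ratio is near 2, without them it is near 0.9 and the median
absolute slope errors of the two designs are comparable. PSE recovery is
essentially indistinguishable between the designs. RMSE of a bounded
estimator inherits the arbitrariness of the bound; treat boundary-flagged
fits separately (the recovery tables report `n_boundary`) when slope
accuracy matters.

## Sensor processing

The biomechanics half of the package reduces raw walking trials to
per-condition gait curves:

* **FSR calibration** (`calibrate_fsr()`): socket-interface force-sensing
  resistors are calibrated against hung weights with force linear in
  conductance, the standard model for this sensor class; pressure is force
  over pad area, weight-normalized to kPa/kg.
* **Filtering** (`lowpass_zero_phase()`): second-order 50 Hz Butterworth,
  applied forward and backward (zero phase, squared magnitude — amplitude at
  the cutoff falls to 1/2). Edges use reflective padding with past samples
  pinned at the edge value, so the DC gain is exactly 1 and a constant
  signal passes through unchanged.
* **Stride segmentation** (`detect_heel_strikes()`): rising crossings of 10%
  body weight on the pylon axial force, with a 0.4 s refractory interval.
  The protocol parameters are exposed; for noisy unfiltered records a
  refractory just below the stride period is the robust setting.
* **Gait-cycle normalization** (`time_normalize_strides()`): each
  heel-strike-to-heel-strike interval is linearly resampled to 101 points
  spanning 0–100% inclusive.
* **Pressure-time integrals** (`pressure_time_integral()`): trapezoidal, with
  time as a 0–1 gait fraction, so a constant pressure integrates to itself.
* **Shank pitch** (`complementary_filter_pitch()`): the accelerometer tilt
  angle $\theta^{acc} = \operatorname{atan2}(a_{fwd}, a_{vert})$ fused with
  integrated gyroscope rate through a first-order complementary filter with
  $\tau = 1$ s — the accelerometer anchors the low frequencies (no drift),
  the gyro supplies the high frequencies (immune to translational
  contamination). The filter is initialized at the first accelerometer
  angle.

`summarize_conditions()` averages normalized strides by task × ankle angle ×
channel and reports peaks, pressure-time integrals, the curve value at a
queried instant (30% of the cycle, midstance, by default), and the
across-condition spread at that instant.

## The synthetic-data generator

No subject data ship with the package; `generate_cohort()` and
`generate_gait_streams()` produce everything the analyses consume, with
ground truth attached so every processing stage is testable.

Cohorts encode the group structure the package targets: level-walking
preferences near 0° (mean 0.5°, SD 2.0° — the SD is a package default, the
tails of reported level-walking preferences being roughly ±3°), a
dorsiflexion shift for ramp ascent of mean +7.8° (SD 4.8°), a plantarflexion
shift for ramp descent of mean −5.3° (SD 3.8°), slopes log-uniform over
0.3–3/°, and a 2% true lapse rate.

Gait streams are deliberately simple physics: a smooth double-bump stance
loading template (so threshold segmentation has a closed-form ground truth);
socket-pressure bumps whose anterior peaks grow linearly with the absolute
ankle/ramp mismatch, calibrated so the 9° tested sweep spans about a 40%
anterior-proximal peak reduction on ramp ascent and 50% anterior-distal on
descent; and a shank-pitch trajectory that deviates from a level-walking
template in proportion to the signed mismatch, most strongly near 30% of the
gait cycle, with per-task midstance sensitivities calibrated so the tested
sweep spans 5.9° (LW), 8.5° (RA) and 5.5° (RD) of midstance pitch variation.
At zero noise the accelerometer reads pure gravity, making the
accelerometer angle exact; translational contamination is part of the noise
specification, and stride-to-stride variability defaults are declared
assumptions (`gait_noise()`), not measured values.

What passing tests therefore show: the pipeline recovers what the generator
encoded — segmentation is exact at zero noise, pitch RMSE stays under 0.5°,
peak pressures return within 1%, and monotone pressure/pitch trends match
the programmed ground truth. What they cannot show: that real sockets,
residual limbs, or walking strategies behave like the generator. The
generator is an oracle for the *code*, not a biomechanical model.

```{r gait}
sim <- generate_gait_streams("RA", ankle_angle = 4.5, n_strides = 4)
cs <- summarize_conditions(process_gait(sim))
filter(cs$summary, channel == "fsr_ant_prox")
```

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible from
it. The package's own recovery studies use 500 replicates per condition and
35-trial sessions (minutes on a single core); the synthetic gait studies use
a handful of strides per condition at 500 Hz, enough for the 50 Hz filter to
be comfortably valid. All of these are configuration, not constants.

## Known limitations

* The final estimator is the fixed-lapse MLE; there is no free-lapse fit,
  no alternative link (logistic, Weibull), and the Bayesian posterior is
  used only for stimulus selection, not reported as the estimate.
* Slope estimates from single 35-trial sessions are noisy and occasionally
  degenerate (see the separation note above); pooled, subject-centered fits
  are the intended group-level summary.
* The gait generator omits inverse dynamics, joint kinetics,
  magnetometer fusion, and stance sub-phases beyond heel strikes; the
  pressure–mismatch model is linear by construction.
* The candidate-range shift heuristic re-runs a session with the same
  responder; with human subjects the analogous adjustment happens once,
  mid-protocol, at the experimenter's discretion.
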