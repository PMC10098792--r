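---
title: "Methods: cuffless BP estimation from multiwavelength PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless BP estimation from multiwavelength PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The model

Arterial blood pressure is the product of cardiac output (CO) and total
peripheral resistance (TPR). Two indices computable from a single
photoplethysmogram track those factors: heart rate (HR, via
beta-adrenergic drive of CO) and the modified normalized pulse volume
(mNPV, the per-beat AC/DC amplitude ratio, via alpha-adrenergic control of
vascular tone and hence TPR). Taking logs of $BP = CO \times TPR$ and
referencing every quantity to a baseline cuff reading (BL1) to suppress
individual differences gives the working model, fitted separately per BP
type (SBP, DBP, MAP) and per LED wavelength:

$$\Delta\ln BP = a\,\Delta\ln HR + b\,\Delta\ln mNPV + c,$$

where $\Delta\ln X = \ln(X / X_{BL1})$. The fit is ordinary least squares
on rows pooled across participants: each participant contributes the three
non-reference measurements (BL2, MA1, MA2), so 14 participants give
$n = 42$ rows per (BP type $\times$ wavelength) cell. Millimetre-of-mercury
estimates are recovered by back-transformation through the participant's
own calibration reading, $\widehat{BP} = BP_{BL1}\exp(\widehat{\Delta\ln
BP})$; the method is calibrated, not calibration-free, by design.

Per-coefficient p-values are two-sided t tests with $n - 3$ degrees of
freedom, the overall test is $F(2, n-3)$, and standardized coefficients are
$\beta_x \cdot SD(x)/SD(y)$. The solver is the normal equations on the
3-column design with an explicit reciprocal-condition-number check: the
design is tiny and fixed, and an explicit solve is deterministic and easy
to verify against an independent routine (the test suite cross-checks it
against `lm()` on random designs). A response with zero variance raises an
error rather than reporting $R^2 = 0$, since a silent zero would corrupt
the wavelength comparison downstream.

## Waveform features

Per cardiac cycle the PPG yields AC (peak-to-trough amplitude), DC (mean
level) and T (interval to the next peak). Window values are means of the
per-beat quantities — HR is the mean of $60/T$ in bpm and mNPV the mean of
per-beat AC/DC — rather than ratios of means; the alternative (averaging AC
and DC first) differs only at second order for the dispersions involved
here, and per-beat averaging is the reading most consistent with
beat-by-beat processing. Analysis windows are half-open $[t_{start},
t_{end})$ with beats assigned by peak time; the default window starts 2 s
after cuff start because cuff pressurization contaminates the first
seconds of the waveform.

The peak detector is deliberately plain: local maxima, a minimum
separation of 0.33 s (a 180 bpm ceiling), and a topographic prominence of
at least 0.3 of the local ($\pm$2 s) amplitude range, which rejects the
diastolic wave while keeping the systolic peak. Polarity is
hardware-dependent in reflectance PPG, so the detector orients the trace
by the sign of the skewness about the mean (sharp, sparse pulses point in
the positively skewed direction) before searching; AC and DC are always
computed on the original samples. Beat spans are trough-to-trough around
each accepted peak, and the first and last peaks, whose spans are cut by
the trace edge, are dropped.

Outlier beats are removed by three rules: (a) beats whose span contains
two or more maxima rising above half the span's amplitude range with no
intervening trough below it — the "maxima continued" pattern typical of
motion artifacts and dicrotic accentuation; (b) absolute interval bounds
$T \in [0.33, 1.5]$ s (40–180 bpm), chosen to bracket any plausible HR in
a healthy adult protocol while catching missed or extra detections; (c) a
relative bound, $T$ within $\pm$30% of the window median, which catches
isolated missed/extra beats even when they stay inside the absolute
bounds. The thresholds are exposed as arguments; none is derived from data.

## What the generator emulates

`generate_session()` simulates the four-measurement protocol with the
statistical structure of the study population the package targets:

* **HR**: rest 72.8 $\pm$ 12.7 bpm, stress 89.8 $\pm$ 15.8 bpm. One cardiac
  truth per participant and condition is shared by all four channels —
  every wavelength sees the same heart.
* **mNPV**: log-normal per channel with resting means 0.0378 (blue),
  0.0364 (green), 0.0206 (red), 0.0247 (NIR) and matching dispersions.
  The rest-to-stress change is modelled as one systemic vasoconstriction
  process: a shared log-scale deviate per participant/condition, with a
  shared rest-to-stress level ratio of 0.529 (the observed ratios at the
  four wavelengths are 0.51–0.54, essentially one number). Consequence:
  $\Delta\ln mNPV$ is identical across channels, which is what makes a
  noiseless session *exactly* recoverable in all 12 regression cells —
  the property the round-trip tests rely on. The cost is that per-channel
  stress means are the resting level times 0.529 (within a few percent of
  the published per-channel values) and per-channel log-SDs are pooled per
  condition; per-channel sample SDs can therefore deviate ~10–15% from the
  published ones. We consider that an acceptable idealisation: the
  published statistics constrain only group means and SDs, not the joint
  cross-channel structure.
* **BP**: the BL1 reference is drawn from 112.3 $\pm$ 12.3 / 68.5 $\pm$
  6.3 mmHg with MAP by the one-third rule $MAP = DBP + (SBP - DBP)/3$
  (which reproduces the published group MAPs exactly). BL2/MA1/MA2
  pressures follow the log-linear model with per-BP-type coefficients
  defaulting to the optimal-wavelength fits (NIR for SBP: $a = 0.373$,
  $b = -0.012$, $c = 0.001$; blue for DBP: $0.203, -0.117, 0.024$; blue
  for MAP: $0.245, -0.084, 0.011$) plus Gaussian log-noise of SD
  `noise_sd_lnBP`. The default 0.05 is the residual scale implied by the
  published fits: with the signal spread of this design
  ($SD(\Delta\ln SBP) \approx 0.07$), $R^2 \approx 0.5$–$0.65$ requires a
  residual SD near $0.07\sqrt{1 - R^2} \approx 0.05$, and the default
  simulated study indeed lands in that $R^2$ range. Setting it to 0
  gives an exactly recoverable model. Because MAP follows its own log-linear
  dynamics, the one-third identity holds exactly at BL1 only; at the other
  conditions it is violated by well under 1 mmHg at default settings.
  Generating MAP from SBP and DBP instead would make the MAP cells only
  approximately log-linear and break the exact round trip.
* **Variance split**: each condition draw mixes a stable participant-phase
  level (70%) with measurement-to-measurement fluctuation (30%,
  `within_frac`), so BL1 and BL2 differ realistically rather than being
  independent redraws or identical copies.
* **Waveforms**: each beat is a fixed template (dominant systolic bump
  plus a smaller, broader diastolic wave) normalised so the emitted trace
  has peak-to-trough amplitude `mnpv * dc` and mean `dc`; beat periods
  carry multiplicative log-normal jitter (default CV 0.04, a typical
  resting beat-to-beat variability). Artifact hooks inject a second
  prominent intra-beat maximum (`double_peak_prob`), silenced beats
  (`missed_beat_prob`), and a decaying cuff-pressurization transient at
  the window start.

What the generator does **not** emulate: optical physics (wavelength
penetration depth, tissue layering) — so it cannot reproduce the *reason*
green performs worse in vivo, only the statistical pattern; baseline
wander, respiration coupling and sensor noise; correlation between a
participant's HR and tone responses (independent by default, as the
published statistics do not constrain it); and cuff quantisation (cuff
values are kept at full precision so that noiseless sessions round-trip
exactly). Passing tests therefore demonstrate algorithmic correctness
under the stated statistical structure, not field performance on real
recordings.

## Evaluation layer

The per-wavelength comparison averages each wavelength's three $R^2$
values (SBP, DBP, MAP) and tests the wavelength effect with a one-way
repeated-measures ANOVA treating BP type as the subject factor: the
additive two-way decomposition $SS_{total} = SS_{channel} + SS_{subject} +
SS_{error}$ with $F = MS_{channel}/MS_{error}$ on $(c-1, (c-1)(r-1)) =
(3, 6)$ degrees of freedom, uncorrected for sphericity (the reference
analysis reports plain $(3,6)$ df). Tukey HSD uses
$q = |\bar m_i - \bar m_j| / \sqrt{MS_{error}/r}$ against the studentized
range at $(c, 6)$. On the published matrix this gives $F(3,6) = 18.74$,
$p = 0.002$, and green significantly below blue, red and NIR with no other
significant pairs. `mean_r2_by_channel()` reports the sample SD ($n-1$);
the published table's SDs match the $n$-denominator convention, a
difference that affects no test.

Agreement uses Bland–Altman statistics on estimated minus measured
pressure: fixed bias $M$, SD of differences, limits of agreement $M \pm
1.96\,SD$, plus the mean and SD of the absolute error and counts in the
absolute-error classes $[0,5)$, $[5,10)$, $[10,15)$, $\ge 15$ mmHg —
half-open bins, since the conventional labels "0–5, 5–10, ..." are
ambiguous at the boundaries. Calibration scatter uses geometric-mean
(reduced major axis) regression, $slope = \mathrm{sign}(r)\,SD(y)/SD(x)$,
which treats both axes symmetrically — appropriate when neither variable
is error-free. Residual normality is checked per fit with Shapiro–Wilk
via `stats::shapiro.test()`. Estimation is evaluated in-sample (the fit
and the evaluation use the same 42 rows), mirroring the reference
procedure; this measures descriptive agreement, not out-of-sample
generalisation.

## Numerical and design notes

* Determinism: every stochastic step runs under the configured seed
  (`withr::with_seed`), and pipeline artifacts embed the package version,
  seed and a configuration hash; reruns are byte-identical.
* The round-trip contract is split deliberately: coefficient recovery to
  1e-8 and BP reproduction to 1e-6 are asserted on generator *truth*
  features, because waveform extraction at 60 Hz carries an irreducible
  discretisation error of order 0.1–1% (peak positions are integer
  samples, the sampled template maximum sits slightly below the continuous
  one). Extraction accuracy has its own tolerances — HR within 1%, mNPV
  within 2% of truth — and the end-to-end extracted-feature fit is
  additionally required to reach $R^2 > 0.999$ on noiseless sessions.
* Problem sizes in the tests (2–6 participants for waveform-level checks,
  14 for design-shape checks, 250 truth-only participants for
  distributional calibration, 50 replicates for stochastic recovery) were
  chosen as the smallest sizes at which the corresponding property is
  expected to hold with comfortable Monte-Carlo margin.
* Degenerate inputs fail loudly with typed conditions
  (`ppgbp_singular_design`, `ppgbp_degenerate_input`, ...), never with
  silently imputed values. A constant trace yields an empty beat table
  (no heartbeat is a data condition, not a programming error); a
  zero-variance regression response raises.

## Limitations

The estimator requires a per-participant cuff calibration (BL1) and has
only been validated here against its own generative model; the synthetic
results say nothing about sensor hardware, motion robustness or
populations outside the emulated one (young healthy adults under a mental
arithmetic stressor). The wavelength comparison operates on three $R^2$
values per wavelength and thus has the low power its $(3,6)$ degrees of
freedom imply.
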