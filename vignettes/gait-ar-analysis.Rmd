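---
title: "Quantifying gait-pattern stability with AR(2) models of vGRF peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gait-pattern stability with AR(2) models of vGRF peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitar)
```

## The model

Each step of walking loads the limb with a characteristic double-hump
vertical ground reaction force (vGRF): a weight-acceptance (impact) peak as
body weight transfers onto the limb, and a propulsive peak at push-off.
Collecting the two peaks of every step in chronological order gives an
interleaved peak time series $y_t$ (two values per step, in body-weight
units). `gaitar` models this series as a second-order autoregressive
process,

$$y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} + \varepsilon_t,$$

with white-noise innovations $\varepsilon_t$. The series is centred about
its mean before fitting, which makes $\delta = 0$ by construction and lets
the model describe the *pattern* of step-to-step fluctuation rather than
the loading level; $\delta$ is reported back as
$\bar y\,(1 - \phi_1 - \phi_2)$.

The process is stationary exactly when both roots of the characteristic
equation $m^2 - \phi_1 m - \phi_2 = 0$,
$$m_{1,2} = \frac{\phi_1 \pm \sqrt{\phi_1^2 + 4\phi_2}}{2},$$
have modulus below one — equivalently, when the coefficient point
$(\phi_1, \phi_2)$ lies strictly inside the triangle with vertices
$(-2,-1)$, $(2,-1)$, $(0,1)$. The package's headline statistic is the
Euclidean distance of the fitted point from the triangle centroid
$(0, -1/3)$, the arithmetic mean of the vertices: a fit near the centroid
is far from every instability boundary, while a fit near an edge is one
small parameter shift away from a non-stationary (unstable) gait pattern.
The unit-root boundary itself is treated as non-stationary, with strict
inequalities and a $10^{-9}$ boundary tolerance.

### Assumptions

* The interleaved peak series is adequately described by a linear AR
  process with constant mean within a condition; order 2 is identified by
  the usual Box–Jenkins signature (slowly decaying ACF, PACF cut-off after
  lag 2) and can be checked per series with `select_order()`.
* Model adequacy is assessed on the residuals: a histogram centred on zero
  and a composite-normality Anderson–Darling test. An $R^2$ is deliberately
  not computed — with serially correlated model errors it has no clean
  interpretation, so residual diagnostics are used instead.
* The group comparison treats participants as independent observations per
  condition in a one-way ANOVA; repeated measures across conditions are
  not modelled. This is a deliberate simplification, flagged in the
  comparison report.

## The estimator and numerical choices

`gait_ar()` fits by **conditional least squares**: after demeaning, $y_t$
is regressed on its $p$ lags with no intercept, which is the canonical
conditional Box–Jenkins method and involves no optimizer choices (a
Yule–Walker option, solving the Toeplitz system of biased
autocorrelations, is available via `method = "yw"`). The innovation
variance is $\mathrm{RSS}/(n_\mathrm{eff} - p)$. ACF estimation uses the
biased (divide-by-$n$) convention, which guarantees a valid correlation
sequence for the Durbin–Levinson PACF recursion. On a singular design
(constant series) the fit errors out rather than regularizing.

The Anderson–Darling test uses the composite-normality case (mean and
variance estimated), with the small-sample adjustment
$A^{2*} = A^2\,(1 + 4/n - 25/n^2)$ compared against the critical value
0.752 at $\alpha = 0.05$. Under this rule the empirical type-I rate at
$n = 100$ is close to nominal (the acceptance suite measures it at about
5–6%).

Order recommendation (`select_order()`) follows the PACF threshold rule:
the largest lag whose partial autocorrelation exceeds $1.96/\sqrt{n}$,
with order 0 returned for white noise. Because roughly 5% of
high-order PACF values exceed the bound by chance, the rule is reported
together with the full correlogram and the bound, so the recommendation is
auditable rather than oracular.

Tukey post-hoc comparisons use the studentized range distribution through
R's `ptukey()`/`qtukey()` (numerical integration of the distribution
function; `qtukey(0.95, 3, 15)` reproduces the published table value 3.673
to three decimals), with the Tukey–Kramer standard error for unequal group
sizes. Compact letter displays use the insertion algorithm: groups sharing
a letter are not significantly different.

## The signal chain

1. **Filtering** — fourth-order Butterworth low-pass at 35 Hz, applied
   forward and backward (zero phase, the biomechanics convention; peak
   *times* are preserved and the effective attenuation is the squared
   single-pass response). Because textbook forward–backward filtering with
   zero initial conditions produces large edge transients, the signal is
   extended by odd reflection with a pad length derived from the filter's
   slowest pole; a constant input is then reproduced to below $10^{-9}$ N.
2. **Stance detection** — heel strike at the upward crossing of 50 N, toe
   off at the following downward crossing, applied to the filtered
   newton-scale signal. Above-threshold runs separated by less than 0.1 s
   are merged and runs shorter than 0.2 s discarded (debouncing against
   noise-induced double crossings near the threshold at walking speeds);
   incomplete boundary stances are dropped. Detection is invariant to
   whether the threshold is expressed in newtons pre-normalization or the
   equivalent body-weight value afterwards.
3. **Normalization** — division by body weight, giving dimensionless BW
   units comparable across participants.
4. **Peak extraction** — the impact peak is the highest local maximum in
   the first half of each stance and the propulsive peak the highest local
   maximum in the second half. The halves are the simplest unambiguous
   split and are exactly verifiable on the synthetic stance template;
   stances lacking an interior local maximum in either half are dropped
   and counted in a QC report rather than raising an error.
5. **Series assembly** — the first 10 steps of each condition are
   discarded (the lead-in applied in software, so synthetic and real
   recordings are treated identically) and the remaining peaks are
   interleaved two-per-step. Both peaks enter one series; impact-only or
   propulsive-only series are available via a flag.

## What the synthetic generator emulates — and what it does not

`simulate_protocol()` builds split-belt walking recordings from
raised-cosine stance templates: a continuously differentiable double hump
that is zero at both stance boundaries, attains the impact and propulsive
peak values exactly at prescribed stance fractions (default 0.25 and
0.75), and has exactly one valley between them. The smooth,
parameter-anchored form was chosen because every property of the template
(peak positions, peak values, single valley) is brute-force verifiable on
a dense grid. Peak-timing fractions are snapped to the sampling grid
within each stance so the sampled waveform attains the template peak
exactly at a sample — without this, 1200 Hz sampling would miss the
analytic maximum by more than the $10^{-6}$ BW tolerance the ground-truth
fidelity checks use.

Defaults and why:

* **Sampling rate** 1200 Hz; **filter cutoff** 35 Hz (validated to be
  below Nyquist at construction).
* **Cadence** 1.6/1.8/2.0 steps/s per limb at 0.75/1.0/1.5 m/s, linear
  in speed between anchors — a monotone map with plausible ordering; the
  generator treats it as the limb's step rate, so one minute at 1.0 m/s
  yields about 108 stances per limb.
* **Duty factor** 0.62: stance occupies 62% of the limb's step cycle.
* **Nominal peak magnitudes** 1.00/1.08/1.20 BW at 0.75/1.0/1.5 m/s,
  strictly increasing in speed. The impact and propulsive nominal values
  are set *equal*: step-to-step fluctuation is applied as one
  multiplicative AR(2) draw per peak event (two per step), so with equal
  nominals the extracted interleaved series is exactly a scaled AR(2)
  process and parameter recovery is a meaningful end-to-end test. Unequal
  nominals would superimpose a deterministic period-2 component that
  biases the fitted coefficients.
* **Fluctuation innovation sd** 0.02 (relative), giving ~2–4% step-to-step
  peak variability — typical of steady treadmill walking.
* **Sensor noise** 2 N additive Gaussian (robustness checks use 5 N),
  clipped so vertical force is never negative; swing phases are exactly
  0 N before noise.
* **Condition-level AR truth**: coefficient centres along the ray from
  the centroid towards the vertex $(2,-1)$ at distances
  0.6/0.7/0.7/0.6/0.9 for the three symmetric and two asymmetric
  conditions, so the 0.50 m/s between-limb condition sits nearest the
  triangle edge. Participant-level truth adds bivariate normal jitter
  (sd 0.2 per axis), rejection-resampled to stay inside the triangle with
  root modulus at most 0.95 (keeping the fluctuation variance bounded).
* **Seeding**: one master seed; every limb, condition, participant and
  noise source draws from a deterministically derived sub-stream, so any
  part of a study can be re-simulated bit-identically.

The generator does **not** emulate: anterior–posterior or medio-lateral
force components, kinematics, belt-speed ramping (speed changes are
instantaneous between segments), crossover steps on a shared belt, signal
artifacts or drop-outs, or the within-participant correlation of real
repeated-measures data. Passing tests on synthetic data therefore
demonstrate that the *chain* — detection, extraction, fitting, mapping,
comparison — is correct and well-calibrated under known dynamics; they do
not show that real walking follows an AR(2) law, which is exactly what the
residual diagnostics are for on real recordings.

## Study-level analysis and problem sizes

`simulate_study()` generates full-waveform recordings for a study
(default 17 participants, five one-minute conditions, both limbs) and
`analyze_study()` runs the complete chain, yielding per-cell coefficients,
centroid distances and mean peak magnitudes; `compare_conditions()` then
mirrors the usual summary-table layout (per-condition mean (sd), ANOVA p,
Tukey letters) for two comparison families: the three symmetric speeds,
and symmetric 1.0 m/s versus the two asymmetric conditions.

Power and calibration studies use `simulate_study_metrics()`, which skips
waveform synthesis and generates the interleaved peak series directly
(n = 110 peaks per cell, about one minute of walking) before fitting. The
signal chain's own fidelity is covered separately at waveform level, so
repeating it hundreds of times inside a power loop would add runtime
without information. The test suite uses 200 replicates for power and
parameter-recovery properties and 1000 replicates for type-I calibration
of the Anderson–Darling and ANOVA procedures; the deterministic property
checks (triangle membership against the root-modulus oracle, root
residuals) run on 10,201-point grids and 10,000 random coefficient pairs.

## Degenerate inputs and tie-breaks

* Constant series: ACF, AR fit and the Anderson–Darling test all error
  explicitly (zero variance) rather than returning NaN.
* `select_order()` returns 0 when no PACF exceeds the bound.
* Stances without an interior local maximum in a half (e.g. a monotone
  ramp) are dropped and counted, never fatal.
* An empty stance search (no 50 N crossing) warns and returns an empty
  table.
* Coefficient points within $10^{-9}$ of a triangle edge are flagged as
  boundary cases and classified non-stationary.
* `build_peak_series()` requires at least two steps to survive the
  lead-in discard; fitting itself requires at least `order + 10` values.

## Known limitations

* The one-way ANOVA ignores the repeated-measures structure (each
  participant contributes to every condition); a mixed model would be
  more efficient but is out of scope, and the report carries a note to
  that effect.
* The AR model assumes a fixed mean within a condition; slow drifts
  (fatigue, adaptation) would be absorbed into the coefficients. The
  de-adaptation wash-out segments supported by the protocol are simulated
  but excluded from analysis for this reason.
* Whether real studies fit the interleaved two-peak series or separate
  impact/propulsive series is a genuine design fork; the interleaved
  series is the default here, and `build_peak_series(interleave = FALSE)`
  provides the alternative.
* Centroid distance compresses two coefficients into one number; two fits
  at the same distance can have different dynamics (monotone vs
  oscillatory decay). The triangle plot and the roots themselves
  disambiguate.
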