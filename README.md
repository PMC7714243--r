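# gaitar

Autoregressive modelling of gait dynamics from vertical ground reaction
forces.

## The problem

Gait asymmetry — walking with the two legs behaving differently — appears in
many populations with impaired neuromuscular control. The standard way to
quantify limb loading is the mean magnitude of the vertical ground reaction
force (vGRF) peaks, but mean peak magnitudes are often insensitive to changes
in the *dynamics* of the gait pattern: two walking conditions can load the
limb identically on average while differing markedly in how each step's
loading depends on the preceding steps.

`gaitar` implements a time-series alternative for researchers and
rehabilitation scientists working with instrumented (split-belt) treadmills.
From each limb's vGRF signal it extracts the weight-acceptance (impact) and
propulsive peak of every step, builds the interleaved peak series
\(y_t\), and fits a second-order autoregressive model

```
y_t = δ + φ₁ y_(t−1) + φ₂ y_(t−2) + ε_t
```

by conditional least squares after Box–Jenkins identification (ACF/PACF).
The AR(2) process is stationary exactly when \((φ₁, φ₂)\) lies inside the
triangle with vertices (−2, −1), (2, −1), (0, 1); equivalently, when both
roots of the characteristic equation \(m² − φ₁ m − φ₂ = 0\) have modulus
below one. Gait-pattern stability is summarized as the Euclidean distance of
the fitted coefficient point from the triangle centroid (0, −1/3): points
near the triangle edge correspond to less stable gait patterns. Distances
are compared across walking conditions with one-way ANOVA and Tukey post-hoc
tests.

A seeded synthetic split-belt generator produces vGRF recordings with known
AR(2) ground truth (double-hump stance waveforms, speed-dependent cadence
and peak magnitudes, step-to-step fluctuations, sensor noise), so the whole
chain is testable without any human data.

## Worked example

```r
library(gaitar)

# one limb, one minute of simulated walking at 1.0 m/s
params <- sim_params(seed = 7)
trial  <- simulate_walking_trial(default_protocol()[2, ], params, "left",
                                 seed = 7, ar_coeffs = c(0.6641, -0.5547))

# filter -> detect stances (50 N) -> normalize -> peaks -> interleaved series
series <- extract_peak_series(trial)[["left.sym_1.0"]]
series
#> vGRF peak series: n = 196 ( left limb, condition sym_1.0 )
#> mean 1.082 BW, sd 0.03102 BW

fit <- gait_ar(series)
fit
#> AR(2) gait model (cls fit, n = 196)
#>    phi1    phi2
#>  0.7167 -0.5823
#> innovation variance: 0.0004793  series mean: 1.082
#> stationary ; distance from triangle centroid (0, -1/3): 0.7588
```

The fitted coefficients (0.72, −0.58) sit close to the generator's ground
truth (0.6641, −0.5547); the centroid distance 0.76 (truth: 0.70) is the
stability statistic. `summary(fit)` adds coefficient standard errors,
characteristic roots and the Anderson–Darling residual normality check;
`plot(fit)` draws the series with its one-step reconstruction and the
coefficient point on the stationarity triangle.

A full simulated study, end to end:

```r
run <- run_pipeline(run_config(n_participants = 17, seed = 1,
                               out_dir = "gaitar_out"))
run$comparison   # per-condition mean (sd) with Tukey letters and ANOVA p
```

With the default generator the AR-distance comparison separates the
0.50 m/s-asymmetric condition from symmetric walking (ANOVA p < 0.001)
while the mean peak vGRF comparison on the same limb stays null — the mean
cannot see what the dynamics reveal, because the constant-speed limb is
loaded identically on average in all three conditions.

A thin command-line wrapper with `run`, `simulate`, `extract-peaks`,
`fit-ar`, `triangle` and `compare` subcommands is installed at
`inst/cli/gaitar.R`.

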