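test_that("stance template is anchored at its boundaries and peaks", {
  expect_equal(stance_waveform(0, 1.1, 1.15, 0.75), 0)
  expect_equal(stance_waveform(1, 1.1, 1.15, 0.75), 0)
  expect_equal(stance_waveform(0.25, 1.1, 1.15, 0.75), 1.1)
  expect_equal(stance_waveform(0.75, 1.1, 1.15, 0.75), 1.15)
  expect_equal(stance_waveform(0.5, 1.1, 1.15, 0.75), 0.75)
})

test_that("dense scan finds exactly two maxima at the template peak times", {
  tt <- seq(0, 1, length.out = 1000)
  y <- stance_waveform(tt, 1.1, 1.15, 0.75, timing = c(0.25, 0.5, 0.75))
  mx <- oracle_local_maxima(y)
  expect_length(mx, 2)
  expect_equal(tt[mx], c(0.25, 0.75), tolerance = 1.01 / 999)
  mn <- oracle_local_minima(y)
  mn <- mn[mn > mx[1] & mn < mx[2]]
  expect_length(mn, 1)
  expect_equal(tt[mn], 0.5, tolerance = 1.01 / 999)
})

test_that("mis-ordered timing fractions and bad magnitudes are rejected", {
  expect_error(stance_waveform(0.5, 1.1, 1.15, 0.75, timing = c(0.5, 0.25, 0.75)),
               "timing")
  expect_error(stance_waveform(0.5, 0.7, 1.15, 0.75), "valley")
})

test_that("a 60 s trial at 1.0 m/s contains ~108 stance phases", {
  p <- sim_params(sensor_noise_sd = 0, fluctuation_sd = 0)
  tr <- simulate_walking_trial(default_protocol()[2, ], p, "left", seed = 5)
  expect_true(abs(max(tr$truth$step_index) - 108) <= 1)
})

test_that("noise-free stance maxima equal the nominal peak model exactly", {
  p <- sim_params(sensor_noise_sd = 0, fluctuation_sd = 0)
  tr <- simulate_walking_trial(default_protocol()[2, ], p, "right", seed = 5)
  nominal <- max(p$peak_model(1.0)) * p$body_weight
  st <- tr$truth_stances
  fs <- tr$sampling_rate
  mx <- vapply(seq_len(nrow(st)), function(k) {
    idx <- (floor(st$start_time[k] * fs) + 1):(ceiling(st$end_time[k] * fs))
    max(tr$force$right[idx])
  }, numeric(1))
  expect_equal(mx, rep(nominal, length(mx)), tolerance = 1e-12)
})

test_that("trial simulation is bit-identical under the same seed", {
  p <- sim_params()
  a <- simulate_walking_trial(default_protocol()[1, ], p, "left", seed = 9)
  b <- simulate_walking_trial(default_protocol()[1, ], p, "left", seed = 9)
  expect_identical(a$force, b$force)
  expect_identical(a$truth, b$truth)
})

test_that("trial duration must allow at least five strides", {
  p <- sim_params()
  short <- gait_protocol("x", 1.0, 1.0, duration = 2)
  expect_error(simulate_walking_trial(short[1, ], p, "left", seed = 1),
               "5 strides")
})

test_that("protocol simulation: cadence symmetry and asymmetry", {
  p <- sim_params(sensor_noise_sd = 0)
  proto <- gait_protocol(c("sym", "asym"), c(1.0, 0.75), c(1.0, 1.0), c(20, 20))
  rec <- simulate_protocol(proto, p, seed = 3)
  stride <- function(cond, lb) {
    st <- rec$truth_stances
    mean(diff(st$start_time[st$condition == cond & st$limb == lb]))
  }
  # equal belt speeds -> equal cadence (stride interval), up to phase offset
  expect_equal(stride("sym", "left"), stride("sym", "right"), tolerance = 1e-9)
  # slower left belt -> longer left stride interval and fewer left steps
  expect_gt(stride("asym", "left"), stride("asym", "right"))
  counts <- table(rec$truth_stances$condition, rec$truth_stances$limb)
  expect_lt(counts["asym", "left"], counts["asym", "right"])
})

test_that("default protocol segments tile the time axis without overlap", {
  p <- sim_params()
  proto <- default_protocol(duration = 10)
  rec <- simulate_protocol(proto, p, seed = 2)
  seg <- rec$metadata$segments
  expect_identical(nrow(seg), 5L)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], max(rec$time) + 1 / rec$sampling_rate,
               tolerance = 1e-9)
  expect_false(any(duplicated(seg$label)))
})

test_that("generator parameters are validated at construction", {
  expect_error(sim_params(ar_coeffs = c(1.2, -0.1)), "triangle")
  expect_error(sim_params(sampling_rate = 60, filter_cutoff = 35), "Nyquist|cutoff")
  expect_error(sim_params(peak_model = function(v) c(impact = 0.8, propulsive = 0.8)),
               ">= 1.0 BW")
  expect_error(sim_params(peak_model = function(v) c(impact = 1.5 - 0.1 * v,
                                                     propulsive = 1.5 - 0.1 * v)),
               "increasing")
  expect_error(sim_params(duty_factor = 1.2))
})

test_that("simulated peak magnitudes are calibrated to walking-speed means", {
  p <- sim_params()
  for (cond in list(list(row = 1, target = 1.0), list(row = 3, target = 1.2))) {
    tr <- simulate_walking_trial(default_protocol()[cond$row, ], p, "left",
                                 seed = 21)
    expect_equal(mean(tr$truth$peak_value_bw), cond$target, tolerance = 0.05)
  }
})

test_that("fluctuation AR truth is stationary for accepted parameter sets", {
  ct <- default_condition_truth()
  expect_true(all(is_stationary(ct$phi1, ct$phi2)))
  expect_equal(centroid_distance(ct$phi1, ct$phi2), ct$distance,
               tolerance = 1e-12)
})
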