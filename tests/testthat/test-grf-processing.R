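test_that("zero-phase low-pass preserves a constant signal", {
  rec <- make_recording(rep(700, 3000))
  out <- lowpass_filter(rec)
  expect_lt(max(abs(out$force$left - 700)), 1e-9)
})

test_that("filter magnitude response passes 5 Hz and rejects 200 Hz", {
  g <- lowpass_gain(c(5, 200), fs = 1200, cutoff = 35, order = 4)
  expect_gt(g[1], 0.99)
  expect_lt(g[2], 0.05)
  # and the applied filter matches the analytic response mid-signal
  t <- (0:11999) / 1200
  rec <- make_recording(500 + 100 * sin(2 * pi * 5 * t))
  out <- lowpass_filter(rec)
  amp <- max(out$force$left[4000:8000]) - 500
  expect_equal(amp / 100, g[1], tolerance = 1e-3)
})

test_that("cutoff at or above Nyquist is rejected", {
  rec <- make_recording(rep(700, 100))
  expect_error(lowpass_filter(rec, cutoff = 600), "Nyquist")
})

test_that("body-weight normalization divides by body weight", {
  rec <- make_recording(c(700, 840, 0), body_weight = 700)
  out <- normalize_bw(rec)
  expect_equal(out$force$left, c(1.0, 1.2, 0))
  expect_identical(out$units, "BW")
  # quiet standing: mean normalized force is 1 BW
  rec2 <- make_recording(rep(650, 5000), body_weight = 650)
  expect_equal(mean(normalize_bw(rec2)$force$left), 1.0, tolerance = 1e-6)
  rec$body_weight <- NULL
  expect_error(normalize_bw(rec), "body_weight")
})

test_that("a square pulse yields one stance at its edges", {
  f <- c(rep(0, 600), rep(400, 720), rep(0, 600))
  rec <- make_recording(f)
  st <- detect_stances(rec, threshold = 50)
  expect_identical(nrow(st), 1L)
  expect_identical(st$heel_strike_index, 601L)
  expect_identical(st$toe_off_index, 600L + 720L)
})

test_that("an all-zero recording yields an empty stance table with a warning", {
  rec <- make_recording(rep(0, 2400))
  expect_warning(st <- detect_stances(rec), "no threshold crossings")
  expect_identical(nrow(st), 0L)
})

test_that("noiseless synthetic trial: stance count matches ground truth", {
  p <- sim_params(sensor_noise_sd = 0)
  tr <- simulate_walking_trial(default_protocol()[2, ], p, "left", seed = 13)
  st <- detect_stances(tr)
  expect_identical(nrow(st), max(tr$truth$step_index))
})

test_that("threshold is consistent across newton and BW scales", {
  p <- sim_params()
  tr <- simulate_walking_trial(default_protocol()[1, ], p, "left", seed = 17)
  st_n <- detect_stances(tr, threshold = 50)
  st_bw <- detect_stances(normalize_bw(tr), threshold = 50 / tr$body_weight)
  expect_identical(st_n$heel_strike_index, st_bw$heel_strike_index)
  expect_identical(st_n$toe_off_index, st_bw$toe_off_index)
})

test_that("zero-noise extracted peaks equal generator ground truth", {
  p <- sim_params(sensor_noise_sd = 0)
  tr <- simulate_walking_trial(default_protocol()[2, ], p, "right", seed = 19)
  st <- detect_stances(tr)
  pk <- extract_peaks(normalize_bw(tr), st)
  expect_identical(nrow(pk), max(tr$truth$step_index))
  expect_identical(unname(attr(pk, "qc")["dropped"]), 0L)
  truth_imp <- tr$truth$peak_value_bw[tr$truth$peak_type == "impact"]
  truth_prp <- tr$truth$peak_value_bw[tr$truth$peak_type == "propulsive"]
  expect_lt(max(abs(pk$impact_value - truth_imp)), 1e-6)
  expect_lt(max(abs(pk$propulsive_value - truth_prp)), 1e-6)
})

test_that("stances without an interior local maximum are dropped, not fatal", {
  f <- c(rep(0, 600), seq(0, 400, length.out = 720), rep(0, 600))  # ramp
  rec <- make_recording(f, body_weight = 700)
  st <- detect_stances(rec)
  pk <- extract_peaks(normalize_bw(rec), st)
  expect_identical(nrow(pk), 0L)
  expect_identical(unname(attr(pk, "qc")["dropped"]), 1L)
})

test_that("peak series interleaves after discarding the lead-in strides", {
  mk_pairs <- function(n) data.frame(
    limb = "left", step_index = seq_len(n),
    impact_value = 1.1, impact_index = seq_len(n) * 100L,
    impact_time = seq_len(n) * 0.5,
    propulsive_value = 1.15, propulsive_index = seq_len(n) * 100L + 40L,
    propulsive_time = seq_len(n) * 0.5 + 0.2)
  s <- build_peak_series(mk_pairs(60), "c", skip_strides = 10)
  expect_identical(s$n, 100L)
  expect_identical(s$type, rep(c("impact", "propulsive"), 50))
  expect_true(all(diff(s$time) > 0))
  expect_identical(build_peak_series(mk_pairs(12), "c")$n, 4L)
  expect_error(build_peak_series(mk_pairs(5), "c"), "at least skip_strides \\+ 2 = 12")
})

test_that("with 5 N sensor noise the chain stays accurate", {
  p <- sim_params(sensor_noise_sd = 5)
  tr <- simulate_walking_trial(default_protocol()[2, ], p, "left", seed = 23)
  filt <- lowpass_filter(tr)
  st <- detect_stances(filt)
  expect_identical(nrow(st), max(tr$truth$step_index))
  pk <- extract_peaks(normalize_bw(filt), st)
  err <- c(abs(pk$impact_value -
                 tr$truth$peak_value_bw[tr$truth$peak_type == "impact"][pk$step_index]),
           abs(pk$propulsive_value -
                 tr$truth$peak_value_bw[tr$truth$peak_type == "propulsive"][pk$step_index]))
  expect_gte(mean(err < 0.02), 0.99)
})

test_that("extract_peak_series runs the whole chain per limb and segment", {
  p <- sim_params()
  proto <- default_protocol(duration = 15)
  rec <- simulate_protocol(proto, p, seed = 31)
  series <- extract_peak_series(rec, skip_strides = 2)
  expect_identical(length(series), 10L)  # 2 limbs x 5 conditions
  s <- series[["left.sym_1.0"]]
  expect_s3_class(s, "peak_series")
  expect_true(all(diff(s$time) > 0))
  expect_identical(s$type[1], "impact")
  expect_error(extract_peak_series(normalize_bw(rec)), "newton")
})
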