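#' Default cadence and peak-magnitude models
#'
#' Plausible walking-speed maps used by the synthetic generator, piecewise
#' linear through anchor speeds with linear extrapolation outside them:
#'
#' * `default_cadence_model()`: per-limb step rate of 1.6, 1.8 and 2.0
#'   steps/s at 0.75, 1.0 and 1.5 m/s (monotone increasing).
#' * `default_peak_model()`: mean stance peak magnitude of 1.00, 1.08 and
#'   1.20 body weights (BW) at the same speeds, returned as
#'   `c(impact = m, propulsive = m)` — the weight-acceptance and push-off
#'   peaks share the same nominal magnitude so the interleaved per-event
#'   fluctuation series is a pure scaled AR(2) process.
#'
#' @return a function of speed (m/s).
#' @export
default_cadence_model <- function() {
  anchors_v <- c(0.75, 1.0, 1.5)
  anchors_c <- c(1.6, 1.8, 2.0)
  function(speed) piecewise_linear(speed, anchors_v, anchors_c)
}

#' @rdname default_cadence_model
#' @export
default_peak_model <- function() {
  anchors_v <- c(0.75, 1.0, 1.5)
  anchors_m <- c(1.00, 1.08, 1.20)
  function(speed) {
    m <- piecewise_linear(speed, anchors_v, anchors_m)
    c(impact = m, propulsive = m)
  }
}

# linear interpolation with linear (not constant) extrapolation, so the
# maps stay strictly monotone outside the anchor range
piecewise_linear <- function(x, xs, ys) {
  if (x <= xs[1]) return(ys[1] + (x - xs[1]) * (ys[2] - ys[1]) / (xs[2] - xs[1]))
  k <- length(xs)
  if (x >= xs[k]) return(ys[k] + (x - xs[k]) * (ys[k] - ys[k - 1]) / (xs[k] - xs[k - 1]))
  approx(xs, ys, xout = x)$y
}

#' Parameters of the synthetic gait generator
#'
#' Collects and validates everything the generator needs: sampling rate,
#' body weight, the cadence and peak-magnitude speed models, the stance
#' fraction (duty factor), the AR(2) coefficients and innovation sd of the
#' step-to-step peak fluctuation process, and the additive sensor noise sd.
#' The AR coefficients must lie strictly inside the stationarity triangle
#' and the sampling rate must exceed twice the downstream filter cutoff.
#'
#' @param sampling_rate Hz (default 1200).
#' @param body_weight newtons (default 702, ~71.6 kg).
#' @param cadence_model function speed -> per-limb step rate (steps/s),
#'   monotone increasing.
#' @param duty_factor stance fraction of the limb's step cycle, in (0, 1).
#' @param peak_model function speed -> c(impact, propulsive) nominal peak
#'   magnitudes in BW; must be >= 1 BW and strictly increasing at the
#'   protocol speeds 0.75/1.0/1.5 m/s.
#' @param ar_coeffs c(phi1, phi2) of the per-event multiplicative peak
#'   fluctuation AR(2) process.
#' @param fluctuation_sd innovation sd of that process (relative, i.e. BW
#'   per BW of nominal peak; default 0.02).
#' @param sensor_noise_sd additive Gaussian sensor noise, newtons
#'   (default 2).
#' @param filter_cutoff downstream low-pass cutoff used for the Nyquist
#'   check (Hz, default 35).
#' @param timing stance-template timing fractions
#'   `c(t_peak1, t_valley, t_peak2)`.
#' @param seed default master seed used when none is supplied to the
#'   simulators.
#' @return a validated list of class `"sim_params"`.
#' @export
sim_params <- function(sampling_rate = 1200, body_weight = 702,
                       cadence_model = default_cadence_model(),
                       duty_factor = 0.62,
                       peak_model = default_peak_model(),
                       ar_coeffs = c(0.6641, -0.5547),
                       fluctuation_sd = 0.02,
                       sensor_noise_sd = 2,
                       filter_cutoff = 35,
                       timing = c(0.25, 0.5, 0.75),
                       seed = 1L) {
  stopifnot(sampling_rate > 0, body_weight > 0,
            duty_factor > 0, duty_factor < 1,
            fluctuation_sd >= 0, sensor_noise_sd >= 0,
            is.function(cadence_model), is.function(peak_model),
            length(ar_coeffs) == 2)
  if (sampling_rate <= 2 * filter_cutoff)
    stop("sampling_rate must exceed twice the filter cutoff (",
         2 * filter_cutoff, " Hz)")
  if (!isTRUE(as.logical(is_stationary(ar_coeffs[1], ar_coeffs[2]))))
    stop("ar_coeffs must lie strictly inside the stationarity triangle")
  speeds <- c(0.75, 1.0, 1.5)
  pk <- vapply(speeds, function(v) base::mean(peak_model(v)), numeric(1))
  if (any(pk < 1.0)) stop("peak_model must be >= 1.0 BW at protocol speeds")
  if (any(diff(pk) <= 0)) stop("peak_model must be strictly increasing in speed")
  cad <- vapply(speeds, cadence_model, numeric(1))
  if (any(diff(cad) <= 0)) stop("cadence_model must be strictly increasing in speed")
  if (!(timing[1] < timing[2] && timing[2] < timing[3] &&
        timing[1] > 0 && timing[3] < 1))
    stop("timing fractions must satisfy 0 < t_peak1 < t_valley < t_peak2 < 1")
  structure(list(sampling_rate = sampling_rate, body_weight = body_weight,
                 cadence_model = cadence_model, duty_factor = duty_factor,
                 peak_model = peak_model, ar_coeffs = ar_coeffs,
                 fluctuation_sd = fluctuation_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 filter_cutoff = filter_cutoff, timing = timing,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Define a split-belt walking protocol
#'
#' An ordered set of treadmill conditions, each with its own left/right
#' belt speed, duration and unique label.  `analysis` marks conditions that
#' enter the statistical comparison (de-adaptation wash-out segments are
#' simulated but excluded by default).
#'
#' @param label character vector of unique condition labels.
#' @param left_speed,right_speed belt speeds, m/s (> 0).
#' @param duration condition durations, seconds (> 0).
#' @param analysis logical; include in downstream analysis (default TRUE).
#' @return a data.frame of class `"gait_protocol"`.
#' @export
gait_protocol <- function(label, left_speed, right_speed, duration,
                          analysis = TRUE) {
  p <- data.frame(label = as.character(label),
                  left_speed = left_speed, right_speed = right_speed,
                  duration = duration,
                  analysis = rep_len(analysis, length(label)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$label)) stop("condition labels must be unique")
  if (any(p$left_speed <= 0) || any(p$right_speed <= 0))
    stop("belt speeds must be positive")
  if (any(p$duration <= 0)) stop("durations must be positive")
  class(p) <- c("gait_protocol", "data.frame")
  p
}

#' The default study protocol
#'
#' Three symmetric conditions (both belts at 0.75, 1.0, 1.5 m/s) and two
#' asymmetric conditions with between-limb speed differences of 0.25 m/s
#' (left 0.75, right 1.0) and 0.50 m/s (left 1.5, right 1.0), one minute
#' each.  With `deadapt = TRUE`, a one-minute symmetric 0.75 m/s wash-out
#' segment follows each asymmetric condition (simulated, excluded from
#' analysis).
#'
#' @param duration seconds per condition (default 60).
#' @param deadapt include de-adaptation segments.
#' @return a [gait_protocol()].
#' @export
default_protocol <- function(duration = 60, deadapt = FALSE) {
  lab <- c("sym_0.75", "sym_1.0", "sym_1.5", "asym_0.25", "asym_0.50")
  ls <- c(0.75, 1.0, 1.5, 0.75, 1.5)
  rs <- c(0.75, 1.0, 1.5, 1.0, 1.0)
  an <- rep(TRUE, 5)
  if (deadapt) {
    lab <- c(lab[1:4], "deadapt_1", lab[5], "deadapt_2")
    ls <- c(ls[1:4], 0.75, ls[5], 0.75)
    rs <- c(rs[1:4], 0.75, rs[5], 0.75)
    an <- c(an[1:4], FALSE, an[5], FALSE)
  }
  gait_protocol(lab, ls, rs, rep(duration, length(lab)), an)
}

#' Condition-level AR(2) ground-truth centres
#'
#' The generator's default per-condition fluctuation dynamics, placed along
#' the ray from the triangle centroid (0, -1/3) towards the vertex (2, -1)
#' at centroid distances 0.6, 0.7, 0.7, 0.6 and 0.9 for the three symmetric
#' and two asymmetric conditions — so the large-asymmetry condition sits
#' nearest the triangle edge (the least stable gait pattern) while peak
#' magnitudes are governed independently by the speed model.
#'
#' @return data.frame with `label`, `phi1`, `phi2`, `distance`.
#' @export
default_condition_truth <- function() {
  d <- c(sym_0.75 = 0.6, sym_1.0 = 0.7, sym_1.5 = 0.7,
         asym_0.25 = 0.6, asym_0.50 = 0.9)
  u <- c(2, -2 / 3) / sqrt(4 + 4 / 9)
  ctr <- triangle_centroid()
  data.frame(label = names(d),
             phi1 = unname(ctr[1] + d * u[1]),
             phi2 = unname(ctr[2] + d * u[2]),
             distance = unname(d),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Draw a participant-level truth point around a condition centre:
# bivariate normal jitter (sd per axis), rejection-resampled until strictly
# inside the triangle with max characteristic-root modulus <= 0.95 (keeps
# the fluctuation process variance bounded).
jitter_truth <- function(phi1, phi2, sd = 0.2, seed = NULL, max_modulus = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  for (i in 1:1000) {
    p1 <- phi1 + rnorm(1, 0, sd)
    p2 <- phi2 + rnorm(1, 0, sd)
    ok <- isTRUE(as.logical(is_stationary(p1, p2))) &&
      max(characteristic_roots(p1, p2)$moduli) <= max_modulus
    if (ok) return(c(phi1 = p1, phi2 = p2))
  }
  stop("could not draw a stationary truth point near (", phi1, ", ", phi2, ")")
}

#' Smooth double-hump stance-phase vGRF template
#'
#' Evaluates a continuously differentiable vertical-GRF stance template on
#' normalized stance time `t_norm` in [0, 1]: zero at both stance
#' boundaries, exactly `impact_peak` at `timing[1]`, exactly
#' `propulsive_peak` at `timing[3]`, and exactly one local minimum
#' (`valley`) at `timing[2]`.  Built from raised-cosine segments whose
#' derivatives vanish at every knot, so the two peaks and the valley are
#' the only interior critical points.
#'
#' @param t_norm numeric vector in [0, 1], fraction of stance.
#' @param impact_peak,propulsive_peak peak magnitudes (BW); must exceed
#'   `valley`.
#' @param valley mid-stance minimum (BW), > 0.
#' @param timing `c(t_peak1, t_valley, t_peak2)` with
#'   0 < t_peak1 < t_valley < t_peak2 < 1.
#' @return force in BW, same length as `t_norm`.
#' @examples
#' stance_waveform(c(0, 0.25, 0.5, 0.75, 1), 1.1, 1.15, 0.75)
#' @export
stance_waveform <- function(t_norm, impact_peak, propulsive_peak, valley,
                            timing = c(0.25, 0.5, 0.75)) {
  tp1 <- timing[1]; tv <- timing[2]; tp2 <- timing[3]
  if (!(0 < tp1 && tp1 < tv && tv < tp2 && tp2 < 1))
    stop("timing fractions must satisfy 0 < t_peak1 < t_valley < t_peak2 < 1")
  if (!(impact_peak > valley && propulsive_peak > valley && valley > 0))
    stop("need peaks > valley > 0")
  if (any(t_norm < 0 | t_norm > 1)) stop("t_norm must lie in [0, 1]")
  rc <- function(u) (1 - cos(pi * u)) / 2  # 0 -> 1, flat at both ends
  f <- numeric(length(t_norm))
  i1 <- t_norm <= tp1
  f[i1] <- impact_peak * rc(t_norm[i1] / tp1)
  i2 <- t_norm > tp1 & t_norm <= tv
  f[i2] <- impact_peak + (valley - impact_peak) * rc((t_norm[i2] - tp1) / (tv - tp1))
  i3 <- t_norm > tv & t_norm <= tp2
  f[i3] <- valley + (propulsive_peak - valley) * rc((t_norm[i3] - tv) / (tp2 - tv))
  i4 <- t_norm > tp2
  f[i4] <- propulsive_peak * (1 - rc((t_norm[i4] - tp2) / (1 - tp2)))
  f
}

#' Simulate one limb of one walking condition
#'
#' Concatenates stance templates at the cadence implied by the limb's belt
#' speed, with per-step impact and propulsive peak magnitudes modulated
#' multiplicatively by an interleaved AR(2) fluctuation process (one draw
#' per peak event, two per step) around the nominal `peak_model(speed)`
#' magnitudes.  Swing phases are exactly 0 N before noise; additive
#' Gaussian sensor noise is applied afterwards and the signal clipped at
#' 0 N.  Peak-timing fractions are snapped to the sampling grid within each
#' stance so the sampled waveform attains the template peak value exactly
#' at a sample; the true peak values and event times are returned as ground
#' truth.
#'
#' @param condition one row of a [gait_protocol()] (or a list with
#'   `label`, `left_speed`, `right_speed`, `duration`).
#' @param params a [sim_params()].
#' @param limb `"left"` or `"right"`.
#' @param seed integer seed (sub-streams for fluctuation and sensor noise
#'   are derived from it).
#' @param ar_coeffs optional `c(phi1, phi2)` overriding
#'   `params$ar_coeffs` (used for condition-dependent ground truth).
#' @param phase_offset start of the first stance, as a fraction of the step
#'   cycle (default 0.3 for left, 0.8 for right, staggering the limbs).
#' @return a `grf_recording` with a single limb channel, ground-truth peak
#'   table (`$truth`) and stance table (`$truth_stances`).
#' @export
simulate_walking_trial <- function(condition, params, limb = c("left", "right"),
                                   seed = params$seed, ar_coeffs = NULL,
                                   phase_offset = NULL) {
  limb <- match.arg(limb)
  if (inherits(condition, "data.frame")) condition <- as.list(condition[1, ])
  speed <- if (limb == "left") condition$left_speed else condition$right_speed
  duration <- condition$duration
  fs <- params$sampling_rate
  cad <- params$cadence_model(speed)
  if (duration * cad < 5)
    stop("condition duration too short: need at least 5 strides at ",
         signif(cad, 3), " steps/s")
  phi <- ar_coeffs %||% params$ar_coeffs
  if (is.null(phase_offset)) phase_offset <- if (limb == "left") 0.3 else 0.8

  cycle <- 1 / cad
  stance_dur <- params$duty_factor * cycle
  t0 <- phase_offset * cycle
  starts <- seq(t0, duration, by = cycle)
  starts <- starts[starts + stance_dur <= duration]
  n_steps <- length(starts)

  nominal <- params$peak_model(speed)
  f <- simulate_ar2_series(phi[1], phi[2], n = 2 * n_steps,
                           noise_sd = params$fluctuation_sd, mean = 0,
                           seed = derive_seed(seed, 1L))
  imp <- nominal[[1]] * (1 + f[seq(1, 2 * n_steps, by = 2)])
  prp <- nominal[[2]] * (1 + f[seq(2, 2 * n_steps, by = 2)])

  nsamp <- round(duration * fs)
  time <- (seq_len(nsamp) - 1) / fs
  force <- numeric(nsamp)
  tp <- params$timing
  truth <- vector("list", n_steps)
  stances <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    i0 <- floor(starts[k] * fs) + 2L      # first sample strictly inside
    i1 <- floor((starts[k] + stance_dur) * fs) + 1L
    i1 <- min(i1, nsamp)
    idx <- i0:i1
    tn <- (time[idx] - starts[k]) / stance_dur
    tn <- pmin(pmax(tn, 0), 1)
    # snap template timing to the sampled grid so peaks are attained exactly
    snap <- function(target) tn[which.min(abs(tn - target))]
    tps <- c(snap(tp[1]), snap(tp[2]), snap(tp[3]))
    if (!(0 < tps[1] && tps[1] < tps[2] && tps[2] < tps[3] && tps[3] < 1))
      tps <- tp  # degenerate grid (very short stance): keep analytic timing
    valley <- 0.75 * min(imp[k], prp[k])
    force[idx] <- params$body_weight *
      stance_waveform(tn, imp[k], prp[k], valley, tps)
    truth[[k]] <- data.frame(
      limb = limb, step_index = k,
      event_time = starts[k] + tps[c(1, 3)] * stance_dur,
      peak_type = c("impact", "propulsive"),
      peak_value_bw = c(imp[k], prp[k]), stringsAsFactors = FALSE)
    stances[[k]] <- data.frame(limb = limb, step_index = k,
                               start_time = starts[k],
                               end_time = starts[k] + stance_dur)
  }
  if (params$sensor_noise_sd > 0) {
    set.seed(derive_seed(seed, 2L))
    force <- force + rnorm(nsamp, 0, params$sensor_noise_sd)
  }
  force <- pmax(force, 0)

  rec <- list(time = time, force = setNames(list(force), limb),
              sampling_rate = fs, body_weight = params$body_weight,
              units = "N",
              metadata = list(
                segments = data.frame(label = condition$label %||% "trial",
                                      start = 0, end = duration,
                                      left_speed = condition$left_speed,
                                      right_speed = condition$right_speed,
                                      analysis = condition$analysis %||% TRUE,
                                      stringsAsFactors = FALSE),
                seed = seed),
              truth = do.call(rbind, truth),
              truth_stances = do.call(rbind, stances))
  class(rec) <- "grf_recording"
  rec
}

#' Simulate a full split-belt protocol for both limbs
#'
#' Runs [simulate_walking_trial()] for every condition and limb with
#' independent noise sub-streams derived from the master seed, and
#' concatenates the segments along one time axis.  Per-condition segment
#' boundaries are recorded in the metadata; ground-truth tables gain a
#' `condition` column.
#'
#' @param protocol a [gait_protocol()].
#' @param params a [sim_params()].
#' @param seed master integer seed.
#' @param ar_truth optional data.frame (`label`, `phi1`, `phi2`) of
#'   condition-specific fluctuation coefficients.
#' @return a two-limb `grf_recording`.
#' @export
simulate_protocol <- function(protocol, params, seed = params$seed,
                              ar_truth = NULL) {
  stopifnot(inherits(protocol, "gait_protocol"))
  fs <- params$sampling_rate
  nc <- nrow(protocol)
  seg_start <- cumsum(c(0, protocol$duration))[seq_len(nc)]
  pieces <- list(left = vector("list", nc), right = vector("list", nc))
  truth <- list(); stances <- list()
  for (i in seq_len(nc)) {
    cond <- as.list(protocol[i, ])
    phi <- NULL
    if (!is.null(ar_truth)) {
      j <- match(cond$label, ar_truth$label)
      if (!is.na(j)) phi <- c(ar_truth$phi1[j], ar_truth$phi2[j])
    }
    for (limb in c("left", "right")) {
      tr <- simulate_walking_trial(cond, params, limb,
                                   seed = derive_seed(seed, (i - 1L) * 2L +
                                                        (limb == "right") + 1L),
                                   ar_coeffs = phi)
      pieces[[limb]][[i]] <- tr$force[[limb]]
      tt <- tr$truth; tt$condition <- cond$label
      tt$event_time <- tt$event_time + seg_start[i]
      ts <- tr$truth_stances; ts$condition <- cond$label
      ts$start_time <- ts$start_time + seg_start[i]
      ts$end_time <- ts$end_time + seg_start[i]
      truth[[length(truth) + 1L]] <- tt
      stances[[length(stances) + 1L]] <- ts
    }
  }
  nsamp <- sum(vapply(pieces$left, length, integer(1)))
  rec <- list(
    time = (seq_len(nsamp) - 1) / fs,
    force = list(left = unlist(pieces$left, use.names = FALSE),
                 right = unlist(pieces$right, use.names = FALSE)),
    sampling_rate = fs, body_weight = params$body_weight, units = "N",
    metadata = list(
      segments = data.frame(label = protocol$label, start = seg_start,
                            end = seg_start + protocol$duration,
                            left_speed = protocol$left_speed,
                            right_speed = protocol$right_speed,
                            analysis = protocol$analysis,
                            stringsAsFactors = FALSE),
      seed = seed),
    truth = do.call(rbind, truth),
    truth_stances = do.call(rbind, stances))
  class(rec) <- "grf_recording"
  rec
}

#' @export
print.grf_recording <- function(x, ...) {
  cat("vGRF recording:", length(x$time), "samples at", x$sampling_rate,
      "Hz (", signif(max(x$time), 4), "s ),",
      paste(names(x$force), collapse = "+"), "limb(s), units", x$units, "\n")
  cat("body weight:", x$body_weight, "N;",
      nrow(x$metadata$segments), "segment(s)\n")
  invisible(x)
}

#' Simulate a multi-participant split-belt study (waveform level)
#'
#' Generates one full protocol recording per participant.  Body weights are
#' drawn around 702 N (sd 107 N); per participant and condition a
#' ground-truth fluctuation coefficient pair is drawn around the
#' condition-level centres (see [default_condition_truth()]) with
#' bivariate-normal jitter (`truth_sd` per axis), rejection-resampled to
#' stay strictly inside the stationarity triangle.
#'
#' @param n_participants number of participants (default 17).
#' @param protocol a [gait_protocol()] (default [default_protocol()]).
#' @param params a [sim_params()]; body weight is overridden per
#'   participant.
#' @param condition_truth data.frame (`label`, `phi1`, `phi2`) of condition
#'   centres.
#' @param truth_sd per-axis sd of the participant-level truth jitter
#'   (default 0.2).
#' @param seed master seed.
#' @return list of class `"gait_study"`: `recordings` (per participant),
#'   `truth` (participant x condition coefficients and distances),
#'   `protocol`, `seed`.
#' @export
simulate_study <- function(n_participants = 17, protocol = default_protocol(),
                           params = sim_params(),
                           condition_truth = default_condition_truth(),
                           truth_sd = 0.2, seed = params$seed) {
  recs <- vector("list", n_participants)
  truth <- list()
  for (p in seq_len(n_participants)) {
    set.seed(derive_seed(seed, 100000L + p))
    bw <- max(rnorm(1, 702, 107), 300)
    pp <- params; pp$body_weight <- bw
    tr <- condition_truth
    for (i in seq_len(nrow(tr))) {
      jt <- jitter_truth(tr$phi1[i], tr$phi2[i], sd = truth_sd,
                         seed = derive_seed(seed, 200000L + p * 100L + i))
      tr$phi1[i] <- jt[1]; tr$phi2[i] <- jt[2]
    }
    tr$distance <- centroid_distance(tr$phi1, tr$phi2)
    recs[[p]] <- simulate_protocol(protocol, pp,
                                   seed = derive_seed(seed, 300000L + p),
                                   ar_truth = tr)
    tr$participant <- p
    truth[[p]] <- tr
  }
  structure(list(recordings = recs, truth = do.call(rbind, truth),
                 protocol = protocol, seed = seed),
            class = "gait_study")
}

#' Simulate study metrics at the peak-series level
#'
#' A fast study generator that skips waveform synthesis and peak
#' extraction: for each participant x condition x limb cell it draws the
#' participant's ground-truth AR(2) coefficients, simulates the interleaved
#' peak series directly (`nominal_peak * (1 + AR(2) fluctuation)`), fits
#' [gait_ar()], and records the mean peak magnitude and centroid distance.
#' Used for power/calibration studies where the signal chain (covered by
#' its own fidelity checks) would only add runtime.
#'
#' @inheritParams simulate_study
#' @param conditions subset of condition labels (default: the asymmetric
#'   comparison family `sym_1.0`, `asym_0.25`, `asym_0.50`).
#' @param limb which limb's belt speed drives the nominal peak (default
#'   `"right"` — held at 1.0 m/s across the asymmetric family, so nominal
#'   peak means are equal by design).
#' @param n_peaks interleaved series length per cell (default 110, about
#'   one minute of walking).
#' @return data.frame with one row per participant x condition: labels,
#'   fitted `phi1`, `phi2`, `ar_distance`, `mean_peak_vgrf_bw`, and the
#'   ground truth `truth_phi1`, `truth_phi2`, `truth_distance`.
#' @export
simulate_study_metrics <- function(n_participants = 17,
                                   conditions = c("sym_1.0", "asym_0.25", "asym_0.50"),
                                   limb = "right",
                                   n_peaks = 110,
                                   params = sim_params(),
                                   condition_truth = default_condition_truth(),
                                   truth_sd = 0.2, seed = params$seed) {
  proto <- default_protocol()
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (ci in seq_along(conditions)) {
      lab <- conditions[ci]
      j <- match(lab, condition_truth$label)
      if (is.na(j)) stop("unknown condition label: ", lab)
      jt <- jitter_truth(condition_truth$phi1[j], condition_truth$phi2[j],
                         sd = truth_sd,
                         seed = derive_seed(seed, 200000L + p * 100L + ci))
      k <- match(lab, proto$label)
      speed <- if (limb == "left") proto$left_speed[k] else proto$right_speed[k]
      nominal <- base::mean(params$peak_model(speed))
      f <- simulate_ar2_series(jt[1], jt[2], n = n_peaks,
                               noise_sd = params$fluctuation_sd, mean = 0,
                               seed = derive_seed(seed, 400000L + p * 100L + ci))
      series <- nominal * (1 + f)
      fit <- gait_ar(series, order = 2)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, limb = limb, condition = lab,
        phi1 = unname(coef(fit)[1]), phi2 = unname(coef(fit)[2]),
        ar_distance = fit$distance,
        mean_peak_vgrf_bw = base::mean(series),
        truth_phi1 = unname(jt[1]), truth_phi2 = unname(jt[2]),
        truth_distance = centroid_distance(jt[1], jt[2]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
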