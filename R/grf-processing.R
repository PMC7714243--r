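#' Zero-phase Butterworth low-pass filter for vGRF channels
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass to every
#' force channel — the biomechanics convention, which preserves peak
#' timing; the effective magnitude response is the squared single-pass
#' response.  The filter is designed with [signal::butter()]; to suppress
#' start-up transients the signal is extended by odd (point) reflection
#' with a pad length derived from the filter's slowest pole, so a constant
#' input is reproduced to well below 1e-9 N.
#'
#' @param recording a `grf_recording`.
#' @param cutoff low-pass cutoff, Hz (default 35); must be below the
#'   Nyquist frequency.
#' @param order filter order for each pass (default 4).
#' @return the recording with filtered force channels and
#'   `metadata$filtered` set.
#' @export
lowpass_filter <- function(recording, cutoff = 35, order = 4) {
  fs <- recording$sampling_rate
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  recording$force <- lapply(recording$force, zero_phase_filter,
                            b = bf$b, a = bf$a)
  recording$metadata$filtered <- list(cutoff = cutoff, order = order)
  recording
}

# forward-backward filtering with odd-reflection padding; pad length chosen
# so the slowest pole's transient decays below ~1e-13 relative
zero_phase_filter <- function(x, b, a) {
  n <- length(x)
  rmax <- max(Mod(polyroot(rev(a))))
  pad <- if (rmax >= 1) n - 1L else ceiling(-50 / log(rmax))
  pad <- min(pad, n - 1L)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

#' Magnitude response of the zero-phase low-pass
#'
#' Analytic gain of the designed filter at given frequencies, for the
#' two-pass (zero-phase) application: the squared modulus of the designed
#' digital filter's frequency response.
#'
#' @param freq frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @inheritParams lowpass_filter
#' @return numeric vector of gains in (0, 1].
#' @export
lowpass_gain <- function(freq, fs = 1200, cutoff = 35, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  w <- 2 * pi * freq / fs
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }, numeric(1))
}

#' Normalize a recording to body weight
#'
#' Divides every force sample by the participant's body weight so
#' magnitudes are in dimensionless body-weight (BW) units, comparable
#' across participants.
#'
#' @param recording a `grf_recording` in newtons with a positive
#'   `body_weight`.
#' @return the recording with `units = "BW"`.
#' @export
normalize_bw <- function(recording) {
  bw <- recording$body_weight
  if (is.null(bw) || is.na(bw) || bw <= 0)
    stop("recording must carry a positive body_weight to normalize")
  if (identical(recording$units, "BW")) return(recording)
  recording$force <- lapply(recording$force, function(f) f / bw)
  recording$units <- "BW"
  recording
}

#' Detect stance phases by force threshold
#'
#' Heel strike is the upward crossing of the force threshold (50 N by
#' convention) and toe off the subsequent downward crossing.  Above-
#' threshold runs separated by less than `min_swing_s` are merged and runs
#' shorter than `min_stance_s` discarded (debouncing); incomplete stances
#' at the recording boundaries are dropped.  The threshold is interpreted
#' in the recording's own units: pass `threshold = 50` for a newton
#' recording or `threshold = 50 / body_weight` after normalization — the
#' two give identical stances.
#'
#' @param recording a `grf_recording`.
#' @param threshold force threshold in the recording's units (default
#'   50 N).
#' @param min_stance_s,min_swing_s debounce durations, seconds.
#' @param limb which channel; defaults to each available limb.
#' @return a data.frame of class `"stance_table"` with columns `limb`,
#'   `heel_strike_index`, `toe_off_index`, `heel_strike_time`,
#'   `toe_off_time` (empty, with a warning, if no crossings are found).
#' @export
detect_stances <- function(recording, threshold = 50, min_stance_s = 0.2,
                           min_swing_s = 0.1, limb = names(recording$force)) {
  fs <- recording$sampling_rate
  out <- lapply(limb, function(lb) {
    f <- recording$force[[lb]]
    above <- f >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (nrow(runs) == 0L) return(NULL)
    # merge runs separated by a short sub-swing gap (noise near threshold)
    min_gap <- round(min_swing_s * fs)
    if (nrow(runs) > 1L) {
      keep <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        if (runs$start[i] - keep$end[nrow(keep)] - 1L < min_gap) {
          keep$end[nrow(keep)] <- runs$end[i]
        } else keep <- rbind(keep, runs[i, ])
      }
      runs <- keep
    }
    runs <- runs[runs$end - runs$start + 1L >= round(min_stance_s * fs), ,
                 drop = FALSE]
    # incomplete stances at the boundaries: signal already above threshold
    # at the first sample, or still above at the last
    if (nrow(runs) && runs$start[1] == 1L) runs <- runs[-1, , drop = FALSE]
    if (nrow(runs) && runs$end[nrow(runs)] == length(f))
      runs <- runs[-nrow(runs), , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    data.frame(limb = lb, heel_strike_index = runs$start,
               toe_off_index = runs$end,
               heel_strike_time = recording$time[runs$start],
               toe_off_time = recording$time[runs$end],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    warning("no threshold crossings found; returning empty stance table")
    out <- data.frame(limb = character(), heel_strike_index = integer(),
                      toe_off_index = integer(), heel_strike_time = numeric(),
                      toe_off_time = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("stance_table", "data.frame")
  out
}

#' Extract impact and propulsive peaks from each stance
#'
#' For every stance phase, the impact (weight-acceptance) peak is the
#' highest local maximum in the first half of the stance and the propulsive
#' peak the highest local maximum in the second half.  Stances lacking an
#' interior local maximum in either half are dropped and counted in the QC
#' attribute rather than raising an error.
#'
#' @param recording a `grf_recording`, normally filtered and normalized to
#'   BW.
#' @param stances a [detect_stances()] table.
#' @return a data.frame of class `"peak_table"`: `limb`, `step_index`,
#'   `impact_value`, `impact_index`, `impact_time`, `propulsive_value`,
#'   `propulsive_index`, `propulsive_time`; attribute `"qc"` holds
#'   `c(detected =, extracted =, dropped =)`.
#' @export
extract_peaks <- function(recording, stances) {
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(stances))) {
    lb <- stances$limb[i]
    f <- recording$force[[lb]]
    hs <- stances$heel_strike_index[i]
    to <- stances$toe_off_index[i]
    mid <- hs + (to - hs) %/% 2L
    p1 <- highest_local_max(f, hs, mid)
    p2 <- highest_local_max(f, mid + 1L, to)
    if (is.null(p1) || is.null(p2)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      limb = lb, step_index = i,
      impact_value = p1$value, impact_index = p1$index,
      impact_time = recording$time[p1$index],
      propulsive_value = p2$value, propulsive_index = p2$index,
      propulsive_time = recording$time[p2$index],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(limb = character(), step_index = integer(),
               impact_value = numeric(), impact_index = integer(),
               impact_time = numeric(), propulsive_value = numeric(),
               propulsive_index = integer(), propulsive_time = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "qc") <- c(detected = nrow(stances), extracted = nrow(out),
                       dropped = dropped)
  class(out) <- c("peak_table", "data.frame")
  out
}

# highest interior local maximum of f on [i0, i1]; plateau-tolerant
# (f[i] > f[i-1] and f[i] >= f[i+1]); NULL if none
highest_local_max <- function(f, i0, i1) {
  if (i1 - i0 < 2L) return(NULL)
  idx <- (i0 + 1L):(i1 - 1L)
  lm <- idx[f[idx] > f[idx - 1L] & f[idx] >= f[idx + 1L]]
  if (!length(lm)) return(NULL)
  best <- lm[which.max(f[lm])]
  list(index = best, value = f[best])
}

#' Assemble the interleaved vGRF peak time series
#'
#' Discards the first `skip_strides` steps (the lead-in, applied in
#' software so synthetic and real recordings are treated identically) and
#' interleaves the remaining impact and propulsive peaks in chronological
#' order into one series per limb — two values per step, the series the AR
#' model is fit to.  Set `interleave = FALSE` to obtain an impact-only or
#' propulsive-only series via `peak_type`.
#'
#' @param pairs an [extract_peaks()] table (single limb).
#' @param condition condition label to attach.
#' @param limb limb label; defaults to the one in `pairs`.
#' @param skip_strides number of initial steps to discard (default 10).
#' @param interleave interleave both peaks (default) or keep one type.
#' @param peak_type `"impact"` or `"propulsive"` when
#'   `interleave = FALSE`.
#' @return an object of class `"peak_series"`: list with `value` (BW),
#'   `time` (s), `type` (alternating `"impact"`/`"propulsive"`), `limb`,
#'   `condition`, `n`.
#' @export
build_peak_series <- function(pairs, condition = NA_character_, limb = NULL,
                              skip_strides = 10, interleave = TRUE,
                              peak_type = c("impact", "propulsive")) {
  peak_type <- match.arg(peak_type)
  if (is.null(limb)) limb <- if (nrow(pairs)) pairs$limb[1] else NA_character_
  need <- skip_strides + 2L  # at least two steps (four peaks) must remain
  if (nrow(pairs) < need)
    stop("too few steps: need at least skip_strides + 2 = ", need,
         " peak pairs, got ", nrow(pairs))
  keep <- pairs[-seq_len(skip_strides), , drop = FALSE]
  if (interleave) {
    o <- order(c(keep$impact_time, keep$propulsive_time))
    value <- c(keep$impact_value, keep$propulsive_value)[o]
    time <- c(keep$impact_time, keep$propulsive_time)[o]
    type <- rep(c("impact", "propulsive"), each = nrow(keep))[o]
  } else if (peak_type == "impact") {
    value <- keep$impact_value; time <- keep$impact_time
    type <- rep("impact", nrow(keep))
  } else {
    value <- keep$propulsive_value; time <- keep$propulsive_time
    type <- rep("propulsive", nrow(keep))
  }
  if (is.unsorted(time, strictly = TRUE))
    stop("peak event times are not strictly increasing")
  structure(list(value = value, time = time, type = type, limb = limb,
                 condition = condition, n = length(value)),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat("vGRF peak series: n =", x$n, "(", x$limb, "limb, condition",
      x$condition, ")\n")
  cat("mean", signif(base::mean(x$value), 4), "BW, sd",
      signif(sd(x$value), 4), "BW\n")
  invisible(x)
}

#' Run the full peak-extraction chain on one recording
#'
#' Convenience wrapper: low-pass filter (optional), stance detection on the
#' newton-scale signal, body-weight normalization, peak extraction and
#' per-limb, per-analysis-segment interleaved series assembly.
#'
#' @param recording a `grf_recording` in newtons.
#' @param cutoff,order filter settings; `cutoff = NULL` skips filtering.
#' @param threshold stance threshold, newtons.
#' @param skip_strides lead-in steps discarded per segment.
#' @param min_stance_s,min_swing_s debounce settings.
#' @return a list of `peak_series`, one per limb x analysis segment, named
#'   `"<limb>.<label>"`; attribute `"qc"` aggregates extraction QC counts.
#' @export
extract_peak_series <- function(recording, cutoff = 35, order = 4,
                                threshold = 50, skip_strides = 10,
                                min_stance_s = 0.2, min_swing_s = 0.1) {
  if (!identical(recording$units, "N"))
    stop("expected a newton-scale recording (threshold is applied pre-normalization)")
  rec <- if (is.null(cutoff)) recording else
    lowpass_filter(recording, cutoff = cutoff, order = order)
  stances <- detect_stances(rec, threshold = threshold,
                            min_stance_s = min_stance_s,
                            min_swing_s = min_swing_s)
  rec_bw <- normalize_bw(rec)
  segs <- rec$metadata$segments
  if (is.null(segs))
    segs <- data.frame(label = "all", start = 0, end = max(rec$time),
                       analysis = TRUE, stringsAsFactors = FALSE)
  segs <- segs[segs$analysis %||% TRUE, , drop = FALSE]
  out <- list(); qc <- c(detected = 0L, extracted = 0L, dropped = 0L)
  for (lb in names(rec$force)) {
    for (i in seq_len(nrow(segs))) {
      st <- stances[stances$limb == lb &
                      stances$heel_strike_time >= segs$start[i] &
                      stances$toe_off_time <= segs$end[i], , drop = FALSE]
      if (nrow(st) == 0L) next
      pk <- extract_peaks(rec_bw, st)
      qc <- qc + attr(pk, "qc")
      out[[paste(lb, segs$label[i], sep = ".")]] <-
        build_peak_series(pk, condition = segs$label[i], limb = lb,
                          skip_strides = skip_strides)
    }
  }
  attr(out, "qc") <- qc
  out
}
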