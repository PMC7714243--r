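#' Write and read vGRF recordings as CSV plus metadata sidecar
#'
#' `write_grf_recording()` writes `<prefix>.csv` with header
#' `time,fz_left,fz_right` (seconds, newtons; absent limbs omitted), a
#' structured-text sidecar `<prefix>_meta.yaml` (body weight in newtons,
#' sampling rate, units, master seed, segment table) and, when the
#' recording carries generator ground truth, `<prefix>_truth.csv` with
#' columns `limb,step_index,event_time,peak_type,peak_value_bw`.
#' `read_grf_recording()` reverses the process.
#'
#' @param recording a `grf_recording`.
#' @param prefix output path prefix (directories must exist).
#' @return the prefix, invisibly.
#' @export
write_grf_recording <- function(recording, prefix) {
  df <- data.frame(time = recording$time)
  for (lb in names(recording$force))
    df[[paste0("fz_", lb)]] <- recording$force[[lb]]
  write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(body_weight_N = recording$body_weight,
               sampling_rate_hz = recording$sampling_rate,
               units = recording$units,
               seed = recording$metadata$seed,
               segments = if (!is.null(recording$metadata$segments))
                 lapply(seq_len(nrow(recording$metadata$segments)), function(i)
                   as.list(recording$metadata$segments[i, ])))
  yaml::write_yaml(meta, paste0(prefix, "_meta.yaml"))
  if (!is.null(recording$truth))
    write.csv(recording$truth[, c("limb", "step_index", "event_time",
                                  "peak_type", "peak_value_bw",
                                  intersect("condition", names(recording$truth)))],
              paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grf_recording
#' @export
read_grf_recording <- function(prefix) {
  df <- read.csv(paste0(prefix, ".csv"))
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  fcols <- grep("^fz_", names(df), value = TRUE)
  force <- setNames(lapply(fcols, function(cn) df[[cn]]),
                    sub("^fz_", "", fcols))
  segs <- NULL
  if (!is.null(meta$segments))
    segs <- do.call(rbind, lapply(meta$segments, as.data.frame))
  rec <- list(time = df$time, force = force,
              sampling_rate = meta$sampling_rate_hz,
              body_weight = meta$body_weight_N,
              units = meta$units %||% "N",
              metadata = list(segments = segs, seed = meta$seed))
  tpath <- paste0(prefix, "_truth.csv")
  if (file.exists(tpath)) rec$truth <- read.csv(tpath)
  class(rec) <- "grf_recording"
  rec
}

#' Write extracted peak series to CSV
#'
#' One row per peak event: `limb,condition,step_index,peak_type,
#' event_time_s,value_bw`.  `step_index` counts peak events within each
#' series.
#'
#' @param series_list list of `peak_series` (as from
#'   [extract_peak_series()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_series_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(limb = s$limb, condition = s$condition,
               step_index = seq_along(s$value), peak_type = s$type,
               event_time_s = s$time, value_bw = s$value,
               stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_series_csv
#' @export
read_peak_series_csv <- function(path) {
  df <- read.csv(path)
  split_keys <- interaction(df$limb, df$condition, drop = TRUE)
  lapply(split(df, split_keys), function(d) {
    d <- d[order(d$event_time_s), ]
    structure(list(value = d$value_bw, time = d$event_time_s,
                   type = d$peak_type, limb = d$limb[1],
                   condition = d$condition[1], n = nrow(d)),
              class = "peak_series")
  })
}

# JSON-ready record of one AR fit (used by the pipeline outputs)
ar_fit_record <- function(fit, participant = NA) {
  list(participant = participant, limb = fit$limb, condition = fit$condition,
       n = fit$n, order = fit$order,
       phi1 = unname(coef(fit)[1]),
       phi2 = if (fit$order >= 2) unname(coef(fit)[2]) else NA,
       sigma2 = fit$sigma2,
       roots = lapply(seq_along(fit$roots), function(i)
         list(re = Re(fit$roots[i]), im = Im(fit$roots[i]),
              modulus = fit$moduli[i])),
       stationary = fit$stationary, distance = fit$distance,
       ad_stat = tryCatch(ad_normality(fit$residuals)$adjusted,
                          error = function(e) NA),
       ad_reject = tryCatch(ad_normality(fit$residuals)$reject,
                            error = function(e) NA))
}
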