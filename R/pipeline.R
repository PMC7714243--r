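#' Analyze a simulated (or loaded) study end to end
#'
#' Runs the full signal chain and model fit for every participant
#' recording: low-pass filter, stance detection (50 N), body-weight
#' normalization, peak extraction, interleaved series assembly, AR(2) fit,
#' and triangle mapping.  Returns the per-participant metric table used by
#' [compare_conditions()].
#'
#' @param study a [simulate_study()] object, or a plain list of
#'   `grf_recording`s.
#' @param cutoff,order,threshold,skip_strides signal-chain settings (see
#'   [extract_peak_series()]).
#' @param ar_order AR model order (default 2).
#' @return list of class `"gait_analysis"`: `metrics` (data.frame
#'   `participant`, `limb`, `condition`, `phi1`, `phi2`, `ar_distance`,
#'   `mean_peak_vgrf_bw`, `n_peaks`, `stationary`), `fits` (nested list),
#'   `points` ([triangle_points()]), `qc`.
#' @export
analyze_study <- function(study, cutoff = 35, order = 4, threshold = 50,
                          skip_strides = 10, ar_order = 2) {
  recs <- if (inherits(study, "gait_study")) study$recordings else study
  rows <- list(); fits <- list(); qc <- c(detected = 0L, extracted = 0L,
                                          dropped = 0L)
  for (p in seq_along(recs)) {
    series <- extract_peak_series(recs[[p]], cutoff = cutoff, order = order,
                                  threshold = threshold,
                                  skip_strides = skip_strides)
    qc <- qc + attr(series, "qc")
    for (s in series) {
      fit <- gait_ar(s, order = ar_order)
      fits[[length(fits) + 1L]] <- ar_fit_record(fit, participant = p)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, limb = s$limb, condition = s$condition,
        phi1 = unname(coef(fit)[1]), phi2 = unname(coef(fit)[2]),
        ar_distance = fit$distance,
        mean_peak_vgrf_bw = base::mean(s$value),
        n_peaks = s$n, stationary = fit$stationary,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  pts <- triangle_points(metrics$phi1, metrics$phi2,
                         participant = metrics$participant,
                         limb = metrics$limb, condition = metrics$condition)
  structure(list(metrics = metrics, fits = fits, points = pts, qc = qc),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Gait AR analysis:", nrow(x$metrics), "fitted series (",
      length(unique(x$metrics$participant)), "participants )\n")
  cat("QC:", paste(names(x$qc), x$qc, sep = "=", collapse = ", "), "\n")
  agg <- aggregate(cbind(ar_distance, mean_peak_vgrf_bw) ~ condition + limb,
                   data = x$metrics, FUN = function(v) round(base::mean(v), 3))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Build and validate a pipeline run configuration
#'
#' Flat key-value configuration for [run_pipeline()].  Unknown keys and
#' out-of-bounds values raise an error enumerating the offenders before
#' any computation starts.
#'
#' @param ... configuration values; see Defaults.
#' @details Recognised keys (defaults): `mode` ("simulate"),
#'   `n_participants` (17), `duration` (60), `seed` (1; mandatory in
#'   simulate mode), `cutoff` (35), `filter_order` (4), `threshold_n`
#'   (50), `skip_strides` (10), `ar_order` (2), `alpha` (0.05), `out_dir`
#'   (NULL = no files written), `write_recordings` (FALSE),
#'   `recording_prefixes` (character vector, recordings mode),
#'   `workbook` (path, workbook mode), `truth_sd` (0.2).
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(mode = "simulate", n_participants = 17, duration = 60,
                   seed = 1L, cutoff = 35, filter_order = 4,
                   threshold_n = 50, skip_strides = 10, ar_order = 2,
                   alpha = 0.05, out_dir = NULL, write_recordings = FALSE,
                   recording_prefixes = NULL, workbook = NULL,
                   truth_sd = 0.2)
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  problems <- character()
  if (!cfg$mode %in% c("simulate", "recordings", "workbook"))
    problems <- c(problems, "mode must be simulate|recordings|workbook")
  if (cfg$mode == "simulate" && (is.null(cfg$seed) || is.na(cfg$seed)))
    problems <- c(problems, "seed is mandatory in simulate mode")
  if (cfg$cutoff >= 1200 / 2)
    problems <- c(problems, "cutoff must be below the Nyquist frequency (600 Hz at 1200 Hz)")
  if (cfg$cutoff <= 0) problems <- c(problems, "cutoff must be positive")
  if (!cfg$filter_order %in% 1:8)
    problems <- c(problems, "filter_order must be in 1..8")
  if (cfg$threshold_n <= 0) problems <- c(problems, "threshold_n must be positive")
  if (cfg$skip_strides < 0) problems <- c(problems, "skip_strides must be >= 0")
  if (!cfg$ar_order %in% 1:6) problems <- c(problems, "ar_order must be in 1..6")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) problems <- c(problems, "alpha must be in (0,1)")
  if (cfg$n_participants < 1) problems <- c(problems, "n_participants must be >= 1")
  if (cfg$mode == "recordings" && is.null(cfg$recording_prefixes))
    problems <- c(problems, "recordings mode needs recording_prefixes")
  if (cfg$mode == "workbook" && is.null(cfg$workbook))
    problems <- c(problems, "workbook mode needs a workbook path")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full gait-AR pipeline
#'
#' Orchestrates simulate (or load) -> extract peaks -> fit AR -> triangle
#' -> condition comparison as one reproducible run.  In simulate mode the
#' synthetic study is generated from the master seed with
#' condition-dependent AR ground truth.  When `out_dir` is set, the stage
#' outputs are written there: `peaks.csv`, `ar_fits.json`,
#' `triangle_points.csv`, `triangle.svg`, `comparison.csv` and a
#' `manifest.yaml` snapshot (config, package version, per-file hashes,
#' QC counts and warnings); recordings are additionally written when
#' `write_recordings` is TRUE.
#'
#' @param config a [run_config()] (or arguments for one).
#' @return list of class `"pipeline_run"`: `analysis` (see
#'   [analyze_study()]), `comparison` ([compare_conditions()]), `truth`
#'   (simulate mode), `manifest`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  warnings_log <- character()
  truth <- NULL
  if (config$mode == "simulate") {
    params <- sim_params(seed = config$seed)
    study <- simulate_study(n_participants = config$n_participants,
                            protocol = default_protocol(duration = config$duration),
                            params = params, truth_sd = config$truth_sd,
                            seed = config$seed)
    truth <- study$truth
  } else if (config$mode == "recordings") {
    study <- lapply(config$recording_prefixes, read_grf_recording)
  } else {
    wb <- read_supplementary_workbook(config$workbook)
    if (identical(attr(wb, "layout"), "summary"))
      stop("workbook contains summary-level data only; AR fitting needs ",
           "peak-level series (use compare_conditions() on the table directly)")
    study <- NULL
  }

  if (config$mode == "workbook") {
    fits <- list(); rows <- list()
    for (s in wb) {
      fit <- gait_ar(s, order = config$ar_order)
      fits[[length(fits) + 1L]] <- ar_fit_record(fit, attr(s, "participant") %||% NA)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = attr(s, "participant") %||% NA, limb = s$limb,
        condition = s$condition, phi1 = unname(coef(fit)[1]),
        phi2 = unname(coef(fit)[2]), ar_distance = fit$distance,
        mean_peak_vgrf_bw = base::mean(s$value), n_peaks = s$n,
        stationary = fit$stationary, stringsAsFactors = FALSE)
    }
    metrics <- do.call(rbind, rows)
    analysis <- structure(list(
      metrics = metrics, fits = fits,
      points = triangle_points(metrics$phi1, metrics$phi2,
                               participant = metrics$participant,
                               limb = metrics$limb,
                               condition = metrics$condition),
      qc = c(detected = NA, extracted = NA, dropped = NA)),
      class = "gait_analysis")
  } else {
    analysis <- analyze_study(study, cutoff = config$cutoff,
                              order = config$filter_order,
                              threshold = config$threshold_n,
                              skip_strides = config$skip_strides,
                              ar_order = config$ar_order)
  }

  comparison <- tryCatch(
    compare_conditions(analysis$metrics, alpha = config$alpha),
    error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste("comparison skipped:", conditionMessage(e)))
      NULL
    })

  manifest <- list(config = unclass(config),
                   package_version = as.character(packageVersion("gaitar")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   qc = as.list(analysis$qc), files = list(),
                   warnings = warnings_log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(name) file.path(config$out_dir, name)
    paths <- character()
    pk_path <- outfile("peaks.csv")
    pk_rows <- analysis$metrics[, c("participant", "limb", "condition",
                                    "n_peaks", "mean_peak_vgrf_bw")]
    write.csv(pk_rows, pk_path, row.names = FALSE); paths <- c(paths, pk_path)
    fit_path <- outfile("ar_fits.json")
    jsonlite::write_json(analysis$fits, fit_path, auto_unbox = TRUE,
                         digits = NA, na = "null"); paths <- c(paths, fit_path)
    tp_path <- outfile("triangle_points.csv")
    write.csv(as.data.frame(analysis$points), tp_path, row.names = FALSE)
    paths <- c(paths, tp_path)
    fig_path <- outfile("triangle.svg")
    render_triangle(analysis$points, fig_path); paths <- c(paths, fig_path)
    if (!is.null(comparison)) {
      cmp_path <- outfile("comparison.csv")
      write.csv(as.data.frame(comparison), cmp_path, row.names = FALSE)
      paths <- c(paths, cmp_path)
    }
    if (isTRUE(config$write_recordings) && config$mode == "simulate")
      for (p in seq_along(study$recordings)) {
        pre <- outfile(sprintf("participant_%02d", p))
        write_grf_recording(study$recordings[[p]], pre)
        paths <- c(paths, paste0(pre, ".csv"))
      }
    manifest$files <- lapply(setNames(paths, basename(paths)), function(f)
      unname(tools::md5sum(f)))
    yaml::write_yaml(manifest, outfile("manifest.yaml"))
  }

  structure(list(analysis = analysis, comparison = comparison,
                 truth = truth, manifest = manifest, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("gaitar pipeline run (mode:", x$config$mode, ", seed:",
      x$config$seed, ")\n\n")
  print(x$analysis)
  if (!is.null(x$comparison)) { cat("\n"); print(x$comparison) }
  invisible(x)
}

#' Read a supplementary workbook of peak or summary data
#'
#' Reads an XLSX workbook (or an equivalent CSV) and auto-detects its
#' layout from the header: peak-level content (columns `participant`,
#' `limb`, `condition`, plus `value`/`value_bw` and optionally
#' `peak_type`, `step`/`step_index`) is parsed into a list of
#' `peak_series`; summary-level content (columns `participant`, `limb`,
#' `condition`, `metric`, `value`, or wide metric columns) into a metric
#' table for [compare_conditions()].  An unrecognized layout raises an
#' error showing the headers that were found.
#'
#' @param path path to an `.xlsx` or `.csv` file.
#' @param sheet sheet index or name (XLSX only).
#' @return a list of `peak_series` (attribute `layout = "peaks"`) or a
#'   metrics data.frame (attribute `layout = "summary"`).
#' @export
read_supplementary_workbook <- function(path, sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else if (ext == "csv") {
    read.csv(path)
  } else stop("unsupported file type: .", ext)
  names(df) <- tolower(names(df))
  if (nrow(df) == 0L)
    stop("workbook is empty (headers found: ",
         paste(names(df), collapse = ", "), ")")
  base_cols <- c("participant", "limb", "condition")
  valcol <- intersect(c("value", "value_bw", "peak_value_bw"), names(df))[1]
  if (all(base_cols %in% names(df)) && !is.na(valcol) &&
      any(c("peak_type", "step", "step_index") %in% names(df))) {
    key <- interaction(df$participant, df$limb, df$condition, drop = TRUE)
    out <- lapply(split(df, key), function(d) {
      ocol <- intersect(c("event_time_s", "step_index", "step"), names(d))[1]
      if (!is.na(ocol)) d <- d[order(d[[ocol]]), ]
      s <- structure(list(value = d[[valcol]],
                          time = if ("event_time_s" %in% names(d))
                            d$event_time_s else seq_len(nrow(d)),
                          type = if ("peak_type" %in% names(d)) d$peak_type
                          else rep(NA_character_, nrow(d)),
                          limb = as.character(d$limb[1]),
                          condition = as.character(d$condition[1]),
                          n = nrow(d)),
                     class = "peak_series")
      attr(s, "participant") <- d$participant[1]
      s
    })
    attr(out, "layout") <- "peaks"
    return(out)
  }
  metric_cols <- intersect(c("mean_peak_vgrf_bw", "ar_distance"), names(df))
  if (all(base_cols %in% names(df)) &&
      ("metric" %in% names(df) || length(metric_cols))) {
    if ("metric" %in% names(df)) {
      wide <- stats::reshape(df[, c(base_cols, "metric", "value")],
                             idvar = base_cols, timevar = "metric",
                             direction = "wide")
      names(wide) <- sub("^value\\.", "", names(wide))
      df <- wide
    }
    message("workbook contains summary-level data; AR fitting is skipped")
    attr(df, "layout") <- "summary"
    return(df)
  }
  stop("unrecognized workbook layout; headers found: ",
       paste(names(df), collapse = ", "))
}
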