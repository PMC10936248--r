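#' Default pipeline configuration
#'
#' Every protocol constant lives here: sampling rates (200 Hz markers,
#' 100 Hz brace, 1.5 kHz EMG), the 6 Hz zero-lag fourth-order Butterworth
#' angle filter, the 60-200 Hz EMG band-pass, the 300-sample (0.2 s)
#' envelope window, the calibration degree, segmentation thresholds and the
#' significance level.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    rates = list(markers_hz = 200, brace_hz = 100, emg_hz = 1500),
    angle_filter = list(order = 4, cutoff_hz = 6),
    emg = list(band_hz = c(60, 200), envelope_window_samples = 300,
               envelope_window_s = 0.2, cardiac = "none"),
    calibration = list(degree = 3, refine = TRUE, extrapolation_guard = 0.05),
    segmentation = list(enter_frac = 0.10, exit_frac = 0.20),
    stats = list(conf_level = 0.95, alpha = 0.05)
  )
}

#' Validate a pipeline configuration
#'
#' Checks internal consistency of a configuration list; in particular that
#' the EMG envelope window matches its stated duration at the EMG sampling
#' rate (300 samples at 1.5 kHz = 0.2 s), that the band-pass fits under the
#' Nyquist limit, and that thresholds are ordered.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly `TRUE`; errors with a message otherwise.
#' @export
validate_config <- function(config) {
  r <- config$rates
  e <- config$emg
  if (!isTRUE(all.equal(e$envelope_window_samples,
                        e$envelope_window_s * r$emg_hz)))
    stop(sprintf("config: envelope window %d samples != %.3f s at %g Hz",
                 e$envelope_window_samples, e$envelope_window_s, r$emg_hz),
         call. = FALSE)
  if (e$band_hz[2] >= r$emg_hz / 2)
    stop("config: EMG band-pass upper edge exceeds Nyquist", call. = FALSE)
  if (config$angle_filter$cutoff_hz >= r$brace_hz / 2)
    stop("config: angle filter cutoff exceeds Nyquist", call. = FALSE)
  s <- config$segmentation
  if (!(s$enter_frac > 0 && s$enter_frac < s$exit_frac && s$exit_frac < 1))
    stop("config: segmentation thresholds must satisfy 0 < enter < exit < 1",
         call. = FALSE)
  if (!(config$calibration$degree %in% 1:5))
    stop("config: calibration degree must be in 1..5", call. = FALSE)
  invisible(TRUE)
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), cfg)
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Marker trial CSV I/O
#'
#' Columns: `time_s`, then `<LABEL>_x_mm`, `<LABEL>_y_mm`, `<LABEL>_z_mm`
#' for each of the eight marker labels.
#'
#' @param trial Named list of n x 3 matrices.
#' @param time_s Timestamps.
#' @param path File path.
#' @export
write_marker_csv <- function(trial, time_s, path) {
  df <- data.frame(time_s = time_s)
  for (l in MARKER_LABELS) {
    m <- trial[[l]]
    df[[paste0(l, "_x_mm")]] <- m[, 1]
    df[[paste0(l, "_y_mm")]] <- m[, 2]
    df[[paste0(l, "_z_mm")]] <- m[, 3]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @return `read_marker_csv`: list with `time_s` and `trial` (named list of
#'   n x 3 matrices).
#' @export
read_marker_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("marker file ", path, ": missing column time_s", call. = FALSE)
  trial <- list()
  for (l in MARKER_LABELS) {
    cols <- paste0(l, c("_x_mm", "_y_mm", "_z_mm"))
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop(sprintf("marker file %s: missing column %s", path, missing[1]),
           call. = FALSE)
    trial[[l]] <- as.matrix(df[cols])
  }
  list(time_s = df$time_s, trial = trial)
}

#' Voltage log CSV I/O (`time_s, v1..v6, trigger`)
#' @param vl A [voltage_log()].
#' @param path File path.
#' @export
write_voltage_csv <- function(vl, path) {
  df <- data.frame(time_s = vl$time_s)
  for (j in 1:6) df[[paste0("v", j)]] <- vl$volts[, j]
  df$trigger <- if (is.null(vl$trigger)) 0 else vl$trigger
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_csv
#' @param expected_rate_hz Optional rate check against the median timestamp
#'   spacing (5% tolerance).
#' @export
read_voltage_csv <- function(path, expected_rate_hz = NULL) {
  df <- read.csv(path)
  need <- c("time_s", paste0("v", 1:6), "trigger")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("voltage file %s: missing column %s", path, missing[1]),
         call. = FALSE)
  rate <- 1 / median(diff(df$time_s))
  if (!is.null(expected_rate_hz) &&
      abs(rate - expected_rate_hz) > 0.05 * expected_rate_hz)
    stop(sprintf("voltage file %s: sample rate %.1f Hz does not match configured %g Hz",
                 path, rate, expected_rate_hz), call. = FALSE)
  voltage_log(df$time_s, as.matrix(df[paste0("v", 1:6)]),
              trigger = df$trigger, sample_rate = rate)
}

#' EMG recording CSV I/O
#' (`time_s, scm_l, scm_r, sc_l, sc_r, tr_l, tr_r, trigger`)
#' @param rec An [emg_recording()].
#' @param path File path.
#' @export
write_emg_csv <- function(rec, path) {
  df <- data.frame(time_s = rec$time_s)
  for (ch in EMG_CHANNELS) df[[tolower(ch)]] <- rec$channels[, ch]
  df$trigger <- if (is.null(rec$trigger)) 0 else rec$trigger
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param expected_rate_hz Optional rate check (5% tolerance).
#' @param participant,visit Identifiers for the loaded recording.
#' @export
read_emg_csv <- function(path, expected_rate_hz = NULL, participant = "P1",
                         visit = "pre") {
  df <- read.csv(path)
  need <- c("time_s", tolower(EMG_CHANNELS), "trigger")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("EMG file %s: missing column %s", path, missing[1]),
         call. = FALSE)
  rate <- 1 / median(diff(df$time_s))
  if (!is.null(expected_rate_hz) &&
      abs(rate - expected_rate_hz) > 0.05 * expected_rate_hz)
    stop(sprintf("EMG file %s: sample rate %.1f Hz does not match configured %g Hz",
                 path, rate, expected_rate_hz), call. = FALSE)
  ch <- as.matrix(df[tolower(EMG_CHANNELS)])
  colnames(ch) <- EMG_CHANNELS
  emg_recording(df$time_s, ch, trigger = df$trigger, sample_rate = rate,
                participant = participant, visit = visit)
}

#' Export a workspace cloud as CSV (`x_mm, y_mm, z_mm`)
#' @param cloud A `workspace_cloud`.
#' @param path File path.
#' @export
write_cloud_csv <- function(cloud, path) {
  pts <- if (inherits(cloud, "workspace_cloud")) cloud$points else as.matrix(cloud)
  df <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic session to disk
#'
#' Emits the CSV dialects the readers consume (marker, voltage and EMG
#' files per trial), a ground-truth JSON per trial, and a session manifest
#' JSON linking them.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs_m <- session$markers$sample_rate
  entries <- list()
  static_path <- file.path(dir, "static_markers.csv")
  st <- session$markers$trials$static
  write_marker_csv(st, seq(0, by = 1 / fs_m, length.out = nrow(st$C7)),
                   static_path)
  for (m in names(session$trials)) {
    tr <- session$trials[[m]]
    entry <- list(motion = m)
    if (!is.null(tr$markers)) {
      p <- file.path(dir, paste0(m, "_markers.csv"))
      write_marker_csv(tr$markers, tr$marker_time_s, p)
      entry$markers <- basename(p)
    }
    if (!is.null(tr$voltages)) {
      p <- file.path(dir, paste0(m, "_voltages.csv"))
      write_voltage_csv(tr$voltages, p)
      entry$voltages <- basename(p)
    }
    if (!is.null(tr$emg)) {
      p <- file.path(dir, paste0(m, "_emg.csv"))
      write_emg_csv(tr$emg, p)
      entry$emg <- basename(p)
    }
    gt <- tr$ground_truth
    gp <- file.path(dir, paste0(m, "_ground_truth.json"))
    jsonlite::write_json(list(angles_deg = gt$angles_deg, q_rad = gt$q,
                              time_s = gt$time_s,
                              cycle_bounds = gt$cycle_bounds,
                              burst_centers_pct = as.list(gt$burst_centers_pct),
                              trigger_time_s = gt$trigger_time_s),
                         gp, auto_unbox = TRUE, digits = NA)
    entry$ground_truth <- basename(gp)
    entries[[m]] <- entry
  }
  chain_path <- file.path(dir, "chain.json")
  write_chain(session$chain, chain_path)
  manifest <- list(participant = session$participant, visit = session$visit,
                   static_markers = basename(static_path),
                   chain = basename(chain_path),
                   trials = unname(entries))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Load and validate a recorded session from a manifest
#'
#' Reads the manifest JSON, loads every referenced stream, converts units,
#' checks schemas and sample rates against the configuration, and verifies
#' trigger presence where EMG is to be synchronized.
#'
#' @param manifest_path Path to a session manifest JSON.
#' @param config Configuration list (default [default_config()]).
#' @return List with `participant`, `visit`, `markers`
#'   ([marker_session()]), `trials` (per motion: `voltages`, `emg`,
#'   optional `ground_truth`), `chain`.
#' @export
load_session <- function(manifest_path, config = default_config()) {
  validate_config(config)
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  if (!identical(man$visit, "pre") && !identical(man$visit, "post"))
    stop("manifest: visit must be 'pre' or 'post'", call. = FALSE)
  chain <- if (!is.null(man$chain)) read_chain(file.path(dir, man$chain))
           else default_chain()
  mtrials <- list()
  st <- read_marker_csv(file.path(dir, man$static_markers))
  mtrials$static <- st$trial
  trials <- list()
  for (entry in man$trials) {
    m <- entry$motion
    tr <- list(motion = m)
    if (!is.null(entry$markers)) {
      mk <- read_marker_csv(file.path(dir, entry$markers))
      mtrials[[m]] <- mk$trial
      rate <- 1 / median(diff(mk$time_s))
      if (abs(rate - config$rates$markers_hz) > 0.05 * config$rates$markers_hz)
        stop(sprintf("marker file %s: sample rate %.1f Hz does not match configured %g Hz",
                     entry$markers, rate, config$rates$markers_hz),
             call. = FALSE)
    }
    if (!is.null(entry$voltages))
      tr$voltages <- read_voltage_csv(file.path(dir, entry$voltages),
                                      expected_rate_hz = config$rates$brace_hz)
    if (!is.null(entry$emg))
      tr$emg <- read_emg_csv(file.path(dir, entry$emg),
                             expected_rate_hz = config$rates$emg_hz,
                             participant = man$participant,
                             visit = man$visit)
    if (!is.null(entry$emg) && !is.null(tr$voltages)) {
      if (!length(rising_edge_times(tr$voltages$time_s, tr$voltages$trigger)))
        stop(sprintf("trial %s: no trigger edge in voltage stream", m),
             call. = FALSE)
      if (!length(rising_edge_times(tr$emg$time_s, tr$emg$trigger)))
        stop(sprintf("trial %s: no trigger edge in EMG stream", m),
             call. = FALSE)
    }
    if (!is.null(entry$ground_truth)) {
      gt <- jsonlite::fromJSON(file.path(dir, entry$ground_truth))
      gt$angles_deg <- as.matrix(gt$angles_deg)
      gt$q <- as.matrix(gt$q_rad)
      tr$ground_truth <- gt
    }
    trials[[m]] <- tr
  }
  list(participant = man$participant, visit = man$visit,
       markers = marker_session(mtrials,
                                sample_rate = config$rates$markers_hz),
       trials = trials, chain = chain, mount = default_mounting())
}
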