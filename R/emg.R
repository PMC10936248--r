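#' EMG channel labels (bilateral sternocleidomastoid, splenius capitis,
#' trapezius)
#' @keywords internal
EMG_CHANNELS <- c("SCM_L", "SCM_R", "SC_L", "SC_R", "TR_L", "TR_R")

#' Assemble a surface-EMG recording
#'
#' Six channels recorded at the neck muscle sites: sternocleidomastoid
#' (SCM), splenius capitis (SC) and trapezius (TR), bilaterally.
#'
#' @param time_s Sample timestamps, s.
#' @param channels n x 6 numeric matrix (mV), columns named as
#'   `EMG_CHANNELS`.
#' @param trigger 0/1 vector marking the synchronization pulse, or `NULL`.
#' @param sample_rate Hz (default 1500).
#' @param participant,visit Identifiers used to guard the visit-wide
#'   normalization pool.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(time_s, channels, trigger = NULL,
                          sample_rate = 1500, participant = "P1",
                          visit = "pre") {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) colnames(channels) <- EMG_CHANNELS
  missing <- setdiff(EMG_CHANNELS, colnames(channels))
  if (length(missing))
    stop("emg_recording: missing channel(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  channels <- channels[, EMG_CHANNELS, drop = FALSE]
  if (!all(is.finite(channels)))
    stop("emg_recording: non-finite samples", call. = FALSE)
  stopifnot(length(time_s) == nrow(channels))
  if (sample_rate <= 2 * 200)
    stop("emg_recording: sample rate must exceed twice the band-pass upper edge",
         call. = FALSE)
  structure(list(time_s = as.numeric(time_s), channels = channels,
                 trigger = trigger, sample_rate = sample_rate,
                 participant = participant, visit = visit),
            class = "emg_recording")
}

rising_edge_times <- function(time_s, trigger) {
  if (is.null(trigger)) return(numeric(0))
  tr <- as.numeric(trigger) > 0.5
  edges <- which(diff(c(FALSE, tr)) == 1L)
  time_s[edges]
}

# cardiac artifact suppression by ensemble-template subtraction: detect
# periodic spikes (~1-1.5 Hz) on the raw signal, average them into a
# template, subtract at each occurrence.
suppress_cardiac <- function(x, fs, rate_hz_range = c(0.8, 2),
                             half_window_s = 0.05) {
  hw <- round(half_window_s * fs)
  min_dist <- round(fs / rate_hz_range[2])
  ax <- abs(x - mean(x))
  thr <- 3 * stats::mad(ax)
  cand <- which(ax > thr)
  if (!length(cand)) return(x)
  # greedy peak picking with refractory distance
  ord <- cand[order(ax[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (i in ord) {
    if (!length(peaks) || all(abs(peaks - i) >= min_dist)) peaks <- c(peaks, i)
  }
  # refine each detection to the signed maximum nearby so the ensemble
  # template is consistently aligned across beats
  peaks <- vapply(peaks, function(p) {
    w <- max(1L, p - hw):min(length(x), p + hw)
    w[which.max(x[w])]
  }, 0L)
  peaks <- sort(unique(peaks[peaks > hw & peaks <= length(x) - hw]))
  if (length(peaks) < 3L) return(x)
  segs <- vapply(peaks, function(p) x[(p - hw):(p + hw)], numeric(2 * hw + 1))
  template <- rowMeans(segs)
  template <- template - mean(template)
  for (p in peaks) {
    idx <- (p - hw):(p + hw)
    x[idx] <- x[idx] - template
  }
  x
}

# steps (a)-(e) of the envelope pipeline, before visit normalization
emg_envelope_unnormalized <- function(rec, window = 300L,
                                      band = c(60, 200), order = 4,
                                      cardiac = c("none", "template")) {
  cardiac <- match.arg(cardiac)
  des <- butter_design(order, band, rec$sample_rate, "band")
  out <- rec$channels
  for (j in seq_len(ncol(out))) {
    x <- as.numeric(rec$channels[, j])
    if (cardiac == "template") x <- suppress_cardiac(x, rec$sample_rate)
    x <- x - mean(x)                                   # (b) DC removal
    x <- filtfilt_zero_phase(des$b, des$a, x)          # (c) band-pass
    x <- abs(x)                                        # (d) full-wave rectify
    out[, j] <- moving_average(x, window)              # (e) linear envelope
  }
  out
}

#' Six-step EMG linear-envelope pipeline
#'
#' Per channel, in order: optional cardiac-artifact suppression, DC-offset
#' removal by mean subtraction, fourth-order zero-phase Butterworth
#' band-pass 60-200 Hz, full-wave rectification, centered 300-sample
#' (0.2 s) moving-average envelope, and normalization of each channel by
#' the largest envelope value recorded in that channel across all trials of
#' the participant's visit (`visit_pool`).
#'
#' @param raw An `emg_recording`.
#' @param visit_pool List of `emg_recording` objects from the same
#'   participant and visit; must include `raw`. Defaults to `list(raw)`.
#' @param window Moving-average window, samples (default 300).
#' @param band Band-pass edges, Hz (default `c(60, 200)`).
#' @param cardiac `"none"` (default; the band-pass already suppresses most
#'   cardiac energy) or `"template"` ensemble subtraction.
#' @return Object of class `envelope_series`: list with `time_s`,
#'   `envelopes` (n x 6 in `[0, 1]`), `normalization` (per-channel visit
#'   maxima), `sample_rate`, `trigger`.
#' @export
process_emg <- function(raw, visit_pool = list(raw), window = 300L,
                        band = c(60, 200), cardiac = "none") {
  stopifnot(inherits(raw, "emg_recording"))
  if (!length(visit_pool))
    stop("process_emg: empty visit pool", call. = FALSE)
  same <- vapply(visit_pool, function(r)
    identical(r$participant, raw$participant) && identical(r$visit, raw$visit),
    TRUE)
  if (!all(same))
    stop("process_emg: visit pool mixes participants or visits", call. = FALSE)
  in_pool <- any(vapply(visit_pool, function(r)
    identical(r$time_s, raw$time_s) && identical(r$channels, raw$channels),
    TRUE))
  if (!in_pool)
    stop("process_emg: visit pool must include the processed recording",
         call. = FALSE)
  env <- emg_envelope_unnormalized(raw, window, band, cardiac = cardiac)
  pool_max <- rep(0, ncol(env))
  for (r in visit_pool) {
    e <- if (identical(r$time_s, raw$time_s) && identical(r$channels, raw$channels))
      env else emg_envelope_unnormalized(r, window, band, cardiac = cardiac)
    pool_max <- pmax(pool_max, apply(e, 2L, max))
  }
  norm <- ifelse(pool_max > 0, pool_max, 1)  # all-zero channel stays zero
  env <- sweep(env, 2L, norm, "/")
  structure(list(time_s = raw$time_s, envelopes = env,
                 normalization = pool_max, sample_rate = raw$sample_rate,
                 trigger = raw$trigger),
            class = "envelope_series")
}

#' Trigger-based synchronization of brace and EMG streams
#'
#' Both acquisition systems record a shared digital trigger pulse. The
#' first rising edge in each stream is mapped to a common t = 0, the EMG
#' stream (envelopes or raw channels) is linearly interpolated onto the
#' brace timeline, and both are cropped to the overlapping interval.
#'
#' @param brace List with `time_s`, a value matrix/vector (`volts`,
#'   `angles` or `values`), and `trigger` (0/1 per sample) - e.g. a
#'   [voltage_log()] or an angle stream carrying a trigger.
#' @param emg An `emg_recording` or `envelope_series`.
#' @return Object of class `synced_recording`: `time_s` (brace timeline,
#'   t = 0 at the trigger), `brace` matrix, `emg` matrix (interpolated),
#'   `sample_rate` (brace rate), `offset_s` (applied EMG shift).
#' @export
synchronize <- function(brace, emg) {
  bt <- rising_edge_times(brace$time_s, brace$trigger)
  if (!length(bt))
    stop("synchronize: no trigger edge in the brace stream", call. = FALSE)
  et <- rising_edge_times(emg$time_s, emg$trigger)
  if (!length(et))
    stop("synchronize: no trigger edge in the EMG stream", call. = FALSE)
  bvals <- brace$volts %||% brace$angles %||% brace$values
  evals <- emg$envelopes %||% emg$channels
  bvals <- as.matrix(bvals); evals <- as.matrix(evals)
  b_time <- brace$time_s - bt[1]
  e_time <- emg$time_s - et[1]
  lo <- max(min(b_time), min(e_time))
  hi <- min(max(b_time), max(e_time))
  keep <- which(b_time >= lo - 1e-12 & b_time <= hi + 1e-12)
  if (!length(keep))
    stop("synchronize: streams do not overlap after alignment", call. = FALSE)
  out_t <- b_time[keep]
  emg_i <- matrix(0, length(out_t), ncol(evals),
                  dimnames = list(NULL, colnames(evals)))
  for (j in seq_len(ncol(evals)))
    emg_i[, j] <- approx(e_time, evals[, j], xout = out_t, rule = 2)$y
  structure(list(time_s = out_t, brace = bvals[keep, , drop = FALSE],
                 emg = emg_i,
                 sample_rate = brace$sample_rate %||% 1 / median(diff(out_t)),
                 offset_s = et[1] - bt[1]),
            class = "synced_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
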