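#' Segment a continuous single-plane trial into movement cycles
#'
#' The in-clinic protocol has each participant repeat, continuously and at
#' self-selected speed, a movement cycle: neutral -> first extreme ->
#' opposite extreme -> neutral. Cycles are delimited on the primary angle
#' by departures from and returns into a neutral band with hysteresis: an
#' excursion opens when the angle leaves the exit band (20% of the trial's
#' peak magnitude by default) and closes on return inside the entry band
#' (10%) after the angle has visited both signs. The reported cycle
#' boundaries are then anchored at the neutral dwell points - the |angle|
#' minima between excursions - so that, on clean data, they coincide with
#' the true neutral-to-neutral cycle limits. Partial excursions at the end
#' of the trial are discarded. The two extrema inside a cycle define its
#' sub-block boundaries (neutral->extreme1, extreme1->extreme2,
#' extreme2->neutral).
#'
#' @param angle Filtered primary-angle series, deg.
#' @param fs Sampling rate, Hz (default 100).
#' @param enter_frac Neutral-band (re-entry) threshold as a fraction of
#'   peak `|angle|` (default 0.10).
#' @param exit_frac Departure threshold (hysteresis), default 0.20.
#' @return List of cycles; each a list with `start`, `end` (sample
#'   indices), `extreme1`, `extreme2` (indices of the two opposite-signed
#'   extrema), `duration_s`. Empty list (with a warning) when no excursion
#'   clears the hysteresis band.
#' @export
segment_cycles <- function(angle, fs = 100, enter_frac = 0.10,
                           exit_frac = 0.20) {
  angle <- as.numeric(angle)
  peak <- max(abs(angle))
  if (peak < 1e-9) {
    warning("segment_cycles: flat signal, no cycles", call. = FALSE)
    return(list())
  }
  enter <- enter_frac * peak
  exit <- exit_frac * peak
  if (abs(angle[1]) > exit)
    stop("segment_cycles: series does not start inside the neutral band",
         call. = FALSE)
  cycles <- list()
  n <- length(angle)
  prev_end <- 1L
  i <- 1L
  while (i <= n) {
    # wait inside neutral territory until the angle leaves the exit band
    while (i <= n && abs(angle[i]) <= exit) i <- i + 1L
    if (i > n) break
    # cycle start: the neutral dwell point (|angle| minimum) preceding the
    # departure; the last such sample so that leading rest is not included
    win <- prev_end:(i - 1L)
    aw <- abs(angle[win])
    start <- win[max(which(aw == min(aw)))]
    seen_pos <- FALSE; seen_neg <- FALSE
    j <- i
    while (j <= n) {
      if (angle[j] > exit) seen_pos <- TRUE
      if (angle[j] < -exit) seen_neg <- TRUE
      if (seen_pos && seen_neg && abs(angle[j]) <= enter) break
      j <- j + 1L
    }
    if (j > n) break  # partial excursion at trial end: discard
    # cycle end: first |angle| minimum of the dwell that follows re-entry
    k <- j
    while (k < n && abs(angle[k + 1L]) <= exit) k <- k + 1L
    dwell <- j:k
    ad <- abs(angle[dwell])
    end <- dwell[which.min(ad)]
    seg <- angle[start:end]
    i1 <- which.max(seg); i2 <- which.min(seg)
    if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
    cycles[[length(cycles) + 1L]] <- list(
      start = start, end = end,
      extreme1 = start + i1 - 1L, extreme2 = start + i2 - 1L,
      duration_s = (end - start) / fs)
    prev_end <- end
    i <- max(end, j) + 1L
  }
  if (!length(cycles))
    warning("segment_cycles: no complete cycles detected", call. = FALSE)
  cycles
}

#' Extract and time-normalize one movement cycle
#'
#' Cuts the primary angle (and optionally per-muscle envelopes) over a
#' segmented cycle span and linearly resamples to 101 points spanning
#' 0-100% of the cycle. Endpoint samples are preserved exactly.
#'
#' @param angle Primary-angle series, deg.
#' @param span One element of the list returned by [segment_cycles()].
#' @param envelopes Optional n x m matrix of muscle envelopes on the same
#'   timeline.
#' @param motion_type Motion label carried on the cycle.
#' @return Object of class `movement_cycle`: `angle` (length 101),
#'   `envelopes` (101 x m or `NULL`), `duration_s`, `motion_type`,
#'   `subblocks` (% cycle positions of the two extrema).
#' @export
extract_cycle <- function(angle, span, envelopes = NULL,
                          motion_type = "axial_rotation") {
  idx <- span$start:span$end
  grid <- seq(span$start, span$end, length.out = 101L)
  a <- approx(idx, angle[idx], xout = grid)$y
  env <- NULL
  if (!is.null(envelopes)) {
    envelopes <- as.matrix(envelopes)
    env <- apply(envelopes[idx, , drop = FALSE], 2L, function(e)
      approx(idx, e, xout = grid)$y)
  }
  structure(list(angle = a, envelopes = env, duration_s = span$duration_s,
                 motion_type = motion_type,
                 subblocks = 100 * (c(span$extreme1, span$extreme2) - span$start) /
                   (span$end - span$start)),
            class = "movement_cycle")
}

#' Average time-normalized movement cycles
#'
#' Pointwise arithmetic mean of the 101-point angle profiles (and
#' envelopes) of the supplied cycles, with the mean duration. Cycles are
#' averaged as given; [analyze_trial()] phase-aligns them first (by the
#' sign of the first extremum) so that opposite-phase cycles do not cancel.
#'
#' @param cycles List of `movement_cycle` objects of the same motion type.
#' @return A mean `movement_cycle`.
#' @export
time_normalize_and_average <- function(cycles) {
  if (!length(cycles))
    stop("time_normalize_and_average: no cycles", call. = FALSE)
  types <- unique(vapply(cycles, function(c) c$motion_type, ""))
  if (length(types) != 1L)
    stop("time_normalize_and_average: mixed motion types: ",
         paste(types, collapse = ", "), call. = FALSE)
  ang <- rowMeans(vapply(cycles, function(c) c$angle, numeric(101L)))
  env <- NULL
  if (!is.null(cycles[[1]]$envelopes)) {
    m <- ncol(cycles[[1]]$envelopes)
    env <- matrix(0, 101L, m, dimnames = dimnames(cycles[[1]]$envelopes))
    for (c in cycles) env <- env + c$envelopes
    env <- env / length(cycles)
  }
  structure(list(angle = ang, envelopes = env,
                 duration_s = mean(vapply(cycles, function(c) c$duration_s, 0)),
                 motion_type = types,
                 subblocks = rowMeans(vapply(cycles, function(c) c$subblocks,
                                             numeric(2L)))),
            class = "movement_cycle")
}

#' Outcome variables of a movement cycle
#'
#' Completion time, signed peak angles, range of motion (max - min) and,
#' when envelopes are attached, each muscle's EMG peak timing as percent of
#' the cycle (argmax of the envelope; ties resolve to the earliest sample).
#'
#' @param cycle A `movement_cycle`.
#' @return List of class `cycle_outcome`: `completion_time_s`,
#'   `max_angle_deg`, `min_angle_deg`, `rom_deg`, `emg_peak_timing_pct`
#'   (named vector or `NULL`).
#' @export
compute_outcomes <- function(cycle) {
  stopifnot(inherits(cycle, "movement_cycle"))
  mx <- max(cycle$angle); mn <- min(cycle$angle)
  timing <- NULL
  if (!is.null(cycle$envelopes)) {
    timing <- apply(cycle$envelopes, 2L, function(e) (which.max(e) - 1L))
    timing <- timing * 100 / (length(cycle$angle) - 1L)
  }
  structure(list(completion_time_s = cycle$duration_s,
                 max_angle_deg = mx, min_angle_deg = mn, rom_deg = mx - mn,
                 emg_peak_timing_pct = timing,
                 motion_type = cycle$motion_type),
            class = "cycle_outcome")
}

#' Paired pre/post statistics
#'
#' Paired t test with 95% confidence interval on post - pre differences,
#' the analysis applied to each outcome variable across the cohort.
#' Zero-variance differences are handled explicitly: nonzero mean gives
#' `t = +/-Inf`, `p = 0`; an all-zero difference vector is flagged
#' degenerate with `p = 1`.
#'
#' @param pre,post Paired per-subject values (equal length, n >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `paired_stats`: `n`, `mean_diff`, `ci_low`,
#'   `ci_high`, `t_stat`, `df`, `p_value`, `significant`, `degenerate`.
#' @export
paired_stats <- function(pre, post, conf_level = 0.95, alpha = 0.05) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post))
    stop("paired_stats: unequal lengths", call. = FALSE)
  n <- length(pre)
  if (n < 2L) stop("paired_stats: need n >= 2 pairs", call. = FALSE)
  d <- post - pre
  m <- mean(d)
  s <- sd(d)
  df <- n - 1L
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  degenerate <- FALSE
  if (s < .Machine$double.eps^0.5 * max(1, abs(m))) {
    if (abs(m) < .Machine$double.eps^0.5) {
      t_stat <- NA_real_; p <- 1; ci <- c(m, m); degenerate <- TRUE
    } else {
      t_stat <- sign(m) * Inf; p <- 0; ci <- c(m, m)
    }
  } else {
    se <- s / sqrt(n)
    t_stat <- m / se
    p <- 2 * pt(-abs(t_stat), df)
    ci <- m + c(-1, 1) * tcrit * se
  }
  structure(list(n = n, mean_diff = m, ci_low = ci[1], ci_high = ci[2],
                 t_stat = t_stat, df = df, p_value = p,
                 significant = is.finite(p) && p < alpha,
                 degenerate = degenerate),
            class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  cat(sprintf("paired t: n=%d, mean diff %.4g (95%% CI %.4g to %.4g), t=%.4g, df=%d, p=%.4g%s\n",
              x$n, x$mean_diff, x$ci_low, x$ci_high, x$t_stat, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Per-trial analysis: filter, segment, normalize, average, outcomes
#'
#' Convenience wrapper running the full single-trial analysis: zero-phase
#' low-pass of the primary angle, cycle segmentation, phase alignment by
#' the sign of the first extremum, time normalization, averaging, and
#' outcome computation.
#'
#' @param angles n x 3 head-angle matrix (deg) at `fs` Hz.
#' @param motion_type Motion label selecting the primary plane.
#' @param envelopes Optional n x m EMG envelope matrix on the same
#'   timeline.
#' @param fs Sampling rate (default 100).
#' @param prefilter Apply [filter_angles()] first (default `TRUE`).
#' @return List with `cycles` (list of `movement_cycle`), `mean_cycle`,
#'   `outcome` (of the mean cycle), `per_cycle_outcomes`.
#' @export
analyze_trial <- function(angles, motion_type, envelopes = NULL, fs = 100,
                          prefilter = TRUE) {
  primary <- as.matrix(angles)[, primary_plane(motion_type)]
  if (prefilter) primary <- filter_angles(primary, fs = fs)
  spans <- segment_cycles(primary, fs = fs)
  if (!length(spans))
    return(list(cycles = list(), mean_cycle = NULL, outcome = NULL,
                per_cycle_outcomes = list()))
  cycles <- lapply(spans, function(s)
    extract_cycle(primary, s, envelopes, motion_type))
  # phase-align by the sign of the first extremum: movements where the
  # participant went the other way first are mirrored in time so that
  # averaging does not cancel opposite-phase cycles
  lead_sign <- vapply(cycles, function(c) {
    half <- c$angle[1:51]
    sign(half[which.max(abs(half))[1]])
  }, 0)
  ref <- lead_sign[1]
  aligned <- lapply(seq_along(cycles), function(k) {
    c <- cycles[[k]]
    if (lead_sign[k] != ref && lead_sign[k] != 0) {
      c$angle <- rev(c$angle)
      if (!is.null(c$envelopes))
        c$envelopes <- c$envelopes[101:1, , drop = FALSE]
      c$subblocks <- sort(100 - c$subblocks)
    }
    c
  })
  mean_cycle <- time_normalize_and_average(aligned)
  list(cycles = aligned, mean_cycle = mean_cycle,
       outcome = compute_outcomes(mean_cycle),
       per_cycle_outcomes = lapply(aligned, compute_outcomes))
}
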