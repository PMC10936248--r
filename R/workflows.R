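#' Head poses from a marker trial
#'
#' Reconstructs, per sample, the head rigid-body frame and the head-top
#' position expressed in the per-sample trunk frame, together with the
#' neutral head frame from the static trial.
#'
#' @param trial Dynamic trial (named list of n x 3 lab-frame marker
#'   matrices).
#' @param static_trial Static (neutral) trial from the same session.
#' @return List with `p_top` (n x 3, trunk frame mm), `R_head` (list of
#'   3x3, trunk frame), `R_head_neutral` (3x3), `head_angles` (n x 3 deg,
#'   decomposed relative to the neutral head frame).
#' @export
head_poses_from_markers <- function(trial, static_trial) {
  ref <- build_reference_frame(static_trial)
  # neutral head orientation expressed in the neutral trunk frame
  Hn <- crossprod(ref$trunk$orientation, ref$head$orientation)
  trunks <- trunk_frames_per_sample(trial)
  n <- nrow(trial$C7)
  p_top <- matrix(0, n, 3L)
  R_head <- vector("list", n)
  ang <- matrix(0, n, 3L,
                dimnames = list(NULL, c("flexion_extension", "lateral_bending",
                                        "axial_rotation")))
  neutral_pose <- pose(c(0, 0, 0), Hn, check = FALSE)
  for (i in seq_len(n)) {
    Rt <- trunks[[i]]$orientation
    ot <- trunks[[i]]$position
    mid <- (trial$HEAD_L[i, ] + trial$HEAD_R[i, ]) / 2
    zy <- orthonormal_frame(trial$HEAD_TOP[i, ] - mid,
                            trial$HEAD_L[i, ] - trial$HEAD_R[i, ])
    Hlab <- cbind(crossprod_vec(zy[, 2], zy[, 1]), zy[, 2], zy[, 1])
    H <- crossprod(Rt, Hlab)              # head frame in trunk coords
    p_top[i, ] <- crossprod(Rt, trial$HEAD_TOP[i, ] - ot)
    R_head[[i]] <- H
    ang[i, ] <- as.numeric(head_angles_from_pose(
      pose(p_top[i, ], H, check = FALSE), neutral_pose))
  }
  list(p_top = p_top, R_head = R_head, R_head_neutral = Hn,
       head_angles = ang)
}

#' Joint trajectories from motion capture by inverse kinematics
#'
#' Converts marker-derived head poses into end-effector pose targets in the
#' brace base frame (base at the C7 marker, oriented by the mounting) and
#' solves the joint trajectory by warm-started inverse kinematics. The
#' brace is assumed zeroed at the neutral posture, so the end-effector
#' orientation target is the neutral forward-kinematics orientation rotated
#' by the marker-derived relative head rotation.
#'
#' @param poses Output of [head_poses_from_markers()].
#' @param chain A `dh_chain`.
#' @param mount Mounting matrix (default [default_mounting()]).
#' @return The [ik_trajectory()] result (`q`, residuals, `converged`).
#' @export
ik_from_mocap <- function(poses, chain, mount = default_mounting()) {
  R6n <- forward_kinematics(chain, rep(0, 6))$orientation
  Hn <- poses$R_head_neutral
  n <- nrow(poses$p_top)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    Rrel <- poses$R_head[[i]] %*% t(Hn)    # trunk/anatomical axes
    T <- diag(4)
    T[1:3, 1:3] <- mount %*% Rrel %*% t(mount) %*% R6n
    T[1:3, 4] <- mount %*% poses$p_top[i, ]
    targets[[i]] <- T
  }
  ik_trajectory(chain, targets, q_init = rep(0, 6))
}

#' Calibrate the brace from a recorded (or synthetic) session
#'
#' Full model-matching workflow: marker trials are converted to joint-angle
#' trajectories by inverse kinematics, interpolated onto the brace
#' timeline, pooled across the session's motion trials, and used to fit
#' the per-joint voltage-to-angle polynomials (with optional head-angle
#' refinement). Neutral voltages are averaged over the initial neutral
#' rest of each trial.
#'
#' @param session A `synthetic_session` (or an object with the same shape:
#'   `markers`, `trials` with `voltages`, `chain`, `mount`).
#' @param degree Polynomial degree (default 3).
#' @param refine Stage-2 head-angle refinement (default `TRUE`).
#' @param neutral_window_s Initial span averaged for neutral voltages
#'   (default 0.4 s).
#' @return A `calibration_model`.
#' @export
calibrate_session <- function(session, degree = 3, refine = TRUE,
                              neutral_window_s = 0.4) {
  chain <- session$chain
  mount <- session$mount %||% default_mounting()
  static_trial <- session$markers$trials$static
  if (is.null(static_trial))
    stop("calibrate_session: session has no static trial", call. = FALSE)
  V_all <- NULL; q_all <- NULL; neutral_rows <- NULL
  fs_m <- session$markers$sample_rate
  for (m in setdiff(names(session$markers$trials), "static")) {
    tr <- session$trials[[m]]
    poses <- head_poses_from_markers(session$markers$trials[[m]], static_trial)
    ik <- ik_from_mocap(poses, chain, mount)
    tm <- seq(0, by = 1 / fs_m, length.out = nrow(ik$q))
    tb <- tr$voltages$time_s
    keep <- tb >= min(tm) & tb <= max(tm)
    q_b <- vapply(1:6, function(j) approx(tm, ik$q[, j], xout = tb[keep])$y,
                  numeric(sum(keep)))
    V_all <- rbind(V_all, tr$voltages$volts[keep, , drop = FALSE])
    q_all <- rbind(q_all, q_b)
    neutral_rows <- rbind(neutral_rows,
                          tr$voltages$volts[tb <= neutral_window_s, ,
                                            drop = FALSE])
  }
  fit_calibration(V_all, q_all, degree = degree, chain = chain,
                  refine = refine,
                  neutral_voltages = colMeans(neutral_rows), mount = mount)
}

#' Validate a calibration against motion capture
#'
#' Reconstructs head angles from the session's voltage streams through the
#' calibrated model and forward kinematics, derives reference head angles
#' from the marker streams, low-pass filters both (zero-lag 4th-order
#' Butterworth, 6 Hz), and reports primary-plane errors per trial.
#'
#' @param model A `calibration_model`.
#' @param session Session to validate on (held out from calibration).
#' @param prefilter Apply the 6 Hz zero-phase low-pass to both series
#'   before differencing (default `TRUE`).
#' @return A `validation_report` (see [validation_errors()]).
#' @export
validate_session <- function(model, session, prefilter = TRUE) {
  chain <- session$chain
  mount <- session$mount %||% default_mounting()
  static_trial <- session$markers$trials$static
  fs_m <- session$markers$sample_rate
  trials <- list()
  for (m in setdiff(names(session$markers$trials), "static")) {
    tr <- session$trials[[m]]
    brace <- apply_calibration(model, tr$voltages, chain, mount)
    poses <- head_poses_from_markers(session$markers$trials[[m]], static_trial)
    tm <- seq(0, by = 1 / fs_m, length.out = nrow(poses$head_angles))
    tb <- tr$voltages$time_s
    keep <- tb >= min(tm) & tb <= max(tm)
    mocap <- vapply(colnames(brace$angles), function(cn)
      approx(tm, poses$head_angles[, cn], xout = tb[keep])$y,
      numeric(sum(keep)))
    b <- brace$angles[keep, , drop = FALSE]
    if (prefilter) {
      fs_b <- tr$voltages$sample_rate
      b <- filter_angles(b, fs = fs_b)
      mocap <- filter_angles(mocap, fs = fs_b)
    }
    trials[[m]] <- list(brace = b, mocap = mocap, motion = m)
  }
  validation_errors(trials)
}

#' Synthetic pre/post cohort with an injected range-of-motion deficit
#'
#' Generates paired pre- and post-operative single-plane trials for a small
#' cohort. Each subject draws individual movement amplitudes (between-
#' subject SD around the stated-world defaults); post-operatively the
#' amplitude toward the affected (positive, dissected-side) extreme is
#' reduced by exactly `delta_deg`. Streams include full within-trial noise.
#'
#' @param n_subjects Cohort size (default 5).
#' @param motion Motion type (default `"lateral_bending"`).
#' @param delta_deg Injected pre -> post decrease of the positive-side
#'   amplitude, deg (default 8).
#' @param between_sd_deg Between-subject SD of baseline amplitudes
#'   (default 3).
#' @param seed Integer seed.
#' @param chain,sensor_map,mount Device model (defaults as elsewhere).
#' @param streams Streams to generate per trial (default voltage only; the
#'   recovery analysis needs no markers or EMG).
#' @return List of subjects; each has `pre` and `post` `synthetic_trial`
#'   objects and `amplitudes` (the generator ground truth).
#' @export
generate_cohort <- function(n_subjects = 5, motion = "lateral_bending",
                            delta_deg = 8, between_sd_deg = 3, seed = 1,
                            chain = default_chain(),
                            sensor_map = default_sensor_map(),
                            mount = default_mounting(),
                            streams = "voltage") {
  set.seed(seed)
  base_amp <- synthetic_spec(motion)$amplitude_deg
  subjects <- vector("list", n_subjects)
  subj_seeds <- sample.int(2^30, 2 * n_subjects)
  for (s in seq_len(n_subjects)) {
    amp_pre <- pmax(base_amp + rnorm(2, 0, between_sd_deg), 10)
    amp_post <- amp_pre - c(delta_deg, 0)
    sp_pre <- synthetic_spec(motion, amplitude_deg = amp_pre)
    sp_post <- synthetic_spec(motion, amplitude_deg = amp_post)
    subjects[[s]] <- list(
      pre = generate_trial(sp_pre, chain, sensor_map, mount,
                           seed = subj_seeds[2 * s - 1], streams = streams,
                           participant = paste0("S", s), visit = "pre"),
      post = generate_trial(sp_post, chain, sensor_map, mount,
                            seed = subj_seeds[2 * s], streams = streams,
                            participant = paste0("S", s), visit = "post"),
      amplitudes = list(pre = amp_pre, post = amp_post))
  }
  subjects
}

#' Pre/post peak-angle change recovered through the full pipeline
#'
#' For each subject of a synthetic cohort, reconstructs head angles from
#' the voltage stream through a calibration model, runs the single-trial
#' analysis (6 Hz zero-phase filter, cycle segmentation, time
#' normalization, averaging) and takes the mean-cycle peak (maximum) angle
#' in the primary plane; then compares visits with the paired t test.
#'
#' @param cohort Output of [generate_cohort()].
#' @param model A `calibration_model` for the device (one model; the device
#'   is calibrated once, not per patient).
#' @param chain,mount Device model.
#' @param motion Motion type analyzed.
#' @return List with `stats` ([paired_stats()] on post - pre peak angle),
#'   `pre`, `post` (per-subject peak angles, deg).
#' @export
cohort_peak_angle_change <- function(cohort, model, chain = default_chain(),
                                     mount = default_mounting(),
                                     motion = "lateral_bending") {
  peak <- function(trial) {
    rec <- apply_calibration(model, trial$voltages, chain, mount)
    res <- analyze_trial(rec$angles, motion, fs = trial$voltages$sample_rate)
    if (is.null(res$outcome))
      stop("cohort_peak_angle_change: no cycles detected", call. = FALSE)
    res$outcome$max_angle_deg
  }
  pre <- vapply(cohort, function(s) peak(s$pre), 0)
  post <- vapply(cohort, function(s) peak(s$post), 0)
  list(stats = paired_stats(pre, post), pre = pre, post = post)
}
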