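#' Assemble a potentiometer voltage log
#'
#' One channel per joint (channel i is the potentiometer on joint Ji),
#' sampled by the brace microcontroller.
#'
#' @param time_s Timestamps, s.
#' @param volts n x 6 matrix of voltages (V).
#' @param trigger 0/1 synchronization pulse per sample, or `NULL`.
#' @param sample_rate Hz (default 100).
#' @param v_supply Supply voltage bounding valid readings (default 3.3 V).
#' @return Object of class `voltage_log`.
#' @export
voltage_log <- function(time_s, volts, trigger = NULL, sample_rate = 100,
                        v_supply = 3.3) {
  volts <- as.matrix(volts)
  stopifnot(ncol(volts) == 6L, length(time_s) == nrow(volts))
  if (!all(is.finite(volts)))
    stop("voltage_log: non-finite voltages", call. = FALSE)
  if (any(volts < 0 | volts > v_supply))
    stop("voltage_log: voltages outside [0, V_supply]", call. = FALSE)
  colnames(volts) <- paste0("v", 1:6)
  structure(list(time_s = as.numeric(time_s), volts = volts,
                 trigger = trigger, sample_rate = sample_rate,
                 v_supply = v_supply),
            class = "voltage_log")
}

poly_eval <- function(coefs, x) {
  # coefs in increasing powers
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[k]
  y
}

#' Fit per-joint voltage-to-angle calibration polynomials
#'
#' Stage 1 fits, for each joint independently, a least-squares polynomial
#' mapping potentiometer voltage to the joint angle obtained by inverse
#' kinematics from synchronized motion-capture data. Stage 2 (on by
#' default) refines all coefficients jointly by minimizing the summed
#' squared head-angle error between the forward-kinematics reconstruction
#' and the reference head angles, which is the quantity the device actually
#' reports.
#'
#' @param voltages A [voltage_log()] or n x 6 voltage matrix, time-aligned
#'   with `q_ik` (see [synchronize()]).
#' @param q_ik n x 6 matrix of reference joint angles (rad).
#' @param degree Polynomial degree, 1-5 (default 3).
#' @param chain A `dh_chain`; required when `refine = TRUE`.
#' @param refine Run the stage-2 head-angle refinement (default `TRUE`).
#' @param neutral_voltages Voltages at the neutral posture (default: column
#'   means of the samples where all reference joint angles are smallest in
#'   magnitude - the first sample by convention in recorded sessions).
#' @param refine_subsample Maximum samples used in the stage-2 objective
#'   (default 300).
#' @return Object of class `calibration_model`: per-joint coefficients
#'   (increasing powers, angle rad as a function of voltage), degree,
#'   per-joint RMS residual (rad), observed voltage ranges, neutral
#'   voltages, monotonicity diagnostic.
#' @export
fit_calibration <- function(voltages, q_ik, degree = 3, chain = NULL,
                            refine = TRUE, neutral_voltages = NULL,
                            refine_subsample = 300L,
                            mount = default_mounting()) {
  V <- if (inherits(voltages, "voltage_log")) voltages$volts else as.matrix(voltages)
  q_ik <- as.matrix(q_ik)
  stopifnot(ncol(V) == 6L, ncol(q_ik) == 6L)
  if (nrow(V) != nrow(q_ik))
    stop("fit_calibration: voltages and joint angles are not aligned",
         call. = FALSE)
  if (degree < 1 || degree > 5)
    stop("fit_calibration: degree must be in 1..5", call. = FALSE)
  n <- nrow(V)
  if (n <= degree + 1L)
    stop(sprintf("fit_calibration: %d samples insufficient for degree %d",
                 n, degree), call. = FALSE)
  # polynomials are parameterized in the centered/scaled voltage
  # u = (V - center)/scale for numerical conditioning of the Vandermonde fit
  center <- colMeans(V)
  scale <- apply(V, 2L, function(v) max(max(v) - min(v), 1e-12)) / 2
  coefs <- matrix(0, 6L, degree + 1L)
  for (j in 1:6) {
    vj <- V[, j]
    if (max(vj) - min(vj) < 1e-9)
      stop(sprintf("fit_calibration: joint J%d has constant voltage (rank-deficient design)", j),
           call. = FALSE)
    X <- outer((vj - center[j]) / scale[j], 0:degree, `^`)
    coefs[j, ] <- as.numeric(solve(crossprod(X), crossprod(X, q_ik[, j])))
  }
  if (is.null(neutral_voltages)) neutral_voltages <- V[1L, ]
  if (refine) {
    if (is.null(chain))
      stop("fit_calibration: stage-2 refinement needs the chain model",
           call. = FALSE)
    idx <- unique(round(seq(1L, n, length.out = min(refine_subsample, n))))
    R_neutral <- forward_kinematics(chain, rep(0, 6))$orientation
    ref_angles <- t(apply(q_ik[idx, , drop = FALSE], 1L, function(q)
      as.numeric(head_angles_relative(
        forward_kinematics(chain, q)$orientation, R_neutral, mount))))
    Vsub <- V[idx, , drop = FALSE]
    objective <- function(theta) {
      cf <- matrix(theta, 6L, degree + 1L)
      err <- 0
      for (i in seq_along(idx)) {
        qhat <- vapply(1:6, function(j)
          poly_eval(cf[j, ], (Vsub[i, j] - center[j]) / scale[j]), 0)
        ha <- head_angles_relative(
          forward_kinematics(chain, qhat)$orientation, R_neutral, mount)
        err <- err + sum((as.numeric(ha) - ref_angles[i, ])^2)
      }
      err
    }
    opt <- stats::optim(as.numeric(coefs), objective, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-10))
    coefs <- matrix(opt$par, 6L, degree + 1L)
  }
  resid <- vapply(1:6, function(j)
    sqrt(mean((poly_eval(coefs[j, ], (V[, j] - center[j]) / scale[j]) -
                 q_ik[, j])^2)), 0)
  vrange <- t(apply(V, 2L, range))
  monotone <- vapply(1:6, function(j) {
    grid <- seq(vrange[j, 1], vrange[j, 2], length.out = 201)
    dd <- diff(poly_eval(coefs[j, ], (grid - center[j]) / scale[j]))
    all(dd >= 0) || all(dd <= 0)
  }, TRUE)
  if (!all(monotone))
    warning("calibration polynomial not monotone over the observed range for joint(s) ",
            paste(which(!monotone), collapse = ", "), call. = FALSE)
  structure(list(coefficients = coefs, degree = degree,
                 center = as.numeric(center), scale = as.numeric(scale),
                 rms_residual_rad = resid, voltage_range = vrange,
                 neutral_voltages = as.numeric(neutral_voltages),
                 monotone = monotone),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> degree %d; per-joint RMS residual (deg): %s\n",
              x$degree,
              paste(sprintf("%.3f", x$rms_residual_rad * 180 / pi),
                    collapse = ", ")))
  invisible(x)
}

#' Reconstruct head angles from potentiometer voltages
#'
#' Maps each voltage sample through the per-joint calibration polynomials
#' to joint angles, runs forward kinematics, and expresses the head pose as
#' anatomical angles relative to the neutral posture (the pose at the
#' stored neutral voltages). Samples whose voltage falls outside the
#' calibrated range by more than the extrapolation guard are flagged but
#' not dropped.
#'
#' @param model A `calibration_model`.
#' @param voltages A [voltage_log()] or n x 6 matrix.
#' @param chain A `dh_chain`.
#' @param mount Mounting matrix giving the anatomical axes in the base
#'   frame (default [default_mounting()]); the end-effector frame itself is
#'   not anatomically aligned, so the relative rotation is conjugated
#'   through it (see [head_angles_relative()]).
#' @param guard Extrapolation guard as a fraction of the calibrated span
#'   (default 0.05).
#' @return List of class `head_angle_series`: `time_s`, `angles` (n x 3,
#'   deg: flexion_extension, lateral_bending, axial_rotation), `q` (n x 6
#'   rad), `out_of_range` (logical), `trigger`, `sample_rate`.
#' @export
apply_calibration <- function(model, voltages, chain,
                              mount = default_mounting(), guard = 0.05) {
  vl <- if (inherits(voltages, "voltage_log")) voltages else
    voltage_log(seq_len(nrow(as.matrix(voltages))) / 100, voltages)
  V <- vl$volts
  if (ncol(V) != nrow(model$coefficients))
    stop("apply_calibration: model/chain joint-count mismatch", call. = FALSE)
  n <- nrow(V)
  Q <- matrix(0, n, 6L)
  oob <- rep(FALSE, n)
  for (j in 1:6) {
    rng <- model$voltage_range[j, ]
    tol <- guard * (rng[2] - rng[1])
    oob <- oob | V[, j] < rng[1] - tol | V[, j] > rng[2] + tol
    Q[, j] <- poly_eval(model$coefficients[j, ],
                        (V[, j] - model$center[j]) / model$scale[j])
  }
  q_neutral <- vapply(1:6, function(j)
    poly_eval(model$coefficients[j, ],
              (model$neutral_voltages[j] - model$center[j]) / model$scale[j]), 0)
  R_neutral <- forward_kinematics(chain, q_neutral)$orientation
  ang <- matrix(0, n, 3L,
                dimnames = list(NULL, c("flexion_extension", "lateral_bending",
                                        "axial_rotation")))
  for (i in seq_len(n)) {
    ang[i, ] <- as.numeric(head_angles_relative(
      forward_kinematics(chain, Q[i, ])$orientation, R_neutral, mount))
  }
  structure(list(time_s = vl$time_s, angles = ang, q = Q,
                 out_of_range = oob, trigger = vl$trigger,
                 sample_rate = vl$sample_rate),
            class = "head_angle_series")
}

#' Primary angle column for a motion type
#' @keywords internal
primary_plane <- function(motion_type) {
  switch(motion_type,
         axial_rotation = "axial_rotation",
         lateral_bending = "lateral_bending",
         flexion_extension = "flexion_extension",
         stop("unknown motion type: ", motion_type, call. = FALSE))
}

#' Validation errors of brace-reconstructed head angles
#'
#' Compares brace and motion-capture head-angle series trial by trial on
#' the primary angle of each single-plane motion, reporting the maximum
#' absolute difference and the RMS difference per trial, plus two
#' aggregates: the group maximum error, and the mean RMS over trials (the
#' reporting rule used for the device's validation).
#'
#' @param trials List of trials; each a list with `brace` (n x 3 angle
#'   matrix, deg), `mocap` (same shape, same timeline) and `motion` (one of
#'   `"axial_rotation"`, `"lateral_bending"`, `"flexion_extension"`).
#' @return Object of class `validation_report`: data.frame `per_trial`
#'   (motion, max_abs_error_deg, rms_error_deg), `max_error_deg`,
#'   `mean_rms_deg`, and `per_plane` (aggregates split by plane).
#' @export
validation_errors <- function(trials) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    col <- primary_plane(tr$motion)
    b <- as.matrix(tr$brace)[, col]
    m <- as.matrix(tr$mocap)[, col]
    if (length(b) != length(m))
      stop(sprintf("validation_errors: trial %d: series lengths differ (%d vs %d)",
                   i, length(b), length(m)), call. = FALSE)
    d <- b - m
    data.frame(trial = i, motion = tr$motion,
               max_abs_error_deg = max(abs(d)),
               rms_error_deg = sqrt(mean(d^2)))
  })
  per_trial <- do.call(rbind, rows)
  per_plane <- do.call(rbind, lapply(split(per_trial, per_trial$motion),
    function(g) data.frame(motion = g$motion[1],
                           max_error_deg = max(g$max_abs_error_deg),
                           mean_rms_deg = mean(g$rms_error_deg))))
  rownames(per_plane) <- NULL
  structure(list(per_trial = per_trial,
                 max_error_deg = max(per_trial$max_abs_error_deg),
                 mean_rms_deg = mean(per_trial$rms_error_deg),
                 per_plane = per_plane),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$per_trial, row.names = FALSE, digits = 4)
  cat(sprintf("group max error %.3f deg; mean RMS %.3f deg\n",
              x$max_error_deg, x$mean_rms_deg))
  invisible(x)
}

#' Save / load a calibration model as JSON
#' @param model A `calibration_model`.
#' @param path Output path.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(list(
    degree = model$degree,
    center = model$center,
    scale = model$scale,
    coefficients = model$coefficients,
    rms_residual_rad = model$rms_residual_rad,
    voltage_range = model$voltage_range,
    neutral_voltages = model$neutral_voltages,
    monotone = model$monotone), path, auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  structure(list(coefficients = as.matrix(j$coefficients),
                 degree = j$degree,
                 center = as.numeric(j$center),
                 scale = as.numeric(j$scale),
                 rms_residual_rad = as.numeric(j$rms_residual_rad),
                 voltage_range = as.matrix(j$voltage_range),
                 neutral_voltages = as.numeric(j$neutral_voltages),
                 monotone = as.logical(j$monotone)),
            class = "calibration_model")
}
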