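#' Six-revolute-joint serial chain model
#'
#' Constructs the Denavit-Hartenberg model of the brace: a serial chain of
#' six revolute joints whose base is mounted at the C7 vertebra and whose
#' end-effector P attaches to the top of the head. The standard (distal)
#' convention is used: each joint transform is
#' `Rot_z(theta0 + q) %*% Trans_z(d) %*% Trans_x(a) %*% Rot_x(alpha)`.
#'
#' Structural constraints mirror the anatomy the device emulates: the axes
#' of J1 and J2 are parallel (lower cervical flexion/extension), J3 and J4
#' are perpendicular to them (lateral bending during flexion/extension), and
#' the axes of J4, J5 and J6 intersect at a common point C that plays the
#' role of the atlanto-axial "ball joint". `validate = TRUE` checks all of
#' these numerically at the neutral configuration.
#'
#' @param a Link lengths, mm (length 6).
#' @param alpha Link twists, rad (length 6).
#' @param d Joint offsets, mm (length 6).
#' @param theta0 Joint variable offsets, rad (length 6); the measured joint
#'   angle q is added to these.
#' @param joint_limits 6x2 matrix of per-joint `[min, max]` in rad.
#' @param validate Check the structural axis constraints (default `TRUE`).
#' @return An object of class `dh_chain`.
#' @export
dh_chain <- function(a, alpha, d, theta0 = rep(0, 6),
                     joint_limits = cbind(rep(-pi, 6), rep(pi, 6)),
                     validate = TRUE) {
  stopifnot(length(a) == 6L, length(alpha) == 6L, length(d) == 6L,
            length(theta0) == 6L)
  joint_limits <- matrix(as.numeric(joint_limits), 6L, 2L)
  if (any(!is.finite(c(a, alpha, d, theta0, joint_limits))))
    stop("dh_chain: non-finite parameter", call. = FALSE)
  if (any(joint_limits[, 1] >= joint_limits[, 2]))
    stop("dh_chain: joint limits must satisfy min < max", call. = FALSE)
  chain <- structure(list(
    a = as.numeric(a), alpha = as.numeric(alpha), d = as.numeric(d),
    theta0 = as.numeric(theta0), joint_limits = joint_limits,
    labels = paste0("J", 1:6)
  ), class = "dh_chain")
  if (validate) validate_chain(chain)
  chain
}

chain_params <- function(chain) {
  cbind(chain$a, chain$alpha, chain$d, chain$theta0)
}

#' Validate the structural axis constraints of a brace chain
#'
#' Checks, at the neutral configuration (q = 0): J1 parallel to J2;
#' J3 and J4 perpendicular to J1/J2; J4, J5, J6 concurrent (pairwise
#' common-perpendicular distance below `tol_c` mm).
#'
#' @param chain A `dh_chain`.
#' @param tol_axis Angular tolerance, rad (default 1e-9).
#' @param tol_c Concurrency tolerance, mm (default 1e-6).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_chain <- function(chain, tol_axis = 1e-9, tol_c = 1e-6) {
  fk <- .fk_cpp(chain_params(chain), rep(0, 6))
  ax <- fk$axes        # columns: z of frames 0..6; joint i axis = col i
  or <- fk$origins
  # J1 || J2
  cross12 <- crossprod_vec(ax[, 1], ax[, 2])
  if (sqrt(sum(cross12^2)) > tol_axis)
    stop("chain: axes of J1 and J2 are not parallel", call. = FALSE)
  for (j in 3:4) {
    if (abs(sum(ax[, 1] * ax[, j])) > tol_axis)
      stop(sprintf("chain: axis of J%d is not perpendicular to J1/J2", j),
           call. = FALSE)
  }
  # concurrency of J4, J5, J6
  idx <- 4:6
  for (i in 1:2) for (j in (i + 1):3) {
    dd <- line_line_distance(or[, idx[i]], ax[, idx[i]],
                             or[, idx[j]], ax[, idx[j]])
    if (dd > tol_c)
      stop(sprintf("chain: axes of J%d and J%d do not intersect (gap %.3g mm)",
                   idx[i], idx[j], dd), call. = FALSE)
  }
  invisible(TRUE)
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# common-perpendicular distance between two lines (point, direction)
line_line_distance <- function(p1, u1, p2, u2) {
  n <- crossprod_vec(u1, u2)
  nn <- sqrt(sum(n^2))
  dp <- p2 - p1
  if (nn < 1e-12) {            # parallel lines
    proj <- dp - sum(dp * u1) / sum(u1^2) * u1
    return(sqrt(sum(proj^2)))
  }
  abs(sum(dp * n)) / nn
}

#' Default brace chain
#'
#' The parameter set shipped with the package: an elbow-like proximal pair
#' (J1, J2 parallel, providing the translation that the lower cervical spine
#' contributes during flexion/extension), a perpendicular J3, and a
#' concurrent distal triple J4-J6 forming the spherical "atlanto-axial"
#' wrist at point C, with the end-effector offset d6 placing P at the top of
#' the head. Values are desk-scale (mm) outputs of the design-phase search
#' run against the synthetic workspace and satisfy all structural
#' constraints; the physical device's numeric table is not reproduced here.
#'
#' @return A validated `dh_chain`.
#' @export
default_chain <- function() {
  dh_chain(
    a      = c(62, 62, 25, 0, 0, 0),
    alpha  = c(0, -pi / 2, 0, pi / 2, pi / 2, 0),
    d      = c(0, 0, 40, 0, 0, 60),
    theta0 = c(35, -70, 0, 0, 90, 0) * pi / 180,
    joint_limits = cbind(rep(-2.6, 6), rep(2.6, 6))
  )
}

#' Forward kinematics of the brace chain
#'
#' Pose of the end-effector P in the base (C7) frame for a given vector of
#' joint angles. Pure function: identical inputs give bitwise-identical
#' output.
#'
#' @param chain A `dh_chain`.
#' @param q Numeric vector of 6 joint angles, rad.
#' @return A `brace_pose`.
#' @export
forward_kinematics <- function(chain, q) {
  q <- as.numeric(q)
  if (length(q) != 6L || any(!is.finite(q)))
    stop("forward_kinematics: q must be 6 finite joint angles", call. = FALSE)
  fk <- .fk_cpp(chain_params(chain), q)
  T <- fk$transform
  pose(T[1:3, 4], T[1:3, 1:3], check = FALSE)
}

#' Position of a joint origin along the chain
#'
#' Base-frame position of the origin of joint `joint_index` (the point on
#' that joint's rotation axis fixed in the preceding link). Used by the
#' clearance check, which tracks J4 relative to the head/C1 separating
#' plane.
#'
#' @param chain A `dh_chain`.
#' @param q Joint angles (rad), or a matrix with 6 columns for a trajectory.
#' @param joint_index Integer in 1..6.
#' @return A 3-vector (mm), or an n x 3 matrix for a trajectory input.
#' @export
point_on_chain <- function(chain, q, joint_index) {
  if (!(is.numeric(joint_index) && length(joint_index) == 1L &&
        joint_index %in% 1:6))
    stop("point_on_chain: joint_index must be in 1..6", call. = FALSE)
  par <- chain_params(chain)
  if (is.matrix(q)) {
    t(apply(q, 1L, function(qi) .fk_cpp(par, qi)$origins[, joint_index]))
  } else {
    .fk_cpp(par, as.numeric(q))$origins[, joint_index]
  }
}

#' Location of the concurrency point C
#'
#' Least-squares intersection of the axes of J4, J5 and J6; for a valid
#' chain these axes meet at a single point, the kinematic stand-in for the
#' atlanto-axial joint center.
#'
#' @param chain A `dh_chain`.
#' @param q Joint angles, rad.
#' @return 3-vector, mm, base frame.
#' @export
chain_point_c <- function(chain, q) {
  fk <- .fk_cpp(chain_params(chain), as.numeric(q))
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (j in 4:6) {
    u <- fk$axes[, j]
    P <- diag(3) - tcrossprod(u)   # projector orthogonal to the axis
    A <- A + P
    b <- b + P %*% fk$origins[, j]
  }
  as.numeric(solve(A, b))
}

#' Inverse kinematics by damped least squares
#'
#' Solves for joint angles reproducing a target pose, using
#' Levenberg-Marquardt iteration on a 6-vector pose error (position in mm
#' stacked with axis-angle orientation error scaled by a 100 mm
#' characteristic length), with joint limits enforced by projection.
#' Non-convergence is not an error: the best-found solution is returned with
#' `converged = FALSE` and its residuals, e.g. for targets outside the
#' reachable set.
#'
#' @param chain A `dh_chain`.
#' @param target A `brace_pose` (or 4x4 homogeneous matrix).
#' @param q_init Initial guess (rad); on a trajectory pass the previous
#'   solution here (see [ik_trajectory()]).
#' @param tol_pos Position tolerance in mm for the converged flag (0.5).
#' @param tol_ori Orientation tolerance in degrees for the flag (0.05).
#' @param max_iter Iteration cap (200).
#' @param lambda Initial damping (1e-3, adapted multiplicatively).
#' @param position_only Solve for position only (used by the reachability
#'   screen in the design search).
#' @return List with `q` (rad), `pos_err` (mm), `ori_err` (deg),
#'   `converged`, `iters`.
#' @export
inverse_kinematics <- function(chain, target, q_init = rep(0, 6),
                               tol_pos = 0.5, tol_ori = 0.05,
                               max_iter = 200, lambda = 1e-3,
                               position_only = FALSE) {
  T <- if (inherits(target, "brace_pose")) pose_to_homogeneous(target)
       else as.matrix(target)
  stopifnot(all(dim(T) == c(4L, 4L)))
  r <- .ik_cpp(chain_params(chain), T, as.numeric(q_init),
               chain$joint_limits[, 1], chain$joint_limits[, 2],
               as.integer(max_iter), lambda, 100,
               tol_pos, tol_ori * pi / 180, position_only, 1e-10)
  r$ori_err <- r$ori_err * 180 / pi
  r
}

#' Trajectory inverse kinematics with warm starts
#'
#' Runs [inverse_kinematics()] over a sequence of target poses, seeding each
#' solve with the previous solution so that the joint trajectory is
#' continuous.
#'
#' @param chain A `dh_chain`.
#' @param targets List of `brace_pose` objects (or 4x4 matrices).
#' @param q_init Seed for the first sample.
#' @inheritParams inverse_kinematics
#' @return List with `q` (n x 6 matrix, rad), `pos_err` (mm), `ori_err`
#'   (deg), `converged` (logical vector).
#' @export
ik_trajectory <- function(chain, targets, q_init = rep(0, 6),
                          tol_pos = 0.5, tol_ori = 0.05,
                          max_iter = 200, lambda = 1e-3) {
  Ts <- lapply(targets, function(t)
    if (inherits(t, "brace_pose")) pose_to_homogeneous(t) else as.matrix(t))
  stacked <- do.call(cbind, Ts)
  r <- .ik_traj_cpp(chain_params(chain), stacked, as.numeric(q_init),
                    chain$joint_limits[, 1], chain$joint_limits[, 2],
                    as.integer(max_iter), lambda, 100,
                    tol_pos, tol_ori * pi / 180, FALSE, 1e-10)
  r$ori_err <- r$ori_err * 180 / pi
  r$converged <- as.logical(r$converged)
  r
}

#' Read / write a chain definition file
#'
#' Chain files are YAML or JSON with per-joint entries
#' `{a, alpha, d, theta0, limits}`; angles are stored in degrees and lengths
#' in mm, converted to radians on load.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return `read_chain`: a validated `dh_chain`.
#' @export
read_chain <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  joints <- spec$joints
  if (length(joints) != 6L)
    stop("chain file must define exactly 6 joints", call. = FALSE)
  g <- function(field) vapply(joints, function(j) as.numeric(j[[field]]), 0)
  lim <- t(vapply(joints, function(j) as.numeric(unlist(j$limits)), c(0, 0)))
  dh_chain(a = g("a"), alpha = g("alpha") * pi / 180, d = g("d"),
           theta0 = g("theta0") * pi / 180, joint_limits = lim * pi / 180)
}

#' @rdname read_chain
#' @param chain A `dh_chain` to serialize.
#' @export
write_chain <- function(chain, path) {
  joints <- lapply(1:6, function(i) list(
    a = chain$a[i], alpha = chain$alpha[i] * 180 / pi, d = chain$d[i],
    theta0 = chain$theta0[i] * 180 / pi,
    limits = chain$joint_limits[i, ] * 180 / pi))
  spec <- list(units = list(length = "mm", angle = "deg"), joints = joints)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(spec, path)
  } else {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.dh_chain <- function(x, ...) {
  cat("<dh_chain> 6 revolute joints (standard D-H convention)\n")
  tab <- data.frame(joint = x$labels, a_mm = x$a, alpha_deg = x$alpha * 180 / pi,
                    d_mm = x$d, theta0_deg = x$theta0 * 180 / pi,
                    lim_lo_deg = x$joint_limits[, 1] * 180 / pi,
                    lim_hi_deg = x$joint_limits[, 2] * 180 / pi)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
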