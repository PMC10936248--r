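#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, used throughout the
#' kinematics and head-angle code.
#'
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
rot_x <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(1, 0, 0,
           0, ct, st,
           0, -st, ct), 3, 3)
}

#' @rdname elementary-rotations
rot_y <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, 0, -st,
           0, 1, 0,
           st, 0, ct), 3, 3)
}

#' @rdname elementary-rotations
rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0,
           -st, ct, 0,
           0, 0, 1), 3, 3)
}

#' Construct a rigid-body pose
#'
#' A pose couples a position (mm) with a proper orthonormal orientation
#' matrix, both expressed in the brace base frame (origin at the C7 mount)
#' unless stated otherwise.
#'
#' @param position Numeric 3-vector, mm.
#' @param orientation 3x3 proper orthonormal matrix.
#' @param check Validate orthonormality (default `TRUE`).
#' @return An object of class `brace_pose`.
#' @export
pose <- function(position, orientation, check = TRUE) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3L)
  orientation <- as.matrix(orientation)
  stopifnot(all(dim(orientation) == c(3L, 3L)))
  if (check) {
    if (!all(is.finite(position)) || !all(is.finite(orientation)))
      stop("pose: non-finite position or orientation", call. = FALSE)
    err <- max(abs(crossprod(orientation) - diag(3)))
    if (err > 1e-6)
      stop("pose: orientation is not orthonormal (max |R'R - I| = ",
           format(err), ")", call. = FALSE)
    if (det(orientation) < 0)
      stop("pose: orientation is not proper (det < 0)", call. = FALSE)
  }
  structure(list(position = position, orientation = orientation),
            class = "brace_pose")
}

#' @export
print.brace_pose <- function(x, ...) {
  cat("<pose> position (mm):", paste(signif(x$position, 6), collapse = ", "), "\n")
  cat("orientation:\n")
  print(signif(x$orientation, 6))
  invisible(x)
}

#' Homogeneous transform of a pose
#' @param p A `brace_pose`.
#' @return 4x4 homogeneous matrix.
#' @keywords internal
pose_to_homogeneous <- function(p) {
  T <- diag(4)
  T[1:3, 1:3] <- p$orientation
  T[1:3, 4] <- p$position
  T
}

#' Head angles relative to a neutral pose
#'
#' Decomposes the relative rotation `neutral' * pose` into three anatomical
#' angles using the intrinsic vertical -> anteroposterior -> mediolateral
#' sequence. The anatomical frame convention is x anterior, y toward the
#' subject's left, z superior (up); sign conventions follow clinical usage:
#' positive flexion/extension = extension, positive lateral bending = toward
#' the right (dissected) side, positive axial rotation = toward the right.
#'
#' Near gimbal lock (|lateral bending| within 0.5 degrees of 90) the result
#' carries attribute `degenerate = TRUE`; the axial/sagittal split is then
#' ill-conditioned although their composition is still exact.
#'
#' @param p A `brace_pose` (current head pose).
#' @param neutral A `brace_pose` recorded in the upright neutral posture.
#' @return An object of class `head_angles`: named numeric vector with
#'   components `flexion_extension`, `lateral_bending`, `axial_rotation`
#'   (degrees, each in (-180, 180]).
#' @export
head_angles_from_pose <- function(p, neutral) {
  R <- crossprod(neutral$orientation, p$orientation)
  head_angles_from_rotation(R)
}

#' Head angles from a relative rotation matrix
#' @param R 3x3 relative rotation (neutral -> current).
#' @return `head_angles` vector, degrees.
#' @export
head_angles_from_rotation <- function(R) {
  # Intrinsic z-x-y factorization R = Rz(a) %*% Rx(b) %*% Ry(c):
  #   R[3,2] = sin b;  R[1,2] = -sin a cos b;  R[2,2] = cos a cos b
  #   R[3,1] = -cos b sin c;  R[3,3] = cos b cos c
  sb <- max(-1, min(1, R[3, 2]))
  b <- asin(sb)
  degenerate <- abs(abs(b) - pi / 2) < 0.5 * pi / 180
  if (abs(cos(b)) < 1e-12) {
    # axial and sagittal axes collapse; put all remaining rotation in axial
    a <- atan2(R[2, 1], R[1, 1])
    cc <- 0
  } else {
    a <- atan2(-R[1, 2], R[2, 2])
    cc <- atan2(-R[3, 1], R[3, 3])
  }
  out <- c(flexion_extension = -cc, lateral_bending = b, axial_rotation = -a) * 180 / pi
  structure(out, degenerate = degenerate, class = "head_angles")
}

#' Compose a relative rotation from head angles
#'
#' Inverse of [head_angles_from_rotation()]: rebuilds the relative rotation
#' from the three anatomical angles under the package's fixed convention.
#'
#' @param angles Numeric vector or `head_angles` with components
#'   `flexion_extension`, `lateral_bending`, `axial_rotation` in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_head_angles <- function(angles) {
  a <- -angles[["axial_rotation"]] * pi / 180
  b <- angles[["lateral_bending"]] * pi / 180
  cc <- -angles[["flexion_extension"]] * pi / 180
  rot_z(a) %*% rot_x(b) %*% rot_y(cc)
}

#' @export
print.head_angles <- function(x, ...) {
  cat(sprintf("flexion/extension %+.2f deg, lateral bending %+.2f deg, axial rotation %+.2f deg\n",
              x[["flexion_extension"]], x[["lateral_bending"]], x[["axial_rotation"]]))
  if (isTRUE(attr(x, "degenerate"))) cat("  [degenerate: near gimbal lock]\n")
  invisible(x)
}
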