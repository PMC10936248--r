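#' Marker labels expected in every trial
#' @keywords internal
MARKER_LABELS <- c("C7", "CHEST", "ACR_L", "ACR_R",
                   "C1", "HEAD_TOP", "HEAD_L", "HEAD_R")

#' Assemble a marker session
#'
#' A marker session holds labelled 3-D trajectories of the eight
#' retro-reflective markers that form the two rigid bodies used in the
#' design phase: four on the trunk (C7, chest, left/right acromion) and four
#' on the head (C1, head top = end-effector reference, left/right head).
#'
#' @param trials Named list; each trial is a named list of n x 3 numeric
#'   matrices (mm), one per marker label.
#' @param sample_rate Sampling rate in Hz (default 200).
#' @param kinds Named character vector mapping trial name to
#'   `"static"`/`"dynamic"`; defaults to `"dynamic"` with any trial named
#'   `"static"` marked static.
#' @return An object of class `marker_session`.
#' @export
marker_session <- function(trials, sample_rate = 200, kinds = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1L, !is.null(names(trials)))
  for (nm in names(trials)) {
    tr <- trials[[nm]]
    missing <- setdiff(MARKER_LABELS, names(tr))
    if (length(missing))
      stop(sprintf("trial '%s': missing marker label(s) %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    ns <- vapply(tr[MARKER_LABELS], nrow, 0L)
    if (length(unique(ns)) != 1L)
      stop(sprintf("trial '%s': unequal sample counts across markers", nm),
           call. = FALSE)
    if (!all(vapply(tr[MARKER_LABELS], function(m) all(is.finite(m)), TRUE)))
      stop(sprintf("trial '%s': non-finite marker coordinates", nm),
           call. = FALSE)
  }
  if (is.null(kinds)) {
    kinds <- setNames(ifelse(names(trials) == "static", "static", "dynamic"),
                      names(trials))
  }
  structure(list(trials = trials, sample_rate = sample_rate, kinds = kinds),
            class = "marker_session")
}

# right-handed orthonormal frame from an origin, a primary axis direction
# and a secondary direction (Gram-Schmidt)
orthonormal_frame <- function(x_dir, y_hint) {
  nx <- sqrt(sum(x_dir^2))
  if (nx < 1e-9) stop("degenerate geometry: zero-length axis", call. = FALSE)
  x <- x_dir / nx
  y <- y_hint - sum(y_hint * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9)
    stop("degenerate geometry: collinear markers", call. = FALSE)
  y <- y / ny
  z <- crossprod_vec(x, y)
  cbind(x, y, z)
}

#' Build trunk and head reference frames from a static trial
#'
#' From the time-averaged marker positions of the upright neutral (static)
#' trial, constructs the trunk frame (origin at C7; x anterior from
#' C7 -> chest, y lateral from right to left acromion after
#' orthogonalization, z superior) and the head frame (origin at head top;
#' x anterior, y left from the head side markers, z superior toward
#' HEAD_TOP). Both orientation matrices are proper orthonormal.
#'
#' @param trial One trial from a [marker_session()] (named list of n x 3
#'   matrices).
#' @return List with `trunk` and `head`, both `brace_pose` objects in the
#'   recording (lab) frame.
#' @export
build_reference_frame <- function(trial) {
  missing <- setdiff(MARKER_LABELS, names(trial))
  if (length(missing))
    stop("static trial missing marker label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  avg <- lapply(trial[MARKER_LABELS], colMeans)
  # trunk: x anterior (C7 -> chest), y left (ACR_R -> ACR_L)
  Rt <- orthonormal_frame(avg$CHEST - avg$C7, avg$ACR_L - avg$ACR_R)
  trunk <- pose(avg$C7, Rt)
  # head: z superior (side-midpoint -> head top), y left (HEAD_R -> HEAD_L)
  mid <- (avg$HEAD_L + avg$HEAD_R) / 2
  zy <- orthonormal_frame(avg$HEAD_TOP - mid, avg$HEAD_L - avg$HEAD_R)
  Rh <- cbind(crossprod_vec(zy[, 2], zy[, 1]), zy[, 2], zy[, 1]) # x = y cross z
  head <- pose(avg$HEAD_TOP, Rh)
  list(trunk = trunk, head = head)
}

#' Per-sample trunk frames over a dynamic trial
#'
#' Builds the trunk frame independently at every sample, for use by
#' [to_trunk_frame()] to remove trunk motion from head marker trajectories.
#'
#' @param trial Trial (named list of n x 3 matrices).
#' @return List of `brace_pose`, one per sample.
#' @export
trunk_frames_per_sample <- function(trial) {
  n <- nrow(trial$C7)
  lapply(seq_len(n), function(i) {
    Rt <- orthonormal_frame(trial$CHEST[i, ] - trial$C7[i, ],
                            trial$ACR_L[i, ] - trial$ACR_R[i, ])
    pose(trial$C7[i, ], Rt, check = FALSE)
  })
}

#' Express marker samples in the per-sample trunk frame
#'
#' Re-expresses a marker trajectory in the trunk coordinate system so that
#' the C7 marker maps to the origin at every sample, removing trunk motion.
#' The result is a workspace point cloud.
#'
#' @param points n x 3 matrix of lab-frame marker positions (mm).
#' @param trunk Either a single `brace_pose` or a list of n poses (one per
#'   sample).
#' @param source Label for the cloud (e.g. `"HEAD_TOP"` or `"C1"`).
#' @return An object of class `workspace_cloud`: list with `points`
#'   (n x 3, trunk frame, mm) and `source`.
#' @export
to_trunk_frame <- function(points, trunk, source = "HEAD_TOP") {
  points <- as.matrix(points)
  if (inherits(trunk, "brace_pose")) trunk <- rep(list(trunk), nrow(points))
  if (length(trunk) != nrow(points))
    stop("to_trunk_frame: one trunk pose required per sample (",
         nrow(points), " samples, ", length(trunk), " poses)", call. = FALSE)
  out <- matrix(0, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    out[i, ] <- crossprod(trunk[[i]]$orientation,
                          points[i, ] - trunk[[i]]$position)
  }
  workspace_cloud(out, source)
}

#' @rdname to_trunk_frame
#' @export
workspace_cloud <- function(points, source = "HEAD_TOP") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  structure(list(points = points, source = source), class = "workspace_cloud")
}

#' @export
print.workspace_cloud <- function(x, ...) {
  cat(sprintf("<workspace_cloud> %d points (trunk frame, mm), source %s\n",
              nrow(x$points), x$source))
  invisible(x)
}
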