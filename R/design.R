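#' Farthest-point subsample of a point cloud
#'
#' Greedy farthest-point sampling, used to reduce a workspace cloud to a
#' representative set before the exhaustive reachability search. The first
#' point is the one farthest from the centroid, so the extreme reach is
#' always evaluated.
#'
#' @param points n x 3 matrix.
#' @param k Number of points to keep.
#' @return Index vector of length `min(k, n)`.
#' @export
farthest_point_sample <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k >= n) return(seq_len(n))
  ctr <- colMeans(points)
  d0 <- rowSums(sweep(points, 2L, ctr)^2)
  idx <- integer(k)
  idx[1] <- which.max(d0)
  mind <- rowSums(sweep(points, 2L, points[idx[1], ])^2)
  for (i in seq_len(k - 1L)) {
    idx[i + 1L] <- which.max(mind)
    dd <- rowSums(sweep(points, 2L, points[idx[i + 1L], ])^2)
    mind <- pmin(mind, dd)
  }
  idx
}

# greedy nearest-neighbour ordering of a small point set, starting from the
# point nearest the centroid
nn_tour <- function(points) {
  n <- nrow(points)
  if (n <= 2L) return(seq_len(n))
  ctr <- colMeans(points)
  remaining <- seq_len(n)
  cur <- remaining[which.min(rowSums(sweep(points, 2L, ctr)^2))]
  tour <- integer(n)
  tour[1] <- cur
  remaining <- setdiff(remaining, cur)
  for (i in 2:n) {
    d <- rowSums(sweep(points[remaining, , drop = FALSE], 2L,
                       points[cur, ])^2)
    cur <- remaining[which.min(d)]
    tour[i] <- cur
    remaining <- setdiff(remaining, cur)
  }
  tour
}

#' Head/C1 separating-plane clearance check
#'
#' The workspace is split by the plane through the C1 marker and the two
#' acromion markers: the head-top marker lies on one side, the C1/neck
#' region on the other. To avoid linkage-head collisions, the J4 joint
#' origin must stay on the C1 side throughout the motion.
#'
#' @param chain A `dh_chain`.
#' @param q_trajectory n x 6 matrix of joint angles (rad).
#' @param c1_point,acr_l,acr_r 3-vectors (mm, base frame) defining the plane.
#' @param head_point 3-vector on the head side of the plane (defines which
#'   side is forbidden); default is the end-effector position at the first
#'   trajectory sample.
#' @return List with `pass` (logical), `first_violation` (sample index or
#'   `NA`), `margin_mm` (minimum signed clearance, positive when clear) and
#'   `normal` (unit plane normal oriented toward the C1 side).
#' @export
check_clearance <- function(chain, q_trajectory, c1_point, acr_l, acr_r,
                            head_point = NULL) {
  q_trajectory <- matrix(as.numeric(q_trajectory), ncol = 6L)
  e1 <- acr_l - c1_point
  e2 <- acr_r - c1_point
  n <- crossprod_vec(e1, e2)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9)
    stop("check_clearance: plane-defining points are collinear", call. = FALSE)
  n <- n / nn
  if (is.null(head_point))
    head_point <- forward_kinematics(chain, q_trajectory[1, ])$position
  side_head <- sum(n * (head_point - c1_point))
  if (abs(side_head) < 1e-9)
    stop("check_clearance: reference head point lies on the plane", call. = FALSE)
  # orient the normal toward the C1 (allowed) side
  if (side_head > 0) n <- -n
  j4 <- point_on_chain(chain, q_trajectory, 4L)
  if (is.null(dim(j4))) j4 <- matrix(j4, 1L, 3L)
  signed <- as.numeric((j4 - matrix(c1_point, nrow(j4), 3L, byrow = TRUE)) %*% n)
  viol <- which(signed < 0)
  list(pass = length(viol) == 0L,
       first_violation = if (length(viol)) viol[1L] else NA_integer_,
       margin_mm = min(signed), normal = n)
}

#' Exhaustive Denavit-Hartenberg parameter search
#'
#' Design-phase search for brace dimensions: over a finite grid of candidate
#' link parameters (the axis twists stay fixed, since they encode the
#' parallel/perpendicular/concurrent structure), each candidate chain is
#' kept iff position-only inverse kinematics reaches every evaluated
#' workspace point within `tol_reach` with joints inside their limits, and
#' (optionally) the J4 clearance check passes along the solved joint
#' trajectory. Feasible candidates are ranked by total link length
#' ascending, a compactness/weight proxy.
#'
#' @param cloud A `workspace_cloud` of points the end-effector must reach
#'   (mm, base frame).
#' @param template A `dh_chain` supplying the fixed structure and the
#'   centers of the search ranges.
#' @param free Character vector of searched entries, each `"a<i>"` or
#'   `"d<i>"` (default `c("a1", "a2")`).
#' @param span Half-width of the search interval around the template value,
#'   mm (default 30).
#' @param step Grid resolution, mm (default 5).
#' @param n_eval Cloud subsample size evaluated per candidate (default 200,
#'   farthest-point sampling).
#' @param tol_reach Reach tolerance, mm (default 2).
#' @param clearance Optional list with `c1`, `acr_l`, `acr_r` (and
#'   optionally `head`) base-frame points enabling the clearance check.
#' @param q_init IK seed (default mid-range of the joint limits).
#' @return A data.frame of feasible candidates sorted by `total_length`,
#'   with one column per free parameter, `reach_fraction`, `total_length`
#'   and a list-column `chain` of the feasible `dh_chain` objects. Zero rows
#'   when nothing is feasible.
#' @export
search_dh_parameters <- function(cloud, template, free = c("a1", "a2"),
                                 span = 30, step = 5, n_eval = 200,
                                 tol_reach = 2, clearance = NULL,
                                 q_init = NULL) {
  pts <- if (inherits(cloud, "workspace_cloud")) cloud$points else as.matrix(cloud)
  if (length(free) == 0L) stop("search_dh_parameters: empty grid", call. = FALSE)
  parsed <- lapply(free, function(f) {
    m <- regmatches(f, regexec("^([ad])([1-6])$", f))[[1]]
    if (length(m) != 3L)
      stop("search_dh_parameters: free entries must look like 'a2' or 'd3'",
           call. = FALSE)
    list(field = m[2], index = as.integer(m[3]))
  })
  grids <- lapply(parsed, function(p) {
    center <- template[[p$field]][p$index]
    seq(center - span, center + span, by = step)
  })
  if (any(lengths(grids) == 0L))
    stop("search_dh_parameters: empty grid", call. = FALSE)
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  sub <- pts[farthest_point_sample(pts, n_eval), , drop = FALSE]
  # order points in a greedy nearest-neighbour tour so the warm-started
  # position IK always moves between nearby targets
  sub <- sub[nn_tour(sub), , drop = FALSE]
  if (is.null(q_init)) q_init <- rowMeans(template$joint_limits)
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cand <- template
    for (j in seq_along(parsed)) {
      cand[[parsed[[j]]$field]][parsed[[j]]$index] <- grid[g, j]
    }
    # a candidate that breaks the structural axis constraints (e.g. a freed
    # wrist offset destroying concurrency) is simply infeasible
    ok <- tryCatch({ validate_chain(cand); TRUE }, error = function(e) FALSE)
    if (!ok) next
    r <- .reach_cpp(chain_params(cand), t(sub),
                    as.numeric(q_init),
                    cand$joint_limits[, 1], cand$joint_limits[, 2],
                    150L, 1e-3, tol_reach, TRUE)
    feasible <- r$reached == nrow(sub)
    clear_ok <- TRUE
    if (feasible && !is.null(clearance)) {
      cl <- check_clearance(cand, r$q, clearance$c1, clearance$acr_l,
                            clearance$acr_r, clearance$head)
      clear_ok <- cl$pass
    }
    if (feasible && clear_ok) {
      results[[g]] <- data.frame(
        grid[g, , drop = FALSE],
        reach_fraction = r$reached / nrow(sub),
        total_length = sum(abs(cand$a)) + sum(abs(cand$d)))
      results[[g]]$chain <- list(cand)
    }
  }
  keep <- !vapply(results, is.null, TRUE)
  if (!any(keep)) {
    out <- grid[0, , drop = FALSE]
    out$reach_fraction <- numeric(0)
    out$total_length <- numeric(0)
    out$chain <- list()
    return(out)
  }
  out <- do.call(rbind, results[keep])
  out[order(out$total_length), , drop = FALSE]
}

#' Operating joint ranges from solved trajectories
#'
#' The brace's joint operating ranges are set from the joint trajectories
#' solved over the recorded dynamic movements, padded by a safety margin,
#' so the device never needs to move beyond what the head-neck actually
#' does.
#'
#' @param q_trajectories List of n x 6 joint-angle matrices (rad).
#' @param margin Safety margin added on both sides, rad (default 5 degrees).
#' @return 6 x 2 matrix of `[min, max]` per joint, rad.
#' @export
derive_joint_limits <- function(q_trajectories, margin = 5 * pi / 180) {
  if (is.matrix(q_trajectories)) q_trajectories <- list(q_trajectories)
  if (length(q_trajectories) == 0L)
    stop("derive_joint_limits: no trajectories supplied", call. = FALSE)
  if (margin < 0) stop("derive_joint_limits: margin must be >= 0", call. = FALSE)
  allq <- do.call(rbind, lapply(q_trajectories, function(m) matrix(m, ncol = 6L)))
  lims <- cbind(apply(allq, 2L, min) - margin, apply(allq, 2L, max) + margin)
  colnames(lims) <- c("min", "max")
  rownames(lims) <- paste0("J", 1:6)
  lims
}
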