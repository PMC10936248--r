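#' Fit a sphere to a workspace point cloud
#'
#' Two-stage fit of the rotation sphere underlying the head-top workspace:
#' an algebraic linear least-squares solution (Coope formulation) followed
#' by geometric (orthogonal-distance) Gauss-Newton refinement minimizing
#' `sum (|p_i - c| - r)^2`. The head-top cloud of a neutral-seated subject
#' is approximately a spherical cap centered at the atlanto-axial rotation
#' center; the fitted center and radius drive the arc-linkage dimensioning
#' in the design phase.
#'
#' @param cloud A `workspace_cloud` (or n x 3 matrix, mm).
#' @param max_iter Gauss-Newton iteration cap (50).
#' @param cond_tol Reciprocal-condition threshold below which the cloud is
#'   declared degenerate (coplanar or near-coplanar), default 1e-10.
#' @return List of class `sphere_fit` with `center` (3-vector, mm),
#'   `radius` (mm), `rms_residual` (mm; RMS of `|dist - radius|`), `n`.
#' @export
fit_sphere <- function(cloud, max_iter = 50, cond_tol = 1e-10) {
  pts <- if (inherits(cloud, "workspace_cloud")) cloud$points else as.matrix(cloud)
  n <- nrow(pts)
  if (n < 4L) stop("fit_sphere: need at least 4 points", call. = FALSE)
  # algebraic stage: |p|^2 = 2 c.p + (r^2 - |c|^2), linear in (c, k)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  AtA <- crossprod(A)
  if (rcond(AtA) < cond_tol)
    stop("fit_sphere: degenerate (coplanar) point cloud", call. = FALSE)
  sol <- solve(AtA, crossprod(A, b))
  center <- as.numeric(sol[1:3])
  radius <- sqrt(max(sol[4] + sum(center^2), 0))
  if (radius <= 0) stop("fit_sphere: degenerate cloud (zero radius)", call. = FALSE)
  # geometric refinement on (center, radius)
  for (it in seq_len(max_iter)) {
    dvec <- sweep(pts, 2L, center)
    dist <- sqrt(rowSums(dvec^2))
    resid <- dist - radius
    # Jacobian of residual: d resid / d center = -(p - c)/|p - c|, d/d r = -1
    u <- dvec / pmax(dist, 1e-12)
    J <- cbind(-u, -1)
    H <- crossprod(J)
    if (rcond(H) < cond_tol)
      stop("fit_sphere: degenerate (coplanar) point cloud", call. = FALSE)
    step <- solve(H, crossprod(J, resid))
    center <- center - as.numeric(step[1:3])
    radius <- radius - step[4]
    if (max(abs(step)) < 1e-12) break
  }
  dist <- sqrt(rowSums(sweep(pts, 2L, center)^2))
  structure(list(center = center, radius = radius,
                 rms_residual = sqrt(mean((dist - radius)^2)), n = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f) mm, radius %.2f mm, RMS residual %.3f mm (n = %d)\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$rms_residual, x$n))
  invisible(x)
}
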