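# canonical axis-aligned marker layout used by several frame tests
canonical_static <- function(n = 5) {
  base <- list(C7 = c(0, 0, 0), CHEST = c(100, 0, 0),
               ACR_L = c(0, 150, 0), ACR_R = c(0, -150, 0),
               C1 = c(20, 0, 110), HEAD_TOP = c(20, 0, 170),
               HEAD_L = c(20, 70, 120), HEAD_R = c(20, -70, 120))
  lapply(base, function(p) matrix(rep(p, each = n), n, 3L))
}

apply_rigid <- function(trial, R, t) {
  lapply(trial, function(m) t(R %*% t(m)) +
           matrix(t, nrow(m), 3L, byrow = TRUE))
}

test_that("reference frames from canonical markers are identity at C7", {
  ref <- build_reference_frame(canonical_static())
  expect_equal(ref$trunk$position, c(0, 0, 0))
  expect_lt(max(abs(ref$trunk$orientation - diag(3))), 1e-12)
  expect_lt(max(abs(ref$head$orientation - diag(3))), 1e-12)
  expect_equal(ref$head$position, c(20, 0, 170))
})

test_that("frame construction is rigid-transform equivariant", {
  set.seed(201)
  st <- canonical_static()
  for (i in 1:10) {
    ang <- runif(3, -pi, pi)
    R <- rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3])
    t <- runif(3, -500, 500)
    ref <- build_reference_frame(apply_rigid(st, R, t))
    expect_lt(max(abs(ref$trunk$position - (R %*% c(0, 0, 0) + t))), 1e-9)
    expect_lt(max(abs(ref$trunk$orientation - R)), 1e-9)
    expect_lt(max(abs(ref$head$orientation - R)), 1e-9)
  }
})

test_that("schema errors name the missing marker", {
  st <- canonical_static()
  st$HEAD_TOP <- NULL
  expect_error(build_reference_frame(st), "HEAD_TOP")
  expect_error(marker_session(list(t1 = st)), "HEAD_TOP")
  # collinear trunk markers are a degenerate geometry
  bad <- canonical_static()
  bad$ACR_L <- bad$CHEST; bad$ACR_R <- bad$CHEST
  expect_error(build_reference_frame(bad), "collinear|degenerate")
})

test_that("to_trunk_frame removes trunk motion", {
  st <- canonical_static(50)
  trunks <- trunk_frames_per_sample(st)
  # a point riding on C7 maps to the origin
  cloud <- to_trunk_frame(st$C7, trunks)
  expect_lt(max(abs(cloud$points)), 1e-12)
  # invariance under a common rigid motion of everything
  set.seed(202)
  R <- rot_z(0.7) %*% rot_x(-0.3); t <- c(123, -45, 678)
  moved <- apply_rigid(st, R, t)
  cloud2 <- to_trunk_frame(moved$HEAD_TOP, trunk_frames_per_sample(moved))
  cloud1 <- to_trunk_frame(st$HEAD_TOP, trunks)
  expect_lt(max(abs(cloud1$points - cloud2$points)), 1e-9)
  # a static head marker under pure trunk rotation traces the inverse
  # rotation (direct matrix-algebra oracle)
  phi <- seq(0, 1, length.out = 50)
  rotated <- st
  for (i in seq_along(phi)) {
    Ri <- rot_z(phi[i])
    for (l in c("C7", "CHEST", "ACR_L", "ACR_R"))
      rotated[[l]][i, ] <- Ri %*% st[[l]][i, ]
  }
  out <- to_trunk_frame(rotated$HEAD_TOP, trunk_frames_per_sample(rotated))
  oracle <- t(vapply(seq_along(phi), function(i)
    as.numeric(t(rot_z(phi[i])) %*% st$HEAD_TOP[i, ]), numeric(3)))
  expect_lt(max(abs(out$points - oracle)), 1e-9)
  expect_error(to_trunk_frame(st$C7, trunks[1:10]), "per sample")
})

test_that("fit_sphere is exact on noiseless spheres", {
  set.seed(203)
  u <- matrix(rnorm(60), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  fit <- fit_sphere(u)
  expect_lt(max(abs(fit$center)), 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
})

test_that("fit_sphere recovers center and radius under noise", {
  set.seed(204)
  ctr <- c(10, 20, 30); rad <- 90
  u <- matrix(rnorm(1500), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * rad, 2, ctr, "+") + matrix(rnorm(1500, 0, 1), ncol = 3)
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center - ctr)), 1)
  expect_lt(abs(fit$radius - rad), 1)
  # consistency: error shrinks with n at fixed noise
  errs <- vapply(c(50, 500, 5000), function(n) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rad, 2, ctr, "+") + matrix(rnorm(3 * n, 0, 1), ncol = 3)
    f <- fit_sphere(pts)
    sqrt(sum((f$center - ctr)^2)) + abs(f$radius - rad)
  }, 0)
  expect_lt(errs[3], errs[1])
})

test_that("fit_sphere rejects degenerate clouds", {
  pts <- cbind(matrix(rnorm(40), ncol = 2), 0)  # coplanar, z = 0
  expect_error(fit_sphere(pts), "degenerate|coplanar")
  expect_error(fit_sphere(matrix(0, 3, 3)), "at least 4")
})

test_that("clearance check separates J4 from the head region", {
  ch <- default_chain()
  q <- matrix(0, 3, 6)
  j4 <- point_on_chain(ch, rep(0, 6), 4)      # base x ~ 134 (superior)
  p_ee <- forward_kinematics(ch, rep(0, 6))$position  # base x ~ 194
  # a plane of constant base x between J4 and the end-effector separates
  # the C1/neck region (below) from the head region (above)
  xmid <- (j4[1] + p_ee[1]) / 2
  c1 <- c(xmid, 0, 0); acr_l <- c(xmid, 40, 120); acr_r <- c(xmid, 40, -120)
  cl <- check_clearance(ch, q, c1, acr_l, acr_r)
  # the plane normal is orthogonal to both in-plane edges (construction)
  expect_lt(abs(sum(cl$normal * (acr_l - c1))), 1e-12)
  expect_lt(abs(sum(cl$normal * (acr_r - c1))), 1e-12)
  expect_true(cl$pass)
  expect_true(is.na(cl$first_violation))
  expect_gt(cl$margin_mm, 0)
  # move the plane above J4's excursion: the first crossing is reported
  xlow <- j4[1] - 10
  cl2 <- check_clearance(ch, q, c1 - c(xmid - xlow, 0, 0),
                         acr_l - c(xmid - xlow, 0, 0),
                         acr_r - c(xmid - xlow, 0, 0),
                         head_point = p_ee)
  expect_false(cl2$pass)
  expect_equal(cl2$first_violation, 1L)
  expect_error(check_clearance(ch, q, c1, c1 + c(1, 0, 0), c1 + c(2, 0, 0)),
               "collinear")
})

test_that("derive_joint_limits pads observed extrema", {
  q <- matrix(0.3, 10, 6)
  lims <- derive_joint_limits(q, margin = 0.1)
  expect_equal(unname(lims[, 1]), rep(0.2, 6), tolerance = 1e-12)
  expect_equal(unname(lims[, 2]), rep(0.4, 6), tolerance = 1e-12)
  # sinusoid of amplitude A: limits within one sample step of +/-(A + m)
  t <- seq(0, 1, length.out = 500)
  A <- 0.8; m <- 0.05
  qs <- matrix(A * sin(2 * pi * t), ncol = 1)[, rep(1, 6)]
  lims <- derive_joint_limits(list(qs), margin = m)
  expect_lt(max(abs(lims[, 2] - (A + m))), A * 2 * pi / 500)
  expect_lt(max(abs(lims[, 1] + (A + m))), A * 2 * pi / 500)
  expect_error(derive_joint_limits(list()), "no trajectories")
  expect_error(derive_joint_limits(q, margin = -1), ">= 0")
})

test_that("exhaustive search recovers a planted chain", {
  ch <- default_chain()
  set.seed(205)
  qs <- matrix(runif(6 * 200, -0.8, 0.8), ncol = 6)
  pts <- t(apply(qs, 1, function(q) forward_kinematics(ch, q)$position))
  cloud <- workspace_cloud(pts)
  res <- search_dh_parameters(cloud, ch, free = c("a1", "a2"),
                              span = 10, step = 5, n_eval = 80)
  expect_gt(nrow(res), 0)
  planted <- res[abs(res$a1 - ch$a[1]) < 1e-9 & abs(res$a2 - ch$a[2]) < 1e-9, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$reach_fraction, 1)
  # ranking is by total link length ascending
  expect_true(!is.unsorted(res$total_length))
  # monotonicity: enlarging the grid never removes a feasible candidate
  res_big <- search_dh_parameters(cloud, ch, free = c("a1", "a2"),
                                  span = 15, step = 5, n_eval = 80)
  small_keys <- paste(res$a1, res$a2)
  big_keys <- paste(res_big$a1, res_big$a2)
  expect_true(all(small_keys %in% big_keys))
})

test_that("search returns empty for undersized candidates and rejects bad input", {
  ch <- default_chain()
  set.seed(206)
  qs <- matrix(runif(6 * 50, -0.8, 0.8), ncol = 6)
  pts <- t(apply(qs, 1, function(q) forward_kinematics(ch, q)$position))
  # shrink every candidate far below the cloud's reach
  short <- dh_chain(a = c(5, 5, 5, 0, 0, 0), alpha = ch$alpha,
                    d = c(0, 0, 5, 0, 0, 5), theta0 = ch$theta0,
                    joint_limits = ch$joint_limits)
  res <- search_dh_parameters(workspace_cloud(pts), short,
                              free = c("a1", "a2"), span = 5, step = 5,
                              n_eval = 20)
  expect_equal(nrow(res), 0L)
  expect_error(search_dh_parameters(workspace_cloud(pts), ch,
                                    free = character(0)), "empty grid")
  expect_error(search_dh_parameters(workspace_cloud(pts), ch,
                                    free = "b9"), "free entries")
})

test_that("farthest-point sampling covers extremes first", {
  set.seed(207)
  pts <- matrix(rnorm(300), ncol = 3)
  idx <- farthest_point_sample(pts, 10)
  expect_equal(length(idx), 10L)
  expect_equal(length(unique(idx)), 10L)
  # the first pick is the farthest point from the centroid
  d <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  expect_equal(idx[1], which.max(d))
})
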