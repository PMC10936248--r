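test_that("chain constructor enforces structural invariants", {
  ch <- default_chain()
  expect_s3_class(ch, "dh_chain")
  expect_true(validate_chain(ch))
  # breaking J1 || J2 parallelism is rejected
  expect_error(dh_chain(a = ch$a, alpha = c(0.3, ch$alpha[-1]), d = ch$d,
                        theta0 = ch$theta0),
               "parallel")
  # breaking wrist concurrency is rejected
  expect_error(dh_chain(a = c(ch$a[1:3], 15, 0, 0), alpha = ch$alpha,
                        d = ch$d, theta0 = ch$theta0),
               "intersect")
  # ill-ordered joint limits
  expect_error(dh_chain(a = ch$a, alpha = ch$alpha, d = ch$d,
                        theta0 = ch$theta0,
                        joint_limits = cbind(rep(1, 6), rep(-1, 6))),
               "limits")
})

test_that("forward kinematics agrees with the naive chain-product oracle", {
  ch <- default_chain()
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    q <- runif(6, ch$joint_limits[, 1], ch$joint_limits[, 2])
    p <- forward_kinematics(ch, q)
    worst <- max(worst, max(abs(pose_to_homogeneous_test(p) - naive_fk(ch, q))))
  }
  expect_lt(worst, 1e-10)
  # purity: repeated evaluation is bitwise identical
  q <- runif(6, -1, 1)
  expect_identical(forward_kinematics(ch, q), forward_kinematics(ch, q))
  expect_error(forward_kinematics(ch, c(1, 2, NA, 4, 5, 6)), "finite")
})

test_that("point C is invariant to the distal three joints", {
  ch <- default_chain()
  set.seed(102)
  for (i in 1:50) {
    q <- runif(6, -1.5, 1.5)
    c1 <- chain_point_c(ch, q)
    q2 <- q; q2[4:6] <- runif(3, -1.5, 1.5)
    expect_lt(max(abs(c1 - chain_point_c(ch, q2))), 1e-9)
  }
})

test_that("point_on_chain exposes joint origins with rigid-link geometry", {
  ch <- default_chain()
  set.seed(103)
  p0 <- point_on_chain(ch, rep(0, 6), 1)
  for (i in 1:20) {
    q <- runif(6, -2, 2)
    # base joint origin never moves
    expect_equal(point_on_chain(ch, q, 1), p0)
    # |P - J6 origin| is the fixed final link offset for all q
    d <- forward_kinematics(ch, q)$position - point_on_chain(ch, q, 6)
    expect_equal(sqrt(sum(d^2)), sqrt(ch$a[6]^2 + ch$d[6]^2), tolerance = 1e-10)
  }
  expect_error(point_on_chain(ch, rep(0, 6), 7), "1..6")
  # trajectory input returns one row per sample
  qtraj <- matrix(runif(18, -1, 1), ncol = 6)
  expect_equal(dim(point_on_chain(ch, qtraj, 4)), c(3L, 3L))
})

test_that("inverse kinematics is a fixed point at the neutral pose", {
  ch <- default_chain()
  tgt <- forward_kinematics(ch, rep(0, 6))
  r <- inverse_kinematics(ch, tgt, q_init = rep(0, 6))
  expect_true(r$converged)
  expect_lt(r$pos_err, 1e-9)
  expect_lt(max(abs(r$q)), 1e-9)
})

test_that("IK round-trips FK on random in-limit targets", {
  ch <- default_chain()
  set.seed(104)
  for (i in 1:100) {
    qs <- runif(6, -1.5, 1.5)
    tgt <- forward_kinematics(ch, qs)
    # seed near the target branch, as on a tracked trajectory
    r <- inverse_kinematics(ch, tgt, q_init = qs + rnorm(6, 0, 0.2))
    expect_true(r$converged)
    expect_lt(r$pos_err, 1e-6)
    expect_lt(r$ori_err, 1e-4)
    # the solved joints are within limits
    expect_true(all(r$q >= ch$joint_limits[, 1] - 1e-12))
    expect_true(all(r$q <= ch$joint_limits[, 2] + 1e-12))
  }
})

test_that("unreachable targets flag non-convergence with a distance residual", {
  ch <- default_chain()
  reach <- sum(abs(ch$a)) + sum(abs(ch$d))
  tgt <- pose(c(10 * reach, 0, 0), diag(3))
  r <- inverse_kinematics(ch, tgt)
  expect_false(r$converged)
  # residual is approximately the distance to the reachable boundary
  expect_gt(r$pos_err, 10 * reach - reach)
  expect_lt(r$pos_err, 10 * reach)
})

test_that("warm-started trajectory IK tracks a continuous motion", {
  ch <- default_chain()
  t <- seq(0, 1, length.out = 40)
  qpath <- outer(sin(2 * pi * t), c(0.4, -0.3, 0.2, 0.5, -0.4, 0.6))
  targets <- lapply(seq_len(nrow(qpath)), function(i)
    forward_kinematics(ch, qpath[i, ]))
  r <- ik_trajectory(ch, targets, q_init = rep(0, 6))
  expect_true(all(r$converged))
  expect_lt(max(r$pos_err), 1e-6)
  # solutions track the generating branch
  expect_lt(max(abs(r$q - qpath)), 1e-6)
})

test_that("head angle decomposition round-trips and flags gimbal lock", {
  # single-axis cases with the stated sign conventions
  a30 <- head_angles_from_rotation(rotation_from_head_angles(
    c(flexion_extension = 0, lateral_bending = 0, axial_rotation = 30)))
  expect_equal(a30[["axial_rotation"]], 30, tolerance = 1e-9)
  expect_lt(abs(a30[["flexion_extension"]]), 1e-9)
  expect_lt(abs(a30[["lateral_bending"]]), 1e-9)

  set.seed(105)
  for (i in 1:50) {
    ang <- c(flexion_extension = runif(1, -80, 80),
             lateral_bending = runif(1, -70, 70),
             axial_rotation = runif(1, -150, 150))
    R <- rotation_from_head_angles(ang)
    back <- head_angles_from_rotation(R)
    expect_lt(max(abs(R - rotation_from_head_angles(back))), 1e-9)
    expect_equal(as.numeric(back), as.numeric(ang), tolerance = 1e-9)
  }
  # identity and gimbal proximity
  id <- head_angles_from_rotation(diag(3))
  expect_equal(as.numeric(id), c(0, 0, 0))
  near <- head_angles_from_rotation(rotation_from_head_angles(
    c(flexion_extension = 10, lateral_bending = 89.8, axial_rotation = 5)))
  expect_true(attr(near, "degenerate"))
})

test_that("head_angles_from_pose uses the neutral frame", {
  ch <- default_chain()
  p <- forward_kinematics(ch, rep(0, 6))
  expect_equal(as.numeric(head_angles_from_pose(p, p)), c(0, 0, 0))
})

test_that("chain serialization round-trips through YAML and JSON", {
  ch <- default_chain()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("chain.", ext))
    write_chain(ch, path)
    ch2 <- read_chain(path)
    expect_equal(ch2$a, ch$a, tolerance = 1e-9)
    expect_equal(ch2$alpha, ch$alpha, tolerance = 1e-9)
    expect_equal(ch2$d, ch$d, tolerance = 1e-9)
    expect_equal(ch2$theta0, ch$theta0, tolerance = 1e-9)
    expect_equal(ch2$joint_limits, ch$joint_limits, tolerance = 1e-9)
  }
})

test_that("pose constructor validates orthonormality", {
  expect_error(pose(c(0, 0, 0), matrix(1, 3, 3)), "orthonormal")
  R <- diag(3); R[1, 1] <- -1  # improper
  expect_error(pose(c(0, 0, 0), R), "proper")
})
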