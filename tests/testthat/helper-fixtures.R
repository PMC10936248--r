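# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# default-noise sessions and a stage-1 calibration model shared by the
# calibration, workflow, CLI and acceptance tests
fx_cal_session <- function() fixture("cal_session", function()
  generate_session(seed = 11, participant = "CAL", visit = "pre"))

fx_val_session <- function() fixture("val_session", function()
  generate_session(seed = 22, participant = "VAL", visit = "pre"))

fx_model <- function() fixture("model", function()
  suppressWarnings(calibrate_session(fx_cal_session(), refine = FALSE)))

# noiseless single-motion trial (voltage stream only)
fx_noiseless_trial <- function(motion = "axial_rotation")
  fixture(paste0("noiseless_", motion), function() {
    sp <- synthetic_spec(motion, marker_noise_mm = 0,
                         voltage_noise_fraction_fs = 0)
    generate_trial(sp, seed = 7, streams = "voltage")
  })

# independent naive forward-kinematics oracle: sequential multiplication of
# the six elementary transforms, written without reference to the package's
# compiled path
naive_fk <- function(chain, q) {
  one <- function(a, alpha, d, theta) {
    ct <- cos(theta); st <- sin(theta); ca <- cos(alpha); sa <- sin(alpha)
    rbind(c(ct, -st * ca,  st * sa, a * ct),
          c(st,  ct * ca, -ct * sa, a * st),
          c(0,   sa,       ca,      d),
          c(0,   0,        0,       1))
  }
  T <- diag(4)
  for (i in 1:6)
    T <- T %*% one(chain$a[i], chain$alpha[i], chain$d[i],
                   chain$theta0[i] + q[i])
  T
}

expect_pose_equal <- function(p, T, tol = 1e-10) {
  expect_lt(max(abs(pose_to_homogeneous_test(p) - T)), tol)
}

pose_to_homogeneous_test <- function(p) {
  T <- diag(4); T[1:3, 1:3] <- p$orientation; T[1:3, 4] <- p$position; T
}
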