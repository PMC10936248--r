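test_that("rope schedule encodes the muscle coordination model", {
  expect_setequal(rope_activation_schedule("axial_rotation", "right")$active,
                  c("SCM_L", "SC_R", "TR_L"))
  expect_setequal(rope_activation_schedule("lateral_bending", "left")$active,
                  c("SCM_L", "SC_L", "TR_L"))
  expect_setequal(rope_activation_schedule("flexion_extension", "flexion")$active,
                  c("SCM_L", "SCM_R"))
  expect_setequal(rope_activation_schedule("flexion_extension", "extension")$active,
                  c("SC_L", "SC_R"))
  # flexion carries trapezius co-activation
  expect_named(rope_activation_schedule("flexion_extension", "flexion")$coactivation,
               c("TR_L", "TR_R"))
  # mirror symmetry under left/right swap
  swap <- function(x) {
    m <- c(SCM_L = "SCM_R", SCM_R = "SCM_L", SC_L = "SC_R", SC_R = "SC_L",
           TR_L = "TR_R", TR_R = "TR_L")
    unname(m[x])
  }
  for (motion in c("axial_rotation", "lateral_bending")) {
    r <- rope_activation_schedule(motion, "right")$active
    l <- rope_activation_schedule(motion, "left")$active
    expect_setequal(l, swap(r))
  }
  expect_error(rope_activation_schedule("shrug", "right"), "unknown motion")
  expect_error(rope_activation_schedule("axial_rotation", "up"), "right")
})

test_that("the sensor map inverse is exact", {
  map <- default_sensor_map()
  set.seed(601)
  q <- matrix(runif(600, -1.3, 1.3), ncol = 6)
  V <- map$volts_from_angle(q)
  expect_lt(max(abs(map$angle_from_volts(V) - q)), 1e-12)
  expect_true(all(V > 0 & V < 3.3))
  # monotone per joint
  grid <- seq(0.3, 3.0, length.out = 100)
  for (j in 1:6) {
    vals <- map$angle_from_volts(matrix(grid, ncol = 1)[, rep(1, 6)])[, j]
    expect_true(all(diff(vals) > 0))
  }
})

test_that("generation is deterministic in the seed", {
  sp <- synthetic_spec("lateral_bending")
  a <- generate_trial(sp, seed = 5, streams = c("voltage", "emg"))
  b <- generate_trial(sp, seed = 5, streams = c("voltage", "emg"))
  expect_identical(a$voltages$volts, b$voltages$volts)
  expect_identical(a$emg$channels, b$emg$channels)
  c <- generate_trial(sp, seed = 6, streams = "voltage")
  expect_false(identical(a$voltages$volts, c$voltages$volts))
})

test_that("prescribed profiles respect the protocol shape", {
  sp <- synthetic_spec("axial_rotation", marker_noise_mm = 0,
                       voltage_noise_fraction_fs = 0)
  tr <- fx_noiseless_trial("axial_rotation")
  gt <- tr$ground_truth
  prim <- gt$angles_deg[, "axial_rotation"]
  # starts and ends inside the neutral band
  expect_lt(abs(prim[1]), 0.1 * max(abs(prim)))
  expect_lt(abs(prim[length(prim)]), 0.1 * max(abs(prim)))
  # exactly cycles_per_trial biphasic excursions
  expect_length(segment_cycles(prim), sp$cycles_per_trial)
  # amplitudes hit the stated world's values
  expect_equal(max(prim), sp$amplitude_deg[1], tolerance = 0.1)
  expect_equal(min(prim), -sp$amplitude_deg[2], tolerance = 0.1)
  # secondary planes carry the stated coupling fraction
  expect_equal(max(abs(gt$angles_deg[, "lateral_bending"])),
               sp$coupling * sp$amplitude_deg[1], tolerance = 0.1)
})

test_that("EMG burst centers match the rope schedule on noiseless envelopes", {
  sp <- synthetic_spec("axial_rotation",
                       emg_burst = list(center1 = 20, center2 = 70,
                                        width = 30, amplitude = 1,
                                        baseline = 0))
  sp$cardiac$amplitude <- 0
  tr <- generate_trial(sp, seed = 9, streams = c("voltage", "emg"))
  env <- process_emg(tr$emg)
  # fold envelope onto % cycle using ground-truth boundaries (EMG clock
  # offset: trigger alignment maps emg time to brace time)
  t_emg <- tr$emg$time_s - 0.5
  centers <- tr$ground_truth$burst_centers_pct
  Tc <- sp$cycle_period_s; pad <- sp$neutral_pad_s
  phase <- ((t_emg - pad) %% Tc) / Tc * 100
  active <- t_emg >= pad & t_emg < pad + sp$cycles_per_trial * Tc
  for (ch in names(centers)) {
    if (is.na(centers[ch])) next
    e <- env$envelopes[active, ch]
    ph <- phase[active]
    expect_lt(abs(ph[which.max(e)] - centers[ch]), 1)  # within 1% cycle
  }
  # inactive channels carry no burst
  quiet <- names(centers)[is.na(centers)]
  for (ch in quiet) expect_lt(max(env$envelopes[, ch]), 1 + 1e-9)
})

test_that("unreachable amplitudes abort generation naming the plane", {
  sp <- synthetic_spec("lateral_bending", amplitude_deg = c(150, 150))
  expect_error(generate_trial(sp, streams = "voltage"),
               "lateral_bending.*unreachable|unreachable.*lateral_bending")
})

test_that("pre/post deltas are injected exactly and sessions assemble", {
  coh <- generate_cohort(n_subjects = 2, seed = 3, delta_deg = 8)
  for (s in coh) {
    expect_equal(s$amplitudes$pre[1] - s$amplitudes$post[1], 8)
    expect_equal(s$amplitudes$pre[2], s$amplitudes$post[2])
  }
  sess <- fx_cal_session()
  expect_s3_class(sess$markers, "marker_session")
  expect_setequal(names(sess$markers$trials),
                  c("static", "axial_rotation", "lateral_bending",
                    "flexion_extension"))
  # marker invariants hold (checked by the constructor) and the voltage and
  # EMG streams carry the shared trigger
  for (m in names(sess$trials)) {
    tr <- sess$trials[[m]]
    expect_gt(length(neckbrace:::rising_edge_times(tr$voltages$time_s,
                                                   tr$voltages$trigger)), 0)
    expect_gt(length(neckbrace:::rising_edge_times(tr$emg$time_s,
                                                   tr$emg$trigger)), 0)
  }
})

test_that("the noiseless digital twin is self-consistent end to end", {
  specs <- lapply(
    c(axial_rotation = "axial_rotation", lateral_bending = "lateral_bending",
      flexion_extension = "flexion_extension"),
    function(m) synthetic_spec(m, marker_noise_mm = 0,
                               voltage_noise_fraction_fs = 0))
  sess <- generate_session(specs = specs, seed = 31, streams = c("markers", "voltage"))
  model <- suppressWarnings(calibrate_session(sess, refine = FALSE))
  for (m in names(sess$trials)) {
    tr <- sess$trials[[m]]
    rec <- apply_calibration(model, tr$voltages, sess$chain, sess$mount)
    expect_lt(max(abs(rec$angles - tr$ground_truth$angles_deg)), 0.05)
  }
})
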