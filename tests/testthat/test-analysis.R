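biphasic <- function(n_cycles = 5, period = 400, pad = 60, A1 = 40, A2 = 40) {
  # raised-cosine biphasic cycles sampled at 100 Hz, as in the protocol
  p <- ((seq_len(n_cycles * period) - 1) %% period) / period
  one <- numeric(length(p))
  i1 <- p < 0.25; i2 <- p >= 0.25 & p < 0.75; i3 <- p >= 0.75
  one[i1] <- A1 / 2 * (1 - cos(pi * p[i1] / 0.25))
  one[i2] <- A1 - (A1 + A2) / 2 * (1 - cos(pi * (p[i2] - 0.25) / 0.5))
  one[i3] <- -A2 / 2 * (1 + cos(pi * (p[i3] - 0.75) / 0.25))
  c(rep(0, pad), one, rep(0, pad))
}

test_that("segmentation returns one cycle per protocol repetition", {
  x <- biphasic(5)
  spans <- segment_cycles(x)
  expect_length(spans, 5L)
  # noiseless boundaries coincide with the generator's neutral crossings
  starts <- vapply(spans, function(s) s$start, 0L)
  ends <- vapply(spans, function(s) s$end, 0L)
  expect_equal(starts, 60 + (0:4) * 400 + 1, tolerance = 2)
  expect_equal(ends, 60 + (1:5) * 400 + 1, tolerance = 2)
  # each cycle has one excursion per side, in order
  for (s in spans) expect_lt(s$extreme1, s$extreme2)
})

test_that("segmentation edge cases behave as specified", {
  expect_warning(out <- segment_cycles(rep(0, 500)), "flat|no cycles")
  expect_length(out, 0L)
  # a trailing partial excursion is discarded
  x <- biphasic(3)
  xpart <- c(x[1:(60 + 2 * 400 + 150)])
  expect_length(segment_cycles(xpart), 2L)
  # series starting outside the neutral band is an error
  expect_error(segment_cycles(c(rep(35, 10), biphasic(2))), "neutral band")
  # count is invariant to noise up to half the hysteresis band
  set.seed(501)
  xn <- biphasic(5) + rnorm(length(biphasic(5)), 0, 0.10 * 40 / 2)
  xn[1] <- 0
  expect_length(segment_cycles(xn), 5L)
})

test_that("time normalization preserves endpoints and averages exactly", {
  x <- biphasic(5)
  spans <- segment_cycles(x)
  cycles <- lapply(spans, function(s) extract_cycle(x, s, motion_type = "lateral_bending"))
  for (k in seq_along(cycles)) {
    expect_length(cycles[[k]]$angle, 101L)
    expect_equal(cycles[[k]]$angle[1], x[spans[[k]]$start])
    expect_equal(cycles[[k]]$angle[101], x[spans[[k]]$end])
  }
  avg <- time_normalize_and_average(cycles)
  # five identical cycles: the mean equals any one of them
  expect_lt(max(abs(avg$angle - cycles[[1]]$angle)), 1e-12)
  expect_equal(avg$duration_s, cycles[[1]]$duration_s)
  expect_error(time_normalize_and_average(list()), "no cycles")
  c2 <- cycles; c2[[2]]$motion_type <- "axial_rotation"
  expect_error(time_normalize_and_average(c2), "mixed")
})

test_that("pure time dilation leaves the normalized mean unchanged", {
  # one waveform sampled at two rates: spans of 101 and 201 samples hit the
  # 101-point grid exactly, so resampling is exact for both
  f <- function(p) sin(2 * pi * p) + 0.3 * sin(4 * pi * p)
  a1 <- f(seq(0, 1, length.out = 101))
  a2 <- f(seq(0, 1, length.out = 201))
  mk <- function(a, dur) structure(
    list(angle = approx(seq_along(a), a,
                        xout = seq(1, length(a), length.out = 101))$y,
         envelopes = NULL, duration_s = dur, motion_type = "axial_rotation",
         subblocks = c(25, 75)), class = "movement_cycle")
  avg <- time_normalize_and_average(list(mk(a1, 1), mk(a2, 2)))
  expect_lt(max(abs(avg$angle - f(seq(0, 1, length.out = 101)))), 1e-6)
  expect_equal(avg$duration_s, 1.5)
})

test_that("cycle outcomes match closed forms", {
  x <- biphasic(1, A1 = 40, A2 = 40)
  span <- segment_cycles(x)[[1]]
  pct <- seq(0, 100, length.out = 101)
  env <- cbind(SCM_L = 0.5 * (1 + cos(pi * pmin(abs(pct - 25), 50) / 15)) *
                 (abs(pct - 25) < 15),
               SCM_R = rep(0.4, 101))
  cyc <- extract_cycle(x, span, motion_type = "lateral_bending")
  cyc$envelopes <- env
  out <- compute_outcomes(cyc)
  expect_equal(out$max_angle_deg, 40, tolerance = 1e-6)
  expect_equal(out$min_angle_deg, -40, tolerance = 1e-6)
  expect_equal(out$rom_deg, 80, tolerance = 1e-6)
  # raised-cosine envelope centered at 25% peaks there
  expect_equal(unname(out$emg_peak_timing_pct["SCM_L"]), 25)
  # constant envelope ties resolve to the earliest sample: 0%
  expect_equal(unname(out$emg_peak_timing_pct["SCM_R"]), 0)
  expect_equal(out$completion_time_s, span$duration_s)
})

test_that("paired_stats reproduces the hand-computed example", {
  pre <- c(10, 10, 10, 10, 10)
  post <- pre + c(1, 2, 3, 4, 5)
  st <- paired_stats(pre, post)
  expect_equal(st$mean_diff, 3)
  expect_equal(st$t_stat, 4.2426, tolerance = 1e-4)
  expect_equal(st$df, 4L)
  expect_equal(st$ci_low, 1.0368, tolerance = 1e-4)
  expect_equal(st$ci_high, 4.9632, tolerance = 1e-4)
  expect_equal(st$p_value, 0.0132, tolerance = 5e-3)
  expect_true(st$significant)
})

test_that("paired_stats agrees with the reference implementation", {
  set.seed(502)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    pre <- rnorm(n, 10, 3)
    post <- pre + rnorm(n, 0.5, 1)
    st <- paired_stats(pre, post)
    tt <- t.test(post, pre, paired = TRUE)
    expect_equal(st$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(c(st$ci_low, st$ci_high), as.numeric(tt$conf.int),
                 tolerance = 1e-8)
    expect_true(st$ci_low <= st$mean_diff && st$mean_diff <= st$ci_high)
  }
})

test_that("paired_stats handles degenerate difference vectors", {
  x <- c(3, 1, 4, 1, 5)
  same <- paired_stats(x, x)
  expect_equal(same$mean_diff, 0)
  expect_true(same$degenerate)
  expect_false(same$significant)
  expect_equal(same$p_value, 1)
  shift <- paired_stats(x, x + 2)
  expect_equal(shift$t_stat, Inf)
  expect_equal(shift$p_value, 0)
  small <- paired_stats(c(0, 0, 0, 0, 0), c(0.1, -0.1, 0.05, -0.05, 0))
  expect_gt(small$p_value, 0.5)
  expect_false(small$significant)
  expect_error(paired_stats(1:3, 1:4), "unequal")
  expect_error(paired_stats(1, 2), "n >= 2")
})

test_that("rom is invariant under a sign-convention flip", {
  x <- biphasic(1, A1 = 35, A2 = 45)
  span <- segment_cycles(x)[[1]]
  o1 <- compute_outcomes(extract_cycle(x, span, motion_type = "lateral_bending"))
  xf <- -x
  o2 <- compute_outcomes(extract_cycle(xf, segment_cycles(xf)[[1]],
                                       motion_type = "lateral_bending"))
  expect_equal(o1$rom_deg, o2$rom_deg, tolerance = 1e-9)
  expect_equal(o1$max_angle_deg, -o2$min_angle_deg, tolerance = 1e-9)
})

test_that("analyze_trial phase-aligns opposite-direction first excursions", {
  x1 <- biphasic(2)
  x2 <- -biphasic(3)
  x <- cbind(flexion_extension = 0 * c(x1, x2),
             lateral_bending = c(x1, x2),
             axial_rotation = 0 * c(x1, x2))
  res <- analyze_trial(x, "lateral_bending", prefilter = FALSE)
  expect_length(res$cycles, 5L)
  # after alignment all cycles peak positive in the first half
  lead <- vapply(res$cycles, function(c) max(c$angle[1:51]), 0)
  expect_true(all(lead > 30))
  expect_equal(res$outcome$rom_deg, 80, tolerance = 1)
})

test_that("a single synthetic cohort replicate recovers the injected deficit", {
  model <- fx_model()
  coh <- generate_cohort(n_subjects = 5, seed = 77)
  # the generator injects the amplitude change exactly
  for (s in coh)
    expect_equal(s$amplitudes$pre - s$amplitudes$post, c(8, 0))
  res <- cohort_peak_angle_change(coh, model)
  expect_lt(abs(mean(res$pre - res$post) - 8), 1.5)
  expect_true(res$stats$ci_high < 0)  # CI of post - pre excludes zero
  expect_true(res$stats$significant)
})
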