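#' Default brace mounting
#'
#' Orientation of the anatomical axes in the chain base frame: columns are
#' the anterior, left and superior unit vectors expressed in base
#' coordinates. The default chain is mounted with its J1 axis mediolateral
#' (base z = left), its first link pointing up (base x = superior) and base
#' y anterior, so the proximal parallel pair provides sagittal-plane
#' translation as the lower cervical spine does.
#'
#' @return 3x3 rotation matrix `N`; `v_base = N %*% v_anatomical`.
#' @export
default_mounting <- function() {
  cbind(anterior = c(0, 1, 0), left = c(0, 0, 1), up = c(1, 0, 0))
}

#' Head angles of an end-effector pose relative to neutral, in anatomical
#' axes
#'
#' The chain's end-effector frame is not anatomically aligned, so the
#' relative rotation is conjugated into the anatomical axes given by the
#' mounting before the intrinsic vertical -> anteroposterior ->
#' mediolateral decomposition.
#'
#' @param R Current end-effector orientation (base frame).
#' @param R_neutral End-effector orientation at the neutral posture.
#' @param mount Mounting matrix `N` (see [default_mounting()]).
#' @return `head_angles` vector, degrees.
#' @export
head_angles_relative <- function(R, R_neutral, mount = default_mounting()) {
  head_angles_from_rotation(t(mount) %*% R %*% t(R_neutral) %*% mount)
}

#' Rope-model muscle activation schedule
#'
#' The six neck muscles can be pictured as six ropes between the shoulders
#' and the head; a subset actuates each single-plane motion. Right axial
#' rotation uses the contralateral sternocleidomastoid (left SCM), the
#' right splenius capitis and the ipsilateral-to-SCM left trapezius;
#' lateral bending uses the three ipsilateral ropes; flexion is driven by
#' the SCM pair (with low-level trapezius co-activation stiffening the
#' head) and extension by the SC pair. Left/right cases are mirror images.
#'
#' @param motion_type One of `"axial_rotation"`, `"lateral_bending"`,
#'   `"flexion_extension"`.
#' @param direction `"right"`/`"left"` for rotation and bending;
#'   `"extension"`/`"flexion"` for the sagittal plane.
#' @return List with `active` (character vector of channel names) and
#'   `coactivation` (named numeric vector of low-level tonic channels).
#' @export
rope_activation_schedule <- function(motion_type, direction) {
  mirror <- function(x) {
    sw <- c(SCM_L = "SCM_R", SCM_R = "SCM_L", SC_L = "SC_R", SC_R = "SC_L",
            TR_L = "TR_R", TR_R = "TR_L")
    unname(sw[x])
  }
  if (motion_type == "axial_rotation") {
    if (!direction %in% c("right", "left"))
      stop("axial_rotation direction must be 'right' or 'left'", call. = FALSE)
    right <- c("SCM_L", "SC_R", "TR_L")
    act <- if (direction == "right") right else mirror(right)
    return(list(active = act, coactivation = numeric(0)))
  }
  if (motion_type == "lateral_bending") {
    if (!direction %in% c("right", "left"))
      stop("lateral_bending direction must be 'right' or 'left'", call. = FALSE)
    left <- c("SCM_L", "SC_L", "TR_L")
    act <- if (direction == "left") left else mirror(left)
    return(list(active = act, coactivation = numeric(0)))
  }
  if (motion_type == "flexion_extension") {
    if (!direction %in% c("flexion", "extension"))
      stop("flexion_extension direction must be 'flexion' or 'extension'",
           call. = FALSE)
    if (direction == "flexion")
      return(list(active = c("SCM_L", "SCM_R"),
                  coactivation = c(TR_L = 0.35, TR_R = 0.35)))
    return(list(active = c("SC_L", "SC_R"), coactivation = numeric(0)))
  }
  stop("unknown motion type: ", motion_type, call. = FALSE)
}

#' True potentiometer sensor map (synthetic ground truth)
#'
#' Per-joint monotone cubic voltage-to-angle characteristic
#' `q = s * (u + k * u^3)`, `u = V - v0`, with distinct mild nonlinearity
#' per joint: in-class for a degree-3 calibration but not for degree 1.
#' The inverse (angle to voltage) is evaluated in closed form via Cardano's
#' formula, so the generator's voltages are exact.
#'
#' @param v0 Neutral voltages (default spread around half of the 3.3 V
#'   supply).
#' @param s Linear sensitivities, rad/V.
#' @param k Cubic shape factors (1/V^2).
#' @return Object of class `sensor_map` with `angle_from_volts(V)` and
#'   `volts_from_angle(q)` operating on n x 6 matrices.
#' @export
default_sensor_map <- function(v0 = c(1.62, 1.66, 1.70, 1.64, 1.68, 1.65),
                               s = c(1.05, 0.95, 1.10, 1.00, 0.90, 1.15),
                               k = c(0.12, 0.18, 0.10, 0.15, 0.20, 0.14)) {
  force(v0); force(s); force(k)
  angle_from_volts <- function(V) {
    V <- as.matrix(V)
    u <- sweep(V, 2L, v0)
    sweep(u + sweep(u^3, 2L, k, "*"), 2L, s, "*")
  }
  volts_from_angle <- function(q) {
    q <- as.matrix(q)
    out <- q
    for (j in seq_len(ncol(q))) {
      # solve k u^3 + u - q/s = 0 (depressed cubic, one real root for k > 0)
      rhs <- q[, j] / (s[j] * k[j])
      p <- 1 / k[j]
      disc <- sqrt(rhs^2 / 4 + p^3 / 27)
      u <- (rhs / 2 + disc)^(1/3) - (pmax(disc - rhs / 2, 0))^(1/3)
      out[, j] <- v0[j] + u
    }
    out
  }
  structure(list(v0 = v0, s = s, k = k,
                 angle_from_volts = angle_from_volts,
                 volts_from_angle = volts_from_angle),
            class = "sensor_map")
}

#' Specification of one synthetic single-plane trial
#'
#' The stated world of the digital twin: five continuous movement cycles
#' per trial, each neutral -> first extreme -> opposite extreme -> neutral,
#' at the group-mean cycle periods observed pre-operatively (3.41 s axial
#' rotation, 4.00 s lateral bending, 3.89 s flexion/extension); healthy
#' full-range amplitudes; 10% kinematic coupling into the secondary planes;
#' 1 mm marker noise; 0.5% full-scale voltage noise; EMG bursts per the
#' rope activation schedule with a 1.2 Hz cardiac artifact.
#'
#' @param motion_type `"axial_rotation"`, `"lateral_bending"` or
#'   `"flexion_extension"`.
#' @param direction First-extreme direction (default `"right"`, or
#'   `"extension"` in the sagittal plane).
#' @param cycles_per_trial Number of movement cycles (default 5).
#' @param cycle_period_s Cycle duration; default is motion-specific (see
#'   above).
#' @param amplitude_deg Length-2 vector: amplitude toward the positive and
#'   negative extreme of the plane (deg). Motion-specific defaults: 70/70
#'   axial, 40/40 bending, 60 extension / 50 flexion.
#' @param coupling Secondary-plane amplitude as a fraction of primary
#'   (default 0.1).
#' @param marker_noise_mm,voltage_noise_fraction_fs Noise levels (defaults
#'   1 mm, 0.005 of the 3.3 V full scale).
#' @param emg_burst Burst parameters: centers (% cycle) of the
#'   first-direction and second-direction bursts, width (% cycle),
#'   amplitude (mV RMS at burst peak), baseline (mV RMS).
#' @param cardiac Cardiac artifact: `rate_hz` and `amplitude` (mV).
#' @param trans_coupling_mm_per_deg Translation of the rotation center C
#'   per degree of posture change: anterior with flexion, toward the bend
#'   side with lateral bending (default 0.3 mm/deg).
#' @param neutral_pad_s Neutral rest before the first and after the last
#'   cycle (default 0.6 s).
#' @param rates Sampling rates: markers, brace, emg (default 200, 100,
#'   1500 Hz).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(motion_type = "axial_rotation",
                           direction = NULL,
                           cycles_per_trial = 5,
                           cycle_period_s = NULL,
                           amplitude_deg = NULL,
                           coupling = 0.1,
                           marker_noise_mm = 1,
                           voltage_noise_fraction_fs = 0.005,
                           emg_burst = list(center1 = 20, center2 = 70,
                                            width = 30, amplitude = 1,
                                            baseline = 0.02),
                           cardiac = list(rate_hz = 1.2, amplitude = 0.04),
                           trans_coupling_mm_per_deg = 0.3,
                           neutral_pad_s = 0.6,
                           rates = c(markers = 200, brace = 100, emg = 1500)) {
  primary_plane(motion_type)  # validates
  if (is.null(direction))
    direction <- if (motion_type == "flexion_extension") "extension" else "right"
  if (is.null(cycle_period_s))
    cycle_period_s <- switch(motion_type, axial_rotation = 3.41,
                             lateral_bending = 4.00, flexion_extension = 3.89)
  if (is.null(amplitude_deg))
    amplitude_deg <- switch(motion_type, axial_rotation = c(70, 70),
                            lateral_bending = c(40, 40),
                            flexion_extension = c(60, 50))
  stopifnot(cycles_per_trial >= 1, all(amplitude_deg >= 0))
  structure(list(motion_type = motion_type, direction = direction,
                 cycles_per_trial = cycles_per_trial,
                 cycle_period_s = cycle_period_s,
                 amplitude_deg = amplitude_deg, coupling = coupling,
                 marker_noise_mm = marker_noise_mm,
                 voltage_noise_fraction_fs = voltage_noise_fraction_fs,
                 emg_burst = emg_burst, cardiac = cardiac,
                 trans_coupling_mm_per_deg = trans_coupling_mm_per_deg,
                 neutral_pad_s = neutral_pad_s, rates = rates),
            class = "synthetic_spec")
}

# translation of the rotation center C with posture: the lower cervical
# spine shifts C anteriorly with flexion and toward the bend side during
# lateral bending (anatomical frame: x anterior, y left, z up)
center_translation <- function(angles_deg_row, spec) {
  k <- spec$trans_coupling_mm_per_deg
  c(-k * angles_deg_row[["flexion_extension"]],
    -k * angles_deg_row[["lateral_bending"]], 0)
}

# biphasic raised-cosine cycle waveform on phase p in [0, 1]:
# 0 -> +A1 (at 25%) -> -A2 (at 75%) -> 0, C1-smooth at the junctions
cycle_waveform <- function(p, A1, A2) {
  y <- numeric(length(p))
  i1 <- p < 0.25
  i2 <- p >= 0.25 & p < 0.75
  i3 <- p >= 0.75
  y[i1] <- A1 / 2 * (1 - cos(pi * p[i1] / 0.25))
  y[i2] <- A1 - (A1 + A2) / 2 * (1 - cos(pi * (p[i2] - 0.25) / 0.5))
  y[i3] <- -A2 / 2 * (1 + cos(pi * (p[i3] - 0.75) / 0.25))
  y
}

# prescribed head-angle profiles (deg, n x 3) on an arbitrary timeline
prescribed_angles <- function(spec, t) {
  s1 <- if (spec$direction %in% c("right", "extension")) 1 else -1
  A <- spec$amplitude_deg
  if (s1 < 0) A <- rev(A)
  T0 <- spec$neutral_pad_s
  Tc <- spec$cycle_period_s
  prim <- numeric(length(t))
  active <- t >= T0 & t < T0 + spec$cycles_per_trial * Tc
  p <- ((t[active] - T0) %% Tc) / Tc
  prim[active] <- s1 * cycle_waveform(p, A[1], A[2])
  ang <- matrix(0, length(t), 3L,
                dimnames = list(NULL, c("flexion_extension", "lateral_bending",
                                        "axial_rotation")))
  ang[, primary_plane(spec$motion_type)] <- prim
  sec <- setdiff(colnames(ang), primary_plane(spec$motion_type))
  for (cn in sec) ang[, cn] <- spec$coupling * prim
  ang
}

trial_duration <- function(spec) {
  2 * spec$neutral_pad_s + spec$cycles_per_trial * spec$cycle_period_s
}

# neutral rigid-body geometry shared by generator and mocap emulation, all
# in the anatomical (trunk) frame with C7 at the origin
synthetic_body <- function(chain, mount) {
  fk <- .fk_cpp(chain_params(chain), rep(0, 6))
  p_n_anat <- as.numeric(t(mount) %*% fk$origins[, 7])
  c_n_anat <- as.numeric(t(mount) %*% fk$origins[, 4])  # wrist center (C)
  mid <- p_n_anat - c(0, 0, 50)
  list(
    R6n = fk$transform[1:3, 1:3],
    p_n = p_n_anat, c_n = c_n_anat,
    # chest marker level with C7 so the constructed trunk frame coincides
    # with the anatomical axes of the stated world
    trunk = list(C7 = c(0, 0, 0), CHEST = c(130, 0, 0),
                 ACR_L = c(0, 180, 0), ACR_R = c(0, -180, 0)),
    head = list(C1 = c_n_anat + c(10, 0, 15),
                HEAD_TOP = p_n_anat,
                HEAD_L = mid + c(0, 70, 0),
                HEAD_R = mid + c(0, -70, 0)))
}

# end-effector target transforms (base frame) for prescribed angles
ee_targets <- function(angles_deg, spec, body, mount) {
  n <- nrow(angles_deg)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    Rrel <- rotation_from_head_angles(angles_deg[i, ])
    c_t <- body$c_n + center_translation(angles_deg[i, ], spec)
    p_anat <- c_t + Rrel %*% (body$p_n - body$c_n)
    Rb <- mount %*% Rrel %*% t(mount)
    T <- diag(4)
    T[1:3, 1:3] <- Rb %*% body$R6n
    T[1:3, 4] <- mount %*% p_anat
    targets[[i]] <- T
  }
  targets
}

#' Generate one ground-truthed synthetic trial
#'
#' Emulates a complete single-plane acquisition: prescribed biphasic
#' raised-cosine head-angle cycles (with secondary-plane coupling and a
#' small sagittal translation of the rotation center C), joint trajectories
#' by inverse kinematics, marker trajectories at 200 Hz in an arbitrary lab
#' frame, potentiometer voltages at 100 Hz through the inverse of the true
#' sensor map, and 6-channel EMG at 1.5 kHz built from a 60-200 Hz
#' band-limited carrier amplitude-modulated by the rope-model burst
#' schedule plus a cardiac spike train. A shared digital trigger edge (at
#' 0.3 s on the physical timeline; the EMG clock runs 0.5 s ahead) is
#' embedded in the voltage and EMG streams.
#'
#' @param spec A [synthetic_spec()].
#' @param chain A `dh_chain` (default [default_chain()]).
#' @param sensor_map A `sensor_map` (default [default_sensor_map()]).
#' @param mount Mounting matrix (default [default_mounting()]).
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param streams Which streams to synthesize, subset of
#'   `c("markers", "voltage", "emg")`.
#' @param participant,visit Identifiers stamped on the streams.
#' @param emg_timing_shift_pct Named per-channel shift of burst centers in
#'   % cycle (models post-operative timing changes), default none.
#' @return List of class `synthetic_trial`: `markers` (named list of n x 3
#'   lab-frame matrices), `voltages` ([voltage_log()]), `emg`
#'   ([emg_recording()]), and `ground_truth` (time, prescribed angles,
#'   joint trajectories, cycle boundaries in brace samples, burst centers
#'   per muscle, trigger time).
#' @export
generate_trial <- function(spec, chain = default_chain(),
                           sensor_map = default_sensor_map(),
                           mount = default_mounting(), seed = 1,
                           streams = c("markers", "voltage", "emg"),
                           participant = "P1", visit = "pre",
                           emg_timing_shift_pct = NULL) {
  set.seed(seed)
  body <- synthetic_body(chain, mount)
  dur <- trial_duration(spec)
  fs_b <- spec$rates[["brace"]]
  t100 <- seq(0, dur, by = 1 / fs_b)
  angles <- prescribed_angles(spec, t100)
  targets <- ee_targets(angles, spec, body, mount)
  ik <- ik_trajectory(chain, targets, q_init = rep(0, 6))
  if (max(ik$pos_err) > 0.1 || max(ik$ori_err) > 0.01)
    stop(sprintf("generate_trial: prescribed %s amplitude unreachable (max position residual %.2f mm)",
                 spec$motion_type, max(ik$pos_err)), call. = FALSE)
  q <- ik$q
  trig_t <- 0.3
  out <- list(spec = spec, participant = participant, visit = visit)

  if ("voltage" %in% streams) {
    V <- sensor_map$volts_from_angle(q)
    sdv <- spec$voltage_noise_fraction_fs * 3.3
    if (sdv > 0) V <- V + matrix(rnorm(length(V), 0, sdv), nrow(V))
    V <- pmin(pmax(V, 0), 3.3)
    out$voltages <- voltage_log(t100, V,
                                trigger = as.numeric(t100 >= trig_t &
                                                       t100 < trig_t + 0.1),
                                sample_rate = fs_b)
  }

  if ("markers" %in% streams) {
    fs_m <- spec$rates[["markers"]]
    tm <- seq(0, dur, by = 1 / fs_m)
    am <- prescribed_angles(spec, tm)
    lab <- lab_frame_transform()
    markers <- synth_markers(am, spec, body, lab, spec$marker_noise_mm)
    out$markers <- markers
    out$marker_time_s <- tm
  }

  if ("emg" %in% streams) {
    out$emg <- synth_emg(spec, dur, trig_t, participant, visit,
                         emg_timing_shift_pct)
  }

  pad <- spec$neutral_pad_s
  bounds <- round((pad + (0:spec$cycles_per_trial) * spec$cycle_period_s) * fs_b) + 1L
  centers <- emg_burst_centers(spec, emg_timing_shift_pct)
  out$ground_truth <- list(time_s = t100, angles_deg = angles, q = q,
                           cycle_bounds = bounds,
                           burst_centers_pct = centers,
                           trigger_time_s = trig_t)
  class(out) <- "synthetic_trial"
  out
}

# fixed arbitrary lab frame so trunk-frame reconstruction does real work
lab_frame_transform <- function() {
  R <- rot_z(25 * pi / 180) %*% rot_x(5 * pi / 180)
  list(R = R, t = c(850, -400, 120))
}

synth_markers <- function(angles_deg, spec, body, lab, noise_mm) {
  n <- nrow(angles_deg)
  out <- lapply(MARKER_LABELS, function(l) matrix(0, n, 3L))
  names(out) <- MARKER_LABELS
  for (i in seq_len(n)) {
    Rrel <- rotation_from_head_angles(angles_deg[i, ])
    c_t <- body$c_n + center_translation(angles_deg[i, ], spec)
    for (l in names(body$trunk))
      out[[l]][i, ] <- lab$R %*% body$trunk[[l]] + lab$t
    for (l in names(body$head)) {
      p <- c_t + Rrel %*% (body$head[[l]] - body$c_n)
      out[[l]][i, ] <- lab$R %*% p + lab$t
    }
  }
  if (noise_mm > 0) {
    for (l in MARKER_LABELS)
      out[[l]] <- out[[l]] + matrix(rnorm(3 * n, 0, noise_mm), n, 3L)
  }
  out
}

emg_burst_centers <- function(spec, shift_pct = NULL) {
  sch1 <- rope_activation_schedule(spec$motion_type, spec$direction)
  opp <- switch(spec$direction, right = "left", left = "right",
                extension = "flexion", flexion = "extension")
  sch2 <- rope_activation_schedule(spec$motion_type, opp)
  centers <- setNames(rep(NA_real_, length(EMG_CHANNELS)), EMG_CHANNELS)
  centers[sch1$active] <- spec$emg_burst$center1
  centers[sch2$active] <- spec$emg_burst$center2
  if (!is.null(shift_pct)) {
    for (ch in names(shift_pct))
      centers[ch] <- centers[ch] + shift_pct[[ch]]
  }
  attr(centers, "coactivation") <-
    c(sch1$coactivation, sch2$coactivation)[!duplicated(
      names(c(sch1$coactivation, sch2$coactivation)))]
  centers
}

synth_emg <- function(spec, dur, trig_t, participant, visit,
                      shift_pct = NULL) {
  fs <- spec$rates[["emg"]]
  clock_offset <- 0.5  # the EMG system's clock starts 0.5 s before the brace's
  t_phys <- seq(0, dur, by = 1 / fs)
  n <- length(t_phys)
  centers <- emg_burst_centers(spec, shift_pct)
  coact <- attr(centers, "coactivation")
  pad <- spec$neutral_pad_s
  Tc <- spec$cycle_period_s
  active <- t_phys >= pad & t_phys < pad + spec$cycles_per_trial * Tc
  phase <- ((t_phys - pad) %% Tc) / Tc * 100
  bump <- function(center_pct) {
    g <- numeric(n)
    hw <- spec$emg_burst$width / 2
    d <- (phase - center_pct + 150) %% 100 - 50  # wrapped distance in % cycle
    in_b <- active & abs(d) < hw
    g[in_b] <- 0.5 * (1 + cos(pi * d[in_b] / hw))
    g
  }
  des <- butter_design(4, c(60, 200), fs, "band")
  # cardiac spike template: biphasic, ~40 ms
  beat_idx <- round(seq(0.1, dur, by = 1 / spec$cardiac$rate_hz) * fs) + 1L
  tpl_len <- round(0.04 * fs)
  tpl <- sin(2 * pi * seq_len(tpl_len) / tpl_len * 2) *
    sin(pi * seq_len(tpl_len) / tpl_len)^2 * spec$cardiac$amplitude / 0.7
  channels <- matrix(0, n, length(EMG_CHANNELS),
                     dimnames = list(NULL, EMG_CHANNELS))
  for (ch in EMG_CHANNELS) {
    carrier <- filtfilt_zero_phase(des$b, des$a, rnorm(n))
    carrier <- carrier / sqrt(mean(carrier^2))
    gain <- spec$emg_burst$baseline
    if (!is.na(centers[ch]))
      gain <- gain + spec$emg_burst$amplitude * bump(centers[ch])
    if (ch %in% names(coact))
      gain <- gain + spec$emg_burst$amplitude * coact[[ch]] * as.numeric(active)
    x <- carrier * gain
    cardiac <- numeric(n)
    for (b in beat_idx) {
      idx <- b:min(b + tpl_len - 1L, n)
      cardiac[idx] <- cardiac[idx] + tpl[seq_along(idx)]
    }
    channels[, ch] <- x + cardiac + rnorm(n, 0, spec$emg_burst$baseline / 4)
  }
  emg_recording(t_phys + clock_offset, channels,
                trigger = as.numeric(t_phys >= trig_t & t_phys < trig_t + 0.1),
                sample_rate = fs, participant = participant, visit = visit)
}

#' Generate a complete synthetic session
#'
#' One clinic visit of the digital twin: a 1 s static (neutral) trial plus
#' one dynamic trial per requested motion type, with a common participant,
#' visit label, chain, sensor map and seed. Seeds for the individual trials
#' are derived deterministically from `seed`.
#'
#' @param motions Motion types to include (default all three single-plane
#'   motions).
#' @param specs Optional named list of [synthetic_spec()] overrides per
#'   motion.
#' @inheritParams generate_trial
#' @return List of class `synthetic_session`: `markers` (a
#'   [marker_session()] with `static` plus one trial per motion),
#'   `trials` (named list of `synthetic_trial`), `chain`, `sensor_map`,
#'   `mount`, `participant`, `visit`.
#' @export
generate_session <- function(motions = c("axial_rotation", "lateral_bending",
                                         "flexion_extension"),
                             specs = NULL, chain = default_chain(),
                             sensor_map = default_sensor_map(),
                             mount = default_mounting(), seed = 1,
                             streams = c("markers", "voltage", "emg"),
                             participant = "P1", visit = "pre") {
  trials <- list()
  mtrials <- list()
  body <- synthetic_body(chain, mount)
  # static trial: 1 s of neutral posture
  set.seed(seed * 1000L + 999L)
  sp0 <- if (!is.null(specs) && !is.null(specs[[motions[1]]]))
    specs[[motions[1]]] else synthetic_spec(motions[1])
  fs_m <- sp0$rates[["markers"]]
  lab <- lab_frame_transform()
  nstat <- fs_m  # 1 s
  a0 <- matrix(0, nstat, 3L,
               dimnames = list(NULL, c("flexion_extension", "lateral_bending",
                                       "axial_rotation")))
  mtrials$static <- synth_markers(a0, sp0, body, lab, sp0$marker_noise_mm)
  for (k in seq_along(motions)) {
    m <- motions[k]
    sp <- if (!is.null(specs) && !is.null(specs[[m]])) specs[[m]] else
      synthetic_spec(m)
    tr <- generate_trial(sp, chain, sensor_map, mount,
                         seed = seed * 1000L + k, streams = streams,
                         participant = participant, visit = visit)
    trials[[m]] <- tr
    if (!is.null(tr$markers)) mtrials[[m]] <- tr$markers
  }
  markers <- if (length(mtrials) > 1L || "markers" %in% streams)
    marker_session(mtrials, sample_rate = fs_m) else NULL
  structure(list(markers = markers, trials = trials, chain = chain,
                 sensor_map = sensor_map, mount = mount,
                 participant = participant, visit = visit),
            class = "synthetic_session")
}
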