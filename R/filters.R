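#' Butterworth digital filter design
#'
#' Designs Butterworth low-pass, high-pass or band-pass filters via the
#' analog prototype and bilinear transform (the classic zpk pipeline). No
#' external DSP dependency is available in this stack, so the design is
#' implemented here and verified in the test suite against the analytic
#' Butterworth magnitude response.
#'
#' @param order Filter order of the analog prototype (a band-pass doubles
#'   the final order).
#' @param cutoff Cutoff frequency/frequencies in Hz: one value for
#'   `"low"`/`"high"`, two for `"band"`.
#' @param fs Sampling rate, Hz.
#' @param type `"low"`, `"high"` or `"band"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (`a[1] = 1`).
#' @export
butter_design <- function(order, cutoff, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("butter_design: cutoff must lie strictly inside (0, fs/2)",
         call. = FALSE)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- complex(0)
  gain <- 1
  fs2 <- 4  # 2 * internal sampling rate of 2 used for the bilinear map
  warped <- 4 * tan(pi * cutoff / fs)  # prewarped analog cutoff
  if (type == "low") {
    p <- warped * p
    gain <- gain * warped^order
  } else if (type == "high") {
    gain <- gain * Re(prod(-p))
    p <- warped / p
    z <- rep(0 + 0i, order)
  } else {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2])
      stop("butter_design: band-pass needs cutoff = c(low, high)", call. = FALSE)
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    p <- p * bw / 2
    p <- c(p + sqrt(p^2 - w0^2), p - sqrt(p^2 - w0^2))
    z <- rep(0 + 0i, order)
    gain <- gain * bw^order
  }
  # bilinear transform to the z-domain
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  poly_from_roots <- function(r) {
    cf <- 1 + 0i
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    Re(cf)
  }
  list(b = gain * poly_from_roots(zd), a = poly_from_roots(pd))
}

# steady-state initial filter state for a unit step (lfilter_zi equivalent):
# starting a constant signal with state zi * x[1] removes the startup
# transient exactly.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1L) return(numeric(0))
  companion_t <- matrix(0, n - 1, n - 1)
  companion_t[1, ] <- -a[-1]
  if (n > 2L) companion_t[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(companion_t)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

apply_iir <- function(b, a, x, zi = NULL) {
  if (is.null(zi)) zi <- rep(0, max(length(a), length(b)) - 1L)
  .lfilter_cpp(b, a, x, zi)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Filters the signal forward then backward so the net phase response is
#' zero and event timing (angle peaks, EMG bursts) is preserved. Edges are
#' handled by odd (point-reflected) extension plus steady-state initial
#' conditions, so a constant signal passes through bit-exactly up to
#' floating point.
#'
#' @param b,a Filter coefficients from [butter_design()].
#' @param x Numeric signal.
#' @param padlen Extension length per edge (default `3 * max(length(a),
#'   length(b))`).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x, padlen = 3L * max(length(a), length(b))) {
  n <- length(x)
  if (n <= padlen)
    stop(sprintf("filtfilt: series too short (%d samples, need > %d)",
                 n, padlen), call. = FALSE)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- apply_iir(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- apply_iir(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Centered moving average with edge shrinkage
#'
#' The EMG linear-envelope smoother: an un-weighted centered moving mean
#' over `window` samples; near the edges the window shrinks to the
#' available samples so no phase shift or padding artifact is introduced.
#' For an even window the span is `[-window/2, window/2 - 1]` samples.
#'
#' @param x Numeric signal.
#' @param window Window size in samples (default 300, i.e. 0.2 s at 1.5 kHz).
#' @return Smoothed signal, same length.
#' @export
moving_average <- function(x, window = 300L) {
  n <- length(x)
  half_lo <- floor(window / 2)
  half_hi <- ceiling(window / 2) - 1L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Low-pass filter brace head-angle series
#'
#' Zero-lag fourth-order Butterworth low-pass at 6 Hz, the standard
#' smoothing applied to the 100 Hz brace joint/head angle streams before
#' segmentation and outcome computation.
#'
#' @param angles Numeric vector, or a matrix/data.frame filtered per column.
#' @param fs Sampling rate, Hz (default 100).
#' @param cutoff Cutoff, Hz (default 6).
#' @param order Filter order (default 4).
#' @return Filtered object of the same shape.
#' @export
filter_angles <- function(angles, fs = 100, cutoff = 6, order = 4) {
  des <- butter_design(order, cutoff, fs, "low")
  if (is.null(dim(angles))) {
    filtfilt_zero_phase(des$b, des$a, as.numeric(angles))
  } else {
    out <- angles
    for (j in seq_len(ncol(angles)))
      out[, j] <- filtfilt_zero_phase(des$b, des$a, as.numeric(angles[, j]))
    out
  }
}
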