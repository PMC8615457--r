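#' Zero-phase low-pass Butterworth filter
#'
#' Smooths a uniformly sampled series with a fourth-order Butterworth
#' low-pass design applied bidirectionally (forward and backward), the
#' standard zero-phase smoother for motion-capture and force-plate data.
#' Each pass attenuates by 3 dB at the cut-off, so the bidirectional
#' amplitude gain at `fc` is 0.5.  Edge transients are suppressed by
#' odd-reflection padding and by starting each pass from the filter's
#' step-response steady state, so a constant series passes through
#' unchanged.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param fc Cut-off frequency in Hz; must be below the Nyquist rate `fs/2`.
#' @param order Filter order of a single pass (default 4).
#' @return Filtered series, same length as `x`, with unit DC gain and zero
#'   phase distortion.
#' @examples
#' t <- seq(0, 2, by = 1 / 120)
#' noisy <- sin(2 * pi * t) + rnorm(length(t), sd = 0.05)
#' smooth <- butterworth_lowpass(noisy, fs = 120, fc = 6)
#' @export
butterworth_lowpass <- function(x, fs, fc, order = 4L) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.numeric(fc) || length(fc) != 1L ||
      fc <= 0 || fs <= 0) {
    stop_wbam("wbam_invalid_cutoff", "fs and fc must be positive scalars")
  }
  if (fc >= fs / 2) {
    stop_wbam("wbam_invalid_cutoff",
              "cut-off %g Hz is at or above the Nyquist rate %g Hz", fc, fs / 2)
  }
  x <- as.numeric(x)
  n <- length(x)
  ba <- signal::butter(order, fc / (fs / 2), type = "low")
  b <- ba$b
  a <- ba$a
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen) {
    stop_wbam("wbam_length_error",
              "series of length %d is too short to filter (need > %d samples)",
              n, padlen)
  }
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- df2t_filter(b, a, ext, zi * ext[1L])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Steady-state initial conditions of a direct-form-II-transposed filter,
#' scaled for unit step input (so a constant c starts with state zi * c).
#' @noRd
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1L]
  b <- c(b, rep(0, n - length(b))) / a[1L]
  # companion matrix of a
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  rhs <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), rhs)
}

#' Single-pass IIR filter in direct form II transposed with initial state.
#' @noRd
df2t_filter <- function(b, a, x, zi) {
  n <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1L] * xm + z[1L]
    for (i in seq_len(n - 2L)) {
      z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
    }
    z[n - 1L] <- b[n] * xm - a[n] * ym
    y[m] <- ym
  }
  y
}
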