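#' Modified Bessel function of the first kind, order zero
#'
#' Power-series evaluation \eqn{I_0(z) = \sum_i ((z/2)^i / i!)^2}, summed
#' until the next term falls below `1e-12` of the running sum.  This is the
#' kernel of the Kaiser window; base R's `besselI()` serves as an independent
#' cross-check in the test suite, never as the implementation.
#'
#' @param z Non-negative numeric vector.
#' @return `I0(z)`, same length as `z`.
#' @examples
#' bessel_i0(c(0, 1, 3))
#' @export
bessel_i0 <- function(z) {
  if (any(z < 0)) stop("`z` must be >= 0", call. = FALSE)
  vapply(z, function(zz) {
    total <- 1.0
    term <- 1.0
    i <- 1L
    half_sq <- (zz / 2)^2
    repeat {
      term <- term * half_sq / (i * i)
      total <- total + term
      if (term < 1e-12 * total) break
      i <- i + 1L
    }
    total
  }, numeric(1))
}

#' Kaiser window
#'
#' \eqn{w[n] = I_0(\beta \sqrt{1 - (2n/N - 1)^2}) / I_0(\beta)} for
#' \eqn{0 \le n \le N} (length `N + 1`, symmetric, unit center for even `N`).
#' `beta` trades main-lobe width against sidelobe level; `beta = 0` gives a
#' rectangular window.
#'
#' @param N Window order (>= 2); the window has `N + 1` points.
#' @param beta Shape parameter (>= 0).
#' @return Numeric vector of length `N + 1` with values in `(0, 1]`.
#' @examples
#' w <- kaiser_window(16, 6)
#' all.equal(w, rev(w))
#' @export
kaiser_window <- function(N, beta) {
  if (!is.numeric(N) || length(N) != 1L || N < 2) {
    stop("`N` must be >= 2", call. = FALSE)
  }
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  n <- 0:N
  arg <- 1 - (2 * n / N - 1)^2
  arg[arg < 0] <- 0  # guard fp noise at the endpoints
  bessel_i0(beta * sqrt(arg)) / bessel_i0(beta)
}

#' FIR bandpass filter specification
#'
#' Parameters of the Kaiser-window FIR bandpass used to pre-process the
#' sampled pulse waveform.  Defaults are the device settings: `N = 128`
#' (129 taps), passband 0.6-5 Hz at `fs` = 10 kHz, i.e. 36-300 beats/min.
#' `beta` defaults to 6 (the device's value is unstated; 6 gives ~60 dB
#' sidelobes).
#'
#' Note a structural property of the windowed-sinc design: resolving the
#' passband edges requires the kernel to span on the order of `1 / fc1`
#' seconds.  At the default `N / fs` = 12.8 ms the kernel is far shorter
#' than `1 / 0.6 Hz`, so the realized response is a short positive smoothing
#' kernel that retains the signal mean rather than a true DC-free bandpass;
#' see the methods vignette.  Configurations with `N / fs` of a few seconds
#' (e.g. `fs = 200`, `N = 2000`) realize the nominal bandpass.
#'
#' @param N Filter order (even, >= 8); the design has `N + 1` taps.
#' @param fc1,fc2 Lower/upper cutoff in Hz, `0 < fc1 < fc2 < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param beta Kaiser shape parameter.
#' @return An object of class `fir_spec`.
#' @export
fir_spec <- function(N = 128, fc1 = 0.6, fc2 = 5, fs = 10000, beta = 6) {
  if (N < 8) stop("`N` must be >= 8", call. = FALSE)
  if (N %% 2 != 0) stop("`N` must be even (integer group delay N/2)", call. = FALSE)
  if (!(fc1 > 0 && fc1 < fc2)) stop("require 0 < fc1 < fc2", call. = FALSE)
  if (fc2 >= fs / 2) stop("`fc2` must be below the Nyquist rate fs/2", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  structure(list(N = as.integer(N), fc1 = fc1, fc2 = fc2, fs = fs, beta = beta),
            class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat(sprintf("<fir_spec> %d taps, passband %g-%g Hz @ fs %g Hz (%g-%g bpm), beta %g\n",
              x$N + 1L, x$fc1, x$fc2, x$fs, x$fc1 * 60, x$fc2 * 60, x$beta))
  invisible(x)
}

#' Design the Kaiser-window FIR bandpass
#'
#' Windowed ideal-bandpass impulse response centered at tap `N/2`:
#' `b[n] = w[n] * h_d[n]` with
#' \eqn{h_d[m] = (\sin(\omega_{c2} m) - \sin(\omega_{c1} m)) / (\pi m)}
#' (`m = n - N/2`), the singular center sample replaced by
#' \eqn{(\omega_{c2} - \omega_{c1}) / \pi}, and digital angular frequencies
#' \eqn{\omega_c = 2\pi f_c / f_s}.  The taps are symmetric, giving linear
#' phase with group delay `N/2` samples.
#'
#' @param spec A [fir_spec()] object.
#' @return Numeric coefficient vector of length `N + 1` with attributes
#'   `group_delay` (samples) and `spec`.
#' @examples
#' b <- design_bandpass(fir_spec())
#' length(b)
#' @export
design_bandpass <- function(spec = fir_spec()) {
  if (!inherits(spec, "fir_spec")) stop("`spec` must be a fir_spec", call. = FALSE)
  wc1 <- 2 * pi * spec$fc1 / spec$fs
  wc2 <- 2 * pi * spec$fc2 / spec$fs
  m <- (0:spec$N) - spec$N / 2
  hd <- ifelse(m == 0,
               (wc2 - wc1) / pi,
               (sin(wc2 * m) - sin(wc1 * m)) / (pi * m))
  b <- kaiser_window(spec$N, spec$beta) * hd
  attr(b, "group_delay") <- spec$N / 2
  attr(b, "spec") <- spec
  b
}

#' Frequency response of an FIR coefficient vector
#'
#' Direct evaluation of \eqn{H(f) = \sum_k b_k e^{-i 2 \pi f k / f_s}}.
#'
#' @param b Coefficient vector.
#' @param f Frequencies in Hz (vector).
#' @param fs Sampling rate in Hz.
#' @return Complex vector `H(f)`.
#' @export
fir_response <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(ff) sum(b * exp(-1i * 2 * pi * ff * k / fs)),
         complex(1))
}

#' Apply an FIR filter to a trace
#'
#' Causal convolution `y[n] = sum_k b[k] x[n - k]` with zero-padded history;
#' the output has the same length as the input.  For the symmetric designs
#' of [design_bandpass()] the filter is linear phase: all features are
#' delayed by the same `group_delay` samples, so transit times measured
#' between two channels filtered with the same `b` are unchanged.  The group
#' delay is reported in the output trace's metadata, not trimmed.
#'
#' @param trace A [signal_trace()].
#' @param b Numeric coefficient vector (non-empty).
#' @return A [signal_trace()] of the same length with
#'   `meta$group_delay_samples` set.
#' @export
fir_filter <- function(trace, b) {
  if (!inherits(trace, "signal_trace")) {
    stop("`trace` must be a signal_trace", call. = FALSE)
  }
  if (length(b) < 1L || !is.numeric(b)) {
    stop("`b` must be a non-empty numeric coefficient vector", call. = FALSE)
  }
  y <- fir_core(trace$x, as.numeric(b))
  gd <- attr(b, "group_delay")
  if (is.null(gd)) gd <- (length(b) - 1) / 2
  meta <- trace$meta
  meta$group_delay_samples <- gd
  signal_trace(y, trace$fs, channel = trace$channel, units = trace$units,
               meta = meta)
}
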