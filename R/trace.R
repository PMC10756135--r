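#' Uniformly sampled waveform
#'
#' Container for a single-channel, uniformly sampled signal.  Sample `n`
#' (0-based) is taken at time `n / fs` seconds; all event tables produced by
#' the package use the same 0-based index convention so that `time = index /
#' fs`.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param channel Channel label, e.g. `"ch1"`.
#' @param units Amplitude units (informational), default `"mV"`.
#' @param meta Named list of free-form metadata (e.g. filter group delay).
#'
#' @return An object of class `signal_trace`: a list with elements `x`, `fs`,
#'   `channel`, `units` and `meta`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1 * (0:999) / 100), fs = 100)
#' tr
#' @export
signal_trace <- function(x, fs, channel = "ch1", units = "mV", meta = list()) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(x)) stop("`x` contains NA values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), fs = as.numeric(fs), channel = channel,
         units = units, meta = meta),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples @ %g Hz (%.3f s), units %s\n",
              x$channel, length(x$x), x$fs, length(x$x) / x$fs, x$units))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$x)

#' @export
as.data.frame.signal_trace <- function(x, ...) {
  data.frame(time_s = (seq_along(x$x) - 1) / x$fs, value = x$x)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
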