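#' Pair detected features across the two channels
#'
#' Matches each proximal-channel (P1) event of the chosen kind with the
#' earliest subsequent distal-channel (P2) event of the same kind whose lag
#' lies in `(0, max_ptt]`.  Pairs never cross (each P2 event is consumed at
#' most once, in order) and unpaired events on either side are dropped and
#' counted.  For physiologic beat trains — inter-beat spacing much larger
#' than `max_ptt` — this greedy pairing coincides with the assignment
#' minimizing total lag subject to non-crossing.
#'
#' @param events_p1,events_p2 Event tables from [detect_features()] for the
#'   proximal and distal channel.
#' @param mode `"pp"` to pair peaks (the device convention: transit time is
#'   measured between the peaks of the two outputs) or `"ff"` to pair the
#'   feet (pre-upstroke troughs).
#' @param max_ptt Largest admissible transit time in seconds (default 0.05,
#'   a loose physiologic bound: >= 0.6 m/s over 3 cm).
#' @param fs Sampling rate in Hz shared by both channels.
#' @return A data.frame of class `beat_pairs` with columns `beat`, `index1`,
#'   `index2`, `time1_s`, `time2_s`, `value1`, `value2`; attributes
#'   `unpaired_p1`, `unpaired_p2` (counts) and `mode`.
#' @export
pair_beats <- function(events_p1, events_p2, mode = c("pp", "ff"),
                       max_ptt = 0.05, fs) {
  mode <- match.arg(mode)
  if (max_ptt <= 0) stop("`max_ptt` must be > 0", call. = FALSE)
  stopifnot_scalar_pos(fs, "fs")
  want <- if (mode == "pp") "peak" else "trough"
  e1 <- events_p1[events_p1$kind == want, , drop = FALSE]
  e2 <- events_p2[events_p2$kind == want, , drop = FALSE]
  max_lag <- max_ptt * fs

  n1 <- nrow(e1)
  n2 <- nrow(e2)
  out_i <- integer(0)
  out_j <- integer(0)
  j <- 1L
  for (i in seq_len(n1)) {
    # advance past P2 events at or before this P1 event
    while (j <= n2 && e2$index[j] <= e1$index[i]) j <- j + 1L
    if (j > n2) break
    lag <- e2$index[j] - e1$index[i]
    if (lag <= max_lag) {
      out_i <- c(out_i, i)
      out_j <- c(out_j, j)
      j <- j + 1L
    }
  }
  pairs <- data.frame(
    beat = seq_along(out_i),
    index1 = e1$index[out_i], index2 = e2$index[out_j],
    time1_s = e1$time_s[out_i], time2_s = e2$time_s[out_j],
    value1 = e1$value[out_i], value2 = e2$value[out_j]
  )
  attr(pairs, "unpaired_p1") <- n1 - length(out_i)
  attr(pairs, "unpaired_p2") <- n2 - length(out_j)
  attr(pairs, "mode") <- mode
  class(pairs) <- c("beat_pairs", "data.frame")
  pairs
}

#' Pulse transit time of paired beats
#'
#' `ptt = (index2 - index1) / fs`; the resolution is one sample period
#' (0.1 ms at 10 kHz).  A non-positive transit time signals mis-ordered
#' channels and is rejected.
#'
#' @param pairs A [pair_beats()] table.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of transit times in seconds, one per pair.
#' @examples
#' # one-sample lag at 10 kHz is 0.1 ms
#' @export
compute_ptt <- function(pairs, fs) {
  stopifnot_scalar_pos(fs, "fs")
  lag <- pairs$index2 - pairs$index1
  if (any(lag <= 0)) {
    stop("non-positive transit time: channels appear mis-ordered", call. = FALSE)
  }
  lag / fs
}

#' Convert transit time to local pulse wave velocity
#'
#' `pwv = L / ptt` over the fixed sensor separation; shorter transit means
#' faster wave and higher pressure.
#'
#' @param ptt Transit time(s) in seconds (> 0).
#' @param L Sensor separation in meters (default 0.03).
#' @return Pulse wave velocity in m/s.
#' @examples
#' ptt_to_pwv(0.005)  # 6 m/s over 3 cm
#' @export
ptt_to_pwv <- function(ptt, L = 0.03) {
  stopifnot_scalar_pos(L, "L")
  if (any(ptt <= 0)) stop("`ptt` must be > 0", call. = FALSE)
  L / ptt
}

#' Aggregate beat-wise PWV samples to a subject-level value
#'
#' The median of the beat-wise values (midpoint of the two central values
#' for even counts), robust to occasional mis-detected beats.
#'
#' @param pwv Numeric vector of beat-wise PWV values (non-empty).
#' @return The median PWV in m/s.
#' @export
aggregate_pwv <- function(pwv) {
  if (length(pwv) < 1L) stop("empty PWV sample list", call. = FALSE)
  median(pwv)
}

#' Beat-wise PWV table from paired events
#'
#' Convenience composition of [compute_ptt()] and [ptt_to_pwv()].
#'
#' @inheritParams compute_ptt
#' @inheritParams ptt_to_pwv
#' @return A data.frame with `beat`, `ptt_s`, `pwv_mps`.
#' @export
pwv_samples <- function(pairs, fs, L = 0.03) {
  ptt <- compute_ptt(pairs, fs)
  data.frame(beat = pairs$beat, ptt_s = ptt, pwv_mps = ptt_to_pwv(ptt, L))
}
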