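#' Measurement session under the alternating reference protocol
#'
#' The clinical protocol alternates the reference sphygmomanometer and the
#' device under test: with 4 reference and 3 test readings, test reading i
#' is compared with the mean of reference readings i and i+1.  A session
#' therefore carries one more reference reading than test readings.
#'
#' @param reference Ordered reference readings in mmHg (length >= 2).
#' @param test Ordered device readings in mmHg (length = reference - 1).
#' @param quantity Which quantity the readings are: `"SBP"`, `"DBP"` or
#'   `"MAP"`.
#' @return An object of class `measurement_session`.
#' @export
measurement_session <- function(reference, test,
                                quantity = c("SBP", "DBP", "MAP")) {
  quantity <- match.arg(quantity)
  if (length(reference) < 2L) {
    stop("need at least 2 reference readings", call. = FALSE)
  }
  if (length(reference) != length(test) + 1L) {
    stop(sprintf(
      "alternating protocol requires length(reference) == length(test) + 1 (got %d and %d)",
      length(reference), length(test)), call. = FALSE)
  }
  structure(list(reference = as.numeric(reference), test = as.numeric(test),
                 quantity = quantity),
            class = "measurement_session")
}

#' Pair device readings with adjacent-mean reference values
#'
#' Test reading i is paired with `(reference[i] + reference[i+1]) / 2`.
#'
#' @param session A [measurement_session()] object.
#' @return A data.frame with columns `test` and `paired_ref` (one row per
#'   device reading).
#' @examples
#' s <- measurement_session(c(120, 118, 122, 120), c(119, 121, 120))
#' pair_references(s)
#' @export
pair_references <- function(session) {
  if (!inherits(session, "measurement_session")) {
    stop("`session` must be a measurement_session", call. = FALSE)
  }
  r <- session$reference
  n <- length(session$test)
  data.frame(test = session$test,
             paired_ref = (r[seq_len(n)] + r[seq_len(n) + 1L]) / 2)
}

#' ISO-style mean difference and standard deviation of paired differences
#'
#' `md = mean(test - ref)` and `std = sqrt(mean((test - ref)^2))` — the
#' uncentered root-mean-square of the differences, exactly as the standard's
#' formula prints it (divisor n, not centered on the mean).  Because the
#' reported clinical convention is ambiguous, the conventional centered
#' sample standard deviation (divisor n - 1) is also returned, clearly
#' labelled.  The algebraic identity `std^2 = uncentered variance =
#' centered variance (divisor n) + md^2` links the two.
#'
#' @param differences Numeric vector of paired differences (test - ref) in
#'   mmHg, non-empty.
#' @return A list with `md`, `std` (uncentered RMS), `sd_centered`
#'   (divisor n - 1; `NA` for a single pair) and `n`.
#' @examples
#' iso_stats(c(1, -1))  # md 0, std 1
#' @export
iso_stats <- function(differences) {
  n <- length(differences)
  if (n < 1L) stop("empty difference vector", call. = FALSE)
  md <- mean(differences)
  std <- sqrt(mean(differences^2))
  list(md = md, std = std,
       sd_centered = if (n >= 2L) sd(differences) else NA_real_,
       n = n)
}

#' ISO 81060-2 headline pass/fail
#'
#' Passes when `|md| <= 5` mmHg and `std <= 8` mmHg (bounds treated as
#' inclusive).
#'
#' @param md Mean difference in mmHg.
#' @param std Standard deviation of differences in mmHg.
#' @return Logical flag.
#' @examples
#' passes_iso(-0.63, 5.14)  # TRUE
#' @export
passes_iso <- function(md, std) {
  abs(md) <= 5 & std <= 8
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` summarized by their mean (bias), centered sample
#' standard deviation, and limits of agreement `bias +/- 1.96 sd`; the
#' plotting coordinates (pairwise mean, difference) are returned for
#' rendering.
#'
#' @param a,b Numeric vectors of equal length `n >= 2` (e.g. device and
#'   reference readings in mmHg).
#' @return An object of class `agreement_report`: list with `bias`,
#'   `sd`, `loa` (length-2 lower/upper), `n`, `points` (data.frame with
#'   `mean` and `diff`), plus ISO fields `md`, `std` (uncentered) and
#'   `passes_iso`.
#' @examples
#' bland_altman(c(120, 118, 125), c(119, 120, 124))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need n >= 2 pairs (SD undefined otherwise)", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sdev <- sd(d)
  iso <- iso_stats(d)
  structure(
    list(bias = bias, sd = sdev,
         loa = c(lower = bias - 1.96 * sdev, upper = bias + 1.96 * sdev),
         n = length(d),
         points = data.frame(mean = (a + b) / 2, diff = d),
         md = iso$md, std = iso$std,
         passes_iso = passes_iso(iso$md, iso$std)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d, bias %.2f mmHg, SD %.2f, LoA [%.2f, %.2f], ISO md %.2f / std %.2f -> %s\n",
    x$n, x$bias, x$sd, x$loa[1], x$loa[2], x$md, x$std,
    if (x$passes_iso) "pass" else "fail"))
  invisible(x)
}
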