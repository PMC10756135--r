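#' Sensor cavity parameters
#'
#' Mechanical description of the airtight sensor cavity: a rubber film of
#' mass `m = rho_medium * S * L_eff` sits on a sealed gas volume `V` at
#' atmospheric pressure `P_A`; compressing the film by `x` raises the cavity
#' pressure adiabatically (ratio of specific heats `gamma_air`, ~1.4 for
#' air), which makes the film-on-gas system equivalent to a mass on a
#' spring.
#'
#' @param rho_medium Density of the film medium in kg/m^3 (default 1100,
#'   a representative rubber; the medium the literature attaches to this
#'   symbol is ambiguous, so it is a single configurable field).
#' @param L_eff Effective film length in meters.
#' @param S Film cross-sectional area in m^2.
#' @param V Cavity volume in m^3.
#' @param P_A Atmospheric pressure in Pa (default 101325).
#' @param gamma_air Ratio of specific heats (default 1.4).
#' @param x Compression displacement in meters (>= 0; must stay below `V/S`).
#' @param m Film mass in kg; computed as `rho_medium * S * L_eff` when
#'   omitted.
#' @return An object of class `cavity_params`.
#' @export
cavity_params <- function(rho_medium = 1100, L_eff = 1e-3, S = 1e-4,
                          V = 2e-7, P_A = 101325, gamma_air = 1.4,
                          x = 0, m = NULL) {
  for (nm in c("rho_medium", "L_eff", "S", "V", "P_A", "gamma_air")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (x < 0) stop("`x` must be >= 0", call. = FALSE)
  if (is.null(m)) m <- rho_medium * S * L_eff
  stopifnot_scalar_pos(m, "m")
  structure(list(m = m, rho_medium = rho_medium, L_eff = L_eff, S = S,
                 V = V, P_A = P_A, gamma_air = gamma_air, x = x),
            class = "cavity_params")
}

#' Cavity pressure increase under film compression
#'
#' Adiabatic compression of the sealed volume: compressing the film by `x`
#' changes the volume by `S * x` and raises the internal pressure by
#' `gamma_air * P_A * S * x / V` (magnitude; the sign convention is a
#' direction, compression means pressure increase).  Linear in `x`.
#'
#' @param params A [cavity_params()] object.
#' @return Pressure increase in Pa.
#' @examples
#' cavity_pressure_delta(cavity_params(x = 1e-5))
#' @export
cavity_pressure_delta <- function(params) {
  if (!inherits(params, "cavity_params")) {
    stop("`params` must be a cavity_params object", call. = FALSE)
  }
  if (params$x >= params$V / params$S) {
    stop("`x` >= V/S: cannot compress beyond the cavity volume", call. = FALSE)
  }
  params$gamma_air * params$P_A * params$S * params$x / params$V
}

#' Natural angular frequency of the sensor cavity
#'
#' The film-on-gas oscillator `x'' = -(gamma S P_A / (rho V L)) x` has
#' natural frequency `sqrt(gamma_air * S * P_A / (rho_medium * V * L_eff))`
#' rad/s.  For the default geometry this sits near 1.3 kHz, well above the
#' pulse band, so the cavity does not color the waveform.
#'
#' @inheritParams cavity_pressure_delta
#' @return Angular frequency in rad/s.
#' @export
cavity_resonance <- function(params) {
  if (!inherits(params, "cavity_params")) {
    stop("`params` must be a cavity_params object", call. = FALSE)
  }
  sqrt(params$gamma_air * params$S * params$P_A /
         (params$rho_medium * params$V * params$L_eff))
}

#' Load resistance for a piezoelectric sensor
#'
#' The sensor's parasitic capacitance together with its load resistor forms
#' a first-order high-pass; placing the cutoff at `f_load` requires
#' `R1 = 1 / (2 pi f_load Cp)`.  With `f_load` = 1 Hz and the nominal
#' 8000 pF +/- 30 % capacitance this gives the ~15-28 MOhm range.
#'
#' @param f_load Load cutoff frequency in Hz (> 0), default 1.
#' @param Cp Parasitic capacitance in F (> 0).
#' @return Load resistance in Ohm.
#' @examples
#' load_resistance(1, 10.4e-9) / 1e6  # ~15 MOhm
#' load_resistance(1, 5.6e-9) / 1e6   # ~28 MOhm
#' @export
load_resistance <- function(f_load = 1, Cp) {
  stopifnot_scalar_pos(f_load, "f_load")
  stopifnot_scalar_pos(Cp, "Cp")
  1 / (2 * pi * f_load * Cp)
}

#' Cutoff frequency of a second-order Sallen-Key section
#'
#' `fc = 1 / (2 pi sqrt(Ra Ca Rb Cb))`; symmetric under swapping the two RC
#' pairs, and for equal pairs reduces to `1 / (2 pi R C)`.  This is the
#' section's natural frequency as the design equations print it.
#'
#' @param Ra,Rb Resistances in Ohm (> 0).
#' @param Ca,Cb Capacitances in F (> 0).
#' @return Cutoff frequency in Hz.
#' @examples
#' sallen_key_cutoff(289.4e3, 1e-6, 289.4e3, 1e-6)  # ~0.55 Hz
#' @export
sallen_key_cutoff <- function(Ra, Ca, Rb, Cb) {
  for (nm in c("Ra", "Ca", "Rb", "Cb")) stopifnot_scalar_pos(get(nm), nm)
  1 / (2 * pi * sqrt(Ra * Ca * Rb * Cb))
}

#' Analog front-end design
#'
#' Component values of the AFE chain: load resistor, gain pair, and the two
#' second-order Sallen-Key sections (high-pass, default cutoff 0.55 Hz, and
#' low-pass, default 10 Hz, which attenuates mains interference).  Each
#' section uses equal R and equal C; given target cutoffs and chosen
#' capacitors the resistors follow from the cutoff formula.
#'
#' @param Cp Sensor parasitic capacitance in F (default 8 nF nominal).
#' @param f_load Load cutoff in Hz (default 1).
#' @param fc_hpf High-pass cutoff in Hz (default 0.55).
#' @param fc_lpf Low-pass cutoff in Hz (default 10); must exceed `fc_hpf`.
#' @param R2,R3 Gain-pair resistors in Ohm (gain `R2 / R3`; default unity).
#' @param C_hpf,C_lpf Section capacitors in F.
#' @return An object of class `afe_design` with all component values and
#'   the realized cutoffs.
#' @examples
#' afe_design()
#' @export
afe_design <- function(Cp = 8e-9, f_load = 1, fc_hpf = 0.55, fc_lpf = 10,
                       R2 = 1e4, R3 = 1e4, C_hpf = 1e-6, C_lpf = 1e-7) {
  if (fc_hpf >= fc_lpf) stop("require fc_hpf < fc_lpf", call. = FALSE)
  for (nm in c("Cp", "f_load", "fc_hpf", "fc_lpf", "R2", "R3", "C_hpf", "C_lpf")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  R1 <- load_resistance(f_load, Cp)
  R45 <- 1 / (2 * pi * fc_hpf * C_hpf)
  R67 <- 1 / (2 * pi * fc_lpf * C_lpf)
  structure(
    list(Cp = Cp, f_load = f_load, R1 = R1, R2 = R2, R3 = R3,
         R4 = R45, R5 = R45, C1 = C_hpf, C2 = C_hpf,
         R6 = R67, R7 = R67, C3 = C_lpf, C4 = C_lpf,
         fc_hpf = sallen_key_cutoff(R45, C_hpf, R45, C_hpf),
         fc_lpf = sallen_key_cutoff(R67, C_lpf, R67, C_lpf),
         gain = R2 / R3),
    class = "afe_design"
  )
}

#' @export
print.afe_design <- function(x, ...) {
  cat(sprintf(
    "<afe_design> R1 %.3g MOhm, gain %g, HPF %.3g Hz (R %.3g kOhm, C %.3g uF), LPF %.3g Hz (R %.3g kOhm, C %.3g uF)\n",
    x$R1 / 1e6, x$gain, x$fc_hpf, x$R4 / 1e3, x$C1 * 1e6,
    x$fc_lpf, x$R6 / 1e3, x$C3 * 1e6))
  invisible(x)
}

# Bilinear transform of a second-order analog rational transfer function
# (b2 s^2 + b1 s + b0) / (a2 s^2 + a1 s + a0) at sampling rate fs,
# s = 2 fs (1 - z^-1) / (1 + z^-1).  Returns digital (b, a), a[1] = 1.
bilinear_tf <- function(b, a, fs) {
  K <- 2 * fs
  bz <- c(b[1] * K^2 + b[2] * K + b[3],
          2 * (b[3] - b[1] * K^2),
          b[1] * K^2 - b[2] * K + b[3])
  az <- c(a[1] * K^2 + a[2] * K + a[3],
          2 * (a[3] - a[1] * K^2),
          a[1] * K^2 - a[2] * K + a[3])
  list(b = bz / az[1], a = az / az[1])
}

# Analog transfer functions of the two Sallen-Key sections as coefficient
# vectors c(s^2, s^1, s^0).
afe_analog_sections <- function(design) {
  hp_a <- c(1, 1 / (design$R4 * design$C1) + 1 / (design$R4 * design$C2),
            1 / (design$R4 * design$C1 * design$R5 * design$C2))
  lp_num <- 1 / (design$R6 * design$C3 * design$R7 * design$C4)
  lp_a <- c(1, 1 / (design$R7 * design$C3) + 1 / (design$R6 * design$C3),
            lp_num)
  list(hpf = list(b = c(1, 0, 0), a = hp_a),
       lpf = list(b = c(0, 0, lp_num), a = lp_a))
}

#' Analytic AFE magnitude response
#'
#' Product of the gain stage and the two Sallen-Key section magnitudes
#' evaluated on the analog (s = j 2 pi f) axis; serves as the continuous
#' reference the discretized simulation approximates.
#'
#' @param design An [afe_design()] object.
#' @param f Frequencies in Hz.
#' @return Magnitude response (dimensionless), same length as `f`.
#' @export
afe_response <- function(design, f) {
  sec <- afe_analog_sections(design)
  s <- 1i * 2 * pi * f
  mag <- function(tf) {
    abs((tf$b[1] * s^2 + tf$b[2] * s + tf$b[3]) /
          (tf$a[1] * s^2 + tf$a[2] * s + tf$a[3]))
  }
  design$gain * mag(sec$hpf) * mag(sec$lpf)
}

#' Simulate the analog front-end chain on a sampled trace
#'
#' Software model of the amplifier and filter chain: scalar gain `R2/R3`,
#' then the second-order Sallen-Key high-pass and low-pass sections
#' discretized by the bilinear transform at the trace's sampling rate.
#' DC is removed by the high-pass; magnitude decreases monotonically above
#' the low-pass cutoff.  Output length equals input length.
#'
#' @param trace A [signal_trace()]; `trace$fs` must be well above
#'   `2 * fc_lpf` for the discretization to be valid.
#' @param design An [afe_design()] object.
#' @return A filtered [signal_trace()] of the same length.
#' @export
simulate_afe_chain <- function(trace, design = afe_design()) {
  if (!inherits(trace, "signal_trace")) {
    stop("`trace` must be a signal_trace", call. = FALSE)
  }
  if (!inherits(design, "afe_design")) {
    stop("`design` must be an afe_design object", call. = FALSE)
  }
  if (trace$fs <= 2 * design$fc_lpf) {
    stop(sprintf("fs = %g Hz too low to discretize the %g Hz low-pass",
                 trace$fs, design$fc_lpf), call. = FALSE)
  }
  sec <- afe_analog_sections(design)
  hp <- bilinear_tf(sec$hpf$b, sec$hpf$a, trace$fs)
  lp <- bilinear_tf(sec$lpf$b, sec$lpf$a, trace$fs)
  y <- design$gain * trace$x
  y <- as.numeric(signal::filter(hp$b, hp$a, y))
  y <- as.numeric(signal::filter(lp$b, lp$a, y))
  meta <- trace$meta
  meta$afe <- list(fc_hpf = design$fc_hpf, fc_lpf = design$fc_lpf,
                   gain = design$gain)
  signal_trace(y, trace$fs, channel = trace$channel, units = trace$units,
               meta = meta)
}
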