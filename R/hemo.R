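#' Arterial parameters for the Moens-Korteweg model
#'
#' Per-subject geometry of the radial artery plus the model constants of the
#' pressure-dependent elastic modulus (Hughes-type law
#' \eqn{E_{inc} = E_0 e^{\xi P}}).  `E0` and `xi` live on the mmHg pressure
#' scale; the incremental modulus is converted to Pa (133.322 Pa/mmHg) before
#' it enters the wave-speed formula, with `D`, `h` in meters and `rho_blood`
#' in kg/m^3.  The defaults for `E0`, `xi` and `rho_blood` are the literature
#' values used by the measurement chain this package models; they are
#' defaults, not constants, because arterial stiffness differs between
#' individuals.
#'
#' @param D Lumen diameter in meters (e.g. `2.5e-3` for 2.5 mm).
#' @param h Wall thickness in meters; must satisfy `h < D`.
#' @param rho_blood Blood density in kg/m^3 (default 1060, i.e. 1.06 g/mL).
#' @param E0 Modulus coefficient on the mmHg scale (default 1428.7).
#' @param xi Stiffness exponent in 1/mmHg (default 0.031).
#'
#' @return An object of class `artery_params`.
#' @examples
#' artery_params(D = 2.5e-3, h = 0.3e-3)
#' @export
artery_params <- function(D = 2.5e-3, h = 0.3e-3, rho_blood = 1060,
                          E0 = 1428.7, xi = 0.031) {
  for (nm in c("D", "h", "rho_blood", "E0", "xi")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (h >= D) {
    stop("wall thickness `h` must be smaller than lumen diameter `D`",
         call. = FALSE)
  }
  structure(list(D = D, h = h, rho_blood = rho_blood, E0 = E0, xi = xi),
            class = "artery_params")
}

#' @export
print.artery_params <- function(x, ...) {
  cat(sprintf(
    "<artery_params> D = %.3g mm, h = %.3g mm, rho = %g kg/m^3, E0 = %g (mmHg scale), xi = %g /mmHg\n",
    x$D * 1e3, x$h * 1e3, x$rho_blood, x$E0, x$xi))
  invisible(x)
}

as_artery <- function(artery) {
  if (!inherits(artery, "artery_params")) {
    stop("`artery` must be created with artery_params()", call. = FALSE)
  }
  artery
}

#' Forward Moens-Korteweg map: pressure to pulse wave velocity
#'
#' Computes \eqn{PWV = \sqrt{E_{inc} h / (D \rho)}} with
#' \eqn{E_{inc} = E_0 e^{\xi P}} taken on the mmHg scale and converted to Pa.
#' Strictly increasing in pressure and in `h`, decreasing in `D`.
#'
#' @param p_map Mean arterial pressure in mmHg (> 0). Vectorized.
#' @param artery An [artery_params()] object.
#' @return Pulse wave velocity in m/s.
#' @seealso [mk_inverse()] for the closed-form inverse.
#' @examples
#' mk_forward(90, artery_params())
#' @export
mk_forward <- function(p_map, artery = artery_params()) {
  artery <- as_artery(artery)
  if (!is.numeric(p_map) || any(!is.finite(p_map)) || any(p_map <= 0)) {
    stop("`p_map` must be positive and finite", call. = FALSE)
  }
  e_inc_pa <- artery$E0 * exp(artery$xi * p_map) * MMHG_PA
  sqrt(e_inc_pa * artery$h / (artery$D * artery$rho_blood))
}

#' Inverse Moens-Korteweg map: pulse wave velocity to pressure
#'
#' Closed-form inversion
#' \eqn{P = \ln(PWV^2 \rho D / (h E_0)) / \xi} (pressure in mmHg after unit
#' normalization).  The returned pressure is interpreted as mean arterial
#' pressure.  The local sensitivity is \eqn{dP/dPWV = 2 / (\xi \, PWV)}, so a
#' 1\% PWV error shifts MAP by about `0.02 / xi` mmHg regardless of the
#' artery geometry.
#'
#' @param pwv Pulse wave velocity in m/s (> 0). Vectorized.
#' @inheritParams mk_forward
#' @return Mean arterial pressure in mmHg.
#' @examples
#' a <- artery_params()
#' mk_inverse(mk_forward(95, a), a)  # returns 95
#' @export
mk_inverse <- function(pwv, artery = artery_params()) {
  artery <- as_artery(artery)
  if (!is.numeric(pwv) || any(!is.finite(pwv)) || any(pwv <= 0)) {
    stop("`pwv` must be positive and finite", call. = FALSE)
  }
  arg <- pwv^2 * artery$rho_blood * artery$D / (artery$h * artery$E0 * MMHG_PA)
  if (any(arg <= 1e-12)) {
    stop("non-physical PWV/artery combination: log argument <= 1e-12",
         call. = FALSE)
  }
  log(arg) / artery$xi
}

#' Mean arterial pressure from a cuff reading
#'
#' The standard approximation MAP = (SBP + 2 DBP) / 3, reflecting that
#' diastole occupies roughly two thirds of the cardiac cycle.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg; `sbp > dbp > 0`
#'   elementwise (equality allowed, giving MAP = SBP = DBP).
#' @return MAP in mmHg.
#' @examples
#' map_from_cuff(120, 80)
#' @export
map_from_cuff <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp < dbp)) {
    stop("require sbp >= dbp > 0", call. = FALSE)
  }
  (sbp + 2 * dbp) / 3
}

#' Split mean arterial pressure into systolic and diastolic estimates
#'
#' The device convention uses a split factor `k`: `DBP = MAP * k` and
#' `SBP = MAP + (1 - k) * DBP`.  Note that this pair does **not** invert
#' [map_from_cuff()]: substituting the two estimates back into
#' (SBP + 2 DBP)/3 does not return MAP.  `method = "consistent"` offers the
#' algebraically consistent alternative `SBP = 3 MAP - 2 DBP`; the default
#' follows the device convention as printed.
#'
#' @param map MAP in mmHg (> 0). Vectorized.
#' @param k Split factor in (0, 1), default 0.76.
#' @param method `"printed"` (device convention, default) or `"consistent"`.
#' @return A list with `sbp` and `dbp` in mmHg.
#' @examples
#' split_map(100)            # dbp 76, sbp 118.24
#' split_map(100, method = "consistent")
#' @export
split_map <- function(map, k = 0.76, method = c("printed", "consistent")) {
  method <- match.arg(method)
  if (any(!is.finite(map)) || any(map <= 0)) {
    stop("`map` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 1) {
    stop("`k` must lie strictly inside (0, 1)", call. = FALSE)
  }
  dbp <- map * k
  sbp <- switch(method,
    printed = map + (1 - k) * dbp,
    consistent = 3 * map - 2 * dbp
  )
  list(sbp = sbp, dbp = dbp)
}

#' Estimate blood pressure from a measured pulse wave velocity
#'
#' Composes [mk_inverse()] (PWV to MAP) with [split_map()] (MAP to SBP/DBP).
#'
#' @inheritParams mk_inverse
#' @inheritParams split_map
#' @return An object of class `bp_estimate`: list with `map`, `sbp`, `dbp`
#'   (mmHg), `k`, and a `provenance` record naming the formula behind each
#'   field.
#' @examples
#' estimate_bp(10, artery_params())
#' @export
estimate_bp <- function(pwv, artery = artery_params(), k = 0.76,
                        method = c("printed", "consistent")) {
  method <- match.arg(method)
  map <- mk_inverse(pwv, artery)
  split <- split_map(map, k = k, method = method)
  structure(
    list(map = map, sbp = split$sbp, dbp = split$dbp, k = k,
         provenance = list(
           map = "Moens-Korteweg inversion of measured PWV",
           sbp = sprintf("MAP split, method '%s', k = %g", method, k),
           dbp = sprintf("MAP * k, k = %g", k))),
    class = "bp_estimate"
  )
}

#' @export
print.bp_estimate <- function(x, ...) {
  cat(sprintf("<bp_estimate> SBP %.1f / DBP %.1f mmHg (MAP %.1f), k = %g\n",
              x$sbp[1], x$dbp[1], x$map[1], x$k))
  invisible(x)
}
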