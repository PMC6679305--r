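#' Convert altitude to barometric pressure (international barometric formula)
#'
#' Standard-atmosphere model used to encode and decode the vertical position
#' of the pelvis in the barometer channel: `p = p0 * (1 - h/44330)^(1/0.1903)`
#' with `p0 = 101325` Pa. Valid throughout the troposphere; sub-metre height
#' changes map to roughly 12 Pa/m near sea level.
#'
#' @param h altitude above mean sea level, m.
#' @return pressure, Pa.
#' @seealso [altitude_from_pressure()] for the exact inverse.
#' @export
#' @examples
#' pressure_from_altitude(0)      # 101325 Pa
#' altitude_from_pressure(pressure_from_altitude(100))
pressure_from_altitude <- function(h) {
  if (any(!is.finite(h)) || any(h >= BARO_SCALE)) {
    abort("altitude must be finite and below the tropospheric model ceiling")
  }
  SEA_LEVEL_PRESSURE * (1 - h / BARO_SCALE)^(1 / BARO_EXPONENT)
}

#' @rdname pressure_from_altitude
#' @param p pressure, Pa; must be positive.
#' @export
altitude_from_pressure <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0)) {
    abort("pressure must be positive and finite")
  }
  BARO_SCALE * (1 - (p / SEA_LEVEL_PRESSURE)^BARO_EXPONENT)
}
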