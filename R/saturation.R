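#' Oxygen-hemoglobin dissociation (Hill approximation)
#'
#' Monotone, analytically invertible saturation curve
#' \eqn{S(P) = P^n / (P^n + P50^n)} used both by the synthetic blood-gas
#' generator and by the gas-exchange estimators, so that quantities the
#' generator encodes (shunt fraction, oxygen contents) round-trip exactly
#' through the estimation path. The default half-saturation tension
#' (P50 = 30 mmHg) and Hill coefficient (n = 2.7) are standard mammalian
#' values appropriate for rabbit blood.
#'
#' @param po2 Oxygen partial pressure (mmHg), non-negative.
#' @param p50 Half-saturation tension (mmHg).
#' @param hill Hill coefficient (dimensionless).
#' @return Fractional saturation in [0, 1).
#' @seealso [o2_tension()] for the exact inverse.
#' @export
#' @examples
#' o2_saturation(30)            # 0.5 at P50
#' o2_tension(o2_saturation(90))  # 90
o2_saturation <- function(po2, p50 = 30, hill = 2.7) {
  if (any(po2 < 0)) pv_stop("po2 must be non-negative")
  pn <- (po2 / p50)^hill
  pn / (1 + pn)
}

#' @rdname o2_saturation
#' @param so2 Fractional saturation in [0, 1).
#' @export
o2_tension <- function(so2, p50 = 30, hill = 2.7) {
  if (any(so2 < 0 | so2 >= 1)) pv_stop("so2 must be in [0, 1)")
  p50 * (so2 / (1 - so2))^(1 / hill)
}
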