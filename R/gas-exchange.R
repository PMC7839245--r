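#' Oxygenation index (PaO2/FiO2)
#'
#' @param pao2 Arterial oxygen tension (mmHg).
#' @param fio2 Inspired oxygen fraction, in (0, 1].
#' @return PaO2/FiO2 in mmHg.
#' @export
#' @examples
#' oxygenation_index(176.4, 0.4)  # 441
oxygenation_index <- function(pao2, fio2) {
  if (any(fio2 <= 0)) pv_stop("fio2 must be > 0")
  pao2 / fio2
}

#' Oxygen content of blood
#'
#' Content = capacity * hb * SO2 + solubility * PO2, the conventional
#' bound-plus-dissolved formula. Constants are configurable; the defaults
#' (1.34 mL O2 per g Hb, 0.003 mL/dL/mmHg dissolved) are the standard
#' physiologic values.
#'
#' @param po2 Oxygen tension (mmHg).
#' @param so2 Fractional saturation in [0, 1].
#' @param hb Hemoglobin (g/dL).
#' @param o2_capacity mL O2 bound per g of saturated hemoglobin.
#' @param o2_solubility Dissolved O2 (mL/dL per mmHg).
#' @return Oxygen content (mL O2/dL).
#' @export
oxygen_content <- function(po2, so2, hb, o2_capacity = 1.34,
                           o2_solubility = 0.003) {
  if (any(po2 < 0) || any(so2 < 0) || any(hb < 0))
    pv_stop("po2, so2 and hb must be non-negative")
  o2_capacity * hb * so2 + o2_solubility * po2
}

#' Alveolar oxygen tension (alveolar gas equation)
#'
#' PAO2 = FiO2 * (Pb - PH2O) - PaCO2 / RQ.
#'
#' @param fio2 Inspired oxygen fraction in (0, 1].
#' @param paco2 Arterial CO2 tension (mmHg).
#' @param pb Barometric pressure (mmHg).
#' @param ph2o Water vapor pressure at body temperature (mmHg).
#' @param rq Respiratory quotient.
#' @return Alveolar PO2 (mmHg).
#' @export
alveolar_po2 <- function(fio2, paco2, pb = 760, ph2o = 47, rq = 0.8) {
  if (any(fio2 <= 0 | fio2 > 1)) pv_stop("fio2 must be in (0, 1]")
  pao2 <- fio2 * (pb - ph2o) - paco2 / rq
  if (any(pao2 <= 0))
    pv_stop("alveolar PO2 <= 0: inputs are non-physical", "pvvent_domain_error")
  pao2
}

#' Pulmonary end-capillary oxygen content
#'
#' Two routes are available. The default ("alveolar") takes end-capillary
#' blood to be equilibrated with alveolar gas: PAO2 from the alveolar gas
#' equation, saturation from the dissociation curve at that tension, content
#' from [oxygen_content()]. The alternative ("saturated") assumes 100%
#' end-capillary saturation.
#'
#' @inheritParams alveolar_po2
#' @param hb Hemoglobin (g/dL).
#' @param route "alveolar" (default) or "saturated".
#' @param p50,hill Dissociation-curve parameters, see [o2_saturation()].
#' @return End-capillary O2 content (mL/dL).
#' @export
end_capillary_content <- function(fio2, paco2, hb, pb = 760, ph2o = 47,
                                  rq = 0.8, route = c("alveolar", "saturated"),
                                  p50 = 30, hill = 2.7) {
  route <- match.arg(route)
  pao2 <- alveolar_po2(fio2, paco2, pb = pb, ph2o = ph2o, rq = rq)
  sc <- if (route == "alveolar") o2_saturation(pao2, p50, hill) else 1
  oxygen_content(pao2, sc, hb)
}

#' Oxygen contents triple
#'
#' Container for the end-capillary, arterial and central-venous oxygen
#' contents that enter the shunt equation. The physiologic ordering
#' cc >= ca >= cv is checked and violations are flagged (attribute
#' `ordering_ok`), not fatal.
#'
#' @param cc_o2,ca_o2,cv_o2 End-capillary, arterial, central venous O2
#'   content (mL/dL).
#' @return An object of class `oxygen_contents`.
#' @export
oxygen_contents <- function(cc_o2, ca_o2, cv_o2) {
  if (any(c(cc_o2, ca_o2, cv_o2) < 0))
    pv_stop("oxygen contents must be non-negative")
  structure(
    list(cc_o2 = cc_o2, ca_o2 = ca_o2, cv_o2 = cv_o2),
    ordering_ok = (cc_o2 >= ca_o2 && ca_o2 >= cv_o2),
    class = "oxygen_contents"
  )
}

#' Intrapulmonary shunt fraction (Qs/Qt)
#'
#' Qs/Qt = (CcO2 - CaO2) / (CcO2 - CvO2): the fraction of cardiac output
#' perfusing unventilated lung, from end-capillary, arterial and central
#' venous oxygen contents. Values outside [0, 1] (possible when the content
#' ordering is non-physiologic) are returned as computed with a warning,
#' never clipped.
#'
#' @param contents An [oxygen_contents()] object, or end-capillary content
#'   if `ca_o2`/`cv_o2` are given separately.
#' @param ca_o2,cv_o2 Optional arterial and venous contents (mL/dL).
#' @return Shunt as a fraction; the percent value is attached as attribute
#'   `percent`.
#' @export
#' @examples
#' shunt_fraction(oxygen_contents(20, 19, 14))  # 1/6
shunt_fraction <- function(contents, ca_o2 = NULL, cv_o2 = NULL) {
  if (inherits(contents, "oxygen_contents")) {
    cc <- contents$cc_o2; ca <- contents$ca_o2; cv <- contents$cv_o2
  } else {
    cc <- contents; ca <- ca_o2; cv <- cv_o2
  }
  if (is.null(ca) || is.null(cv)) pv_stop("arterial and venous contents required")
  if (isTRUE(all.equal(cc, cv)))
    pv_stop("Qs/Qt undefined: CcO2 equals CvO2", "pvvent_domain_error")
  qs_qt <- (cc - ca) / (cc - cv)
  if (qs_qt < 0 || qs_qt > 1)
    warning("Qs/Qt outside [0, 1]: check content ordering", call. = FALSE)
  structure(qs_qt, percent = 100 * qs_qt)
}

#' Shunt fraction from a blood-gas sample
#'
#' Convenience wrapper: reconstructs the three oxygen contents from an
#' arterial/venous blood-gas sample (as produced by [generate_blood_gas()]
#' or assembled from analyzer readings) and applies [shunt_fraction()].
#' End-capillary content is taken by the alveolar-gas route with the same
#' dissociation curve used throughout the package.
#'
#' @param sample A `blood_gas_sample` or a list with fields `pao2`, `paco2`,
#'   `sao2`, `hb`, `fio2`, `pvo2`, `svo2`.
#' @inheritParams end_capillary_content
#' @return Shunt fraction as in [shunt_fraction()].
#' @export
shunt_from_sample <- function(sample, pb = 760, ph2o = 47, rq = 0.8,
                              p50 = 30, hill = 2.7,
                              route = c("alveolar", "saturated")) {
  route <- match.arg(route)
  cc <- end_capillary_content(sample$fio2, sample$paco2, sample$hb,
                              pb = pb, ph2o = ph2o, rq = rq, route = route,
                              p50 = p50, hill = hill)
  ca <- oxygen_content(sample$pao2, sample$sao2, sample$hb)
  cv <- oxygen_content(sample$pvo2, sample$svo2, sample$hb)
  shunt_fraction(oxygen_contents(cc, ca, cv))
}
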