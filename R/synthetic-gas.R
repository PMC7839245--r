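#' Parameters of the forward gas-exchange model
#'
#' The forward model that turns a ventilation state (delivered volumes,
#' rate, recruited fraction) into a consistent arterial/venous blood-gas
#' sample: linear CO2 clearance (PaCO2 inversely proportional to alveolar
#' ventilation), an alveolar-gas/shunt-mixing route for oxygen, and a shunt
#' that grows linearly with the derecruited fraction.
#'
#' @param hb Hemoglobin (g/dL).
#' @param barometric_pressure Pb (mmHg).
#' @param water_vapor_pressure PH2O at body temperature (mmHg).
#' @param respiratory_quotient RQ, dimensionless in (0.5, 1.5].
#' @param baseline_shunt Shunt fraction at full recruitment, in [0, 1).
#' @param shunt_per_closed_fraction Added shunt per unit of closed fraction.
#' @param co2_production VCO2 (mL/min, whole animal).
#' @param dead_space Series + anatomic dead space (mL/kg).
#' @param pvo2 Mixed/central venous oxygen tension (mmHg).
#' @return Object of class `gas_exchange_sim_params`.
#' @export
gas_exchange_sim_params <- function(hb = 12, barometric_pressure = 760,
                                    water_vapor_pressure = 47,
                                    respiratory_quotient = 0.8,
                                    baseline_shunt = 0.05,
                                    shunt_per_closed_fraction = 0.7,
                                    co2_production = 18.5, dead_space = 2,
                                    pvo2 = 40) {
  vals <- c(hb, barometric_pressure, water_vapor_pressure,
            respiratory_quotient, co2_production, dead_space, pvo2)
  if (any(vals <= 0)) pv_stop("all gas-exchange parameters must be positive")
  if (baseline_shunt < 0 || baseline_shunt >= 1)
    pv_stop("baseline_shunt must be in [0, 1)")
  if (respiratory_quotient <= 0.5 || respiratory_quotient > 1.5)
    pv_stop("respiratory_quotient must be in (0.5, 1.5]")
  structure(
    list(hb = hb, barometric_pressure = barometric_pressure,
         water_vapor_pressure = water_vapor_pressure,
         respiratory_quotient = respiratory_quotient,
         baseline_shunt = baseline_shunt,
         shunt_per_closed_fraction = shunt_per_closed_fraction,
         co2_production = co2_production, dead_space = dead_space,
         pvo2 = pvo2),
    class = "gas_exchange_sim_params"
  )
}

# mmHg per (mL/min)/(L/min): PaCO2 = 0.863 * VCO2 / VA (BTPS convention)
CO2_CLEARANCE_K <- 0.863

#' Generate a consistent arterial/venous blood-gas sample
#'
#' Forward model: PaCO2 from the alveolar-ventilation equation
#' PaCO2 = 0.863 VCO2 / VA; alveolar PO2 from the alveolar gas equation;
#' end-capillary content at alveolar tension; shunt
#' s = baseline + gain * (1 - open_fraction); arterial content mixes
#' end-capillary and venous blood by s; PaO2 is then recovered from the
#' arterial content by inverting the monotone content-vs-tension map.
#' By construction, feeding the sample to [shunt_from_sample()] recovers s.
#'
#' @param lung A [lung_model_state()] (supplies `open_fraction`).
#' @param vt_mlkg Achieved tidal volume (mL/kg).
#' @param rr Achieved respiratory rate (breaths/min).
#' @param fio2 Inspired oxygen fraction.
#' @param params A [gas_exchange_sim_params()].
#' @param weight_kg Animal mass (kg).
#' @return Object of class `blood_gas_sample`: `pao2`, `paco2`, `sao2`,
#'   `hb`, `fio2`, `pvo2`, `svo2`, `etco2` (fraction) and ground-truth
#'   `shunt_true`.
#' @export
generate_blood_gas <- function(lung, vt_mlkg, rr, fio2 = 0.4, params =
                                 gas_exchange_sim_params(),
                               weight_kg = 3.4) {
  stopifnot(inherits(lung, "lung_model_state"),
            inherits(params, "gas_exchange_sim_params"))
  va <- (vt_mlkg - params$dead_space) * weight_kg * rr / 1000  # L/min
  if (va <= 0)
    pv_stop("alveolar ventilation must be > 0 (VT below dead space?)",
            "pvvent_domain_error")
  paco2 <- CO2_CLEARANCE_K * params$co2_production / va
  pb <- params$barometric_pressure; ph2o <- params$water_vapor_pressure
  pao2_alv <- alveolar_po2(fio2, paco2, pb, ph2o, params$respiratory_quotient)

  shunt <- params$baseline_shunt +
    params$shunt_per_closed_fraction * (1 - lung$open_fraction)
  shunt <- min(shunt, 0.999)

  cc <- oxygen_content(pao2_alv, o2_saturation(pao2_alv), params$hb)
  svo2 <- o2_saturation(params$pvo2)
  cv <- oxygen_content(params$pvo2, svo2, params$hb)
  ca <- (1 - shunt) * cc + shunt * cv
  if (ca < 0) pv_stop("negative arterial content", "pvvent_domain_error")

  # invert content(pao2) = ca; monotone increasing in pao2
  f <- function(p) oxygen_content(p, o2_saturation(p), params$hb) - ca
  pao2 <- uniroot(f, lower = 1e-6, upper = pao2_alv, tol = 1e-12)$root

  structure(
    list(pao2 = pao2, paco2 = paco2, sao2 = o2_saturation(pao2),
         hb = params$hb, fio2 = fio2, pvo2 = params$pvo2, svo2 = svo2,
         etco2 = paco2 / (pb - ph2o), shunt_true = shunt,
         site = "arterial"),
    class = "blood_gas_sample"
  )
}
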