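#' Ventilator settings
#'
#' Protocol defaults: PEEP 3 cmH2O, FiO2 0.4, inspiratory:expiratory ratio
#' 1:3, target tidal volume 7 mL/kg. The driving pressure (peak inspiratory
#' pressure minus PEEP) is either given or calibrated once at the start of a
#' run to deliver the target VT, then held constant. In PVV mode a
#' [build_pvv_pattern()] schedule modulates the per-breath driving pressure
#' and period; PCV delivers identical breaths.
#'
#' @param peep End-expiratory pressure (cmH2O), >= 0.
#' @param driving_pressure Peak pressure minus PEEP (cmH2O); `NULL` to
#'   calibrate at run start.
#' @param ie_ratio Inspiratory over expiratory time (default 1/3).
#' @param fio2 Inspired O2 fraction in (0.21, 1].
#' @param target_vt Target mean tidal volume (mL/kg).
#' @param rr Initial respiratory rate (breaths/min).
#' @param mode "pcv" or "pvv".
#' @param pattern A `ventilation_pattern` (required for PVV).
#' @param rise_time Pressure rise/fall time of the "square" profile (s);
#'   default 50 ms avoids flow impulses.
#' @return Object of class `vent_settings`.
#' @export
vent_settings <- function(peep = 3, driving_pressure = NULL, ie_ratio = 1/3,
                          fio2 = 0.4, target_vt = 7, rr = 23,
                          mode = c("pcv", "pvv"), pattern = NULL,
                          rise_time = 0.05) {
  mode <- match.arg(mode)
  if (peep < 0) pv_stop("peep must be >= 0")
  if (!is.null(driving_pressure) && driving_pressure <= 0)
    pv_stop("driving_pressure must be > 0")
  if (fio2 <= 0.21 || fio2 > 1) pv_stop("fio2 must be in (0.21, 1]")
  if (ie_ratio <= 0) pv_stop("ie_ratio must be > 0")
  if (mode == "pvv" && is.null(pattern))
    pv_stop("PVV mode requires a ventilation pattern")
  structure(
    list(peep = peep, driving_pressure = driving_pressure,
         ie_ratio = ie_ratio, fio2 = fio2, target_vt = target_vt, rr = rr,
         mode = mode, pattern = pattern, rise_time = rise_time),
    class = "vent_settings"
  )
}

insp_fraction <- function(ie_ratio) ie_ratio / (1 + ie_ratio)

#' Pressure waveform for a single breath
#'
#' Square-ish pressure-controlled profile: linear rise over `rise_time` to
#' the plateau `peep + driving_pressure * pressure_ratio`, hold for the
#' inspiratory fraction of the (ratio-scaled) period, linear fall back to
#' PEEP for the expiration. PCV uses ratios (1, 1) for every breath.
#'
#' @param settings A [vent_settings()] with `driving_pressure` set.
#' @param pressure_ratio,period_ratio Per-breath pattern ratios (> 0 and
#'   >= 0 for pressure; an apneic breath has ratio 0).
#' @param sampling_rate Hz (>= 100 for simulation fidelity).
#' @return List of class `breath_waveform`: `time` (s), `pressure` (cmH2O),
#'   `t_insp` (s), `period` (s), `sampling_rate`.
#' @export
make_breath_waveform <- function(settings, pressure_ratio = 1,
                                 period_ratio = 1, sampling_rate = 1000) {
  stopifnot(inherits(settings, "vent_settings"))
  if (is.null(settings$driving_pressure))
    pv_stop("driving_pressure must be set (or calibrated) first")
  if (pressure_ratio < 0 || period_ratio <= 0)
    pv_stop("pressure_ratio must be >= 0 and period_ratio > 0")
  period <- (60 / settings$rr) * period_ratio
  t_insp <- period * insp_fraction(settings$ie_ratio)
  n <- round(period * sampling_rate)
  if (round(t_insp * sampling_rate) < 2)
    pv_stop("inspiratory time shorter than two samples",
            "pvvent_argument_error")
  t <- (seq_len(n) - 1) / sampling_rate
  plateau <- settings$driving_pressure * pressure_ratio
  rise <- min(settings$rise_time, t_insp / 2)
  p <- numeric(n)
  ins <- t < t_insp
  if (rise > 0) {
    p[ins] <- plateau * pmin(1, t[ins] / rise)
    fall <- !ins & t < t_insp + rise
    p[fall] <- plateau * pmax(0, 1 - (t[fall] - t_insp) / rise)
  } else {
    p[ins] <- plateau
  }
  structure(
    list(time = t, pressure = settings$peep + p, t_insp = t_insp,
         period = period, sampling_rate = sampling_rate,
         peep = settings$peep),
    class = "breath_waveform"
  )
}

#' Apply a pressure waveform to the lung model
#'
#' Solves the single-compartment equation of motion
#' `Paw(t) = R V'(t) + E_eff V(t) + PEEP` for flow and volume, with
#' `E_eff = h_tissue / open_fraction` and R the airway resistance plus the
#' low-frequency tissue resistance at the breathing frequency (see
#' [breathing_frequency_resistance()]). The linear ODE is integrated with
#' the exact exponential update per sample (pressure held constant within a
#' sample), so the solution is stiff-safe at any R/E ratio.
#'
#' @param waveform A [make_breath_waveform()] result.
#' @param lung A [lung_model_state()].
#' @param v0 Initial compartment volume above FRC (L), e.g. trapped volume
#'   from the previous breath.
#' @return List of class `pressure_flow_signal`: data.frame `signal`
#'   (time, airway_pressure, flow, volume), `delivered_vt` (L, peak
#'   inspired volume), `end_volume` (L, above FRC at end-expiration),
#'   `e_eff`, `r_eff`.
#' @export
apply_to_lung <- function(waveform, lung, v0 = 0) {
  stopifnot(inherits(waveform, "breath_waveform"),
            inherits(lung, "lung_model_state"))
  e_eff <- effective_elastance(lung)
  r_eff <- breathing_frequency_resistance(lung, 1 / waveform$period)
  dt <- 1 / waveform$sampling_rate
  pd <- waveform$pressure - waveform$peep   # distending pressure above PEEP
  n <- length(pd)
  decay <- exp(-e_eff * dt / r_eff)
  v <- numeric(n)
  vprev <- v0
  for (i in seq_len(n)) {
    veq <- pd[i] / e_eff
    v[i] <- veq + (vprev - veq) * decay
    vprev <- v[i]
  }
  flow <- c(v[1] - v0, diff(v)) / dt
  sig <- data.frame(time = waveform$time, airway_pressure = waveform$pressure,
                    flow = flow, volume = v)
  structure(
    list(signal = sig, delivered_vt = max(v) - v0, end_volume = v[n],
         e_eff = e_eff, r_eff = r_eff,
         sampling_rate = waveform$sampling_rate, peep = waveform$peep,
         t_insp = waveform$t_insp),
    class = "pressure_flow_signal"
  )
}

# Closed-form delivered volume for a square pressure step (rise_time = 0):
# VT = (dP / E) (1 - exp(-T_insp E / R)). Used by the breath-by-breath
# simulator where sampling every breath would be wasteful.
delivered_vt_closed_form <- function(dp, e_eff, r_eff, t_insp) {
  (dp / e_eff) * (1 - exp(-t_insp * e_eff / r_eff))
}

#' Respiratory-rate controller targeting normocapnia
#'
#' Bounded proportional stepper: if the simulated end-tidal CO2 fraction is
#' above the normocapnic band the rate is increased by `step` (more
#' alveolar ventilation washes out CO2), below the band it is decreased;
#' inside the band it is left alone. The rate never leaves `bounds`; if the
#' requested change is clipped, the result carries attribute
#' `saturated = TRUE`.
#'
#' @param rr Current respiratory rate (breaths/min).
#' @param etco2 Simulated end-tidal CO2 fraction (e.g. 0.058 for 5.8%).
#' @param band Normocapnia band (fractions), default 5.5-6%.
#' @param step Rate increment per adaptation epoch (breaths/min).
#' @param bounds Allowed rate range (breaths/min).
#' @return New respiratory rate.
#' @export
adapt_rr_for_normocapnia <- function(rr, etco2, band = c(0.055, 0.060),
                                     step = 1, bounds = c(10, 60)) {
  new_rr <- rr
  if (etco2 > band[2]) new_rr <- rr + step
  else if (etco2 < band[1]) new_rr <- rr - step
  clipped <- min(bounds[2], max(bounds[1], new_rr))
  structure(clipped, saturated = (clipped != new_rr))
}

#' Detect intrinsic PEEP (air trapping) in a breath signal
#'
#' Flags a breath when the end-expiratory flow magnitude exceeds
#' `threshold` times the peak expiratory flow magnitude — expiration was
#' cut short, so alveolar pressure has not returned to the set PEEP. The
#' auto-PEEP magnitude is the model alveolar pressure above PEEP at
#' end-expiration, `E_eff * V(end)`.
#'
#' @param signal A [apply_to_lung()] result.
#' @param threshold Fraction of peak expiratory flow (default 0.05).
#' @return List: `flag` (logical), `magnitude` (cmH2O), `trapped_volume`
#'   (L).
#' @export
detect_auto_peep <- function(signal, threshold = 0.05) {
  stopifnot(inherits(signal, "pressure_flow_signal"))
  s <- signal$signal
  exp_phase <- s$time >= signal$t_insp
  if (!any(exp_phase)) pv_stop("no expiratory phase in signal")
  ef <- s$flow[exp_phase]
  peak_exp <- max(-ef, 0)
  end_flow <- -ef[length(ef)]
  if (peak_exp <= 0)                      # zero-flow record
    return(list(flag = FALSE, magnitude = 0, trapped_volume = 0))
  flag <- end_flow > threshold * peak_exp
  list(flag = flag,
       magnitude = if (flag) signal$e_eff * signal$end_volume else 0,
       trapped_volume = if (flag) signal$end_volume else 0)
}

#' Simulate hours of PCV or PVV ventilation on the synthetic lung
#'
#' Breath-by-breath closed-form simulation of a pressure-controlled run:
#' the driving pressure is calibrated once at the start (recruited lung,
#' initial rate) to deliver the target VT and then held constant; the
#' recruitment maneuver (two 10-s holds) precedes the run; each breath
#' delivers the closed-form single-compartment volume, the recruitment
#' state evolves per breath, and every `epoch_min` the respiratory rate is
#' adapted toward the normocapnic end-tidal CO2 band using the forward
#' gas-exchange model. Hourly summaries (H0-H6 for a 6-h run) record
#' mechanics, delivered volumes, blood-gas indices and the recruited
#' fraction.
#'
#' @param settings A [vent_settings()]; `mode` picks PCV or PVV.
#' @param lung A [lung_model_state()].
#' @param gas A [gas_exchange_sim_params()].
#' @param hours Duration (h).
#' @param weight_kg Animal mass (kg).
#' @param epoch_min Controller adaptation epoch (min).
#' @param seed Optional seed (the run itself is deterministic; the seed
#'   fixes any downstream stochastic use of the outputs).
#' @return Object of class `vent_run`: `hourly` data.frame (timepoint,
#'   hour, open_fraction, e_eff, mean_vt_mlkg, rr, etco2_pct, paco2, pao2,
#'   pao2_fio2, shunt_pct), `breaths` data.frame (time_s, vt_mlkg),
#'   `settings`, `final_lung`.
#' @export
simulate_ventilation <- function(settings, lung = lung_model_state(),
                                 gas = gas_exchange_sim_params(),
                                 hours = 6, weight_kg = 3.4,
                                 epoch_min = 5, seed = NULL) {
  stopifnot(inherits(settings, "vent_settings"))
  if (!is.null(seed)) set.seed(seed)
  lung <- recruitment_maneuver(lung)

  rr <- settings$rr
  f_b <- rr / 60
  e0 <- effective_elastance(lung)
  r0 <- breathing_frequency_resistance(lung, f_b)
  t_insp0 <- (60 / rr) * insp_fraction(settings$ie_ratio)
  target_l <- settings$target_vt * weight_kg / 1000
  dp <- settings$driving_pressure %||%
    (target_l * e0 / (1 - exp(-t_insp0 * e0 / r0)))

  ratios <- if (settings$mode == "pvv") {
    settings$pattern$entries[, c("pressure_ratio", "period_ratio")]
  } else data.frame(pressure_ratio = 1, period_ratio = 1)
  np <- nrow(ratios)

  total_s <- hours * 3600
  epoch_s <- epoch_min * 60
  t_now <- 0
  k <- 0L                      # pattern cursor
  next_epoch <- epoch_s
  next_hour <- 0
  vt_epoch <- c(); per_epoch <- c()
  vt_hour <- c()
  times <- c(); vts <- c()
  hourly <- list()
  etco2 <- NA_real_

  record_hour <- function(hour, lung, rr, vt_mean) {
    bg <- generate_blood_gas(lung, vt_mean, rr, settings$fio2, gas,
                             weight_kg)
    data.frame(
      timepoint = sprintf("H%d", hour), hour = hour,
      open_fraction = lung$open_fraction,
      e_eff = effective_elastance(lung),
      mean_vt_mlkg = vt_mean, rr = rr,
      etco2_pct = 100 * bg$etco2, paco2 = bg$paco2, pao2 = bg$pao2,
      pao2_fio2 = oxygenation_index(bg$pao2, settings$fio2),
      shunt_pct = 100 * bg$shunt_true
    )
  }

  while (t_now < total_s) {
    k <- k + 1L
    row <- ratios[((k - 1L) %% np) + 1L, ]
    period <- (60 / rr) * row$period_ratio
    t_insp <- period * insp_fraction(settings$ie_ratio)
    e_eff <- effective_elastance(lung)
    r_eff <- breathing_frequency_resistance(lung, 1 / period)
    vt_l <- delivered_vt_closed_form(dp * row$pressure_ratio, e_eff, r_eff,
                                     t_insp)
    vt_mlkg <- vt_l * 1000 / weight_kg

    if (next_hour == 0) {                  # H0: first delivered breath
      hourly[[length(hourly) + 1L]] <- record_hour(0, lung, rr, vt_mlkg)
      next_hour <- 3600
    }

    lung <- evolve_lung_state(lung, vt_mlkg, period)
    t_now <- t_now + period
    vt_epoch <- c(vt_epoch, vt_mlkg); per_epoch <- c(per_epoch, period)
    vt_hour <- c(vt_hour, vt_mlkg)
    times <- c(times, t_now); vts <- c(vts, vt_mlkg)

    if (t_now >= next_epoch) {
      rr_eff <- 60 / mean(per_epoch)
      bg <- generate_blood_gas(lung, mean(vt_epoch), rr_eff, settings$fio2,
                               gas, weight_kg)
      etco2 <- bg$etco2
      rr <- as.numeric(adapt_rr_for_normocapnia(rr, etco2))
      vt_epoch <- c(); per_epoch <- c()
      next_epoch <- next_epoch + epoch_s
    }
    if (t_now >= next_hour) {
      hourly[[length(hourly) + 1L]] <-
        record_hour(round(next_hour / 3600), lung, rr, mean(vt_hour))
      vt_hour <- c()
      next_hour <- next_hour + 3600
    }
  }

  structure(
    list(hourly = do.call(rbind, hourly),
         breaths = data.frame(time_s = times, vt_mlkg = vts),
         settings = settings, final_lung = lung,
         driving_pressure = dp),
    class = "vent_run"
  )
}

#' @export
print.vent_run <- function(x, ...) {
  cat(sprintf("<vent_run> %s, %d breaths, driving pressure %.2f cmH2O\n",
              toupper(x$settings$mode), nrow(x$breaths),
              x$driving_pressure))
  print(x$hourly, row.names = FALSE)
  invisible(x)
}
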