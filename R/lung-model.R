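#' Mechanical lung model state with recruitment dynamics
#'
#' A single "virtual lung": constant-phase tissue parameters (damping G,
#' elastance H) behind a Newtonian airway (resistance Raw, inertance Iaw),
#' plus a recruited fraction of lung units that evolves breath by breath.
#' Effective tissue elastance is `h_tissue / open_fraction`, so closure of
#' units stiffens the lung. Closure proceeds exponentially at `close_rate`
#' under monotonous ventilation; a breath larger than `reopen_threshold`
#' reopens a fraction `reopen_gain` of the currently closed units.
#'
#' Defaults describe an emphysematous (COPD) rabbit lung whose slow
#' derecruitment loses roughly 15-20% of open units over 6 h of monotonous
#' 7 mL/kg ventilation, while breaths above 9 mL/kg recruit.
#'
#' @param raw Airway resistance (cmH2O.s/L).
#' @param iaw Airway inertance (cmH2O.s^2/L).
#' @param g_tissue Tissue damping G (cmH2O/L).
#' @param h_tissue Tissue elastance H (cmH2O/L).
#' @param open_fraction Fraction of recruited units, in (0, 1].
#' @param close_rate Fraction of open units closing per minute.
#' @param reopen_threshold Breath size (mL/kg) above which units reopen.
#' @param reopen_gain Fraction of closed units reopened per qualifying breath.
#' @return Object of class `lung_model_state`.
#' @export
lung_model_state <- function(raw = 25, iaw = 0.02, g_tissue = 45,
                             h_tissue = 330, open_fraction = 1,
                             close_rate = 5e-4, reopen_threshold = 9,
                             reopen_gain = 0.1) {
  if (raw <= 0 || g_tissue <= 0 || h_tissue <= 0)
    pv_stop("raw, g_tissue and h_tissue must be > 0")
  if (iaw < 0) pv_stop("iaw must be >= 0")
  if (open_fraction <= 0 || open_fraction > 1)
    pv_stop("open_fraction must be in (0, 1]")
  if (close_rate < 0 || reopen_gain < 0 || reopen_gain > 1)
    pv_stop("close_rate >= 0 and reopen_gain in [0, 1] required")
  structure(
    list(raw = raw, iaw = iaw, g_tissue = g_tissue, h_tissue = h_tissue,
         open_fraction = open_fraction, close_rate = close_rate,
         reopen_threshold = reopen_threshold, reopen_gain = reopen_gain),
    class = "lung_model_state"
  )
}

#' @export
print.lung_model_state <- function(x, ...) {
  cat(sprintf(
    "<lung_model_state> Raw=%.3g Iaw=%.3g G=%.3g H=%.3g (cmH2O units), open=%.3f\n",
    x$raw, x$iaw, x$g_tissue, x$h_tissue, x$open_fraction))
  invisible(x)
}

#' Effective tissue elastance of a partially recruited lung
#'
#' E_eff = H / open_fraction: closed units do not accept volume, so the
#' remaining units share the full tidal volume.
#'
#' @param state A [lung_model_state()].
#' @return Elastance (cmH2O/L).
#' @export
effective_elastance <- function(state) state$h_tissue / state$open_fraction

#' Low-frequency resistance of the lung at the breathing frequency
#'
#' The constant-phase tissue compartment contributes a real part
#' G / omega^alpha at angular frequency omega; added to the Newtonian
#' airway resistance this gives the resistance a slow pressure-controlled
#' breath "sees". This is the documented mapping from (Raw, G, H) to the
#' single-compartment R used by the time-domain simulator.
#'
#' @param state A [lung_model_state()].
#' @param f_breath Breathing frequency (Hz).
#' @return Resistance (cmH2O.s/L).
#' @export
breathing_frequency_resistance <- function(state, f_breath) {
  if (f_breath <= 0) pv_stop("f_breath must be > 0")
  alpha <- (2 / pi) * atan(state$h_tissue / state$g_tissue)
  state$raw + state$g_tissue / (2 * pi * f_breath)^alpha
}

#' Advance the recruitment state by one breath
#'
#' `open_fraction` decays exponentially at `close_rate` over the breath
#' duration `dt`; if the delivered breath exceeds `reopen_threshold`, a
#' fraction `reopen_gain` of the closed units reopens. The result is kept
#' in (0, 1].
#'
#' @param state A [lung_model_state()].
#' @param breath_vt Delivered breath size (mL/kg), >= 0.
#' @param dt Time elapsed (s).
#' @return Updated `lung_model_state`.
#' @export
evolve_lung_state <- function(state, breath_vt, dt) {
  stopifnot(inherits(state, "lung_model_state"))
  if (breath_vt < 0) pv_stop("breath_vt must be >= 0")
  if (dt < 0) pv_stop("dt must be >= 0")
  open <- state$open_fraction * exp(-state$close_rate * dt / 60)
  if (breath_vt > state$reopen_threshold)
    open <- open + state$reopen_gain * (1 - open)
  state$open_fraction <- min(1, max(.Machine$double.eps, open))
  state
}

#' Recruitment maneuver (sustained inflation)
#'
#' Normalizes lung volume history: a sustained high-pressure inflation
#' (protocol: 25 cmH2O held for 10 s, applied twice) resets the recruited
#' fraction to its configured maximum. Idempotent.
#'
#' @param state A [lung_model_state()].
#' @param max_open Recruited fraction after the maneuver (default 1).
#' @param n_holds,hold_s,hold_pressure Protocol bookkeeping (two 10-s holds
#'   at 25 cmH2O); recorded on the result as attribute `maneuver`.
#' @return Updated `lung_model_state`.
#' @export
recruitment_maneuver <- function(state, max_open = 1, n_holds = 2,
                                 hold_s = 10, hold_pressure = 25) {
  stopifnot(inherits(state, "lung_model_state"))
  state$open_fraction <- max_open
  attr(state, "maneuver") <- list(n_holds = n_holds, hold_s = hold_s,
                                  hold_pressure = hold_pressure)
  state
}
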