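#' Default forced-oscillation frequency set
#'
#' Fifteen components spanning 0.5-20.75 Hz, constructed as prime multiples
#' of a 0.25 Hz base (primes 2, 7, 11, 17, 23, 29, 37, 41, 47, 53, 59, 67,
#' 71, 79, 83). Distinct primes guarantee that no component is an integer
#' multiple of another, so harmonic distortion of one component never lands
#' on another; the minimum spacing of 1 Hz keeps the components spectrally
#' resolvable in a 10-s record.
#'
#' @return Numeric vector of 15 frequencies (Hz).
#' @export
default_fot_frequencies <- function() {
  0.25 * c(2, 7, 11, 17, 23, 29, 37, 41, 47, 53, 59, 67, 71, 79, 83)
}

#' Forced-oscillation forcing design
#'
#' Specification of the small-amplitude pseudorandom pressure forcing
#' applied during an end-expiratory pause: component frequencies, total
#' peak-to-peak amplitude, duration and (optionally) fixed phases.
#'
#' @param frequencies Component frequencies (Hz); default
#'   [default_fot_frequencies()].
#' @param amplitude_pp Realized peak-to-peak amplitude of the summed signal
#'   (cmH2O); default 2.
#' @param duration Signal duration (s); default 10.
#' @param phases Optional per-component phases (radians); if `NULL`,
#'   [design_forcing_signal()] chooses low-crest-factor phases.
#' @return Object of class `forcing_design`.
#' @export
forcing_design <- function(frequencies = default_fot_frequencies(),
                           amplitude_pp = 2, duration = 10, phases = NULL) {
  if (any(frequencies <= 0)) pv_stop("frequencies must be > 0")
  if (amplitude_pp <= 0 || duration <= 0)
    pv_stop("amplitude_pp and duration must be > 0")
  if (!is.null(phases) && length(phases) != length(frequencies))
    pv_stop("phases must match frequencies in length")
  # non-harmonic check: no component an integer multiple of another
  rat <- outer(frequencies, frequencies, "/")
  diag(rat) <- NA
  if (any(abs(rat - round(rat)) < 1e-9 & round(rat) >= 1, na.rm = TRUE))
    warning("some components are integer multiples of others", call. = FALSE)
  structure(
    list(frequencies = sort(frequencies), amplitude_pp = amplitude_pp,
         duration = duration, phases = phases),
    class = "forcing_design"
  )
}

#' Synthesize the pseudorandom forcing signal
#'
#' Sum of sinusoids at exactly the design frequencies. Unless the design
#' fixes phases, a seeded random search picks the phase set with the lowest
#' crest factor among `n_candidates` draws (keeping the peak excursion small
#' for a given spectral content). The summed signal is then scaled so its
#' realized peak-to-peak amplitude equals `amplitude_pp` exactly.
#'
#' @param design A [forcing_design()].
#' @param sampling_rate Hz; must exceed twice the highest component.
#' @param seed Integer seed for the phase search.
#' @param n_candidates Phase sets tried in the crest-factor search.
#' @return List of class `forcing_signal`: `time` (s), `signal` (cmH2O),
#'   `design` (with the chosen phases filled in), `sampling_rate`,
#'   `crest_factor`.
#' @export
design_forcing_signal <- function(design = forcing_design(),
                                  sampling_rate = 1000, seed = NULL,
                                  n_candidates = 64) {
  stopifnot(inherits(design, "forcing_design"))
  if (sampling_rate <= 2 * max(design$frequencies))
    pv_stop("sampling_rate must exceed twice the highest component (aliasing)",
            "pvvent_argument_error")
  if (!is.null(seed)) set.seed(seed)
  n <- round(design$duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  w <- 2 * pi * design$frequencies

  synth <- function(ph) {
    x <- numeric(n)
    for (k in seq_along(w)) x <- x + sin(w[k] * t + ph[k])
    x
  }

  if (is.null(design$phases)) {
    best <- NULL; best_cf <- Inf
    for (i in seq_len(n_candidates)) {
      ph <- runif(length(w), 0, 2 * pi)
      x <- synth(ph)
      cf <- max(abs(x)) / sqrt(mean(x^2))
      if (cf < best_cf) { best_cf <- cf; best <- ph }
    }
    design$phases <- best
  }
  x <- synth(design$phases)
  x <- x * design$amplitude_pp / (max(x) - min(x))
  structure(
    list(time = t, signal = x, design = design,
         sampling_rate = sampling_rate,
         crest_factor = max(abs(x)) / sqrt(mean(x^2))),
    class = "forcing_signal"
  )
}
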