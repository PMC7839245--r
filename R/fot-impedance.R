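#' Impedance spectrum container
#'
#' Complex respiratory input impedance Zrs = Paw / V' at a set of forcing
#' frequencies, with a per-frequency magnitude-squared coherence as the
#' quality metric.
#'
#' @param frequency Hz.
#' @param z_real,z_imag Real and imaginary parts (cmH2O.s/L).
#' @param coherence Per-frequency coherence in [0, 1].
#' @return data.frame of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequency, z_real, z_imag,
                               coherence = rep(NA_real_, length(frequency))) {
  n <- length(frequency)
  if (length(z_real) != n || length(z_imag) != n || length(coherence) != n)
    pv_stop("frequency, z_real, z_imag and coherence lengths must match")
  if (any(coherence < -1e-9 | coherence > 1 + 1e-9, na.rm = TRUE))
    pv_stop("coherence must be in [0, 1]")
  df <- data.frame(frequency = frequency, z_real = z_real, z_imag = z_imag,
                   coherence = pmin(1, pmax(0, coherence)))
  class(df) <- c("impedance_spectrum", "data.frame")
  df
}

as_complex_z <- function(spectrum) complex(real = spectrum$z_real,
                                           imaginary = spectrum$z_imag)

#' Estimate respiratory impedance from pressure and flow records
#'
#' Welch-style cross-spectral estimator: the 10-s pressure and flow records
#' are split into overlapping windows (default 4 s with 95% overlap), Hann
#' tapered and Fourier transformed; Zrs at each design frequency is the
#' averaged flow-pressure cross-spectrum over the flow auto-spectrum at the
#' nearest frequency bin (with the default 4-s windows, the bin grid is
#' 0.25 Hz and all default components fall exactly on bins). The
#' cross-spectral form is robust to uncorrelated noise; the per-frequency
#' coherence is returned as quality metric. Design frequencies with
#' negligible flow power are excluded (with a warning); more than one third
#' excluded is an error.
#'
#' @param pressure,flow Numeric vectors, same length (cmH2O, L/s).
#' @param sampling_rate Hz.
#' @param design A [forcing_design()] giving the frequencies to read out.
#' @param window_s Window length (s).
#' @param overlap Fractional window overlap in [0, 1).
#' @return An [impedance_spectrum()].
#' @export
estimate_impedance <- function(pressure, flow, sampling_rate,
                               design = forcing_design(), window_s = 4,
                               overlap = 0.95) {
  if (length(pressure) != length(flow))
    pv_stop("pressure and flow must have equal length")
  nwin <- round(window_s * sampling_rate)
  if (length(flow) < nwin)
    pv_stop("record shorter than one analysis window", "pvvent_argument_error")
  if (overlap < 0 || overlap >= 1) pv_stop("overlap must be in [0, 1)")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(flow) - nwin + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))  # Hann

  s_qp <- s_qq <- s_pp <- 0
  for (s0 in starts) {
    idx <- s0:(s0 + nwin - 1L)
    p <- fft((pressure[idx] - mean(pressure[idx])) * win)
    q <- fft((flow[idx] - mean(flow[idx])) * win)
    s_qp <- s_qp + Conj(q) * p
    s_qq <- s_qq + Mod(q)^2
    s_pp <- s_pp + Mod(p)^2
  }
  freqs_bin <- (seq_len(nwin) - 1) * sampling_rate / nwin
  bins <- vapply(design$frequencies,
                 function(f) which.min(abs(freqs_bin - f)), integer(1))

  qq <- s_qq[bins]
  usable <- qq > max(s_qq) * 1e-10
  if (sum(!usable) > length(bins) / 3)
    pv_stop("more than one third of design frequencies have no flow power",
            "pvvent_domain_error")
  if (any(!usable))
    warning(sprintf("%d design frequencies excluded for zero flow power",
                    sum(!usable)), call. = FALSE)
  z <- s_qp[bins] / qq
  coh <- Mod(s_qp[bins])^2 / (qq * s_pp[bins])
  out <- impedance_spectrum(design$frequencies[usable],
                            Re(z)[usable], Im(z)[usable],
                            pmin(1, coh[usable]))
  attr(out, "n_windows") <- length(starts)
  out
}

#' Average impedance spectra over measurement epochs
#'
#' Complex mean per frequency of repeated recordings at one timepoint
#' (protocol: three epochs per timepoint); coherence is averaged.
#'
#' @param spectra List of [impedance_spectrum()] objects on identical grids.
#' @return An [impedance_spectrum()].
#' @export
average_epochs <- function(spectra) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$frequency
  for (s in spectra)
    if (!isTRUE(all.equal(s$frequency, f0)))
      pv_stop("frequency grids differ between epochs", "pvvent_argument_error")
  zm <- Reduce(`+`, lapply(spectra, as_complex_z)) / length(spectra)
  coh <- Reduce(`+`, lapply(spectra, function(s) s$coherence)) /
    length(spectra)
  impedance_spectrum(f0, Re(zm), Im(zm), coh)
}

#' Subtract breathing-circuit impedance
#'
#' The measured spectrum contains the breathing circuit in series with the
#' respiratory system; the calibration spectrum of the circuit alone is
#' removed by complex subtraction per frequency.
#'
#' @param z_measured,z_circuit [impedance_spectrum()] objects on identical
#'   grids.
#' @return An [impedance_spectrum()] of the respiratory system alone.
#' @export
subtract_circuit_impedance <- function(z_measured, z_circuit) {
  if (!isTRUE(all.equal(z_measured$frequency, z_circuit$frequency)))
    pv_stop("frequency grids differ", "pvvent_argument_error")
  z <- as_complex_z(z_measured) - as_complex_z(z_circuit)
  impedance_spectrum(z_measured$frequency, Re(z), Im(z),
                     z_measured$coherence)
}
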