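#' Parameters for the spontaneous-breathing simulator
#'
#' Calibration defaults reproduce the breathing statistics of awake COPD
#' rabbits measured by whole-body plethysmography: mean tidal volume
#' 7.1 mL/kg with a coefficient of variation of 12.6%, mean respiratory rate
#' 22.9 /min with CV 12.9%. Breath amplitudes and periods follow lognormal
#' marginals (positivity) with mild AR(1) autocorrelation on the latent
#' scale.
#'
#' @param mean_vt Mean breath amplitude (mL/kg equivalent, arbitrary
#'   pressure units before calibration).
#' @param cv_vt Coefficient of variation of amplitudes (fraction).
#' @param mean_rr Mean respiratory rate (breaths/min).
#' @param cv_rr Coefficient of variation of breath periods (fraction).
#' @param ar1_coeff AR(1) coefficient of successive latent amplitudes/periods,
#'   in (-1, 1).
#' @param artifact_rate Movement artifacts per minute (Poisson rate).
#' @param artifact_duration Artifact duration (s).
#' @param sampling_rate Sampling rate of the synthesized trace (Hz).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `breathing_sim_params`.
#' @export
breathing_sim_params <- function(mean_vt = 7.1, cv_vt = 0.126,
                                 mean_rr = 22.9, cv_rr = 0.129,
                                 ar1_coeff = 0.3,
                                 artifact_rate = 0.5, artifact_duration = 2,
                                 sampling_rate = 200, seed = NULL) {
  if (cv_vt < 0 || cv_rr < 0) pv_stop("cv_vt and cv_rr must be >= 0")
  if (mean_vt <= 0 || mean_rr <= 0 || sampling_rate <= 0)
    pv_stop("mean_vt, mean_rr and sampling_rate must be > 0")
  if (abs(ar1_coeff) >= 1) pv_stop("ar1_coeff must be in (-1, 1)")
  if (artifact_rate < 0 || artifact_duration < 0)
    pv_stop("artifact settings must be non-negative")
  structure(
    list(mean_vt = mean_vt, cv_vt = cv_vt, mean_rr = mean_rr, cv_rr = cv_rr,
         ar1_coeff = ar1_coeff, artifact_rate = artifact_rate,
         artifact_duration = artifact_duration,
         sampling_rate = sampling_rate, seed = seed),
    class = "breathing_sim_params"
  )
}

# Stationary AR(1) process with N(0,1) marginals.
ar1_series <- function(n, phi) {
  z <- numeric(n)
  z[1] <- rnorm(1)
  if (n > 1) {
    innov <- rnorm(n - 1, sd = sqrt(1 - phi^2))
    for (i in 2:n) z[i] <- phi * z[i - 1] + innov[i - 1]
  }
  z
}

# Lognormal draws with exact target mean and CV, AR(1)-correlated latents.
lognormal_ar1 <- function(n, mean, cv, phi) {
  if (cv == 0) return(rep(mean, n))
  sigma2 <- log(1 + cv^2)
  mu <- log(mean) - sigma2 / 2
  exp(mu + sqrt(sigma2) * ar1_series(n, phi))
}

#' Plethysmograph recording container
#'
#' A sampled pressure-like trace with its sampling rate and any known
#' movement-artifact intervals (seconds from record start, half-open).
#'
#' @param samples Numeric vector.
#' @param sampling_rate Hz, > 0.
#' @param artifact_intervals Two-column matrix or list of `c(start, end)`
#'   pairs in seconds; normalized to a sorted, merged matrix.
#' @return Object of class `pleth_recording` with fields `samples`,
#'   `sampling_rate`, `artifact_intervals`, `duration`.
#' @export
pleth_recording <- function(samples, sampling_rate,
                            artifact_intervals = NULL) {
  if (sampling_rate <= 0) pv_stop("sampling_rate must be > 0")
  duration <- length(samples) / sampling_rate
  iv <- normalize_intervals(artifact_intervals, duration)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         artifact_intervals = iv, duration = duration),
    class = "pleth_recording"
  )
}

# Sort, clip to [0, duration], merge overlaps; returns n x 2 matrix.
normalize_intervals <- function(iv, duration) {
  if (is.null(iv) || length(iv) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  m <- if (is.matrix(iv)) iv else do.call(rbind, iv)
  m[, 1] <- pmax(0, m[, 1]); m[, 2] <- pmin(duration, m[, 2])
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' @export
print.pleth_recording <- function(x, ...) {
  cat(sprintf("<pleth_recording> %.1f s @ %g Hz, %d artifact interval(s)\n",
              x$duration, x$sampling_rate, nrow(x$artifact_intervals)))
  invisible(x)
}

#' Simulate a spontaneous-breathing plethysmograph recording
#'
#' Synthesizes a pressure-like trace as a concatenation of half-sine breath
#' deflections whose amplitudes and periods are drawn from autocorrelated
#' lognormal processes with the requested means and CVs. Movement artifacts
#' (broadband high-amplitude bursts, Poisson-placed) are injected and the
#' true intervals annotated. The per-breath ground truth is returned in
#' `$breaths`.
#'
#' @param params A [breathing_sim_params()] object.
#' @param duration_s Recording length (s); default 600 (a ten-minute
#'   recording).
#' @return A `pleth_recording` with an extra field `breaths`
#'   (data.frame: index, amplitude, period, inspiratory_time, onset).
#' @export
generate_spontaneous_breathing <- function(params, duration_s = 600) {
  stopifnot(inherits(params, "breathing_sim_params"))
  if (duration_s < 2 * 60 / params$mean_rr)
    pv_stop("duration shorter than two mean breath periods",
            "pvvent_argument_error")
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_rate
  mean_period <- 60 / params$mean_rr

  # draw more breaths than fit, then truncate at duration
  n_guess <- ceiling(duration_s / mean_period * (1 + 6 * params$cv_rr)) + 8
  amps <- lognormal_ar1(n_guess, params$mean_vt, params$cv_vt,
                        params$ar1_coeff)
  periods <- lognormal_ar1(n_guess, mean_period, params$cv_rr,
                           params$ar1_coeff)
  onsets <- cumsum(c(0, periods))
  keep <- which(onsets[-1] <= duration_s)        # breaths fully inside
  amps <- amps[keep]; periods <- periods[keep]; onsets <- onsets[keep]

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (i in seq_along(amps)) {
    i0 <- floor(onsets[i] * fs) + 1
    i1 <- min(n, floor((onsets[i] + periods[i]) * fs))
    if (i1 < i0) next
    tt <- t[i0:i1] - onsets[i]
    x[i0:i1] <- amps[i] * sin(pi * tt / periods[i])
  }

  # artifacts: Poisson count, uniform placement, broadband burst
  iv <- NULL
  n_art <- rpois(1, params$artifact_rate * duration_s / 60)
  if (n_art > 0 && params$artifact_duration > 0) {
    starts <- sort(runif(n_art, 0, max(0, duration_s - params$artifact_duration)))
    iv <- cbind(starts, starts + params$artifact_duration)
    for (k in seq_len(nrow(iv))) {
      j0 <- floor(iv[k, 1] * fs) + 1
      j1 <- min(n, floor(iv[k, 2] * fs))
      x[j0:j1] <- x[j0:j1] +
        runif(j1 - j0 + 1, -3 * params$mean_vt, 3 * params$mean_vt)
    }
  }

  rec <- pleth_recording(x, fs, iv)
  rec$breaths <- data.frame(
    index = seq_along(amps), amplitude = amps, period = periods,
    inspiratory_time = periods / 2, onset = onsets
  )
  rec
}
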