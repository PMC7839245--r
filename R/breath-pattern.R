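#' Detect breaths in a plethysmograph recording
#'
#' Segments a pressure-like trace into breaths: the signal is conditioned
#' with a low-pass filter (default corner 3 Hz, 2nd-order Butterworth,
#' zero-phase) and a slow rolling-mean baseline subtraction (the band-pass
#' for breathing frequencies); inspiratory peaks are found by peak-prominence
#' detection, with prominence at least `prominence_frac` of the median peak
#' height; breath amplitude is the peak-to-preceding-trough excursion and
#' the breath period the inter-peak interval. Breaths overlapping annotated
#' artifact intervals — or spanning an excision boundary left by
#' [remove_artifact_segments()] — are excluded.
#'
#' @param recording A [pleth_recording()].
#' @param lowpass_hz Low-pass corner frequency (Hz).
#' @param baseline_s Rolling-mean baseline window (s).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   median detected peak height.
#' @param min_period_s Minimum credible breath period (s); peaks closer
#'   than this are merged.
#' @return data.frame of class `breath_table`: `index`, `amplitude`,
#'   `period` (s), `inspiratory_time` (s), `peak_time` (s).
#' @export
detect_breaths <- function(recording, lowpass_hz = 3, baseline_s = 5,
                           prominence_frac = 0.25, min_period_s = 0.5) {
  stopifnot(inherits(recording, "pleth_recording"))
  fs <- recording$sampling_rate
  x <- recording$samples
  if (length(x) < 2 * fs * min_period_s)
    pv_stop("record too short for breath detection", "pvvent_argument_error")

  xl <- lowpass_signal(x, fs, lowpass_hz)
  xf <- detrend_signal(xl, fs, baseline_s)

  pk <- pracma::findpeaks(xf, minpeakdistance = max(1L, round(min_period_s * fs)),
                          zero = "0")
  if (is.null(pk) || nrow(pk) == 0)
    pv_stop("no breaths found in recording", "pvvent_empty_result")
  # prominence filter relative to median peak height
  thr <- prominence_frac * median(pk[, 1])
  prom <- pk[, 1] - pmax(xf[pk[, 3]], xf[pk[, 4]])
  pk <- pk[prom >= thr & pk[, 1] > 0, , drop = FALSE]
  if (nrow(pk) == 0)
    pv_stop("no breaths found in recording", "pvvent_empty_result")
  pk <- pk[order(pk[, 2]), , drop = FALSE]

  ipk <- pk[, 2]                 # peak sample index
  # amplitude from the low-pass (undetrended) signal: the rolling-mean
  # baseline is only for robust peak finding and would distort excursions.
  # The trough is the signal minimum between successive kept peaks.
  nb <- length(ipk)
  half_win <- round(fs * 60 / 20)    # fallback lookback ~ one breath
  itr <- integer(nb)
  for (i in seq_len(nb)) {
    lo <- if (i == 1) max(1L, ipk[i] - half_win) else ipk[i - 1]
    seg <- lo:ipk[i]
    itr[i] <- seg[which.min(xl[seg])]
  }
  amplitude <- xl[ipk] - xl[itr]
  peak_time <- (ipk - 1) / fs
  trough_time <- (itr - 1) / fs

  n <- length(ipk)
  if (n >= 2) {
    gaps <- diff(peak_time)
    period <- c(gaps[1], gaps)
  } else period <- NA_real_
  insp <- peak_time - trough_time

  br <- data.frame(index = seq_len(n), amplitude = amplitude,
                   period = period, inspiratory_time = insp,
                   peak_time = peak_time)

  # exclusion: breaths overlapping artifact intervals or splice boundaries
  iv <- recording$artifact_intervals
  splices <- attr(recording, "splice_points")
  span_lo <- trough_time
  span_hi <- peak_time + period / 2
  drop <- rep(FALSE, n)
  if (nrow(iv) > 0) {
    for (k in seq_len(nrow(iv)))
      drop <- drop | (span_lo < iv[k, 2] & span_hi > iv[k, 1])
  }
  if (!is.null(splices) && length(splices) > 0) {
    for (s in splices) drop <- drop | (span_lo < s & span_hi > s)
  }
  br <- br[!drop, , drop = FALSE]
  if (nrow(br) == 0)
    pv_stop("all detected breaths fall in artifact segments",
            "pvvent_empty_result")
  br$index <- seq_len(nrow(br))
  class(br) <- c("breath_table", "data.frame")
  br
}

# Zero-phase 2nd-order Butterworth low-pass.
lowpass_signal <- function(x, fs, lowpass_hz) {
  ny <- fs / 2
  if (lowpass_hz >= ny) return(x)
  bf <- signal::butter(2, lowpass_hz / ny, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Rolling-mean baseline subtraction (slow drift removal for peak finding).
detrend_signal <- function(x, fs, baseline_s) {
  w <- max(3L, round(baseline_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  base <- stats::filter(x, rep(1 / w, w), sides = 2)
  base[is.na(base)] <- mean(x)
  as.numeric(x - base)
}

#' Excise artifact segments from a recording
#'
#' Removes the annotated (or, if absent, automatically detected) movement
#' artifact intervals from the trace and records the splice points so that
#' downstream breath detection never computes a period across an excision
#' boundary. Automatic detection flags windows whose rolling RMS exceeds
#' `rms_factor` times the record's median rolling RMS — movement artifacts
#' are broadband bursts far larger than tidal deflections.
#'
#' @param recording A [pleth_recording()].
#' @param window_s Rolling-RMS window (s) for automatic detection.
#' @param rms_factor Detection threshold multiplier.
#' @return A `pleth_recording` with segments removed, empty
#'   `artifact_intervals`, and attribute `splice_points` (times, s, in the
#'   excised record) plus `removed_s` (total excised duration).
#' @export
remove_artifact_segments <- function(recording, window_s = 0.5,
                                     rms_factor = 3) {
  stopifnot(inherits(recording, "pleth_recording"))
  fs <- recording$sampling_rate
  iv <- recording$artifact_intervals
  if (nrow(iv) == 0) iv <- detect_artifact_intervals(recording, window_s,
                                                     rms_factor)
  if (nrow(iv) == 0) {
    out <- recording
    attr(out, "splice_points") <- numeric(0)
    attr(out, "removed_s") <- 0
    return(out)
  }
  n <- length(recording$samples)
  keep <- rep(TRUE, n)
  for (k in seq_len(nrow(iv))) {
    j0 <- max(1L, floor(iv[k, 1] * fs) + 1L)
    j1 <- min(n, ceiling(iv[k, 2] * fs))
    keep[j0:j1] <- FALSE
  }
  # splice points: cumulative kept-duration at each removed block start
  starts <- floor(iv[, 1] * fs) + 1L
  kept_before <- cumsum(keep)
  splice <- unique(kept_before[pmin(pmax(starts, 1L), n)] / fs)

  out <- pleth_recording(recording$samples[keep], fs, NULL)
  attr(out, "splice_points") <- splice
  attr(out, "removed_s") <- sum(!keep) / fs
  out
}

# Rolling-RMS outlier rule; returns merged intervals (s).
detect_artifact_intervals <- function(recording, window_s = 0.5,
                                      rms_factor = 3) {
  fs <- recording$sampling_rate
  x <- recording$samples - median(recording$samples)
  w <- max(3L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  rms <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  rms[is.na(rms)] <- median(rms, na.rm = TRUE)
  flag <- rms > rms_factor * median(rms)
  if (!any(flag)) return(normalize_intervals(NULL, recording$duration))
  # expand by half a window, then merge runs into intervals
  r <- rle(as.vector(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind((starts[r$values] - 1) / fs - window_s / 2,
              ends[r$values] / fs + window_s / 2)
  normalize_intervals(iv, recording$duration)
}

#' Build a normalized PVV driving pattern from detected breaths
#'
#' Converts the first `n_breaths` artifact-free breaths into the ventilator
#' driving schedule: per-breath pressure ratio amplitude_i / mean(amplitude)
#' and period ratio period_i / mean(period), renormalized so both means are
#' exactly 1 (to 1e-9). Temporal order is preserved; the pattern is intended
#' to be replayed in a loop.
#'
#' @param breaths A `breath_table` (from [detect_breaths()]) or any
#'   data.frame with `amplitude` and `period` columns.
#' @param n_breaths Number of breaths the pattern must contain
#'   (default 382, a full pattern file).
#' @return Object of class `ventilation_pattern`: data.frame `entries`
#'   (breath_index, pressure_ratio, period_ratio), `n_breaths`,
#'   `source_meta`.
#' @export
build_pvv_pattern <- function(breaths, n_breaths = 382) {
  if (inherits(breaths, "breath_schedule"))
    breaths <- data.frame(amplitude = breaths$vt, period = breaths$period)
  if (!all(c("amplitude", "period") %in% names(breaths)))
    pv_stop("breaths must have amplitude and period columns")
  ok <- stats::complete.cases(breaths[, c("amplitude", "period")])
  b <- breaths[ok, , drop = FALSE]
  if (n_breaths < 1) pv_stop("n_breaths must be >= 1")
  if (nrow(b) < n_breaths)
    pv_stop(sprintf("need %d breaths, only %d available after exclusion",
                    n_breaths, nrow(b)), "pvvent_argument_error")
  b <- b[seq_len(n_breaths), ]
  if (any(b$amplitude <= 0) || any(b$period <= 0))
    pv_stop("breath amplitudes and periods must be > 0")
  pr <- b$amplitude / mean(b$amplitude)
  qr <- b$period / mean(b$period)
  pr <- pr / mean(pr)   # exact renormalization
  qr <- qr / mean(qr)
  structure(
    list(entries = data.frame(breath_index = seq_len(n_breaths),
                              pressure_ratio = pr, period_ratio = qr),
         n_breaths = n_breaths,
         source_meta = list(created = "build_pvv_pattern",
                            n_input_breaths = nrow(breaths))),
    class = "ventilation_pattern"
  )
}

#' @export
print.ventilation_pattern <- function(x, ...) {
  cat(sprintf("<ventilation_pattern> %d breaths; pressure-ratio CV %.1f%%, period-ratio CV %.1f%%\n",
              x$n_breaths,
              100 * sd(x$entries$pressure_ratio) / mean(x$entries$pressure_ratio),
              100 * sd(x$entries$period_ratio) / mean(x$entries$period_ratio)))
  invisible(x)
}

#' Rescale a pattern to target mean rate and tidal volume
#'
#' Produces the per-breath ventilation schedule for a replicate of the
#' recorded pattern at a different average respiratory rate and tidal
#' volume, maintaining the exact breath-to-breath pressure and frequency
#' ratios: vt_i = target_mean_vt * pressure_ratio_i and
#' period_i = (60 / target_mean_rr) * period_ratio_i. Coefficients of
#' variation and all successive ratios are preserved exactly.
#'
#' @param pattern A [build_pvv_pattern()] result.
#' @param target_mean_rr Target mean respiratory rate (breaths/min).
#' @param target_mean_vt Target mean tidal volume (mL/kg).
#' @return data.frame of class `breath_schedule`: `breath_index`, `vt`
#'   (mL/kg), `period` (s).
#' @export
rescale_pattern <- function(pattern, target_mean_rr, target_mean_vt) {
  stopifnot(inherits(pattern, "ventilation_pattern"))
  if (target_mean_rr <= 0 || target_mean_vt <= 0)
    pv_stop("targets must be > 0")
  sched <- data.frame(
    breath_index = pattern$entries$breath_index,
    vt = target_mean_vt * pattern$entries$pressure_ratio,
    period = (60 / target_mean_rr) * pattern$entries$period_ratio
  )
  class(sched) <- c("breath_schedule", "data.frame")
  sched
}

#' Pattern summary statistics (mean, CV, min, max)
#'
#' Breath-pattern characteristics as reported for ventilation variables:
#' for tidal volume the per-breath series itself; for respiratory rate the
#' instantaneous rate 60/period_i. CV is the sample standard deviation over
#' the mean, in percent.
#'
#' @param vt Per-breath tidal volumes (mL/kg), or a `breath_schedule`.
#' @param period Per-breath periods (s); ignored when `vt` is a schedule.
#' @return data.frame: rows VT and RR, columns mean, cv_pct, min, max.
#' @export
#' @examples
#' pattern_statistics(c(4, 6, 8, 10), rep(2.5, 4))
pattern_statistics <- function(vt, period = NULL) {
  if (inherits(vt, "breath_schedule")) {
    period <- vt$period
    vt <- vt$vt
  }
  if (length(vt) < 2 || is.null(period) || length(period) < 2)
    pv_stop("at least two breaths required (CV undefined for one)",
            "pvvent_argument_error")
  rr <- 60 / period
  stat <- function(x) c(mean = mean(x), cv_pct = 100 * sd(x) / mean(x),
                        min = min(x), max = max(x))
  out <- as.data.frame(rbind(VT = stat(vt), RR = stat(rr)))
  out$variable <- rownames(out)
  out[, c("variable", "mean", "cv_pct", "min", "max")]
}
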