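#' Airway-tissue mechanics parameters
#'
#' Parameters of the respiratory mechanics model: Newtonian airway
#' resistance `raw` and inertance `iaw` in series with a constant-phase
#' tissue compartment of damping `g_tissue` and elastance `h_tissue`. The
#' tissue exponent is derived, not free:
#' alpha = (2/pi) * atan(h_tissue / g_tissue).
#'
#' @param raw Airway resistance (cmH2O.s/L), > 0.
#' @param iaw Airway inertance (cmH2O.s^2/L), >= 0.
#' @param g_tissue Tissue damping G (cmH2O/L), > 0.
#' @param h_tissue Tissue elastance H (cmH2O/L), > 0.
#' @param fit_residual Normalized objective value when produced by a fit.
#' @return Object of class `mechanics_params` with derived field `alpha`.
#' @export
mechanics_params <- function(raw, iaw, g_tissue, h_tissue,
                             fit_residual = NA_real_) {
  if (raw <= 0 || g_tissue <= 0 || h_tissue <= 0)
    pv_stop("raw, g_tissue and h_tissue must be > 0")
  if (iaw < 0) pv_stop("iaw must be >= 0")
  structure(
    list(raw = raw, iaw = iaw, g_tissue = g_tissue, h_tissue = h_tissue,
         alpha = (2 / pi) * atan(h_tissue / g_tissue),
         fit_residual = fit_residual),
    class = "mechanics_params"
  )
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat(sprintf(
    "<mechanics_params> Raw=%.4g cmH2O.s/L  Iaw=%.4g cmH2O.s2/L  G=%.4g  H=%.4g cmH2O/L  alpha=%.4f\n",
    x$raw, x$iaw, x$g_tissue, x$h_tissue, x$alpha))
  if (!is.na(x$fit_residual))
    cat(sprintf("  fit residual %.3g%s\n", x$fit_residual,
                if (isTRUE(attr(x, "boundary"))) "  [boundary-pinned]" else ""))
  invisible(x)
}

#' Model impedance of the airway + constant-phase tissue model
#'
#' Z(f) = Raw + i 2 pi f Iaw + (G - iH) / (2 pi f)^alpha with
#' alpha = (2/pi) atan(H/G). The tissue term has constant phase across
#' frequency; G and H set viscous loss and elastic storage.
#'
#' @param params A [mechanics_params()] (or list with raw, iaw, g_tissue,
#'   h_tissue).
#' @param frequencies Hz, all > 0 (the model is singular at f = 0).
#' @return An [impedance_spectrum()] with coherence 1 (noise-free model).
#' @export
constant_phase_model <- function(params, frequencies) {
  if (any(frequencies <= 0))
    pv_stop("constant-phase model is singular at f <= 0",
            "pvvent_argument_error")
  w <- 2 * pi * frequencies
  alpha <- (2 / pi) * atan(params$h_tissue / params$g_tissue)
  z <- params$raw + 1i * w * params$iaw +
    complex(real = params$g_tissue, imaginary = -params$h_tissue) / w^alpha
  impedance_spectrum(frequencies, Re(z), Im(z), rep(1, length(frequencies)))
}

#' Fit the constant-phase model to a measured impedance spectrum
#'
#' Global optimization by seeded multi-start bounded local minimization
#' (`nlminb`): the objective is the sum over frequencies of the squared
#' modulus of (Z_measured - Z_model), optionally weighted by 1/|Z_measured|^2.
#' Starts are drawn log-uniformly (raw, g, h) / uniformly (iaw) inside the
#' bounds. Solutions pinned at a bound are returned but flagged
#' (attribute `boundary`), never silently.
#'
#' @param z_rs An [impedance_spectrum()] with >= 6 usable frequencies.
#' @param bounds Named list of `c(lower, upper)` for raw, iaw, g_tissue,
#'   h_tissue.
#' @param n_starts Number of multi-start local searches.
#' @param seed Integer seed for start generation.
#' @param weighting "none" (default) or "modulus" (1/|Z|^2 weights).
#' @return A [mechanics_params()] with `fit_residual` (objective normalized
#'   by n and mean |Z|^2) and attributes `boundary`, `n_converged`,
#'   `starts_used`.
#' @export
fit_constant_phase <- function(z_rs,
                               bounds = list(raw = c(1, 200),
                                             iaw = c(0, 1),
                                             g_tissue = c(1, 500),
                                             h_tissue = c(10, 2000)),
                               n_starts = 20, seed = 1,
                               weighting = c("none", "modulus")) {
  weighting <- match.arg(weighting)
  keep <- is.na(z_rs$coherence) | z_rs$coherence > 0
  f <- z_rs$frequency[keep]
  if (length(f) < 6)
    pv_stop("need at least 6 usable frequencies", "pvvent_argument_error")
  zm <- as_complex_z(z_rs)[keep]
  wgt <- if (weighting == "modulus") 1 / pmax(Mod(zm)^2, 1e-12) else
    rep(1, length(zm))
  w <- 2 * pi * f

  obj <- function(par) {
    g <- par[3]; h <- par[4]
    alpha <- (2 / pi) * atan(h / g)
    z <- par[1] + 1i * w * par[2] +
      complex(real = g, imaginary = -h) / w^alpha
    sum(wgt * Mod(zm - z)^2)
  }

  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (!is.null(seed)) set.seed(seed)
  draw_start <- function() {
    s <- numeric(4)
    for (j in c(1, 3, 4))       # log-uniform for positive scale params
      s[j] <- exp(runif(1, log(max(lo[j], 1e-3)), log(hi[j])))
    s[2] <- runif(1, lo[2], hi[2])
    s
  }

  best <- NULL; n_conv <- 0L
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::nlminb(draw_start(), obj, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    pv_stop("all optimization starts failed", "pvvent_fit_error")

  p <- best$par
  rel <- function(x, l, u) (x - l) / max(u - l, 1e-12)
  on_bound <- any(rel(p, lo, hi) < 1e-6 | rel(p, lo, hi) > 1 - 1e-6)
  out <- mechanics_params(p[1], p[2], p[3], p[4],
                          fit_residual = best$objective /
                            (length(zm) * mean(Mod(zm)^2)))
  attr(out, "boundary") <- on_bound
  attr(out, "n_converged") <- n_conv
  attr(out, "starts_used") <- n_starts
  if (on_bound)
    warning("fitted parameters pinned at a bound; inspect the spectrum",
            call. = FALSE)
  out
}
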