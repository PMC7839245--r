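test_that("a single-component forcing realizes its peak-to-peak exactly", {
  d <- forcing_design(frequencies = 1, amplitude_pp = 2)
  fs <- design_forcing_signal(d, 1000, seed = 1)
  expect_equal(max(fs$signal) - min(fs$signal), 2, tolerance = 1e-12)
})

test_that("the default forcing has 15 in-band non-harmonic components", {
  f <- default_fot_frequencies()
  expect_length(f, 15)
  expect_true(all(f >= 0.5 & f <= 21))
  rat <- outer(f, f, "/")
  diag(rat) <- 1.5
  expect_false(any(abs(rat - round(rat)) < 1e-9))
  fs <- design_forcing_signal(forcing_design(), 1000, seed = 2)
  expect_equal(max(fs$signal) - min(fs$signal), 2, tolerance = 1e-12)
})

test_that("forcing energy stays on the design frequencies", {
  fs <- design_forcing_signal(forcing_design(), 1000, seed = 3)
  # 4-s rectangular FFT puts the 0.25 Hz-multiple components on exact bins
  x <- fs$signal[1:4000]
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(sp) - 1) * 1000 / 4000
  on_design <- freqs %in% default_fot_frequencies()
  half <- seq_len(2000)
  expect_lt(sum(sp[half][!on_design[half]]) / sum(sp[half]), 0.01)
})

test_that("undersampled designs raise an aliasing error", {
  expect_error(design_forcing_signal(forcing_design(), sampling_rate = 30),
               class = "pvvent_argument_error")
})

test_that("the estimator recovers a pure resistance", {
  des <- forcing_design()
  truth <- impedance_spectrum(des$frequencies, rep(25, 15), rep(0, 15))
  pf <- synth_pf_pair(truth, des)
  zs <- estimate_impedance(pf$pressure, pf$flow, 1000, des)
  expect_lt(max(abs(zs$z_real - 25)), 0.1)
  expect_lt(max(abs(zs$z_imag)), 0.1)
})

test_that("the estimator recovers pure elastance and inertance reactances", {
  des <- forcing_design()
  w <- 2 * pi * des$frequencies
  e <- 400
  truth_e <- impedance_spectrum(des$frequencies, rep(0, 15), -e / w)
  pf_e <- synth_pf_pair(truth_e, des)
  zs_e <- estimate_impedance(pf_e$pressure, pf_e$flow, 1000, des)
  expect_lt(max(abs(zs_e$z_imag - (-e / w))), 0.1)

  iaw <- 0.1
  truth_i <- impedance_spectrum(des$frequencies, rep(0, 15), w * iaw)
  pf_i <- synth_pf_pair(truth_i, des)
  zs_i <- estimate_impedance(pf_i$pressure, pf_i$flow, 1000, des)
  expect_lt(max(abs(zs_i$z_imag - w * iaw)), 0.1)
})

test_that("the estimator is robust to 20 dB additive noise", {
  des <- forcing_design()
  truth <- constant_phase_model(mechanics_params(25, 0.02, 45, 330),
                                des$frequencies)
  pf <- synth_pf_pair(truth, des)
  set.seed(2)
  addn <- function(x) x + rnorm(length(x), sd = sqrt(mean(x^2)) / 10)
  zs <- estimate_impedance(addn(pf$pressure), addn(pf$flow), 1000, des)
  expect_lt(max_z_rel_err(zs, truth), 0.03)
  expect_true(all(zs$coherence > 0.95))
})

test_that("design frequencies without flow power are excluded or fatal", {
  des <- forcing_design()
  sub <- forcing_design(frequencies = des$frequencies[1:13])
  truth <- impedance_spectrum(sub$frequencies, rep(25, 13), rep(0, 13))
  pf <- synth_pf_pair(truth, sub)
  expect_warning(zs <- estimate_impedance(pf$pressure, pf$flow, 1000, des),
                 regexp = "excluded")
  expect_equal(nrow(zs), 13)

  few <- forcing_design(frequencies = des$frequencies[1:7])
  truth7 <- impedance_spectrum(few$frequencies, rep(25, 7), rep(0, 7))
  pf7 <- synth_pf_pair(truth7, few)
  expect_error(suppressWarnings(
    estimate_impedance(pf7$pressure, pf7$flow, 1000, des)),
    class = "pvvent_domain_error")
})

test_that("epoch averaging is the complex mean and permutation-invariant", {
  f <- default_fot_frequencies()
  mk <- function(re) impedance_spectrum(f, rep(re, 15), rep(-5, 15),
                                        rep(0.9, 15))
  s <- list(mk(20), mk(25), mk(30))
  avg <- average_epochs(s)
  expect_equal(avg$z_real, rep(25, 15))
  expect_equal(avg$z_imag, rep(-5, 15))
  expect_equal(avg$coherence, rep(0.9, 15))
  expect_equal(average_epochs(s[c(3, 1, 2)]), avg)
  expect_equal(average_epochs(list(mk(20), mk(20), mk(20)))$z_real,
               rep(20, 15))
  bad <- impedance_spectrum(f + 0.1, rep(1, 15), rep(0, 15))
  expect_error(average_epochs(list(mk(20), bad)),
               class = "pvvent_argument_error")
})

test_that("circuit subtraction is exact complex subtraction", {
  f <- default_fot_frequencies()
  lungz <- constant_phase_model(mechanics_params(25, 0.02, 45, 330), f)
  tube <- impedance_spectrum(f, rep(5, 15), 2 * pi * f * 0.003)
  composite <- impedance_spectrum(f, lungz$z_real + tube$z_real,
                                  lungz$z_imag + tube$z_imag)
  back <- subtract_circuit_impedance(composite, tube)
  expect_equal(back$z_real, lungz$z_real, tolerance = 1e-9)
  expect_equal(back$z_imag, lungz$z_imag, tolerance = 1e-9)

  zero <- impedance_spectrum(f, rep(0, 15), rep(0, 15))
  expect_equal(subtract_circuit_impedance(composite, zero)$z_real,
               composite$z_real)
  # subtract then add back
  again <- subtract_circuit_impedance(composite, back)
  expect_equal(again$z_real, tube$z_real, tolerance = 1e-12)
})

test_that("the constant-phase model obeys its closed forms", {
  # G = H: alpha is exactly 1/2
  m <- mechanics_params(10, 0, 50, 50)
  expect_equal(m$alpha, 0.5)
  # H -> 0: tissue term tends to a frequency-independent real G
  m0 <- mechanics_params(10, 0, 50, 1e-9)
  z0 <- constant_phase_model(m0, c(1, 5, 20))
  expect_lt(max(abs(z0$z_real - 60)), 1e-4)
  expect_lt(max(abs(z0$z_imag)), 1e-6)
  # worked example against independent complex arithmetic
  mx <- mechanics_params(20, 0.01, 40, 400)
  zx <- constant_phase_model(mx, 5)
  alpha <- (2 / pi) * atan(10)
  expect_equal(alpha, 0.93655, tolerance = 1e-5)
  z_hand <- 20 + 2i * pi * 5 * 0.01 + (40 - 400i) / (10 * pi)^alpha
  expect_equal(zx$z_real, Re(z_hand), tolerance = 1e-9)
  expect_equal(zx$z_imag, Im(z_hand), tolerance = 1e-9)
  expect_error(constant_phase_model(mx, 0), class = "pvvent_argument_error")
})

test_that("fitting is invariant to frequency ordering", {
  f <- default_fot_frequencies()
  z <- constant_phase_model(mechanics_params(25, 0.02, 45, 330), f)
  ix <- c(8, 3, 15, 1, 10, 2, 14, 5, 9, 4, 13, 6, 11, 7, 12)
  zp <- impedance_spectrum(z$frequency[ix], z$z_real[ix], z$z_imag[ix])
  fit1 <- fit_constant_phase(z, n_starts = 8, seed = 4)
  fit2 <- fit_constant_phase(zp, n_starts = 8, seed = 4)
  expect_equal(fit1$raw, fit2$raw, tolerance = 1e-6)
  expect_equal(fit1$h_tissue, fit2$h_tissue, tolerance = 1e-6)
})

test_that("a pure-resistor spectrum pins tissue parameters and is flagged", {
  f <- default_fot_frequencies()
  zr <- impedance_spectrum(f, rep(25, 15), rep(0, 15))
  expect_warning(fit <- fit_constant_phase(zr, n_starts = 8, seed = 2),
                 regexp = "bound")
  expect_true(isTRUE(attr(fit, "boundary")))
  expect_equal(fit$raw, 25, tolerance = 0.15)
})

test_that("added noise never decreases the median fit residual", {
  f <- default_fot_frequencies()
  z0 <- constant_phase_model(mechanics_params(25, 0.02, 45, 330), f)
  set.seed(6)
  res_at_noise <- function(sd_rel, nrep = 8) {
    median(vapply(seq_len(nrep), function(i) {
      zn <- impedance_spectrum(f, z0$z_real * (1 + sd_rel * rnorm(15)),
                               z0$z_imag * (1 + sd_rel * rnorm(15)))
      suppressWarnings(
        fit_constant_phase(zn, n_starts = 6, seed = i)$fit_residual)
    }, numeric(1)))
  }
  r0 <- res_at_noise(0)
  r5 <- res_at_noise(0.05)
  expect_lte(r0, r5)
})
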