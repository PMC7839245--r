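# Shared fixtures, built in code at test time.

# Pure sinusoidal "breathing" at a given frequency.
sine_recording <- function(f = 0.4, duration = 60, fs = 200, amp = 1) {
  t <- (seq_len(duration * fs) - 1) / fs
  pleth_recording(amp * sin(2 * pi * f * t), fs)
}

# Multisine pressure/flow pair consistent with a given impedance spectrum:
# flow is the unit-amplitude multisine, pressure the Z-filtered version.
synth_pf_pair <- function(spectrum, design, sampling_rate = 1000,
                          seed = 5, amp = 0.02) {
  fsig <- design_forcing_signal(design, sampling_rate, seed = seed)
  t <- fsig$time
  flow <- numeric(length(t)); pres <- numeric(length(t))
  for (k in seq_along(design$frequencies)) {
    f <- design$frequencies[k]; ph <- fsig$design$phases[k]
    zk <- complex(real = spectrum$z_real[k], imaginary = spectrum$z_imag[k])
    flow <- flow + amp * sin(2 * pi * f * t + ph)
    pres <- pres + amp * Mod(zk) * sin(2 * pi * f * t + ph + Arg(zk))
  }
  list(pressure = pres, flow = flow, time = t, design = fsig$design)
}

max_z_rel_err <- function(est, truth) {
  ze <- complex(real = est$z_real, imaginary = est$z_imag)
  zt <- complex(real = truth$z_real, imaginary = truth$z_imag)
  max(Mod(ze - zt) / Mod(zt))
}

# Small PVV pattern derived from a seeded synthetic recording.
fixture_pattern <- function(seed = 5, n = NULL) {
  p <- breathing_sim_params(seed = seed, artifact_rate = 0)
  rec <- generate_spontaneous_breathing(p, 600)
  br <- detect_breaths(rec)
  build_pvv_pattern(br, n_breaths = n %||% min(382, nrow(br)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
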