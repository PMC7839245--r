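test_that("breath waveforms follow the settings arithmetic", {
  s <- vent_settings(peep = 3, driving_pressure = 10, rr = 24,
                     rise_time = 0)
  wf <- make_breath_waveform(s)
  expect_equal(wf$period, 2.5)
  expect_equal(wf$t_insp, 0.625)
  expect_equal(max(wf$pressure), 13)
  expect_equal(min(wf$pressure), 3)

  # apneic breath: ratio 0 -> flat PEEP trace
  wf0 <- make_breath_waveform(s, pressure_ratio = 0)
  expect_true(all(wf0$pressure == 3))
})

test_that("mean PVV driving pressure over a loop equals the PCV plateau", {
  pat <- fixture_pattern(seed = 8, n = 100)
  s <- vent_settings(peep = 3, driving_pressure = 10, rr = 24,
                     rise_time = 0, mode = "pvv", pattern = pat)
  plateaus <- vapply(seq_len(100), function(i) {
    max(make_breath_waveform(s, pat$entries$pressure_ratio[i],
                             pat$entries$period_ratio[i])$pressure)
  }, numeric(1))
  expect_equal(mean(plateaus - 3), 10, tolerance = 1e-6)
})

test_that("the lung solver matches the RC-charging closed form", {
  s <- vent_settings(driving_pressure = 10, rr = 24, rise_time = 0)
  wf <- make_breath_waveform(s)
  lung <- lung_model_state(raw = 20, iaw = 0, g_tissue = 1e-6,
                           h_tissue = 400)
  pf <- apply_to_lung(wf, lung)
  vt_cf <- (10 / 400) * (1 - exp(-0.625 * 400 / 20))
  expect_equal(pf$delivered_vt, vt_cf, tolerance = 5e-3)

  # quasi-static limit: R -> 0 gives VT = dP / E
  lung_r0 <- lung_model_state(raw = 1e-4, iaw = 0, g_tissue = 1e-6,
                              h_tissue = 400)
  pf0 <- apply_to_lung(wf, lung_r0)
  expect_equal(pf0$delivered_vt, 10 / 400, tolerance = 1e-6)

  # doubling elastance halves the quasi-static volume
  lung_2e <- lung_model_state(raw = 1e-4, iaw = 0, g_tissue = 1e-6,
                              h_tissue = 800)
  expect_equal(apply_to_lung(wf, lung_2e)$delivered_vt,
               pf0$delivered_vt / 2, tolerance = 1e-6)
})

test_that("per-breath volume bookkeeping is self-consistent", {
  s <- vent_settings(driving_pressure = 10, rr = 40)
  wf <- make_breath_waveform(s)
  lung <- lung_model_state(raw = 40, iaw = 0, g_tissue = 1e-6,
                           h_tissue = 80)   # slow lung: traps volume
  pf <- apply_to_lung(wf, lung)
  dt <- 1 / pf$sampling_rate
  inspired <- pf$delivered_vt
  expired <- inspired - pf$end_volume
  net_integral <- sum(pf$signal$flow) * dt
  expect_equal(inspired - expired, pf$end_volume, tolerance = 1e-12)
  expect_equal(net_integral, pf$end_volume, tolerance = 1e-3 * inspired)
})

test_that("the rate controller steps toward the normocapnic band", {
  expect_equal(as.numeric(adapt_rr_for_normocapnia(23, 0.0575)), 23)
  expect_equal(as.numeric(adapt_rr_for_normocapnia(23, 0.07)), 24)
  expect_equal(as.numeric(adapt_rr_for_normocapnia(23, 0.04)), 22)
  hi <- adapt_rr_for_normocapnia(60, 0.07)
  expect_equal(as.numeric(hi), 60)
  expect_true(attr(hi, "saturated"))
})

test_that("the closed-loop controller holds EtCO2 near the band", {
  run <- simulate_ventilation(vent_settings(mode = "pcv"))
  after_burnin <- run$hourly$etco2_pct[run$hourly$hour >= 1]
  in_band <- after_burnin >= 5.5 - 0.2 & after_burnin <= 6.0 + 0.2
  expect_gte(mean(in_band), 0.9)
})

test_that("recruitment maneuver restores the recruited fraction", {
  st <- lung_model_state(open_fraction = 0.7)
  r1 <- recruitment_maneuver(st)
  expect_equal(r1$open_fraction, 1)
  expect_equal(recruitment_maneuver(r1)$open_fraction, 1)  # idempotent
  expect_equal(effective_elastance(r1), r1$h_tissue)
})

test_that("auto-PEEP is flagged exactly when expiration is cut short", {
  # long expiration relative to the time constant: no trapping
  s <- vent_settings(driving_pressure = 10, rr = 24, rise_time = 0)
  lung <- lung_model_state(raw = 20, iaw = 0, g_tissue = 1e-6,
                           h_tissue = 400)  # tau = 0.05 s << T_exp
  pf <- apply_to_lung(make_breath_waveform(s), lung)
  ap <- detect_auto_peep(pf)
  expect_false(ap$flag)
  expect_equal(ap$magnitude, 0)

  # T_exp equal to one time constant: e^-1 of the volume is trapped
  lung2 <- lung_model_state(raw = 40, iaw = 0, g_tissue = 1e-6,
                            h_tissue = 80)          # tau = 0.5 s
  s2 <- vent_settings(driving_pressure = 10, rr = 60 / (4 * 0.5 / 3),
                      rise_time = 0)                # T_exp = 0.5 s
  pf2 <- apply_to_lung(make_breath_waveform(s2), lung2)
  ap2 <- detect_auto_peep(pf2)
  expect_true(ap2$flag)
  expect_equal(pf2$end_volume / pf2$delivered_vt, exp(-1),
               tolerance = 5e-3)
  expect_equal(ap2$magnitude, pf2$e_eff * pf2$end_volume)

  # zero-flow signal: nothing to flag
  pf0 <- pf
  pf0$signal$flow[] <- 0
  expect_false(detect_auto_peep(pf0)$flag)
})

test_that("settings stay constant over a simulated run", {
  run <- simulate_ventilation(vent_settings(mode = "pcv"), hours = 2)
  expect_length(unique(run$driving_pressure), 1)
  expect_identical(run$settings$peep, 3)
  expect_identical(run$settings$fio2, 0.4)
  expect_equal(nrow(run$hourly), 3)  # H0, H1, H2
})
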