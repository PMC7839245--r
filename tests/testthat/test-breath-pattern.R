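test_that("a pure sinusoid segments into breaths of the exact period", {
  rec <- sine_recording(f = 0.4, duration = 60, fs = 200)
  br <- detect_breaths(rec)
  expect_equal(nrow(br), 24)
  expect_true(all(abs(br$period - 2.5) <= 1 / rec$sampling_rate + 1e-9))
})

test_that("detected amplitude variability matches generator ground truth", {
  p <- breathing_sim_params(seed = 42, artifact_rate = 0)
  rec <- generate_spontaneous_breathing(p, 600)
  br <- detect_breaths(rec)
  cv_det <- 100 * sd(br$amplitude) / mean(br$amplitude)
  cv_true <- 100 * sd(rec$breaths$amplitude) / mean(rec$breaths$amplitude)
  expect_lt(abs(cv_det - cv_true), 1)
  expect_equal(nrow(br), nrow(rec$breaths))
})

test_that("zero-variance breathing is detected as identical breaths", {
  p <- breathing_sim_params(cv_vt = 0, cv_rr = 0, artifact_rate = 0,
                            seed = 1)
  rec <- generate_spontaneous_breathing(p, 120)
  br <- detect_breaths(rec)
  core <- br$amplitude[3:(nrow(br) - 2)]   # edge breaths see filter transients
  expect_lt(diff(range(core)) / mean(core), 1e-3)
})

test_that("a recording fully covered by artifacts yields an empty-result error", {
  rec <- sine_recording(duration = 30)
  rec$artifact_intervals <- pvvent:::normalize_intervals(cbind(0, 30), 30)
  expect_error(detect_breaths(rec), class = "pvvent_empty_result")
})

test_that("artifact excision is identity without artifacts and bookkeeps durations", {
  rec <- sine_recording(duration = 60)
  out <- remove_artifact_segments(rec)
  expect_identical(out$samples, rec$samples)
  expect_identical(attr(out, "removed_s"), 0)

  # one 5-s annotated artifact in a 600-s record -> 595 s remain
  p <- breathing_sim_params(seed = 3, artifact_rate = 0)
  rec6 <- generate_spontaneous_breathing(p, 600)
  rec6$artifact_intervals <- pvvent:::normalize_intervals(cbind(100, 105), 600)
  out6 <- remove_artifact_segments(rec6)
  expect_equal(out6$duration, 595, tolerance = 1e-6)
  expect_length(attr(out6, "splice_points"), 1)
})

test_that("the amplitude-outlier detector removes annotated artifact samples", {
  p <- breathing_sim_params(seed = 12, artifact_rate = 1,
                            artifact_duration = 2)
  rec <- generate_spontaneous_breathing(p, 600)
  blind <- pleth_recording(rec$samples, rec$sampling_rate)  # no annotations
  det <- pvvent:::detect_artifact_intervals(blind)
  fs <- rec$sampling_rate
  n <- length(rec$samples)
  mark <- function(iv) {
    v <- rep(FALSE, n)
    for (k in seq_len(nrow(iv)))
      v[max(1, floor(iv[k, 1] * fs) + 1):min(n, ceiling(iv[k, 2] * fs))] <- TRUE
    v
  }
  truth <- mark(rec$artifact_intervals)
  found <- mark(det)
  expect_gte(sum(truth & found) / sum(truth), 0.95)
  expect_lt(sum(found & !truth) / sum(!truth), 0.05)
})

test_that("pattern construction follows the ratio arithmetic", {
  br <- data.frame(amplitude = c(5, 7, 9), period = c(2, 2, 2))
  pat <- build_pvv_pattern(br, n_breaths = 3)
  expect_equal(pat$entries$pressure_ratio, c(5, 7, 9) / 7)
  expect_equal(pat$entries$period_ratio, c(1, 1, 1))

  eq <- build_pvv_pattern(data.frame(amplitude = rep(4, 5),
                                     period = rep(3, 5)), n_breaths = 5)
  expect_true(all(eq$entries$pressure_ratio == 1))
  expect_true(all(eq$entries$period_ratio == 1))
})

test_that("patterns always have unit mean ratios and report shortfalls", {
  pat <- fixture_pattern(seed = 8, n = 150)
  expect_lt(abs(mean(pat$entries$pressure_ratio) - 1), 1e-9)
  expect_lt(abs(mean(pat$entries$period_ratio) - 1), 1e-9)
  br <- data.frame(amplitude = 1:5, period = rep(2, 5))
  expect_error(build_pvv_pattern(br, n_breaths = 382),
               regexp = "only 5", class = "pvvent_argument_error")
})

test_that("rescaling preserves CV exactly and scales means exactly", {
  pat <- fixture_pattern(seed = 8, n = 150)
  sch <- rescale_pattern(pat, target_mean_rr = 22.9, target_mean_vt = 7.1)
  cv <- function(x) sd(x) / mean(x)
  expect_identical(cv(sch$vt), cv(pat$entries$pressure_ratio))
  expect_identical(cv(sch$period), cv(pat$entries$period_ratio))
  expect_equal(mean(sch$vt), 7.1, tolerance = 1e-12)
  expect_equal(mean(60 / mean(sch$period)), 22.9, tolerance = 1e-12)

  # explicit ratios: (0.5, 1.5) at VT 8 -> breaths of 4 and 12
  pat2 <- build_pvv_pattern(data.frame(amplitude = c(1, 3),
                                       period = c(2, 2)), n_breaths = 2)
  sch2 <- rescale_pattern(pat2, 20, 8)
  expect_equal(sch2$vt, c(4, 12))
})

test_that("build/rescale round-trips reproduce the ratios", {
  pat <- fixture_pattern(seed = 8, n = 150)
  sch <- rescale_pattern(pat, 30, 6)
  pat2 <- build_pvv_pattern(sch, n_breaths = nrow(sch))
  expect_equal(pat2$entries$pressure_ratio, pat$entries$pressure_ratio,
               tolerance = 1e-9)
  expect_equal(pat2$entries$period_ratio, pat$entries$period_ratio,
               tolerance = 1e-9)
  # rescaling twice equals rescaling once to the final targets
  sch_b <- rescale_pattern(build_pvv_pattern(sch, nrow(sch)), 25, 9)
  sch_once <- rescale_pattern(pat, 25, 9)
  expect_equal(sch_b$vt, sch_once$vt, tolerance = 1e-9)
  expect_equal(sch_b$period, sch_once$period, tolerance = 1e-9)
})

test_that("looped playback has identical per-loop statistics", {
  pat <- fixture_pattern(seed = 8, n = 100)
  sch <- rescale_pattern(pat, 22.9, 7.1)
  three <- rbind(sch, sch, sch)
  s1 <- pattern_statistics(sch)
  s3 <- pattern_statistics(three)
  # population moments identical per loop; sample CV differs only through
  # the n-1 denominator, so compare mean/min/max exactly
  expect_equal(s1$mean, s3$mean, tolerance = 1e-12)
  expect_equal(s1$min, s3$min)
  expect_equal(s1$max, s3$max)
})

test_that("pattern statistics match hand-computed values", {
  st <- pattern_statistics(c(4, 6, 8, 10), rep(60 / 24, 4))
  vt <- st[st$variable == "VT", ]
  expect_equal(vt$mean, 7)
  expect_equal(vt$cv_pct, 100 * sd(c(4, 6, 8, 10)) / 7, tolerance = 1e-12)
  expect_equal(round(vt$cv_pct, 1), 36.9)
  cst <- pattern_statistics(rep(5, 4), rep(2, 4))
  expect_true(all(cst$cv_pct == 0))
  expect_true(all(cst$min == cst$max))
  expect_error(pattern_statistics(5, 2), class = "pvvent_argument_error")
})

test_that("default schedules reproduce the PVV table statistics", {
  pat <- fixture_pattern(seed = 42)
  sch <- rescale_pattern(pat, target_mean_rr = 22.9, target_mean_vt = 7.1)
  st <- pattern_statistics(sch)
  vt <- st[st$variable == "VT", ]
  expect_lt(abs(vt$cv_pct - 12.6), 3)
  expect_lt(abs(vt$min - 3.7), 1.5)
  expect_lt(abs(vt$max - 10.7), 1.5)
})
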