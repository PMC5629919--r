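test_that("baseline shifting reproduces the hemodynamic-delay bookkeeping", {
  spec <- feedback_spec(shift_at_begin_s = 5, shift_at_end_s = 1)
  iv <- effective_baseline_interval(c(50, 70), spec)
  expect_equal(iv$interval, c(55, 71))
  expect_equal(iv$duration_s, 16)
  expect_true(iv$valid)

  spec0 <- feedback_spec(shift_at_begin_s = 0, shift_at_end_s = 0)
  iv0 <- effective_baseline_interval(c(50, 70), spec0)
  expect_equal(iv0$interval, c(50, 70))

  # 8-s block shifted by 5 leaves 3 s: below the 4-s hard minimum
  spec5 <- feedback_spec(shift_at_begin_s = 5, shift_at_end_s = 0)
  iv5 <- effective_baseline_interval(c(50, 58), spec5)
  expect_equal(iv5$duration_s, 3)
  expect_false(iv5$valid)

  expect_error(effective_baseline_interval(c(70, 50), spec), "onset < offset")
})

test_that("baseline levels average the channel-averaged signal over the interval", {
  fs <- 10
  n <- 1000
  spec <- feedback_spec(channels = 1:2, shift_at_begin_s = 5, shift_at_end_s = 1)
  hbo <- matrix(0.3, n, 2)
  hb <- matrix(-0.1, n, 2)
  iv <- effective_baseline_interval(c(50, 70), spec)
  bl <- compute_baseline_level(hbo, hb, iv, fs, spec)
  expect_equal(bl$oxy_bl, 0.3)
  expect_equal(bl$deoxy_bl, -0.1)
  expect_equal(bl$n_samples, 160L) # 16 s at 10 Hz

  # linear ramp averages to its midpoint over the interval
  ramp <- matrix(seq(0, 1, length.out = n), n, 1)
  spec1 <- feedback_spec(channels = 1, shift_at_begin_s = 5, shift_at_end_s = 1)
  blr <- compute_baseline_level(ramp, ramp, iv, fs, spec1)
  mid <- mean(ramp[(floor(55 * fs) + 1):(floor(71 * fs)), 1])
  expect_equal(blr$oxy_bl, mid)

  # invalid interval produces no level
  bad <- effective_baseline_interval(
    c(50, 58), feedback_spec(shift_at_begin_s = 5, shift_at_end_s = 0)
  )
  expect_false(compute_baseline_level(hbo, hb, bad, fs, spec)$valid)
  spec_empty <- feedback_spec(channels = 1:2)
  spec_empty$channels <- integer(0)
  expect_error(compute_baseline_level(hbo, hb, iv, fs, spec_empty),
               "empty channel selection")
})

test_that("feedback values implement the oxy/deoxy/combined definitions", {
  level <- list(oxy_bl = 0.5, deoxy_bl = -0.2, valid = TRUE)
  fb <- feedback_value(0.5, -0.2, level, feedback_spec())
  expect_equal(fb$fb_oxy, 0) # at baseline: zero feedback

  # a deoxy decrease of 0.2 below baseline gives +0.2 (inversion)
  fb2 <- feedback_value(0.5, -0.4, level, feedback_spec(source = "deoxy"))
  expect_equal(fb2$fb_deoxy, 0.2)
  expect_equal(fb2$fb, 0.2)

  set.seed(51)
  for (i in 1:10) {
    o <- stats::rnorm(1)
    d <- stats::rnorm(1)
    fbr <- feedback_value(o, d, level, feedback_spec(source = "combined"))
    expect_equal(fbr$fb_combined, (fbr$fb_oxy + fbr$fb_deoxy) / 2,
                 tolerance = 1e-12)
  }
  expect_error(feedback_value(1, 1, list(valid = FALSE), feedback_spec()),
               "suppressed")
})

test_that("thermometer mapping clamps, rounds half away from zero, and is monotone", {
  expect_equal(thermometer_level(0.25, 0.5, 10), 5L) # half full
  expect_equal(thermometer_level(-3, 0.5, 10), 0L)
  expect_equal(thermometer_level(2, 0.5, 10), 10L)
  expect_equal(thermometer_level(0.333, 1, 10), 3L)
  expect_equal(thermometer_level(0.35, 1, 10), 4L) # exact half rounds up
  fbs <- seq(-0.2, 1.2, by = 0.01)
  lv <- thermometer_level(fbs, 1, 10)
  expect_true(all(diff(lv) >= 0))
  expect_error(thermometer_level(0.5, 0, 10), "max_val")
  expect_error(thermometer_level(0.5, 1, 0), "levels")
})

test_that("feedback sessions ramp with the response and suppress without a baseline", {
  fs <- 7.8125
  p <- protocol(fs, list(
    baseline = rbind(c(0, 20), c(40, 60), c(80, 100)),
    modulation = rbind(c(20, 40), c(60, 80), c(100, 120))
  ), 120)
  n <- protocol_n_samples(p)
  resp <- convolve_boxcar_hrf(condition_mask(p, "modulation", n), fs) * 0.3
  hbo <- matrix(resp, n, 2)
  hb <- -hbo / 3
  spec <- feedback_spec(source = "oxy", channels = 1:2, max_val_oxy = 0.6)
  out <- run_feedback_session(hbo, hb, p, spec)
  expect_gt(nrow(out), 0)
  # levels ramp toward half-full as the 0.3-step response rises against 0.6
  expect_equal(max(out$level), 5L)
  expect_true(all(out$level >= 0 & out$level <= 10))
  # causality of the emission schedule: nothing before the first baseline
  # completes (first modulation block at 20 s, end-shift 1 s)
  expect_gte(min(out$t_s), 20 + spec$shift_at_end_s - 1 / fs)

  zero <- run_feedback_session(matrix(0, n, 2), matrix(0, n, 2), p, spec)
  expect_equal(unique(zero$fb), 0)
  expect_equal(unique(zero$level), 0L)

  # modulation before any baseline block is suppressed
  p2 <- protocol(fs, list(
    baseline = rbind(c(20, 40)),
    modulation = rbind(c(0, 20), c(40, 60))
  ), 60)
  n2 <- protocol_n_samples(p2)
  out2 <- run_feedback_session(matrix(1, n2, 1), matrix(1, n2, 1), p2,
                               feedback_spec(channels = 1))
  expect_true(all(out2$t_s >= 40))

  expect_warning(
    none <- run_feedback_session(hbo, hb, p, spec,
                                 baseline_condition = "missing"),
    "no baseline condition"
  )
  expect_equal(nrow(none), 0L)
})

test_that("feedback never decreases when HbO rises or Hb falls", {
  level <- list(oxy_bl = 0, deoxy_bl = 0, valid = TRUE)
  oxy_seq <- seq(-1, 1, by = 0.1)
  fb_oxy <- vapply(oxy_seq, function(o) {
    feedback_value(o, 0, level, feedback_spec(source = "oxy"))$fb
  }, numeric(1))
  expect_true(all(diff(fb_oxy) >= 0))
  fb_deoxy <- vapply(oxy_seq, function(d) {
    feedback_value(0, d, level, feedback_spec(source = "deoxy"))$fb
  }, numeric(1))
  expect_true(all(diff(fb_deoxy) <= 0)) # falling Hb -> rising feedback
})

test_that("spec validation enforces the hard limits", {
  expect_error(feedback_spec(shift_at_begin_s = -1), "shifts")
  expect_error(feedback_spec(max_val_oxy = 0), "max values")
  expect_error(feedback_spec(thermometer_levels = 0), "thermometer")
  expect_error(feedback_spec(min_baseline_s = 2), "4 s")
})
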