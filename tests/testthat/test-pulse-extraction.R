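# Pulse extraction: baseline, segmentation, feature recovery.

test_that("baseline estimation is robust to pulses and noise", {
  flat <- data.frame(time_ms = seq(0, 100, by = 0.1))
  flat$current <- 1.0
  expect_equal(estimate_baseline(flat), 1.0)

  dipped <- flat
  dipped$current[300:400] <- 0.9
  expect_equal(estimate_baseline(dipped), 1.0)

  expect_error(estimate_baseline(flat[1:50, , drop = FALSE]), "100 samples")

  geom <- nps_geometry()
  pop <- simulate_population(younger_population_spec(n_cells = 3, seed = 2))
  tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = 1e-4), seed = 5)
  b <- estimate_baseline(tr)
  # the trace is mostly baseline; the median of ~n baseline samples has
  # standard error ~ 1.25 * sigma / sqrt(n)
  expect_lt(abs(b - 1.0), 3 * 1e-4 / sqrt(0.3 * nrow(tr)))
})

test_that("segmentation finds the expected sub-pulse structure", {
  geom <- nps_geometry()
  pop <- simulate_population(older_population_spec(n_cells = 4, seed = 6))
  tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = 0))
  det <- detect_subpulses(tr, geom)
  expect_equal(nrow(det$events), 4)
  expect_true(all(det$events$flag == "ok"))
  expect_true(all(det$events$n_subpulses ==
                    geom$n_pre_pores + 1L + geom$n_post_pores))
  # per event: n_pre pre, one contraction, n_post post sub-pulses
  tab <- table(det$subpulses$event_id, det$subpulses$region)
  expect_true(all(tab[, "pre"] == geom$n_pre_pores))
  expect_true(all(tab[, "contraction"] == 1))
  expect_true(all(tab[, "post"] == geom$n_post_pores))

  # empty trace gives an empty event list
  flat <- data.frame(time_ms = seq(0, 100, by = 0.1), current = 1.0)
  det0 <- detect_subpulses(flat, geom)
  expect_equal(nrow(det0$events), 0)
})

test_that("coincident transits are flagged and excluded, not dropped silently", {
  geom <- nps_geometry()
  pop <- simulate_population(younger_population_spec(n_cells = 2, seed = 8))
  tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = 0),
                       entry_times_ms = c(50, 120))  # overlapping events
  det <- detect_subpulses(tr, geom)
  expect_true(all(det$events$flag == "coincident"))
  feats <- extract_features(det, geom)
  expect_equal(nrow(feats), 0)
  expect_true(all(attr(feats, "flags")$flag == "coincident"))
})

test_that("noiseless extraction round-trips the simulator ground truth", {
  geom <- nps_geometry()
  dt <- 0.1  # ms at the 10 kHz default
  for (seed in 1:3) {
    pop <- simulate_population(older_population_spec(n_cells = 6, seed = seed))
    tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = 0))
    feats <- extract_features(detect_subpulses(tr, geom), geom)
    expect_equal(nrow(feats), nrow(pop))
    # depths to 1e-9 relative, durations to one sampling interval
    expect_lt(max(abs(feats$dI_np / pop$dI_np - 1)), 1e-9)
    expect_lt(max(abs(feats$dI_c / pop$dI_c - 1)), 1e-9)
    expect_lte(max(abs(feats$dT_cont_ms - pop$dT_cont_ms)), dt + 1e-9)
    # recovery classes reproduce exactly
    got <- recovery_bins()[mechanonps:::bin_recovery_index(feats$dT_r_ms)]
    expect_identical(got, pop$recovery_class)
  }
})

test_that("recovery timing lands in the true bin and honours the window", {
  geom <- nps_geometry()
  base <- simulate_population(younger_population_spec(n_cells = 1, seed = 1))

  cell <- transform(base, recovery_time_ms = 55, recovery_class = "50-60ms")
  tr <- simulate_trace(cell, geom, acquisition_spec(noise_sd = 0))
  feats <- extract_features(detect_subpulses(tr, geom), geom)
  expect_gte(feats$dT_r_ms, 50)
  expect_lt(feats$dT_r_ms, 60)

  cell0 <- transform(base, recovery_time_ms = 0, recovery_class = "0ms")
  tr <- simulate_trace(cell0, geom, acquisition_spec(noise_sd = 0))
  feats <- extract_features(detect_subpulses(tr, geom), geom)
  expect_equal(feats$dT_r_ms, 0)

  cinf <- transform(base, recovery_time_ms = Inf, recovery_class = "Inf")
  tr <- simulate_trace(cinf, geom, acquisition_spec(noise_sd = 0))
  feats <- extract_features(detect_subpulses(tr, geom), geom)
  expect_identical(feats$dT_r_ms, Inf)
})

test_that("baseline noise up to 1e-3 changes no recovery-bin assignment", {
  geom <- nps_geometry()
  for (seed in 1:3) {
    pop <- rbind(
      simulate_population(younger_population_spec(n_cells = 5, seed = seed)),
      simulate_population(older_population_spec(n_cells = 5, seed = seed + 50))
    )
    ref <- NULL
    for (noise in c(0, 1e-4, 1e-3)) {
      tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = noise),
                           seed = seed)
      feats <- extract_features(detect_subpulses(tr, geom), geom)
      expect_equal(nrow(feats), nrow(pop))
      bins <- mechanonps:::bin_recovery_index(feats$dT_r_ms)
      if (is.null(ref)) ref <- bins else expect_identical(bins, ref)
    }
  }
})

test_that("trace CSV io round-trips and validates", {
  geom <- nps_geometry()
  pop <- simulate_population(younger_population_spec(n_cells = 1, seed = 4))
  tr <- simulate_trace(pop, geom, acquisition_spec(noise_sd = 1e-4))
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$current, tr$current, tolerance = 1e-12)
  expect_equal(attr(tr2, "sampling_rate_hz"), 10000, tolerance = 1e-6)
  unlink(f)
})
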