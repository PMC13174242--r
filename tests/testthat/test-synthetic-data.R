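# Synthetic-data generators: populations, traces, CyTOF matrices.

test_that("population generator validates its spec", {
  expect_error(population_spec(n_cells = 0), "n_cells")
  expect_error(population_spec(recovery_distribution = c(0.5, 0.5, 0, 0, 0.1)),
               "summing to 1")
  expect_error(population_spec(sd_diameter_um = 0), "positive")
})

test_that("populations are deterministic and match their spec moments", {
  spec <- population_spec(mean_diameter_um = 17.5, sd_diameter_um = 1.0,
                          n_cells = 1000, seed = 7)
  pop1 <- simulate_population(spec)
  pop2 <- simulate_population(spec)
  expect_identical(pop1, pop2)
  # CLT check on the mean diameter (truncation at wc is ~7 sd away)
  expect_lt(abs(mean(pop1$D_cell_um) - 17.5), 3 * 1.0 / sqrt(1000))
  # recovery mixture within 4 SE at n = 1000
  p_hat <- as.numeric(table(factor(pop1$recovery_class,
                                   levels = recovery_bins())) / 1000)
  p_true <- spec$recovery_distribution
  se <- sqrt(p_true * (1 - p_true) / 1000)
  expect_true(all(abs(p_hat - p_true) <= 4 * pmax(se, 1e-6)))
  # physical invariants of the ground truth
  expect_true(all(pop1$dI_c > pop1$dI_np))
  expect_true(all(pop1$dI_np > 0 & pop1$dI_np < 1))
  expect_true(all(pop1$dT_cont_ms > 0))
  expect_true(all(pop1$strain > 0 & pop1$strain < 1))
})

test_that("trace simulator encodes recovery classes as specified", {
  geom <- nps_geometry()
  base <- simulate_population(younger_population_spec(n_cells = 1, seed = 1))

  # immediate recovery: first post-contraction depth equals dI_np exactly
  cell0 <- transform(base, recovery_time_ms = 0, recovery_class = "0ms")
  tr <- simulate_trace(cell0, geom, acquisition_spec(noise_sd = 0))
  det <- detect_subpulses(tr, geom)
  post <- det$subpulses[det$subpulses$region == "post", ]
  expect_equal(post$depth[1], cell0$dI_np, tolerance = 1e-9)

  # infinite recovery: every post sub-pulse within the window stays deeper
  cinf <- transform(base, recovery_time_ms = Inf, recovery_class = "Inf")
  tr <- simulate_trace(cinf, geom, acquisition_spec(noise_sd = 0))
  det <- detect_subpulses(tr, geom)
  sp <- det$subpulses
  exit_ms <- sp$t_end_ms[sp$region == "contraction"]
  post <- sp[sp$region == "post", ]
  in_window <- (post$t_start_ms - exit_ms) <= 120
  expect_true(all(post$depth[in_window] > cinf$dI_np))

  # transit guard
  big <- transform(base, D_cell_um = 25)
  expect_error(simulate_trace(big, geom), "pore width")
})

test_that("CyTOF generator is null without effects and shifts as configured", {
  null <- simulate_cytof(groups = c("younger", "older"), effects = list(),
                         n_per_group = 400, seed = 3)
  expect_equal(length(setdiff(names(null),
                              c("cell_id", "lineage", "group", "condition"))),
               27)
  lfc_null <- vapply(cytof_panel(), function(m) {
    mean(log(null[null$group == "older", m])) -
      mean(log(null[null$group == "younger", m]))
  }, numeric(1))
  se <- 0.5 * sqrt(2 / 400)
  expect_true(all(abs(lfc_null) < 4 * se))

  shifted <- simulate_cytof(groups = c("younger", "older"),
                            effects = list(older = c(KRT19 = -1.0)),
                            n_per_group = 500, seed = 4)
  lfc <- mean(log(shifted[shifted$group == "older", "KRT19"])) -
    mean(log(shifted[shifted$group == "younger", "KRT19"]))
  expect_lt(abs(lfc - (-1.0)), 3 * 0.5 * sqrt(2 / 500))

  expect_error(simulate_cytof(effects = list(older = c(NOPE = 1))),
               "absent from the panel")
  expect_identical(simulate_cytof(n_per_group = 10, seed = 9),
                   simulate_cytof(n_per_group = 10, seed = 9))
})
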