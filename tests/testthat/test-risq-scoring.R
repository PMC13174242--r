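# Mechano-RISQ scoring and its inferential wrapper.

test_that("baseline rate and RISQ follow their definitions", {
  preds <- rep(c("older", "younger"), c(10, 90))
  labs <- rep("younger", 100)
  expect_equal(baseline_error_rate(preds, labs), 0.10)
  expect_error(baseline_error_rate(rep("younger", 50), rep("younger", 50)),
               "baseline rate is 0")
  expect_identical(baseline_error_rate(preds, labs),
                   baseline_error_rate(preds, labs))

  expect_equal(mechano_risq(preds, b = 0.10), 1.0)
  expect_equal(mechano_risq(rep(c("older", "younger"), c(30, 70)), 0.10), 3.0)
  expect_equal(mechano_risq(rep("younger", 20), 0.10), 0)
  expect_error(mechano_risq(character(0), 0.1), "empty")
  # linearity in the older-classified fraction
  expect_equal(mechano_risq(rep(c("older", "younger"), c(20, 80)), 0.10),
               2 * mechano_risq(rep(c("older", "younger"), c(10, 90)), 0.10))
})

test_that("Crawford-Howell matches hand computation and is calibrated", {
  ch <- crawford_howell(6, 1:5)
  expect_equal(ch$t, 3 / (sd(1:5) * sqrt(6 / 5)), tolerance = 1e-12)
  expect_equal(ch$t, 1.732, tolerance = 1e-3)
  expect_equal(ch$df, 4)
  expect_equal(ch$p, 0.158, tolerance = 1e-2)
  expect_equal(crawford_howell(3, 1:5)$t, 0)
  expect_equal(crawford_howell(3, 1:5)$p, 1)
  expect_error(crawford_howell(1, c(2, 2, 2)), "constant")
  expect_error(crawford_howell(1, 2), "n >= 2")

  # null calibration: p uniform when the case is drawn from the normative
  # distribution (KS test over simulated cases)
  set.seed(71)
  p <- replicate(10000, {
    crawford_howell(rnorm(1), rnorm(10))$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("power simulation is calibrated and monotone", {
  expect_warning(ch_power_simulation(10, iterations = 50), "unstable")
  p0 <- ch_power_simulation(18, cohens_d = 0, iterations = 4000, seed = 2)
  expect_lt(abs(p0 - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  p1 <- ch_power_simulation(18, cohens_d = 1, iterations = 2000, seed = 2)
  p3 <- ch_power_simulation(18, cohens_d = 3, iterations = 2000, seed = 2)
  expect_gte(p3, p1)
  n5 <- ch_power_simulation(5, cohens_d = 3, iterations = 2000, seed = 2)
  expect_gte(p3, n5)
  # the fixed-case convention at d = 3, n = 18 clears 0.97
  expect_gt(ch_power_simulation(18, cohens_d = 3, iterations = 2000, seed = 2,
                                case_noise = FALSE), 0.97)
})

test_that("type-I error stays at alpha across normative sizes", {
  for (n_norm in c(5, 10, 18)) {
    rejection_rate <- ch_power_simulation(n_norm, cohens_d = 0,
                                          iterations = 10000,
                                          seed = 100 + n_norm)
    # within the binomial 99% CI of alpha
    expect_lt(abs(rejection_rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 10000))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(4)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group Wilcoxon and Fisher match enumeration oracles", {
  expect_gte(group_compare(c(1, 2, 3), c(1, 2, 3)), 0.99)
  # fully separated n = 5/5: exact two-sided p = 2/choose(10,5)
  expect_equal(group_compare(1:5, 6:10), 2 / choose(10, 5), tolerance = 1e-12)
  # rank-based: invariant under monotone transforms
  expect_equal(group_compare(exp(1:5), exp(6:10)), group_compare(1:5, 6:10))
  expect_error(group_compare(numeric(0), 1:3), "non-empty")

  expect_equal(perturbation_fisher(matrix(c(10, 10, 10, 10), 2)), 1)
  # [[10,0],[0,10]]: hypergeometric enumeration gives 2/choose(20,10)
  expect_equal(perturbation_fisher(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  m <- matrix(c(12, 3, 5, 9), 2)
  expect_equal(perturbation_fisher(m), perturbation_fisher(m[2:1, ]))
  expect_error(perturbation_fisher(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("the per-sample RISQ table combines scoring and inference", {
  set.seed(8)
  preds <- data.frame(
    sample_id = rep(c("HR-1", "AR-9"), c(100, 100)),
    class = c(sample(c("older", "younger"), 100, TRUE, c(0.45, 0.55)),
              sample(c("older", "younger"), 100, TRUE, c(0.55, 0.45)))
  )
  normative <- c(0.8, 0.9, 1.0, 1.1, 1.2, 1.05, 0.95)
  tab <- risq_table(preds, b = 0.12, normative_risq = normative)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_adj >= tab$p))
  expect_equal(tab$risq, tab$p_older / 0.12)
  expect_equal(tab$df, rep(6, 2))
})
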