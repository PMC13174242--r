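# CyTOF layer: differential expression, frozen signatures, transfer.

test_that("differential expression applies the dual significance threshold", {
  null <- simulate_cytof(groups = c("younger", "older"), effects = list(),
                         n_per_group = 200, seed = 5)
  dep0 <- dep_analysis(null, "younger", "older")
  expect_equal(nrow(dep0), 27)
  expect_true(all(dep0$p_adj >= dep0$p))
  expect_true(all(dep0$p_adj <= pmin(1, dep0$p * 27) + 1e-12))
  expect_equal(sum(dep0$significant), 0)

  planted <- simulate_cytof(groups = c("younger", "older"),
                            effects = list(older = c(pRb = 1.0, KRT19 = -1.0)),
                            n_per_group = 500, seed = 6, noise_sd = 0.3)
  dep1 <- dep_analysis(planted, "younger", "older")
  expect_true(all(c("pRb", "KRT19") %in% dep1$marker[dep1$significant]))
  expect_gt(dep1$lfc[dep1$marker == "pRb"], 0.5)
  expect_lt(dep1$lfc[dep1$marker == "KRT19"], -0.5)

  # a shift below the |LFC| threshold is never significant, whatever the p
  small <- simulate_cytof(groups = c("younger", "older"),
                          effects = list(older = c(pS6 = 0.3)),
                          n_per_group = 800, seed = 7, noise_sd = 0.3)
  dep2 <- dep_analysis(small, "younger", "older")
  expect_false(dep2$significant[dep2$marker == "pS6"])

  # constant marker: recorded with p = 1, not dropped
  cm <- null
  cm$KRT14 <- 1
  dep3 <- dep_analysis(cm, "younger", "older")
  expect_equal(dep3$p[dep3$marker == "KRT14"], 1)
  expect_error(dep_analysis(null[1:3, ], "younger", "older"), ">= 2 cells")
})

test_that("signatures separate groups, are seed-stable and fail on permuted labels", {
  m <- simulate_cytof(groups = c("younger", "older"),
                      effects = list(older = age_effects()),
                      n_per_group = 300, seed = 8)
  sig <- train_signature(m, c("younger", "older"), seed = 11)
  expect_gt(sig$test_auc, 0.9)
  sig2 <- train_signature(m, c("younger", "older"), seed = 11)
  expect_identical(sig$test, sig2$test)

  perm <- m
  perm$group <- mechanonps:::with_seed(13, sample(perm$group))
  sigp <- train_signature(perm, c("younger", "older"), seed = 11)
  expect_lt(abs(sigp$test_auc - 0.5), 0.12)

  only_y <- m[m$group == "younger", ]
  expect_error(train_signature(only_y, c("younger", "older")), "class absent")
})

test_that("frozen transfer evaluates perturbations without touching the model", {
  ctrl <- simulate_cytof(groups = c("younger", "older"),
                         effects = list(older = age_effects() * 0.5),
                         n_per_group = 300, seed = 15)
  sig <- train_signature(ctrl, c("younger", "older"), seed = 17)
  checksum_before <- sig$checksum

  # held-out control condition: AUC close to train-time test AUC
  ctrl2 <- simulate_cytof(groups = c("younger", "older"),
                          effects = list(older = age_effects() * 0.5),
                          n_per_group = 300, seed = 16, condition = "control2")
  tv_ctrl <- transfer_evaluate(sig, ctrl2)
  expect_lt(abs(tv_ctrl$auc - sig$test_auc), 0.05)

  # perturbation amplifying the age signature raises the transfer AUC
  pert <- simulate_cytof(groups = c("younger", "older"),
                         effects = list(older = age_effects() * 1.5),
                         n_per_group = 300, seed = 16, condition = "KRT14OE")
  tv_pert <- transfer_evaluate(sig, pert)
  expect_gt(tv_pert$auc, tv_ctrl$auc)
  expect_identical(sig$checksum, checksum_before)
  expect_identical(sum(as.integer(sig$model_raw)), checksum_before)

  expect_error(transfer_evaluate(sig, pert[0, ]), "empty")
  expect_error(transfer_evaluate(sig, pert[, 1:10]), "lacks markers")
})

test_that("DeLong comparison separates unequal classifiers and is symmetric", {
  set.seed(19)
  lab <- factor(rep(c("younger", "older"), each = 500),
                levels = c("younger", "older"))
  good <- c(rnorm(500, 0), rnorm(500, 4))
  null <- rnorm(1000)
  r_good <- pROC::roc(lab, good, levels = c("younger", "older"),
                      direction = "<", quiet = TRUE)
  r_null <- pROC::roc(lab, null, levels = c("younger", "older"),
                      direction = "<", quiet = TRUE)
  cmp <- delong_compare(r_good, r_null)
  expect_lt(cmp$p, 0.001)
  expect_true(cmp$paired)
  expect_equal(delong_compare(r_null, r_good)$p, cmp$p)
  # identical scores: no difference
  expect_equal(delong_compare(r_good, r_good)$p, 1)
})
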