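# MechanoAge ensemble: down-sampling, training, prediction, ROC,
# importance, learning curves.

test_that("fold down-sampling balances classes deterministically", {
  y <- factor(rep(c("older", "younger"), c(80, 20)))
  idx <- downsample_fold(y, seed = 3)
  expect_equal(as.numeric(table(y[idx])), c(20, 20))
  expect_identical(idx, downsample_fold(y, seed = 3))
  expect_false(identical(idx, downsample_fold(y, seed = 4)))

  balanced <- factor(rep(c("older", "younger"), 25))
  expect_identical(downsample_fold(balanced, 1), seq_along(balanced))
  expect_error(downsample_fold(factor(rep("older", 10)), 1), "degenerate")
})

test_that("training is deterministic and separates separable populations", {
  ft <- separable_feature_table(150, seed = 17)
  idx <- mechanonps:::with_seed(2, sample(nrow(ft), 220))
  train <- ft[idx, ]
  test <- ft[-idx, ]

  b1 <- train_mechanoage(train, light_config(seed = 5))
  b2 <- train_mechanoage(train, light_config(seed = 5))
  p1 <- predict(b1, test)
  expect_identical(p1, predict(b2, test))
  expect_true(all(p1$prob_older >= 0 & p1$prob_older <= 1))
  expect_identical(as.character(p1$class),
                   ifelse(p1$prob_older >= 0.5, "older", "younger"))
  # duplicated row predicts identically
  expect_identical(predict(b1, test[c(1, 1), ])$prob_older[1],
                   predict(b1, test[c(1, 1), ])$prob_older[2])

  ev <- evaluate_roc(p1$prob_older, test$label)
  expect_gt(ev$auc, 0.9)

  expect_error(train_mechanoage(train[, -1], light_config()), "missing feature")
  expect_error(predict(b1, test[, -2]), "lacks feature")
})

test_that("stacked ensemble is not dominated by its base learners", {
  ft <- separable_feature_table(120, seed = 23)
  idx <- mechanonps:::with_seed(3, sample(nrow(ft), 180))
  b <- train_mechanoage(ft[idx, ], light_config(seed = 9))
  test <- ft[-idx, ]
  x <- apply_yeo_johnson(test[, b$cols], b$yj)
  stack_auc <- evaluate_roc(predict(b, test)$prob_older, test$label)$auc
  base_aucs <- vapply(b$base, function(l) {
    evaluate_roc(mechanonps:::predict_prob_older(l, x), test$label)$auc
  }, numeric(1))
  expect_gte(stack_auc, max(base_aucs) - 0.02)
})

test_that("model bundles serialise without changing predictions", {
  ft <- separable_feature_table(60, seed = 29)
  b <- train_mechanoage(ft, light_config(seed = 2))
  f <- tempfile(fileext = ".rds")
  save_mechanoage(b, f)
  b2 <- load_mechanoage(f)
  expect_identical(predict(b2, ft), predict(b, ft))
  unlink(f)
})

test_that("ROC evaluation matches known cases and DeLong CI brackets the AUC", {
  lab <- factor(rep(c("younger", "older"), each = 50),
                levels = c("younger", "older"))
  perfect <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  # a degenerate (AUC = 1) curve makes the DeLong interval collapse; pROC
  # warns about it, which is the behaviour we want surfaced
  ev <- suppressWarnings(evaluate_roc(perfect, lab))
  expect_equal(ev$auc, 1.0)
  # symmetry: AUC(scores) + AUC(-scores) = 1
  set.seed(99)
  s <- runif(100)
  expect_equal(evaluate_roc(s, lab)$auc + evaluate_roc(-s, lab)$auc, 1)
  # null scores at n = 2000: AUC close to 0.5
  set.seed(7)
  lab2 <- factor(rep(c("younger", "older"), each = 1000),
                 levels = c("younger", "older"))
  ev2 <- evaluate_roc(runif(2000), lab2)
  expect_gt(ev2$auc, 0.47); expect_lt(ev2$auc, 0.53)
  expect_lte(ev2$ci_lower, ev2$auc); expect_gte(ev2$ci_upper, ev2$auc)
  expect_error(evaluate_roc(runif(5), factor(rep("older", 5))), "both classes")
})

test_that("consensus importance ranks the planted signal above pure noise", {
  ft <- separable_feature_table(150, seed = 31)
  set.seed(12)
  ft$D_cell_um <- rnorm(nrow(ft))  # overwrite with pure noise
  b <- train_mechanoage(ft, light_config(seed = 4))
  vi <- variable_importance(b)
  expect_true(all(vapply(c("bagged", "rf", "et"),
                         function(l) max(vi[[l]]) == 100, logical(1))))
  # wCDI carries the planted group shift; the noise column must rank below
  expect_lt(vi$consensus[vi$feature == "D_cell_um"],
            vi$consensus[vi$feature == "wCDI"])
  grp <- attr(vi, "group_importance")
  expect_true("recovery_time (cumulative)" %in% grp$feature_group)
})

test_that("cell-level learning curve improves and stabilises with size", {
  ft <- separable_feature_table(220, seed = 37)
  lc <- learning_curve_cells(ft, sizes = c(30, 250), reps = 3,
                             config = light_config(), seed = 41)
  expect_equal(nrow(lc$summary), 2)
  # more cells: better mean AUC, smaller spread
  expect_gt(lc$summary$mean_auc[2], lc$summary$mean_auc[1])
  expect_lt(lc$summary$se_auc[2], lc$summary$se_auc[1])
  expect_error(learning_curve_cells(ft, sizes = 10000, config = light_config()),
               "exceeds")
  # single rep under a fixed seed reproduces
  l1 <- learning_curve_cells(ft, sizes = 60, reps = 1,
                             config = light_config(), seed = 5)
  l2 <- learning_curve_cells(ft, sizes = 60, reps = 1,
                             config = light_config(), seed = 5)
  expect_identical(l1$curve, l2$curve)
})

test_that("donor-level learning curve runs leave-one-sample-out prefixes", {
  coh <- rbind(
    cbind(simulate_population(separable_younger_spec(25, 43)),
          donor_id = rep(c("Y1", "Y2", "Y3"), length.out = 25), age = 30),
    cbind(simulate_population(separable_older_spec(25, 44)),
          donor_id = rep(c("O1", "O2", "O3"), length.out = 25), age = 60)
  )
  ft <- build_feature_table(coh)
  ls <- learning_curve_samples(ft, orders = 2, config = light_config(),
                               seed = 3)
  expect_true(all(c("order", "n_donors", "auc") %in% names(ls)))
  expect_equal(max(ls$n_donors), 6)
  # at the full prefix every donor is evaluable and the AUC is defined
  expect_true(all(!is.na(ls$auc[ls$n_donors == 6])))
  # identical seeds reproduce
  ls2 <- learning_curve_samples(ft, orders = 2, config = light_config(),
                                seed = 3)
  expect_identical(ls, ls2)
})
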