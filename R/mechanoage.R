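# MechanoAge: stacked tree-ensemble classification of chronological age
# class (younger < 35 y vs older > 50 y) from single-cell mechanophenotype
# features.
#
# Three base learners -- bagged decision trees (50 bootstrap resamples),
# a tuned random forest and extremely randomised trees -- are trained under
# repeated stratified k-fold cross-validation with fold-internal
# down-sampling of the majority class, optimising ROC AUC. Their
# out-of-fold class probabilities feed a gradient-boosted meta-learner
# (binary logistic objective) tuned by its own cross-validation. All
# randomness flows from a single config seed through named substreams.

#' MechanoAge training configuration
#'
#' Defaults follow the reference training protocol: 50 bootstrap resamples
#' for the bagged trees, random-forest tuning over up to 30 mtry values,
#' default (untuned) extremely randomised trees, repeated 10-fold / 5-repeat
#' cross-validation optimising ROC AUC with fold-internal down-sampling, and
#' a gradient-boosted meta-learner tuned over 10 boosting lengths under
#' 5-fold cross-validation. Smaller `folds`/`repeats`/`num_trees` give a
#' cheaper but otherwise identical procedure.
#'
#' @param folds,repeats repeated k-fold cross-validation design for the
#'   base learners.
#' @param bagged_resamples bootstrap resamples (trees) of the bagged learner.
#' @param rf_tune_length number of mtry values tried for the random forest
#'   (capped at the number of features).
#' @param num_trees trees per random-forest / extra-trees fit.
#' @param meta_folds,meta_tune_length meta-learner cross-validation design
#'   (boosting-round grid of length `meta_tune_length`).
#' @param class_threshold probability threshold for calling a cell "older".
#' @param downsample down-sample the majority class within each training
#'   fold (validation folds are never touched).
#' @param seed master seed; every stochastic step derives a named substream
#'   from it.
#' @return list of class `mechanoage_config`.
#' @export
mechanoage_config <- function(folds = 10L, repeats = 5L,
                              bagged_resamples = 50L,
                              rf_tune_length = 30L,
                              num_trees = 500L,
                              meta_folds = 5L,
                              meta_tune_length = 10L,
                              class_threshold = 0.5,
                              downsample = TRUE,
                              seed = 1L) {
  if (folds < 2L || meta_folds < 2L) stopf("cross-validation needs >= 2 folds")
  if (class_threshold <= 0 || class_threshold >= 1) {
    stopf("`class_threshold` must lie in (0, 1)")
  }
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 bagged_resamples = as.integer(bagged_resamples),
                 rf_tune_length = as.integer(rf_tune_length),
                 num_trees = as.integer(num_trees),
                 meta_folds = as.integer(meta_folds),
                 meta_tune_length = as.integer(meta_tune_length),
                 class_threshold = class_threshold,
                 downsample = isTRUE(downsample),
                 seed = as.integer(seed)),
            class = "mechanoage_config")
}

#' Down-sample the majority class within a training fold
#'
#' Randomly reduces the majority class to the minority-class size;
#' validation and test rows are never down-sampled. Deterministic under the
#' given seed; balanced input is returned unchanged.
#'
#' @param labels factor of fold-training labels (two classes present).
#' @param seed integer seed.
#' @return integer indices (into `labels`) of the retained rows, in
#'   increasing order.
#' @export
downsample_fold <- function(labels, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  tab <- tab[tab > 0]
  if (length(tab) < 2L) {
    stopf("degenerate fold: both classes must be present before down-sampling")
  }
  n_min <- min(tab)
  keep <- with_seed(seed, {
    unlist(lapply(names(tab), function(lv) {
      idx <- which(labels == lv)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
  })
  sort(keep)
}

# xgboost settings shared by all gradient-boosted fits.
xgb_params <- function() {
  list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
       nthread = 1, verbosity = 0)
}

fit_xgb <- function(x, y01, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
  xgboost::xgb.train(params = xgb_params(), data = dtrain,
                     nrounds = nrounds)
}

predict_xgb <- function(model, x) {
  as.numeric(stats::predict(model, as.matrix(x)))
}

# Fit one base learner; all expose predict_prob_older().
fit_base_learner <- function(kind, x, y, config, mtry = NULL, seed = 1L) {
  p <- ncol(x)
  if (kind == "bagged") {
    model <- with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = config$bagged_resamples, mtry = p))
  } else if (kind == "rf") {
    model <- ranger::ranger(x = x, y = y, probability = TRUE,
                            num.trees = config$num_trees,
                            mtry = mtry, seed = seed, num.threads = 1,
                            importance = "impurity")
  } else if (kind == "et") {
    model <- ranger::ranger(x = x, y = y, probability = TRUE,
                            num.trees = config$num_trees,
                            mtry = max(1L, floor(sqrt(p))),
                            splitrule = "extratrees", num.random.splits = 1,
                            seed = seed, num.threads = 1,
                            importance = "impurity")
  } else {
    stopf("unknown learner `%s`", kind)
  }
  structure(list(kind = kind, model = model), class = "mnps_base_learner")
}

predict_prob_older <- function(learner, x) {
  if (learner$kind == "bagged") {
    unname(stats::predict(learner$model, x, type = "prob")[, "older"])
  } else {
    unname(stats::predict(learner$model, data = x,
                          num.threads = 1)$predictions[, "older"])
  }
}

base_importance <- function(learner) {
  if (learner$kind == "bagged") {
    randomForest::importance(learner$model)[, "MeanDecreaseGini"]
  } else {
    ranger::importance(learner$model)
  }
}

#' Train the MechanoAge stacked ensemble
#'
#' Implements the full training protocol on a ten-feature design matrix
#' from [build_feature_table()]:
#' 1. fit Yeo-Johnson transforms on the continuous training columns;
#' 2. create repeated stratified k-fold assignments;
#' 3. in each fold, down-sample the majority class of the fold-training
#'    rows and fit the three base learners, the random forest over an mtry
#'    grid of up to `rf_tune_length` values (winner selected by mean
#'    out-of-fold AUC), collecting out-of-fold "older" probabilities;
#' 4. train the gradient-boosted meta-learner on the per-row mean
#'    out-of-fold base probabilities, choosing the boosting length by
#'    `meta_folds`-fold cross-validated AUC (down-sampling maintained);
#' 5. refit the three base learners and the meta-learner on the full
#'    (down-sampled) training data with the selected hyperparameters.
#'
#' Predictions from a fitted bundle are deterministic, and identical seeds
#' and data give identical bundles.
#'
#' @param features data frame from [build_feature_table()] with the 10
#'   feature columns and a complete `label` factor.
#' @param config a [mechanoage_config()].
#' @param continuous names of the continuous columns (Yeo-Johnson is
#'   fitted on these only).
#' @return object of class `mechanoage_bundle`: fitted preprocessing state,
#'   the three base learners, the stacked meta-learner, fold assignments
#'   and tuning summaries.
#' @seealso [predict.mechanoage_bundle()], [evaluate_roc()],
#'   [variable_importance()].
#' @export
train_mechanoage <- function(features, config = mechanoage_config(),
                             continuous = c("D_cell_um", "wCDI", "dT_cont_ms",
                                            "L_deform_um", "delta_deform")) {
  stopifnot(inherits(config, "mechanoage_config"))
  cols <- feature_columns(continuous)
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L) {
    stopf("missing feature columns: %s", paste(missing, collapse = ", "))
  }
  y <- features$label
  if (is.null(y) || any(is.na(y))) stopf("every training row needs a label")
  y <- factor(y, levels = c("younger", "older"))
  if (nlevels(droplevels(y)) < 2L) stopf("both classes must be present")
  if (nrow(features) < config$folds) stopf("fewer rows than folds")
  seed <- config$seed

  x_raw <- features[, cols, drop = FALSE]
  yj <- fit_yeo_johnson(x_raw[, continuous, drop = FALSE])
  x <- apply_yeo_johnson(x_raw, yj)

  folds <- with_seed(derive_seed(seed, "folds"),
                     caret::createMultiFolds(y, k = config$folds,
                                             times = config$repeats))
  p <- length(cols)
  mtry_grid <- unique(round(seq(1, p,
                                length.out = min(config$rf_tune_length, p))))
  n <- nrow(x)

  learners <- c("bagged", "et")
  oof_sum <- matrix(0, n, 3, dimnames = list(NULL, c("bagged", "rf", "et")))
  oof_cnt <- matrix(0, n, 3, dimnames = list(NULL, c("bagged", "rf", "et")))
  rf_sum <- matrix(0, n, length(mtry_grid))
  rf_cnt <- matrix(0, n, length(mtry_grid))
  rf_fold_auc <- matrix(NA_real_, length(folds), length(mtry_grid))

  for (f in seq_along(folds)) {
    tr <- folds[[f]]
    ho <- setdiff(seq_len(n), tr)
    if (length(ho) == 0L) next
    ds <- if (config$downsample) {
      tr[downsample_fold(y[tr], derive_seed(seed, paste0("ds-", f)))]
    } else {
      tr
    }
    xf <- x[ds, , drop = FALSE]
    yf <- factor(y[ds], levels = c("younger", "older"))
    xh <- x[ho, , drop = FALSE]

    for (kind in learners) {
      fitted <- fit_base_learner(kind, xf, yf, config,
                                 seed = derive_seed(seed, paste0(kind, "-", f)))
      pr <- predict_prob_older(fitted, xh)
      oof_sum[ho, kind] <- oof_sum[ho, kind] + pr
      oof_cnt[ho, kind] <- oof_cnt[ho, kind] + 1
    }
    for (m in seq_along(mtry_grid)) {
      rf <- fit_base_learner("rf", xf, yf, config, mtry = mtry_grid[m],
                             seed = derive_seed(seed, paste0("rf-", f, "-", m)))
      pr <- predict_prob_older(rf, xh)
      rf_sum[ho, m] <- rf_sum[ho, m] + pr
      rf_cnt[ho, m] <- rf_cnt[ho, m] + 1
      rf_fold_auc[f, m] <- auc_rank(pr, y[ho] == "older")
    }
  }

  mtry_auc <- colMeans(rf_fold_auc, na.rm = TRUE)
  best_m <- which.max(mtry_auc)
  oof_sum[, "rf"] <- rf_sum[, best_m]
  oof_cnt[, "rf"] <- rf_cnt[, best_m]
  if (any(oof_cnt == 0)) {
    stopf("some rows were never held out; increase repeats or folds")
  }
  meta_x <- oof_sum / oof_cnt

  # --- gradient-boosted meta-learner on out-of-fold probabilities ---------
  nrounds_grid <- round(seq(20, 20 * config$meta_tune_length,
                            length.out = config$meta_tune_length))
  mfolds <- with_seed(derive_seed(seed, "meta-folds"),
                      caret::createFolds(y, k = config$meta_folds,
                                         returnTrain = TRUE))
  meta_auc <- matrix(NA_real_, length(mfolds), length(nrounds_grid))
  for (f in seq_along(mfolds)) {
    tr <- mfolds[[f]]
    ho <- setdiff(seq_len(n), tr)
    ds <- if (config$downsample) {
      tr[downsample_fold(y[tr], derive_seed(seed, paste0("meta-ds-", f)))]
    } else {
      tr
    }
    for (g in seq_along(nrounds_grid)) {
      fit <- fit_xgb(meta_x[ds, , drop = FALSE],
                     as.integer(y[ds] == "older"), nrounds_grid[g])
      meta_auc[f, g] <- auc_rank(predict_xgb(fit, meta_x[ho, , drop = FALSE]),
                                 y[ho] == "older")
    }
  }
  best_nrounds <- nrounds_grid[which.max(colMeans(meta_auc, na.rm = TRUE))]

  # --- final refits on the full (down-sampled) training data --------------
  ds_final <- if (config$downsample) {
    downsample_fold(y, derive_seed(seed, "final-ds"))
  } else {
    seq_len(n)
  }
  xd <- x[ds_final, , drop = FALSE]
  yd <- factor(y[ds_final], levels = c("younger", "older"))
  base_final <- list(
    bagged = fit_base_learner("bagged", xd, yd, config,
                              seed = derive_seed(seed, "final-bagged")),
    rf = fit_base_learner("rf", xd, yd, config, mtry = mtry_grid[best_m],
                          seed = derive_seed(seed, "final-rf")),
    et = fit_base_learner("et", xd, yd, config,
                          seed = derive_seed(seed, "final-et"))
  )
  meta_final <- fit_xgb(meta_x[ds_final, , drop = FALSE],
                        as.integer(yd == "older"), best_nrounds)

  structure(list(
    yj = yj,
    base = base_final,
    meta = meta_final,
    config = config,
    cols = cols,
    continuous = continuous,
    folds = folds,
    mtry_grid = mtry_grid,
    best_mtry = mtry_grid[best_m],
    mtry_auc = mtry_auc,
    best_nrounds = best_nrounds,
    oof_probabilities = meta_x,
    levels = c("younger", "older")
  ), class = "mechanoage_bundle")
}

#' @export
print.mechanoage_bundle <- function(x, ...) {
  cat("MechanoAge stacked ensemble\n")
  cat(sprintf("  features: %d (%s + 5 recovery indicators)\n",
              length(x$cols), paste(x$continuous, collapse = ", ")))
  cat(sprintf("  base learners: bagged trees (%d resamples), random forest (mtry = %d), extra trees\n",
              x$config$bagged_resamples, x$best_mtry))
  cat(sprintf("  meta-learner: gradient boosting, %d rounds\n", x$best_nrounds))
  cat(sprintf("  CV design: %d folds x %d repeats, seed %d\n",
              x$config$folds, x$config$repeats, x$config$seed))
  invisible(x)
}

#' Predict age class probabilities for new cells
#'
#' Applies the frozen preprocessing state (no refitting on new data), the
#' three base learners and the stacked meta-learner.
#'
#' @param object a `mechanoage_bundle`.
#' @param newdata data frame containing the bundle's feature columns.
#' @param ... unused.
#' @return data frame with `prob_older` and `class` (a `cell_id` column is
#'   carried through when present).
#' @export
predict.mechanoage_bundle <- function(object, newdata, ...) {
  missing <- setdiff(object$cols, names(newdata))
  if (length(missing) > 0L) {
    stopf("newdata lacks feature columns: %s", paste(missing, collapse = ", "))
  }
  x <- apply_yeo_johnson(newdata[, object$cols, drop = FALSE], object$yj)
  base_probs <- vapply(object$base, predict_prob_older, numeric(nrow(x)),
                       x = x)
  if (nrow(x) == 1L) base_probs <- matrix(base_probs, nrow = 1,
                                          dimnames = list(NULL, names(object$base)))
  colnames(base_probs) <- names(object$base)
  prob <- predict_xgb(object$meta, base_probs)
  out <- data.frame(
    prob_older = prob,
    class = factor(ifelse(prob >= object$config$class_threshold,
                          "older", "younger"),
                   levels = c("younger", "older"))
  )
  if (!is.null(newdata$cell_id)) out <- cbind(cell_id = newdata$cell_id, out)
  out
}

#' Save or load a fitted MechanoAge bundle
#'
#' The gradient-boosted meta-learner is converted to its raw byte
#' serialisation so a reloaded bundle reproduces predictions exactly.
#'
#' @param bundle a `mechanoage_bundle`.
#' @param path file path (`.rds`).
#' @return `load_mechanoage()` returns the bundle; `save_mechanoage()`
#'   returns `path` invisibly.
#' @export
save_mechanoage <- function(bundle, path) {
  stopifnot(inherits(bundle, "mechanoage_bundle"))
  bundle$meta_raw <- xgboost::xgb.save.raw(bundle$meta)
  bundle$meta <- NULL
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_mechanoage
#' @export
load_mechanoage <- function(path) {
  bundle <- readRDS(path)
  bundle$meta <- xgboost::xgb.load.raw(bundle$meta_raw)
  bundle$meta_raw <- NULL
  bundle
}
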