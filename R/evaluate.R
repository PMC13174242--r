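# Classifier evaluation: ROC/AUC with DeLong confidence intervals,
# consensus variable importance, and the two learning-curve analyses used
# to justify study size.

#' ROC analysis with DeLong confidence interval
#'
#' Computes the ROC curve and AUC of "older"-class probabilities against
#' true labels, with a 95% confidence interval by the DeLong method.
#'
#' @param prob_older numeric scores (probability of the "older" class).
#' @param labels factor/character with levels younger/older.
#' @param conf_level confidence level for the DeLong interval.
#' @return list with `auc`, `ci_lower`, `ci_upper` and the underlying
#'   `pROC::roc` object (`roc`).
#' @export
evaluate_roc <- function(prob_older, labels, conf_level = 0.95) {
  labels <- factor(labels, levels = c("younger", "older"))
  if (nlevels(droplevels(labels)) < 2L) {
    stopf("ROC needs both classes in `labels`")
  }
  r <- pROC::roc(response = labels, predictor = prob_older,
                 levels = c("younger", "older"), direction = "<",
                 quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = conf_level, method = "delong")
  list(auc = as.numeric(pROC::auc(r)),
       ci_lower = as.numeric(ci[1]), ci_upper = as.numeric(ci[3]),
       roc = r)
}

#' Consensus variable importance of a MechanoAge bundle
#'
#' Per-feature importance is taken from each base learner (Gini impurity
#' decrease), rescaled so each learner's largest score is 100, and averaged
#' across learners into a consensus ranking. Because recovery time enters
#' the model as five binary indicators, their cumulative contribution is
#' additionally reported as a feature group.
#'
#' @param bundle a fitted `mechanoage_bundle`.
#' @return data frame (one row per feature, sorted by consensus) with
#'   per-learner rescaled scores and the `consensus` column; the grouped
#'   recovery-time total is in `attr(, "group_importance")`.
#' @export
variable_importance <- function(bundle) {
  stopifnot(inherits(bundle, "mechanoage_bundle"))
  imp <- vapply(bundle$base, function(l) {
    v <- base_importance(l)[bundle$cols]
    mx <- max(v)
    if (!is.finite(mx) || mx <= 0) rep(0, length(v)) else 100 * v / mx
  }, numeric(length(bundle$cols)))
  rownames(imp) <- bundle$cols
  out <- data.frame(feature = bundle$cols, imp,
                    consensus = rowMeans(imp), row.names = NULL)
  out <- out[order(-out$consensus), ]
  rownames(out) <- NULL
  rec <- recovery_indicator_columns()
  grp <- data.frame(
    feature_group = c("recovery_time (cumulative)", setdiff(bundle$cols, rec)),
    consensus = c(sum(out$consensus[out$feature %in% rec]),
                  out$consensus[match(setdiff(bundle$cols, rec), out$feature)])
  )
  grp <- grp[order(-grp$consensus), ]
  rownames(grp) <- NULL
  attr(out, "group_importance") <- grp
  out
}

#' Cell-level learning curve
#'
#' Draws random subsamples of the training cells at each requested size
#' (`reps` times each), trains the full stacked ensemble on the subsample
#' and evaluates AUC on one fixed held-out set, tracing how performance and
#' its spread change with the number of cells.
#'
#' @param features labelled feature table ([build_feature_table()]).
#' @param sizes training-subsample sizes (each <= available training rows).
#' @param reps random draws per size.
#' @param config a [mechanoage_config()]; use a light configuration here,
#'   one ensemble is trained per size x rep.
#' @param holdout_frac fraction of cells reserved once as the fixed
#'   evaluation set.
#' @param seed seed controlling the split and the draws.
#' @return list with `curve` (size, rep, auc) and `summary` (per size:
#'   mean AUC and standard error).
#' @export
learning_curve_cells <- function(features, sizes, reps = 5L,
                                 config = mechanoage_config(),
                                 holdout_frac = 0.3, seed = 1L) {
  y <- factor(features$label, levels = c("younger", "older"))
  ho_idx <- with_seed(derive_seed(seed, "lc-split"),
                      caret::createDataPartition(y, p = holdout_frac,
                                                 list = FALSE)[, 1])
  train_pool <- setdiff(seq_len(nrow(features)), ho_idx)
  if (max(sizes) > length(train_pool)) {
    stopf("largest size (%d) exceeds available training rows (%d)",
          max(sizes), length(train_pool))
  }
  holdout <- features[ho_idx, , drop = FALSE]
  rows <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      idx <- with_seed(derive_seed(seed, sprintf("lc-%d-%d", s, r)),
                       sample(train_pool, s))
      sub <- features[idx, , drop = FALSE]
      if (nlevels(droplevels(sub$label)) < 2L) next
      cfg <- config
      cfg$seed <- derive_seed(seed, sprintf("lc-train-%d-%d", s, r))
      bundle <- train_mechanoage(sub, cfg)
      pred <- predict(bundle, holdout)
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, rep = r,
        auc = evaluate_roc(pred$prob_older, holdout$label)$auc
      )
    }
  }
  curve <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(curve, curve$size), function(d) {
    data.frame(size = d$size[1], mean_auc = mean(d$auc),
               se_auc = stats::sd(d$auc) / sqrt(nrow(d)), n_reps = nrow(d))
  }))
  rownames(summ) <- NULL
  list(curve = curve, summary = summ)
}

#' Donor-level learning curve with leave-one-sample-out validation
#'
#' For each of `orders` random donor inclusion orders, grows the cohort one
#' donor at a time; each prefix is evaluated by leave-one-sample-out
#' validation (train on the prefix minus one donor, predict that donor's
#' cells, pool all held-out predictions into one AUC). Donor prefixes whose
#' training remainder would contain a single class are skipped and logged.
#'
#' @param features labelled feature table with a `donor_id` column.
#' @param orders number of random inclusion orders.
#' @param config a [mechanoage_config()]; keep it light, the number of
#'   ensembles trained grows quadratically with donors.
#' @param seed seed controlling order shuffles and training.
#' @return data frame (order, n_donors, auc) with `NA` where a prefix was
#'   not evaluable; skipped donor folds are counted in
#'   `attr(, "n_skipped_folds")`.
#' @export
learning_curve_samples <- function(features, orders = 50L,
                                   config = mechanoage_config(), seed = 1L) {
  if (is.null(features$donor_id)) stopf("features need a `donor_id` column")
  donors <- unique(features$donor_id)
  if (length(donors) < 3L) stopf("need at least 3 donors")
  donor_class <- vapply(donors, function(d) {
    as.character(features$label[features$donor_id == d][1])
  }, character(1))
  rows <- list()
  n_skipped <- 0L
  for (o in seq_len(orders)) {
    ord <- with_seed(derive_seed(seed, paste0("order-", o)), sample(donors))
    for (k in 2:length(ord)) {
      prefix <- ord[seq_len(k)]
      if (length(unique(donor_class[match(prefix, donors)])) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(order = o, n_donors = k,
                                                auc = NA_real_)
        next
      }
      pooled_prob <- numeric(0)
      pooled_lab <- character(0)
      for (d in prefix) {
        train_donors <- setdiff(prefix, d)
        tr <- features[features$donor_id %in% train_donors, , drop = FALSE]
        if (nlevels(droplevels(tr$label)) < 2L) {
          n_skipped <- n_skipped + 1L
          next
        }
        cfg <- config
        cfg$seed <- derive_seed(seed, sprintf("loso-%d-%d-%s", o, k, d))
        bundle <- train_mechanoage(tr, cfg)
        te <- features[features$donor_id == d, , drop = FALSE]
        pred <- predict(bundle, te)
        pooled_prob <- c(pooled_prob, pred$prob_older)
        pooled_lab <- c(pooled_lab, as.character(te$label))
      }
      auc <- if (length(unique(pooled_lab)) == 2L) {
        auc_rank(pooled_prob, pooled_lab == "older")
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(order = o, n_donors = k,
                                              auc = auc)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped_folds") <- n_skipped
  out
}
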