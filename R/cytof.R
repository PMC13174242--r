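# CyTOF analysis layer: per-protein differential expression, gradient-
# boosted expression signatures trained on unperturbed control cells, and
# frozen-model transfer onto perturbation conditions with DeLong
# comparisons.

cytof_marker_columns <- function(x) {
  setdiff(names(x), c("cell_id", "lineage", "group", "condition"))
}

transform_intensity <- function(v, transform = c("log1p", "arcsinh", "log")) {
  transform <- match.arg(transform)
  switch(transform,
         log1p = log1p(v),
         arcsinh = asinh(v / 5),
         log = log(pmax(v, .Machine$double.eps)))
}

#' Differential protein expression between two groups
#'
#' Per-marker comparison on log-transformed intensities: the log fold
#' change is the difference of group means (group_b minus group_a), the
#' p-value comes from a two-sided Wilcoxon rank-sum test on the transformed
#' intensities, and Bonferroni correction is applied over the panel.
#' A marker is significant when the adjusted p-value is < `alpha` AND
#' |LFC| > `lfc_threshold`. Markers constant in both groups are recorded
#' with p = 1, not dropped.
#'
#' @param matrix_df expression data frame ([simulate_cytof()] layout:
#'   metadata columns + one intensity column per marker).
#' @param group_a,group_b group labels to compare (both >= 2 cells).
#' @param transform intensity transform for the LFC: `"log1p"` (default),
#'   `"arcsinh"` (cofactor 5) or `"log"`.
#' @param alpha,lfc_threshold the dual significance thresholds
#'   (defaults: adjusted p < 0.05 and |LFC| > 0.5).
#' @return data frame `marker, lfc, p, p_adj, significant`.
#' @export
dep_analysis <- function(matrix_df, group_a, group_b,
                         transform = "log1p",
                         alpha = 0.05, lfc_threshold = 0.5) {
  markers <- cytof_marker_columns(matrix_df)
  a <- matrix_df[matrix_df$group == group_a, , drop = FALSE]
  b <- matrix_df[matrix_df$group == group_b, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stopf("both groups need >= 2 cells")
  }
  res <- lapply(markers, function(m) {
    va <- transform_intensity(a[[m]], transform)
    vb <- transform_intensity(b[[m]], transform)
    lfc <- mean(vb) - mean(va)
    p <- if (stats::sd(c(va, vb)) == 0) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    }
    data.frame(marker = m, lfc = lfc, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out$significant <- out$p_adj < alpha & abs(out$lfc) > lfc_threshold
  rownames(out) <- NULL
  out
}

#' Train a frozen gradient-boosted expression signature
#'
#' Trains a binary gradient-boosted classifier for one biological
#' comparison (e.g. younger vs older, or younger vs high-risk) on
#' unperturbed control cells of one lineage (luminal by default): a
#' stratified 70/30 train-test split, 5-fold cross-validated selection of
#' the boosting length maximising AUC, a final fit on the training split,
#' and freezing -- the stored model is a raw byte serialisation that
#' [transfer_evaluate()] applies without any parameter update.
#'
#' @param matrix_df expression data frame (control condition cells are
#'   selected automatically when a `condition` column is present).
#' @param classes length-2 character: the negative and positive group
#'   labels, in that order.
#' @param lineage lineage subset (`NULL` to use all cells).
#' @param transform intensity transform applied to the features.
#' @param train_frac training fraction of the stratified split.
#' @param cv_folds folds for boosting-length selection.
#' @param nrounds_grid candidate boosting lengths.
#' @param seed seed for split, folds and fits.
#' @return object of class `cytof_signature`: frozen model bytes, marker
#'   schema, classes, the held-out test AUC (`test_auc`) and test
#'   predictions.
#' @export
train_signature <- function(matrix_df, classes = c("younger", "older"),
                            lineage = "luminal", transform = "log1p",
                            train_frac = 0.7, cv_folds = 5L,
                            nrounds_grid = seq(20L, 200L, by = 20L),
                            seed = 1L) {
  stopifnot(length(classes) == 2L)
  d <- matrix_df
  if (!is.null(lineage) && !is.null(d$lineage)) {
    d <- d[d$lineage == lineage, , drop = FALSE]
  }
  if (!is.null(d$condition)) d <- d[d$condition == "control", , drop = FALSE]
  d <- d[d$group %in% classes, , drop = FALSE]
  y <- factor(d$group, levels = classes)
  if (any(table(y) == 0L)) {
    stopf("class absent from the control data: %s",
          paste(classes[table(y) == 0L], collapse = ", "))
  }
  markers <- cytof_marker_columns(d)
  x <- as.matrix(d[, markers, drop = FALSE])
  x <- apply(x, 2, transform_intensity, transform = transform)
  y01 <- as.integer(y == classes[2])

  tr_idx <- with_seed(derive_seed(seed, "split"),
                      caret::createDataPartition(y, p = train_frac,
                                                 list = FALSE)[, 1])
  te_idx <- setdiff(seq_len(nrow(x)), tr_idx)

  folds <- with_seed(derive_seed(seed, "cv"),
                     caret::createFolds(y[tr_idx], k = cv_folds,
                                        returnTrain = TRUE))
  cv_auc <- matrix(NA_real_, length(folds), length(nrounds_grid))
  for (f in seq_along(folds)) {
    ftr <- tr_idx[folds[[f]]]
    fho <- tr_idx[-folds[[f]]]
    for (g in seq_along(nrounds_grid)) {
      fit <- fit_xgb(x[ftr, , drop = FALSE], y01[ftr], nrounds_grid[g])
      cv_auc[f, g] <- auc_rank(predict_xgb(fit, x[fho, , drop = FALSE]),
                               y01[fho] == 1L)
    }
  }
  best <- nrounds_grid[which.max(colMeans(cv_auc, na.rm = TRUE))]
  model <- fit_xgb(x[tr_idx, , drop = FALSE], y01[tr_idx], best)

  test_scores <- predict_xgb(model, x[te_idx, , drop = FALSE])
  test_auc <- auc_rank(test_scores, y01[te_idx] == 1L)

  structure(list(
    model_raw = xgboost::xgb.save.raw(model),
    markers = markers,
    classes = classes,
    transform = transform,
    nrounds = best,
    test_auc = test_auc,
    test = data.frame(score = test_scores,
                      group = as.character(y[te_idx]),
                      stringsAsFactors = FALSE),
    checksum = sum(as.integer(xgboost::xgb.save.raw(model)))
  ), class = "cytof_signature")
}

#' @export
print.cytof_signature <- function(x, ...) {
  cat(sprintf("CyTOF expression signature: %s vs %s\n",
              x$classes[1], x$classes[2]))
  cat(sprintf("  %d markers, %d boosting rounds, held-out test AUC %.3f\n",
              length(x$markers), x$nrounds, x$test_auc))
  invisible(x)
}

#' Apply a frozen signature to a perturbation condition
#'
#' Scores every cell of the condition matrix with the frozen model (no
#' retraining or parameter update) and evaluates the ROC/AUC against the
#' cells' chronological-class labels.
#'
#' @param signature a `cytof_signature`.
#' @param condition_df expression data frame sharing the training marker
#'   schema; must contain cells of both signature classes.
#' @return list with `auc`, `ci_lower`, `ci_upper`, the `pROC::roc` object
#'   (`roc`) and the per-cell `scores`.
#' @export
transfer_evaluate <- function(signature, condition_df) {
  stopifnot(inherits(signature, "cytof_signature"))
  if (nrow(condition_df) == 0L) stopf("empty condition matrix")
  missing <- setdiff(signature$markers, names(condition_df))
  if (length(missing) > 0L) {
    stopf("condition matrix lacks markers: %s", paste(missing, collapse = ", "))
  }
  d <- condition_df[condition_df$group %in% signature$classes, , drop = FALSE]
  if (length(unique(d$group)) < 2L) {
    stopf("condition matrix must contain cells of both signature classes")
  }
  x <- as.matrix(d[, signature$markers, drop = FALSE])
  x <- apply(x, 2, transform_intensity, transform = signature$transform)
  model <- xgboost::xgb.load.raw(signature$model_raw)
  scores <- predict_xgb(model, x)
  labels <- factor(d$group, levels = signature$classes)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = signature$classes, direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(r, method = "delong")
  list(auc = as.numeric(pROC::auc(r)),
       ci_lower = as.numeric(ci[1]), ci_upper = as.numeric(ci[3]),
       roc = r, scores = scores)
}

#' DeLong comparison of two ROC curves
#'
#' Two-sided DeLong test of the difference between two AUCs; paired when
#' both ROC curves were computed on the same cells, unpaired otherwise
#' (auto-detected from the response vectors unless `paired` is given).
#'
#' @param roc_a,roc_b `pROC::roc` objects (e.g. from
#'   [transfer_evaluate()]`$roc` or [evaluate_roc()]`$roc`).
#' @param paired logical; `NULL` to auto-detect.
#' @return list with `p` and the test `statistic`.
#' @export
delong_compare <- function(roc_a, roc_b, paired = NULL) {
  if (is.null(paired)) {
    paired <- length(roc_a$response) == length(roc_b$response) &&
      all(as.character(roc_a$response) == as.character(roc_b$response))
  }
  ht <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = paired)
  list(p = ht$p.value, statistic = unname(ht$statistic), paired = paired)
}
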