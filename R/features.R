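# Feature engineering: recovery-time dummy coding, Yeo-Johnson
# normalisation and the ten-feature design matrix consumed by MechanoAge.

#' Names of the ten model features
#'
#' Five continuous mechanophenotype features (free diameter, wCDI,
#' contraction transit time, deformation length, transverse deformation)
#' plus five binary recovery-time indicators.
#'
#' @param continuous which continuous columns to use; the fifth continuous
#'   feature is an interpretation (the published feature list is not
#'   enumerated in full) and can be swapped here.
#' @return character vector of length 10.
#' @export
feature_columns <- function(continuous = c("D_cell_um", "wCDI", "dT_cont_ms",
                                           "L_deform_um", "delta_deform")) {
  c(continuous, recovery_indicator_columns())
}

recovery_indicator_columns <- function() {
  c("recovery_0ms", "recovery_50_60ms", "recovery_60_70ms",
    "recovery_70_120ms", "recovery_inf")
}

# Bin index (1..5) of a recovery time; shared by the dummy coder and the
# phenotype pipeline.
bin_recovery_index <- function(dT_r_ms) {
  if (any(is.na(dT_r_ms)) || any(dT_r_ms[is.finite(dT_r_ms)] < 0)) {
    stopf("recovery times must be >= 0 or Inf")
  }
  idx <- integer(length(dT_r_ms))
  idx[is.infinite(dT_r_ms)] <- 5L
  fin <- is.finite(dT_r_ms)
  v <- dT_r_ms[fin]
  idx[fin] <- ifelse(v < 50, 1L,
               ifelse(v < 60, 2L,
                ifelse(v < 70, 3L,
                 ifelse(v <= 120, 4L, 5L))))
  n_sub50 <- sum(fin & dT_r_ms > 0 & dT_r_ms < 50)
  attr(idx, "n_sub50") <- n_sub50
  idx
}

#' One-hot encode recovery times into the five recovery bins
#'
#' Recovery time is categorical by construction of the device (discrete
#' post-contraction sensing segments), and is coded as five binary
#' indicators: 0 ms; 50-60 ms; 60-70 ms; 70-120 ms; infinite recovery.
#' Finite values in (0, 50) ms, which the printed bins do not cover and the
#' device effectively cannot produce, are assigned to the "0 ms" bin and
#' their count reported in the `n_sub50` attribute; finite values above the
#' 120 ms observation window are treated as infinite.
#'
#' @param dT_r_ms numeric vector of recovery times (ms), `Inf` for the
#'   infinite-recovery sentinel.
#' @return integer matrix with one row per value and the five indicator
#'   columns of [recovery_indicator_columns()]; each row sums to exactly 1.
#' @examples
#' bin_recovery(c(0, 55, Inf))
#' @export
bin_recovery <- function(dT_r_ms) {
  idx <- bin_recovery_index(dT_r_ms)
  m <- matrix(0L, nrow = length(idx), ncol = 5L,
              dimnames = list(NULL, recovery_indicator_columns()))
  m[cbind(seq_along(idx), as.integer(idx))] <- 1L
  attr(m, "n_sub50") <- attr(idx, "n_sub50")
  m
}

#' Fit Yeo-Johnson transformations per column
#'
#' Estimates one Yeo-Johnson lambda per continuous column by maximum
#' likelihood (via [car::powerTransform()]), to improve normality before
#' model training. Fitting must be restricted to the training partition;
#' the fitted object is then applied unchanged to validation data.
#' Constant columns get lambda = 1 (identity) with a warning.
#'
#' @param x data frame or matrix of continuous columns.
#' @return object of class `yj_transform`: named lambda vector.
#' @export
fit_yeo_johnson <- function(x) {
  x <- as.data.frame(x)
  lambdas <- vapply(names(x), function(nm) {
    col <- x[[nm]]
    if (!is.numeric(col)) stopf("column `%s` is not numeric", nm)
    if (stats::sd(col) == 0 || !all(is.finite(col))) {
      warning(sprintf("column `%s` is constant; lambda undefined, using identity",
                      nm), call. = FALSE)
      return(1)
    }
    # convergence chatter on small samples is harmless (any lambda gives a
    # monotone transform); a hard failure falls back to the identity
    tryCatch(
      suppressWarnings(
        unname(stats::coef(car::powerTransform(col, family = "yjPower")))
      ),
      error = function(e) {
        warning(sprintf("Yeo-Johnson fit failed for `%s`; using identity", nm),
                call. = FALSE)
        1
      })
  }, numeric(1))
  structure(list(lambda = lambdas), class = "yj_transform")
}

#' Apply a fitted Yeo-Johnson transformation
#'
#' @param x data frame with (at least) the columns the transform was fitted
#'   on.
#' @param transform a `yj_transform` from [fit_yeo_johnson()].
#' @return `x` with the fitted columns replaced by their transformed values;
#'   the transform is monotone, so orderings are preserved.
#' @export
apply_yeo_johnson <- function(x, transform) {
  stopifnot(inherits(transform, "yj_transform"))
  x <- as.data.frame(x)
  for (nm in names(transform$lambda)) {
    if (!nm %in% names(x)) stopf("column `%s` missing from data", nm)
    x[[nm]] <- car::yjPower(x[[nm]], transform$lambda[[nm]])
  }
  x
}

#' Build the ten-feature design matrix for MechanoAge
#'
#' Assembles per-cell phenotypes into the model's design matrix: five
#' continuous features plus the five recovery indicators, with the
#' chronological class label attached from donor metadata (older > 50 y,
#' younger < 35 y). Cells from donors aged in between are excluded (the
#' model is trained on the two extreme groups only) and counted in the
#' `n_excluded` attribute. Rows with missing features are excluded
#' upstream, not imputed.
#'
#' @param phenotypes data frame from [process_trace()] /
#'   [simulate_population()], containing the continuous features and either
#'   `recovery_class` or `dT_r_ms`/`recovery_time_ms`, plus optionally
#'   `donor_id` and `age`.
#' @param continuous names of the five continuous feature columns.
#' @return data frame with exactly the 10 columns of [feature_columns()],
#'   plus `label` (factor younger/older, `NA` when no age is available),
#'   `cell_id` and `donor_id` when present; attribute `n_excluded` counts
#'   cells dropped for intermediate donor age.
#' @export
build_feature_table <- function(phenotypes,
                                continuous = c("D_cell_um", "wCDI",
                                               "dT_cont_ms", "L_deform_um",
                                               "delta_deform")) {
  ph <- as.data.frame(phenotypes)
  cols <- feature_columns(continuous)
  if (nrow(ph) == 0L) {
    out <- as.data.frame(matrix(numeric(), 0, length(cols),
                                dimnames = list(NULL, cols)))
    out$label <- factor(character(), levels = c("younger", "older"))
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  missing_cont <- setdiff(continuous, names(ph))
  if (length(missing_cont) > 0L) {
    stopf("phenotypes lack continuous feature columns: %s",
          paste(missing_cont, collapse = ", "))
  }
  if (!is.null(ph$recovery_class)) {
    idx <- match(ph$recovery_class, recovery_bins())
    if (any(is.na(idx))) stopf("unknown recovery class label")
    dummies <- matrix(0L, nrow(ph), 5L,
                      dimnames = list(NULL, recovery_indicator_columns()))
    dummies[cbind(seq_len(nrow(ph)), idx)] <- 1L
  } else {
    rt <- if (!is.null(ph$dT_r_ms)) ph$dT_r_ms else ph$recovery_time_ms
    if (is.null(rt)) stopf("need `recovery_class`, `dT_r_ms` or `recovery_time_ms`")
    dummies <- bin_recovery(rt)
  }
  out <- cbind(ph[, continuous, drop = FALSE], as.data.frame(dummies))

  keep <- rep(TRUE, nrow(ph))
  if (!is.null(ph$age)) {
    label <- ifelse(is.na(ph$age), NA_character_,
                    ifelse(ph$age > 50, "older",
                           ifelse(ph$age < 35, "younger", "intermediate")))
    keep <- is.na(label) | label != "intermediate"
    label[!keep] <- NA_character_
  } else if (!is.null(ph$group)) {
    # simulated populations carry their group label directly
    label <- ifelse(ph$group %in% c("younger", "older"), ph$group,
                    NA_character_)
  } else {
    label <- rep(NA_character_, nrow(ph))
  }
  out$label <- factor(label, levels = c("younger", "older"))
  if (!is.null(ph$cell_id)) out$cell_id <- ph$cell_id
  if (!is.null(ph$donor_id)) out$donor_id <- ph$donor_id
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}
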