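# Mechano-RISQ: deviation of a sample's "older"-classification rate from
# the average-risk baseline, with single-case inference (Crawford-Howell),
# simulation-based power, Benjamini-Hochberg correction and the group-level
# tests used for perturbation experiments.

#' Baseline error rate from an average-risk reference set
#'
#' The proportion of reference cells of the given chronological class that
#' the core model classifies as "older" although they come from average-risk
#' donors of the other class. For the canonical direction
#' (`reference_class = "younger"`) this is the misclassification rate of
#' average-risk young cells; `reference_class = "older"` gives the
#' predicted-older rate of average-risk old cells, the baseline used when
#' scoring knockdown experiments on older donors. The reference set must be
#' validation data never used in training.
#'
#' @param reference_predictions factor/character of predicted classes.
#' @param reference_labels factor/character of true chronological classes.
#' @param reference_class chronological class defining the baseline.
#' @return baseline rate `b` in (0, 1).
#' @export
baseline_error_rate <- function(reference_predictions, reference_labels,
                                reference_class = c("younger", "older")) {
  reference_class <- match.arg(reference_class)
  sel <- reference_labels == reference_class
  if (sum(sel) == 0L) {
    stopf("no reference cells of class `%s`", reference_class)
  }
  b <- mean(reference_predictions[sel] == "older")
  if (b == 0) {
    stopf(paste0("baseline rate is 0: RISQ would be undefined; ",
                 "use a larger reference set"))
  }
  b
}

#' Mechano-RISQ score of a sample
#'
#' Ratio of the sample's fraction of cells classified "older" to the
#' baseline rate `b`: 1.0 means no deviation from the average-risk
#' baseline; values above/below 1.0 mean an increased/decreased
#' older-classification rate.
#'
#' @param sample_predictions factor/character of predicted classes for the
#'   sample's cells (>= 1 cell).
#' @param b baseline rate from [baseline_error_rate()] (> 0).
#' @return the RISQ ratio (>= 0).
#' @examples
#' mechano_risq(rep(c("older", "younger"), c(30, 70)), b = 0.10)  # 3.0
#' @export
mechano_risq <- function(sample_predictions, b) {
  if (length(sample_predictions) < 1L) stopf("empty sample")
  if (!is.numeric(b) || b <= 0) stopf("baseline `b` must be > 0")
  mean(sample_predictions == "older") / b
}

#' Crawford-Howell single-case t-test
#'
#' Compares one case value against a small normative sample:
#' \deqn{t = \frac{x^* - \bar{x}}{s\sqrt{(n+1)/n}}, \quad df = n - 1,}
#' a method validated for single-case versus normative-group comparisons
#' (it widens the ordinary one-sample interval to account for the case
#' being a single draw).
#'
#' @param case_value the single case score.
#' @param normative_values numeric vector of the normative group
#'   (n >= 2, non-constant).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `t`, `df`, `p`.
#' @examples
#' crawford_howell(6, 1:5)  # t = 1.732, df = 4
#' @export
crawford_howell <- function(case_value, normative_values,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(normative_values)
  if (n < 2L) stopf("normative sample must have n >= 2")
  s <- stats::sd(normative_values)
  if (s == 0) stopf("normative sample is constant; t undefined")
  t_stat <- (case_value - mean(normative_values)) / (s * sqrt((n + 1) / n))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t_stat), df),
              greater = stats::pt(t_stat, df, lower.tail = FALSE),
              less = stats::pt(t_stat, df))
  list(t = t_stat, df = df, p = p)
}

#' Monte-Carlo power of the Crawford-Howell test
#'
#' Estimates power by simulation: in each iteration a normative sample of
#' size `n_norm` is drawn from N(0, 1) and a case shifted by `cohens_d`
#' standard deviations is tested at level `alpha`; power is the rejection
#' fraction.
#'
#' Two conventions exist for the case value. With `case_noise = TRUE`
#' (default) the case is drawn from the shifted population
#' (`N(cohens_d, 1)`), so at `cohens_d = 0` the rejection rate calibrates
#' to `alpha`; the case's own sampling noise then caps attainable power
#' (about 0.78 at `n_norm = 18`, `cohens_d = 3`). With
#' `case_noise = FALSE` the case sits exactly at `cohens_d` standard
#' deviations, the convention under which this design reaches power > 0.97.
#'
#' @param n_norm normative sample size (>= 2).
#' @param cohens_d standardised case shift (default 3).
#' @param alpha significance level.
#' @param iterations Monte-Carlo iterations (default 10000; fewer than 100
#'   warns about instability).
#' @param seed integer seed.
#' @param alternative sidedness passed to [crawford_howell()].
#' @param case_noise whether the case carries its own sampling noise
#'   (see Details).
#' @return power estimate in `[0, 1]`.
#' @export
ch_power_simulation <- function(n_norm, cohens_d = 3, alpha = 0.05,
                                iterations = 10000L, seed = 1L,
                                alternative = "two.sided",
                                case_noise = TRUE) {
  if (n_norm < 2L) stopf("`n_norm` must be >= 2")
  if (iterations < 100L) {
    warning("fewer than 100 iterations gives an unstable power estimate",
            call. = FALSE)
  }
  with_seed(seed, {
    rejections <- vapply(seq_len(iterations), function(i) {
      norm <- stats::rnorm(n_norm)
      case <- cohens_d + if (case_noise) stats::rnorm(1) else 0
      crawford_howell(case, norm, alternative = alternative)$p < alpha
    }, logical(1))
    mean(rejections)
  })
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Standard step-up false-discovery-rate correction (with monotonicity
#' enforcement), applied across all samples of one analysis panel.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return adjusted p-values, never smaller than the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Group comparison of RISQ scores (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test between two groups of per-sample RISQ
#' scores (exact for small tie-free samples, normal approximation with tie
#' correction otherwise) -- the appropriate non-parametric test given
#' unequal per-donor sample sizes and no normality assumption.
#'
#' @param risq_a,risq_b numeric score vectors (both non-empty).
#' @return two-sided p-value.
#' @export
group_compare <- function(risq_a, risq_b) {
  if (length(risq_a) == 0L || length(risq_b) == 0L) {
    stopf("both groups must be non-empty")
  }
  suppressWarnings(stats::wilcox.test(risq_a, risq_b,
                                      alternative = "two.sided")$p.value)
}

#' Fisher's exact test for perturbation experiments
#'
#' Two-sided exact test on the 2x2 table of older/younger classification
#' counts in a perturbation condition versus its control -- appropriate for
#' a binary classification outcome with small cell counts in some strata.
#'
#' @param counts 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts: rows = condition/control, columns = older/younger.
#' @return two-sided p-value.
#' @examples
#' perturbation_fisher(matrix(c(30, 10, 70, 90), 2))
#' @export
perturbation_fisher <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2L, 2L))) stopf("`counts` must be a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    stopf("counts must be non-negative integers")
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Per-sample Mechano-RISQ table with single-case inference
#'
#' Computes, for each sample, the fraction of cells classified "older", the
#' RISQ ratio against the supplied baseline, the Crawford-Howell statistic
#' of the sample's RISQ against the normative average-risk RISQ
#' distribution, and Benjamini-Hochberg adjusted p-values across the panel.
#'
#' @param predictions data frame with `sample_id` and predicted `class` per
#'   cell.
#' @param b baseline rate ([baseline_error_rate()]).
#' @param normative_risq numeric vector of RISQ scores from the normative
#'   average-risk samples (n >= 2).
#' @param alternative sidedness of the Crawford-Howell test.
#' @return data frame `sample_id, n_cells, p_older, baseline, risq, t, df,
#'   p, p_adj`.
#' @export
risq_table <- function(predictions, b, normative_risq,
                       alternative = "two.sided") {
  stopifnot(all(c("sample_id", "class") %in% names(predictions)))
  rows <- lapply(split(predictions, predictions$sample_id), function(d) {
    p_older <- mean(d$class == "older")
    risq <- p_older / b
    ch <- crawford_howell(risq, normative_risq, alternative = alternative)
    data.frame(sample_id = d$sample_id[1], n_cells = nrow(d),
               p_older = p_older, baseline = b, risq = risq,
               t = ch$t, df = ch$df, p = ch$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
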