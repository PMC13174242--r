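# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the given seed and restores the caller's RNG state
#' afterwards, so library functions never clobber user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named RNG substream seed from a master seed
#'
#' All stochastic steps (fold creation, down-sampling, individual learners)
#' draw their seeds from one master seed via a label hash, so a single config
#' seed determines the whole pipeline while steps stay decoupled.
#'
#' @param seed master integer seed.
#' @param label character tag naming the substream.
#' @return integer in `[1, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1013L)
  as.integer((abs(as.numeric(seed) * 69621 + h) %% 2147483646) + 1)
}

# Rank-based AUC of `scores` for the positive class; fast path used for
# internal hyperparameter tuning (user-facing ROC goes through pROC).
auc_rank <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n2 <- sum(!is_positive)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}
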