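#' Chi-square standard residual
#'
#' Pearson residual of a single contingency cell, \eqn{(O - E)/\sqrt{E}}.
#' Cells with residual magnitude of 2 or more are conventionally read as
#' deviating from independence.
#'
#' @param observed Observed count(s), nonnegative.
#' @param expected Expected count(s) under the null, strictly positive.
#' @return Numeric vector of residuals.
#' @examples
#' standard_residual(16, 4) # 6
#' @export
standard_residual <- function(observed, expected) {
  if (!is.numeric(observed) || !is.numeric(expected)) {
    stop("observed and expected must be numeric")
  }
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop("expected counts must be positive")
  }
  (observed - expected) / sqrt(expected)
}

# 2x2 Pearson chi-square, by default without continuity correction so the
# residuals are the raw Pearson components. Returns NULL on degenerate
# margins (zero row/column sum). The residuals are unaffected by `correct`.
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(
    p = ht$p.value,
    expected = ht$expected,
    residuals = ht$residuals,
    statistic = unname(ht$statistic)
  )
}

# Deterministic derivation of a child seed from a parent seed and an
# integer offset; stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  as.integer((s * 48271 + 1013904223 * as.numeric(offset)) %% m)
}

# Two-sided Wilcoxon rank-sum p-value with the package-wide conventions:
# constant pooled values give p = 1 (flagged upstream).
rank_sum_p <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
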