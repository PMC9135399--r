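# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# Pearson residuals of a contingency table from its marginals.
oracle_residuals <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  (tab - e) / sqrt(e)
}

oracle_chisq_p <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stats::pchisq(sum((tab - e)^2 / e), df = 1, lower.tail = FALSE)
}

# Average ranks computed from scratch (sort positions, tied runs averaged).
oracle_rank <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1L
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman rho as Pearson correlation of average ranks, via raw sums.
oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Two-sided Mann-Whitney p with normal approximation, tie correction and
# continuity correction (the large-sample convention).
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- oracle_rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- w - n1 * n2 / 2
  ties <- table(c(x, y))
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  correction <- sign(z) * 0.5
  z <- (z - correction) / sigma
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
}

# OLS via the closed-form normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- (sum(y) - b * sum(x)) / n
  c(intercept = a, slope = b)
}

# Partner lookup by exhaustive double loop over a plain complex list.
oracle_partners <- function(proteins, complexes) {
  out <- character(0)
  for (cx in complexes) {
    if (any(proteins %in% cx)) out <- c(out, cx)
  }
  setdiff(unique(out), proteins)
}

oracle_cooccur <- function(a, b, complexes) {
  both <- 0L
  either <- 0L
  for (cx in complexes) {
    ha <- a %in% cx
    hb <- b %in% cx
    if (ha && hb) both <- both + 1L
    if (ha || hb) either <- either + 1L
  }
  if (either == 0L) NA_real_ else both / either
}
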