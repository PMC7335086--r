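# Vectorized one-vs-rest Wilcoxon rank-sum tests across the rows of a
# matrix. Uses the normal approximation with tie correction and continuity
# correction, matching wilcox.test(exact = FALSE, correct = TRUE); the
# looped wilcox.test is the oracle in the test suite. Ranks and tie terms
# depend only on the matrix, so they are computed once and reused for every
# cluster comparison.

rank_matrix <- function(X) {
  R <- t(apply(X, 1, rank))
  # sum of (t^3 - t) over tie groups, per row
  tie <- apply(X, 1, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  list(ranks = R, tie = as.numeric(tie))
}

# Two-sided p-values and mean differences for rows of X, group `in_idx`
# (logical or integer index over columns) versus the rest.
ranksum_rows <- function(X, in_idx, rk = NULL) {
  if (is.null(rk)) rk <- rank_matrix(X)
  n <- ncol(X)
  in_l <- logical(n); in_l[in_idx] <- TRUE
  n1 <- sum(in_l); n2 <- n - n1
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  W <- rowSums(rk$ranks[, in_l, drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - rk$tie / (n * (n - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  p[p > 1] <- 1
  delta <- rowMeans(X[, in_l, drop = FALSE]) - rowMeans(X[, !in_l, drop = FALSE])
  data.frame(p = p, delta = delta, row.names = rownames(X))
}
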