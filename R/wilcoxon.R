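#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Lightweight paired signed-rank test returning the two-sided p-value. Zero
#' differences are dropped before ranking (the classic Wilcoxon convention).
#' With n <= 25 remaining pairs and no tied absolute differences the exact
#' null distribution is used (via \code{psignrank}); otherwise the normal
#' approximation with continuity correction and the usual tie correction.
#'
#' This is the test applied to paired per-participant mean RTs inside the
#' power Monte Carlo; it is kept minimal and vectorisable so it can be called
#' tens of thousands of times per power curve. Results agree with
#' \code{stats::wilcox.test(x, y, paired = TRUE)} on continuous data.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5 recommended).
#' @return A list with elements \code{statistic} (V, the sum of ranks of
#'   positive differences), \code{p_value}, \code{n_used} (pairs after
#'   dropping zeros) and \code{exact} (logical).
#' @examples
#' wilcoxon_two_sided(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))  # p = 0.03125
#' @export
wilcoxon_two_sided <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length (paired samples)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L, exact = FALSE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(v, n),
                 stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    list(statistic = v, p_value = p, n_used = n, exact = TRUE)
  } else {
    list(statistic = v, p_value = signrank_normal_p(v, n, r),
         n_used = n, exact = FALSE)
  }
}

# Normal approximation with continuity and tie correction, two-sided.
signrank_normal_p <- function(v, n, r) {
  e <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- v - e
  z <- sign(z) * pmax(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Vectorised exact two-sided p-values for a matrix of paired differences
# (rows = replicates). Assumes continuous data (no zeros/ties almost surely);
# rows with ties or zeros fall back to wilcoxon_two_sided().
wilcoxon_p_rows <- function(d) {
  n <- ncol(d)
  a <- abs(d)
  rk <- t(apply(a, 1L, rank))
  v <- rowSums(rk * (d > 0))
  has_zero <- rowSums(d == 0) > 0
  has_tie <- apply(rk, 1L, anyDuplicated) > 0
  ok <- !(has_zero | has_tie)
  p <- numeric(nrow(d))
  if (n <= 25) {
    p[ok] <- pmin(1, 2 * pmin(stats::psignrank(v[ok], n),
                              stats::psignrank(v[ok] - 1, n,
                                               lower.tail = FALSE)))
  } else {
    e <- n * (n + 1) / 4
    s <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- v[ok] - e
    z <- sign(z) * pmax(0, abs(z) - 0.5) / s
    p[ok] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  for (i in which(!ok))
    p[i] <- wilcoxon_two_sided(d[i, ], rep(0, n))$p_value
  p
}
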