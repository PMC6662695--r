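#' Two-sided Mann-Whitney rank test
#'
#' The U statistic counts, over all `length(x) * length(y)` pairs, how
#' often an `x` value exceeds a `y` value (ties count one half). The
#' two-sided p-value is exact -- from the full null distribution of U --
#' whenever the smaller sample has at most 8 observations and the pooled
#' data carry no ties; otherwise the normal approximation with tie and
#' continuity corrections is used. The exact two-sided p is
#' `2 * min(P(U <= u), P(U >= u))`, capped at 1.
#'
#' If every pooled value is identical the test is vacuous and `p = 1` is
#' returned with a message.
#'
#' @param x,y numeric vectors (each non-empty, finite).
#' @param exact_max largest min(n) for which the exact distribution is
#'   used (default 8).
#' @return list with elements `U` (for `x` against `y`), `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_two_sided <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("empty sample")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    message("all pooled values identical; p = 1 by convention")
    return(list(U = u, p = 1, method = "degenerate"))
  }
  if (!ties && min(n1, n2) <= exact_max) {
    cdf <- mw_exact_cdf(n1, n2)        # P(U <= u), u = 0..n1*n2
    p_le <- cdf[u + 1]
    p_ge <- 1 - if (u >= 1) cdf[u] else 0
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  nt <- table(pooled)
  n <- n1 + n2
  tie_term <- sum(nt^3 - nt) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    message("degenerate rank variance; p = 1 by convention")
    return(list(U = u, p = 1, method = "degenerate"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# Exact null CDF of the Mann-Whitney U for sample sizes (n1, n2) without
# ties, by the standard counting recursion
#   N(u; n1, n2) = N(u - n2; n1 - 1, n2) + N(u; n1, n2 - 1),
# equivalent to enumerating all choose(n1 + n2, n1) rank assignments.
mw_exact_cdf <- function(n1, n2) {
  counts <- list()
  for (i in 0:n1) {
    row <- list()
    for (j in 0:n2) {
      if (i == 0 || j == 0) {
        row[[j + 1]] <- rep(1, 1)  # only u = 0 possible
      } else {
        a <- c(rep(0, j), counts[[i]][[j + 1]])        # shift by n2' = j
        b <- row[[j]]                                  # same i, j - 1
        len <- max(length(a), length(b))
        a <- c(a, rep(0, len - length(a)))
        b <- c(b, rep(0, len - length(b)))
        row[[j + 1]] <- a + b
      }
    }
    counts[[i + 1]] <- row
  }
  freq <- counts[[n1 + 1]][[n2 + 1]]
  freq <- c(freq, rep(0, n1 * n2 + 1 - length(freq)))
  cumsum(freq) / sum(freq)
}
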