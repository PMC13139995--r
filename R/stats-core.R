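#' Exact binomial tail probabilities
#'
#' Upper tail `P(X >= k)` and lower tail `P(X <= k)` for
#' `X ~ Binomial(n, p0)`, computed in log-space via [stats::pbinom] so they
#' stay exact for n up to 1e6. Vectorized over `k`, `n`, `p0`.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @examples
#' binomialUpperTail(3, 10, 0.1) # 0.0702...
#' @export
binomialUpperTail <- function(k, n, p0) {
  stopifnot(all(k >= 0), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' @rdname binomialUpperTail
#' @export
binomialLowerTail <- function(k, n, p0) {
  stopifnot(all(k >= -1), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  stats::pbinom(k, n, p0, lower.tail = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classic FDR step-up: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped to 1, returned in the input
#' order. `NA` p-values propagate as `NA` and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    qs <- cummin(m / seq(m, 1) * pv[o])
    qv <- numeric(m)
    qv[o] <- pmin(1, qs)
    q[ok] <- qv
  }
  q
}

#' Wilcoxon rank-sum test with midranks and exact small-sample enumeration
#'
#' Two-sided rank-sum (Mann-Whitney) test. The statistic `W` is the
#' Mann-Whitney U for the first sample (rank sum of `x` minus
#' `n1 (n1 + 1) / 2`), using midranks for ties. For combined sample size
#' `n1 + n2 <= 10` (or `exact = TRUE`) the p-value is an exact enumeration
#' over all assignments of the pooled values to the two groups; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` switches at combined n = 10.
#' @return List with `statistic` (W), `p_value`, `n1`, `n2`, `method`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value # exact 0.1
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- n <= 10L

  if (exact) {
    idx <- utils::combn(n, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    us <- rs - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tiecorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  list(statistic = w, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, neither constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearsonCorTest <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}
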