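#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation over all tables with the observed
#' margins whose hypergeometric probability does not exceed that of the
#' observed table (with a relative tolerance of 1e-7 on the comparison, as is
#' conventional to absorb floating-point ties). Probabilities are computed in
#' log space via \code{lchoose}, so library-scale margins are safe.
#'
#' @param tab a 2x2 matrix of non-negative counts, or a numeric vector
#'   \code{c(a, b, c, d)} read row-wise (rows = samples, columns =
#'   in-class / not-in-class).
#' @return the two-sided p-value.
#' @examples
#' fisherExactTwoSided(matrix(c(1, 11, 9, 3), 2)) # ~0.00276
#' @export
fisherExactTwoSided <- function(tab) {
  t <- .as2x2(tab)
  a <- t[1, 1]; b <- t[1, 2]; cc <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  obs <- logp[match(a, x)]
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  min(1, p)
}

#' Chi-square test with Yates continuity correction for a 2x2 table
#'
#' The statistic is \eqn{\sum (|O - E| - 0.5)^2 / E} over the four cells,
#' with the correction clipped at zero when \eqn{|O - E| < 0.5}; the p-value
#' is the upper tail of the chi-square distribution with one degree of
#' freedom. Degenerate tables (a zero margin) return statistic 0, p = 1.
#'
#' @inheritParams fisherExactTwoSided
#' @return list with \code{statistic} and \code{p.value}.
#' @examples
#' chi2Yates(matrix(c(45277, 53417, 257563 - 45277, 526811 - 53417), 2))
#' @export
chi2Yates <- function(tab) {
  t <- .as2x2(tab)
  rs <- rowSums(t); cs <- colSums(t); N <- sum(t)
  if (any(rs == 0) || any(cs == 0))
    return(list(statistic = 0, p.value = 1))
  E <- outer(rs, cs) / N
  dev <- pmax(abs(t - E) - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)} in sorted order,
#' mapped back to the input order. \code{NA} p-values are propagated and do
#' not count towards \code{m}.
#'
#' @param p numeric vector of p-values in [0,1] (NAs allowed).
#' @return numeric vector of adjusted q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0,1]")
  m <- length(pv)
  q <- rep(NA_real_, length(p))
  if (m) {
    o <- order(pv)
    qs <- pmin(1, m * pv[o] / seq_len(m))
    qs <- rev(cummin(rev(qs)))
    qv <- numeric(m); qv[o] <- qs
    q[ok] <- qv
  }
  q
}

.as2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
    t <- tab
  } else if (is.numeric(tab) && length(tab) == 4L) {
    t <- matrix(tab, 2, 2, byrow = TRUE)
  } else stop("tab must be a 2x2 matrix or a length-4 numeric vector")
  if (any(is.na(t)) || any(t < 0) || any(t != round(t)))
    stop("tab must hold non-negative integer counts")
  if (sum(t) == 0) stop("at least one margin must be positive")
  t
}
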