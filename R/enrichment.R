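#' Upper-tail cumulative binomial enrichment probability
#'
#' Probability of observing at least `x` carriers in a set of `n` genes when
#' each gene independently carries the feature with background frequency `f`:
#' P(X >= x) with X ~ Binomial(n, f). This single kernel backs both the
#' cluster annotation enrichment and the upstream-motif enrichment tests.
#'
#' @param x Observed carrier count(s), 0 <= x <= n.
#' @param n Set size(s), positive integer.
#' @param f Background carrier frequency in [0, 1].
#' @return Numeric vector of upper-tail probabilities in [0, 1].
#' @examples
#' cbd_enrichment_p(5, 20, 0.1)  # ~0.0432
#' @export
cbd_enrichment_p <- function(x, n, f) {
  stopifnot(all(x >= 0), all(x <= n), all(f >= 0), all(f <= 1), all(n >= 1))
  # P(X >= x); pbinom's upper tail is strict, so shift by one
  stats::pbinom(x - 1, size = n, prob = f, lower.tail = FALSE)
}

#' Two-sided significance of a Pearson correlation coefficient
#'
#' t-test on r with n - 2 degrees of freedom, the standard significance
#' test for a product-moment correlation.
#'
#' @param r Correlation coefficient(s) in [-1, 1].
#' @param n Number of paired observations (must be >= 3).
#' @return Two-sided p-value(s); exact 0 when |r| = 1.
#' @keywords internal
pcc_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  if (any(!exact)) {
    rr <- r[!exact]
    tt <- abs(rr) * sqrt((n - 2) / (1 - rr^2))
    p[!exact] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
  p
}
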