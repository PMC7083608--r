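# Independent oracles used to cross-check the implementation. These stay
# deliberately separate from the code paths they verify.

## pooled 2x2 G-statistic: 2 * sum O * ln(O/E) over the
## (group x meth/unmeth) table built from summed counts
g_stat_pooled <- function(meth_a, cov_a, meth_b, cov_b) {
  O <- matrix(c(sum(meth_a), sum(cov_a) - sum(meth_a),
                sum(meth_b), sum(cov_b) - sum(meth_b)), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(ifelse(O > 0, O * log(O / E), 0))
}

## Weir-Cockerham theta through the nested-ANOVA mean squares
## (MSP/MSI/MSG route), an independent derivation of the same estimator
wc_theta_anova <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  p1 <- (c1[2] + 2 * c1[3]) / (2 * n1)
  p2 <- (c2[2] + 2 * c2[3]) / (2 * n2)
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  SSG <- 0.5 * (c1[2] + c2[2])
  ssi <- function(cc, p) 2 * (cc[1] * p^2 + cc[2] * (0.5 - p)^2 + cc[3] * (1 - p)^2)
  SSI <- ssi(c1, p1) + ssi(c2, p2)
  SSP <- 2 * (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)
  MSP <- SSP; MSI <- SSI / (N - 2); MSG <- SSG / N
  nc <- N - (n1^2 + n2^2) / N
  s2a <- (MSP - MSI) / (2 * nc)
  s2b <- (MSI - MSG) / 2
  den <- s2a + s2b + MSG
  if (den == 0) return(NA_real_)
  s2a / den
}

## exact permutation p for the one-tailed delta test by full enumeration
exhaustive_delta_p <- function(e, o) {
  pooled <- c(e, o)
  n <- length(pooled)
  ne <- length(e)
  d_obs <- mean(e) - mean(o)
  cmb <- utils::combn(n, ne)
  ds <- apply(cmb, 2, function(ix) mean(pooled[ix]) - mean(pooled[-ix]))
  sum(ds < d_obs) / ncol(cmb)
}

## classical two-sided hypergeometric p for a 2x2 table (a b / c d)
hyper_two_sided <- function(a, b, c, d) {
  m <- a + b
  x <- 0:m
  probs <- stats::dhyper(x, a + c, b + d, m)
  sum(probs[probs <= probs[a + 1] * (1 + 1e-7)])
}
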