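#' Beta-binomial distribution under the mean/overdispersion parameterization
#'
#' The allele-count model used throughout the ASE framework is a beta-binomial
#' with mean success probability `p` and overdispersion (intra-class
#' correlation) `rho`, mapped to the classical shape parameters as
#' `alpha = p * (1 - rho) / rho` and `beta = (1 - p) * (1 - rho) / rho`.
#' At `rho = 0` the distribution degenerates continuously to the binomial.
#'
#' @param x Integer vector of successes.
#' @param size Integer number of trials.
#' @param p Mean success probability, in (0, 1).
#' @param rho Overdispersion parameter, in [0, 1).
#' @param log Return log-probabilities?
#'
#' @return `dbetabinom()` returns (log-)probabilities; `rbetabinom()` returns
#'   random draws.
#' @export
dbetabinom <- function(x, size, p, rho, log = FALSE) {
  stopifnot(size >= 0, p > 0, p < 1, rho >= 0, rho < 1)
  if (rho == 0) {
    return(stats::dbinom(x, size, p, log = log))
  }
  ab <- betabinom_shapes(p, rho)
  lp <- lchoose(size, x) +
    lbeta(x + ab[["alpha"]], size - x + ab[["beta"]]) -
    lbeta(ab[["alpha"]], ab[["beta"]])
  lp[x < 0 | x > size] <- -Inf
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @param n Number of draws.
#' @export
rbetabinom <- function(n, size, p, rho) {
  stopifnot(all(p > 0), all(p < 1), length(rho) == 1, rho >= 0, rho < 1)
  if (rho == 0) {
    return(stats::rbinom(n, size, p))
  }
  theta <- stats::rbeta(n, p * (1 - rho) / rho,
                        (1 - p) * (1 - rho) / rho)
  stats::rbinom(n, size, theta)
}

betabinom_shapes <- function(p, rho) {
  c(alpha = p * (1 - rho) / rho, beta = (1 - p) * (1 - rho) / rho)
}

#' Upper-tail beta-binomial probability P(X >= m)
#'
#' Exact upper tail of the overdispersed allele-count model, the test
#' statistic of the per-SNP ASE tests. The tail is accumulated from the full
#' log-pmf built by the forward ratio recurrence
#' `pmf(x+1)/pmf(x) = (t-x)(x+alpha) / ((x+1)(t-x-1+beta))`,
#' summed with log-sum-exp; at `rho = 0` the exact binomial tail is used.
#'
#' @param m Observed major-allele read count (vectorised).
#' @param t Total read count (vectorised).
#' @param p Expected major-allele fraction under the null, in (0, 1).
#' @param rho Overdispersion, in [0, 1); 0 gives the binomial.
#'
#' @return Probability vector `P(X >= m)`; exactly 1 when `m <= 0`.
#' @examples
#' betabin_tail(10, 10, 0.5, 0)     # 0.5^10
#' betabin_tail(8, 10, 0.5, 0.05)
#' @export
betabin_tail <- function(m, t, p, rho = 0.05) {
  if (any(t < 0) || any(m > t)) {
    stop("betabin_tail: require 0 <= m <= t")
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("betabin_tail: p must lie strictly inside (0, 1)")
  }
  if (any(rho < 0) || any(rho >= 1)) {
    stop("betabin_tail: rho must lie in [0, 1)")
  }
  if (length(m) == 0 || length(t) == 0) return(numeric(0))
  n <- max(length(m), length(t), length(p), length(rho))
  m <- rep_len(m, n); t <- rep_len(t, n)
  p <- rep_len(p, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (rho[i] == 0) {
      stats::pbinom(m[i] - 1, t[i], p[i], lower.tail = FALSE)
    } else {
      betabin_tail_one(m[i], t[i], p[i], rho[i])
    }
  }
  out
}

betabin_tail_one <- function(m, t, p, rho) {
  if (m <= 0) return(1)
  ab <- betabinom_shapes(p, rho)
  a <- ab[["alpha"]]; b <- ab[["beta"]]
  # log pmf at 0 via B(a, t+b)/B(a, b) = prod_{i<t} (b+i)/(a+b+i);
  # the direct lbeta difference cancels catastrophically for tiny rho
  i <- seq_len(t) - 1
  lp0 <- sum(log(b + i) - log(a + b + i))
  x <- seq_len(t) - 1  # 0 .. t-1
  lratio <- log(t - x) + log(x + a) - log(x + 1) - log(t - x - 1 + b)
  lpmf <- c(lp0, lp0 + cumsum(lratio))
  tail <- lpmf[(m + 1):(t + 1)]
  mx <- max(tail)
  min(1, exp(mx) * sum(exp(tail - mx)))
}
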