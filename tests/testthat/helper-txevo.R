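# shared fixtures and independent oracles, built in code

# brute-force beta-binomial upper tail by direct log-beta pmf summation;
# independent of the package's recurrence-based implementation
oracle_betabin_tail <- function(m, t, p, rho) {
  if (m <= 0) return(1)
  if (rho == 0) {
    return(sum(vapply(m:t, function(x) stats::dbinom(x, t, p),
                      numeric(1))))
  }
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  sum(vapply(m:t, function(x) {
    exp(lchoose(t, x) + lbeta(x + a, t - x + b) - lbeta(a, b))
  }, numeric(1)))
}

# explicit-loop double-centring distance correlation (V-statistic)
oracle_dcor <- function(x, y) {
  n <- length(x)
  dc <- function(v) {
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) d[i, j] <- abs(v[i] - v[j])
    A <- matrix(0, n, n)
    gm <- mean(d)
    for (i in 1:n) for (j in 1:n) {
      A[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + gm
    }
    A
  }
  A <- dc(x); B <- dc(y)
  dcov2 <- 0; vx <- 0; vy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    vx <- vx + A[i, j]^2
    vy <- vy + B[i, j]^2
  }
  sqrt((dcov2 / n^2) / sqrt((vx / n^2) * (vy / n^2)))
}

# exhaustive hairpin oracle: every loop placement, explicit base pairing
oracle_hairpin <- function(seq_chr, offset, loop_len = 3:5, min_stem = 3) {
  pair <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_chr, "")[[1]]
  n <- length(chars)
  for (L in loop_len) {
    for (s in seq(offset - L + 1, offset)) {
      e <- s + L - 1
      if (s - min_stem < 1 || e + min_stem > n) next
      ok <- TRUE
      for (k in 1:min_stem) {
        # stem base k out from the loop 5' end pairs with base k out 3'
        if (pair[[chars[s - k]]] != chars[e + k]) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# two disjoint-support toy signatures over the 192 channels
toy_signatures <- function() {
  channels <- spectrum_channels()
  s1 <- as.numeric(grepl("\\[A>G\\]", channels) |
                     grepl("\\[T>C\\]", channels))
  s2 <- as.numeric(grepl("\\[C>T\\]", channels) |
                     grepl("\\[G>A\\]", channels))
  sig <- cbind(S1 = s1 / sum(s1), S2 = s2 / sum(s2))
  rownames(sig) <- channels
  sig
}

# multinomial spectrum drawn from a signature mixture
draw_spectrum <- function(n_variants, signatures, weights) {
  probs <- drop(as.matrix(signatures) %*% weights)
  counts <- drop(stats::rmultinom(1, n_variants, probs))
  structure(stats::setNames(as.integer(counts), rownames(signatures)),
            n_skipped = 0L, class = "txevo_spectrum")
}

tiny_cohort <- function(seed = 1, n_genes = 60, ...) {
  generate_cohort(cohort_config(n_tumours = 2, regions_per_tumour = 2,
                                n_genes = n_genes, snps_per_gene = 2,
                                seed = seed, ...))
}
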