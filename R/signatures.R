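#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||^2` subject to `x >= 0`. Used for signature
#' exposure fitting; deterministic, no randomness.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @param tol Dual-feasibility tolerance.
#' @return Nonnegative coefficient vector of length n.
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  P <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!P) && any(w[!P] > tol) && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      z[P] <- drop(qr.coef(qr(Ap), b))
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Fit signature exposures to a substitution spectrum
#'
#' Non-negative least squares of the count-normalized spectrum on the
#' (column-normalized) signature matrix; weights are renormalized to sum
#' to at most 1. Following the eligibility rule of the framework, regions
#' with 20 or fewer variants are refused (strictly more than 20 are
#' required).
#'
#' @param spectrum 192-channel count vector ([build_spectrum()]).
#' @param signatures 192 x k nonnegative matrix, columns the signatures
#'   (column sums 1; renormalized if not).
#' @param min_variants Eligibility threshold, exclusive (default 20).
#' @return One-row tibble of class `txevo_exposure_fit`: `eligible`,
#'   `n_variants`, `residual_cosine`, and one `exposure_*` column per
#'   signature (NA when ineligible).
#' @export
fit_exposures <- function(spectrum, signatures, min_variants = 20) {
  signatures <- as.matrix(signatures)
  stopifnot(length(spectrum) == nrow(signatures))
  if (is.null(colnames(signatures))) {
    colnames(signatures) <- paste0("S", seq_len(ncol(signatures)))
  }
  total <- sum(spectrum)
  k <- ncol(signatures)
  if (total <= min_variants) {
    out <- tibble::tibble(eligible = FALSE, n_variants = as.integer(total),
                          residual_cosine = NA_real_)
    out[paste0("exposure_", colnames(signatures))] <-
      as.list(rep(NA_real_, k))
    class(out) <- c("txevo_exposure_fit", class(out))
    return(out)
  }
  S <- sweep(signatures, 2, colSums(signatures), "/")
  y <- as.numeric(spectrum) / total
  w <- nnls_fit(S, y)
  if (sum(w) > 1) w <- w / sum(w)
  recon <- drop(S %*% w)
  rc <- if (sum(recon) == 0) 0 else cosine_similarity(y, recon)
  out <- tibble::tibble(eligible = TRUE, n_variants = as.integer(total),
                        residual_cosine = rc)
  out[paste0("exposure_", colnames(signatures))] <- as.list(w)
  class(out) <- c("txevo_exposure_fit", class(out))
  out
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' De novo signature extraction by non-negative matrix factorization
#'
#' Factorizes a 192 x n matrix of per-sample spectra into `k`
#' column-stochastic signatures and nonnegative exposures using
#' multiplicative Frobenius updates with multiple seeded restarts (the
#' lowest-loss restart is kept), making the result deterministic for a
#' given `seed`. This is a stand-in for heavier Bayesian nonparametric
#' extraction tools; `k` must be chosen by the user.
#'
#' @param spectra 192 x n nonnegative matrix (columns = samples).
#' @param k Number of signatures (<= number of samples).
#' @param n_restarts Random restarts (default 10).
#' @param max_iter Update iterations per restart (default 2000).
#' @param seed Seed controlling the restarts (default 1).
#' @return List of class `txevo_nmf`: `signatures` (192 x k,
#'   column-stochastic), `exposures` (k x n, scaled so
#'   `signatures %*% exposures` approximates the spectra),
#'   `exposures_norm` (per-sample proportions), `loss`.
#' @export
extract_signatures <- function(spectra, k, n_restarts = 10,
                               max_iter = 2000, seed = 1) {
  V <- as.matrix(spectra)
  if (any(V < 0)) stop("spectra must be nonnegative")
  if (sum(V) == 0) stop("all-zero spectra matrix")
  if (k > ncol(V)) stop("k exceeds the number of samples")
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  run_once <- function() {
    W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
    H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    }
    list(W = W, H = H, loss = sum((V - W %*% H)^2))
  }
  best <- with_local_seed(seed, {
    fits <- lapply(seq_len(n_restarts), function(i) run_once())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "loss"))]]
  })
  cs <- colSums(best$W)
  cs[cs == 0] <- 1
  W <- sweep(best$W, 2, cs, "/")
  H <- sweep(best$H, 1, cs, "*")
  colnames(W) <- rownames(H) <- paste0("S", seq_len(k))
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  hs <- colSums(H)
  hs[hs == 0] <- 1
  structure(list(signatures = W, exposures = H,
                 exposures_norm = sweep(H, 2, hs, "/"),
                 loss = best$loss),
            class = "txevo_nmf")
}

#' @export
print.txevo_nmf <- function(x, ...) {
  cat("NMF signature extraction:", ncol(x$signatures), "signatures x",
      ncol(x$exposures), "samples; loss", format(x$loss, digits = 4), "\n")
  invisible(x)
}

#' Intratumour heterogeneity of signature exposures
#'
#' Per tumour and signature: the standard deviation of the exposure
#' across the tumour's regions divided by the mean exposure of that
#' signature across the whole cohort. Undefined (flagged) when the cohort
#' mean is zero or the tumour has fewer than two regions.
#'
#' @param exposures Tibble with columns `tumour_id`, `region_id`,
#'   `signature`, `exposure`.
#' @return Tibble per tumour x signature: `sd_regions`, `cohort_mean`,
#'   `ith`, `defined`.
#' @export
signature_ith <- function(exposures) {
  cohort <- dplyr::group_by(exposures, .data$signature) |>
    dplyr::summarise(cohort_mean = mean(.data$exposure), .groups = "drop")
  dplyr::group_by(exposures, .data$tumour_id, .data$signature) |>
    dplyr::summarise(sd_regions = stats::sd(.data$exposure),
                     n_regions = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cohort, by = "signature") |>
    dplyr::mutate(
      defined = .data$cohort_mean > 0 & .data$n_regions >= 2,
      ith = ifelse(.data$defined,
                   .data$sd_regions / .data$cohort_mean, NA_real_)
    )
}
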