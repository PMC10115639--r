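#' Median-of-ratios normalization of a gene-by-region count matrix
#'
#' Size factor per region = median, over the reference genes, of the ratio
#' of the region's count to the gene's geometric mean across regions.
#' Genes containing any zero are excluded from the reference set. Counts
#' are divided by the size factor.
#'
#' @param counts Nonnegative numeric matrix, genes x regions (rownames =
#'   gene ids, colnames = region ids).
#' @return List with `normalized` (matrix) and `size_factors` (named
#'   vector).
#' @export
median_of_ratios_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two regions")
  if (any(counts < 0)) stop("counts must be nonnegative")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) stop("no gene has nonzero counts in all regions")
  log_gm <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm))
  })
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Filter to expressed genes
#'
#' Keeps genes with strictly more than `min_count` reads in at least
#' `min_frac` of the cohort's regions.
#'
#' @param counts Genes x regions count matrix.
#' @param min_count Count threshold, exclusive (default 5).
#' @param min_frac Minimum fraction of regions (default 0.2).
#' @return Character vector of retained gene ids (rownames).
#' @export
filter_expressed_genes <- function(counts, min_count = 5, min_frac = 0.2) {
  counts <- as.matrix(counts)
  keep <- rowMeans(counts > min_count) >= min_frac
  rownames(counts)[keep]
}

#' Empirical distance correlation (V-statistic)
#'
#' Distance correlation from double-centred pairwise-distance matrices
#' (the biased V-statistic estimator of the energy-statistics
#' formulation). It is 1 for exactly linearly dependent vectors and 0 only
#' under independence in the population version.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Value in [0, 1]; `NA` when either vector is constant (distance
#'   variance zero).
#' @export
distance_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  dcenter <- function(v) {
    d <- abs(outer(v, v, "-"))
    sweep(sweep(d, 1, rowMeans(d)), 2, colMeans(d)) + mean(d)
  }
  A <- dcenter(x)
  B <- dcenter(y)
  dcov2 <- sum(A * B) / n^2
  dvarx <- sum(A * A) / n^2
  dvary <- sum(B * B) / n^2
  if (dvarx <= 0 || dvary <= 0) return(NA_real_)
  sqrt(dcov2 / sqrt(dvarx * dvary))
}

#' Intratumour expression distance (I-TED)
#'
#' For every region of each multiregion tumour, I-TED is the mean, over
#' the other regions of the same tumour, of one minus the distance
#' correlation between the two regions' transformed expression profiles
#' over the cohort's top variable genes. Tumour-level I-TED is the median
#' over the tumour's regions — a pairwise construction that is independent
#' of the number of regions sampled.
#'
#' Counts are normalized by [median_of_ratios_normalize()], restricted to
#' expressed genes ([filter_expressed_genes()]), transformed (default
#' `log2(x + 1)` as a variance-stabilizing stand-in), and the `n_top` most
#' variable genes across the whole cohort are used (variance of the
#' transformed values; ties broken by gene id).
#'
#' @param counts Genes x regions count matrix for the whole cohort.
#' @param region_info Tibble with columns `region_id` (matching colnames)
#'   and `tumour_id`.
#' @param n_top Number of most-variable genes (default 500).
#' @param transform Function applied to the normalized matrix (default
#'   `log2(x+1)`).
#' @param min_count,min_frac Passed to [filter_expressed_genes()].
#' @return Tibble: `tumour_id`, `region_id`, `ited_region`,
#'   `ited_tumour`; single-region tumours are flagged `computed = FALSE`.
#' @export
ited <- function(counts, region_info, n_top = 500,
                 transform = function(x) log2(x + 1),
                 min_count = 5, min_frac = 0.2) {
  counts <- as.matrix(counts)
  stopifnot(all(colnames(counts) %in% region_info$region_id))
  keep <- filter_expressed_genes(counts, min_count, min_frac)
  if (length(keep) < 2) stop("fewer than two expressed genes")
  norm <- median_of_ratios_normalize(counts[keep, , drop = FALSE])
  tr <- transform(norm$normalized)
  v <- apply(tr, 1, stats::var)
  ord <- order(-v, rownames(tr))
  top <- tr[ord[seq_len(min(n_top, nrow(tr)))], , drop = FALSE]

  info <- tibble::as_tibble(region_info)
  res <- info |>
    dplyr::group_by(.data$tumour_id) |>
    dplyr::group_map(function(g, key) {
      regions <- g$region_id
      if (length(regions) < 2) {
        return(tibble::tibble(tumour_id = key$tumour_id,
                              region_id = regions,
                              ited_region = NA_real_,
                              ited_tumour = NA_real_,
                              computed = FALSE))
      }
      dmat <- matrix(0, length(regions), length(regions))
      for (i in seq_along(regions)) {
        for (j in seq_along(regions)) {
          if (i < j) {
            dc <- distance_correlation(top[, regions[i]],
                                       top[, regions[j]])
            dmat[i, j] <- dmat[j, i] <- 1 - dc
          }
        }
      }
      per_region <- rowSums(dmat) / (length(regions) - 1)
      tibble::tibble(tumour_id = key$tumour_id, region_id = regions,
                     ited_region = per_region,
                     ited_tumour = stats::median(per_region),
                     computed = TRUE)
    }) |>
    dplyr::bind_rows()
  res
}

#' Model folded RNA B-allele frequency given tumour transcript fraction
#'
#' Expected major-allele fraction of RNA reads at a heterozygous SNP in a
#' segment with tumour allele-specific copy numbers `(n_major, n_minor)`
#' when a fraction `rho` of transcripts derives from tumour cells and the
#' non-tumour component is diploid heterozygous:
#' `(rho * n_major + (1 - rho)) / (rho * (n_major + n_minor) + 2 * (1 - rho))`.
#'
#' @param rho Tumour transcript fraction, in [0, 1].
#' @param n_major,n_minor Integer allele-specific copy numbers.
#' @return Expected folded BAF in [0.5, 1] (for `n_major >= n_minor`).
#' @export
model_folded_baf <- function(rho, n_major, n_minor) {
  (rho * n_major + (1 - rho)) /
    (rho * (n_major + n_minor) + 2 * (1 - rho))
}

#' Estimate the tumour transcript fraction from RNA allele frequencies
#'
#' The ploidy-adjusted proportion of all transcripts in a bulk sample that
#' derive from tumour cells. SNP-level RNA BAFs (oriented on the DNA major
#' allele) are first averaged within each copy-number segment and the
#' segment mean is folded onto `[0.5, 1]`; a grid search over `rho` in
#' [0, 1] (step `grid_step`) then minimizes the SNP-weighted squared error
#' of the folded segment means against [model_folded_baf()]. Aggregating
#' before folding matters: folding individual noisy BAFs biases
#' near-balanced segments upward, whereas segment means are nearly
#' noise-free. Balanced segments contribute a `rho`-independent constant
#' and the fit is unidentifiable (flagged) when every segment is
#' allelically balanced.
#'
#' @param snps Tibble with columns `baf` (RNA B-allele frequency on the
#'   major allele), `major_cn`, `minor_cn` (integer allele-specific copy
#'   numbers of the containing segment) and optionally `segment_id`
#'   (defaults to one segment per distinct copy-number pair).
#' @param grid_step Grid resolution (default 0.001).
#' @return One-row tibble: `rho_rna`, `fit_loss`, `identifiable`,
#'   `n_snps`.
#' @export
estimate_transcript_fraction <- function(snps, grid_step = 0.001) {
  snps <- tibble::as_tibble(snps)
  if (nrow(snps) == 0) stop("no SNPs supplied")
  if (!"segment_id" %in% names(snps)) {
    snps$segment_id <- paste0(snps$major_cn, "_", snps$minor_cn)
  }
  segs <- snps |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      baf = pmax(mean(.data$baf), 1 - mean(.data$baf)),
      n_major = pmax(.data$major_cn[1], .data$minor_cn[1]),
      n_minor = pmin(.data$major_cn[1], .data$minor_cn[1]),
      n = dplyr::n(), .groups = "drop")
  if (all(segs$n_major == segs$n_minor)) {
    return(tibble::tibble(rho_rna = NA_real_, fit_loss = NA_real_,
                          identifiable = FALSE, n_snps = nrow(snps)))
  }
  grid <- seq(0, 1, by = grid_step)
  loss <- vapply(grid, function(r) {
    sum(segs$n * (segs$baf -
                    model_folded_baf(r, segs$n_major, segs$n_minor))^2)
  }, numeric(1))
  best <- which.min(loss)
  tibble::tibble(rho_rna = grid[best], fit_loss = loss[best],
                 identifiable = TRUE, n_snps = nrow(snps))
}
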