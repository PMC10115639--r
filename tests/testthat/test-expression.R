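test_that("median-of-ratios normalization: scale invariance and reference set", {
  set.seed(1)
  a <- rpois(50, 100) + 1
  counts <- cbind(r1 = a, r2 = 2 * a)
  rownames(counts) <- paste0("g", 1:50)
  res <- median_of_ratios_normalize(counts)
  expect_equal(res$size_factors[["r2"]] / res$size_factors[["r1"]], 2)
  expect_equal(res$normalized[, "r1"], res$normalized[, "r2"])
  # identical regions -> size factors 1
  same <- cbind(r1 = a, r2 = a)
  rownames(same) <- paste0("g", 1:50)
  expect_equal(unname(median_of_ratios_normalize(same)$size_factors),
               c(1, 1))
  # genes with zeros are excluded from the reference set: forcing a huge
  # count into a zero-containing gene must not move the size factors
  z <- counts
  z[1, 1] <- 0
  res_z <- median_of_ratios_normalize(z)
  z2 <- z
  z2[1, 2] <- 1e6
  expect_equal(median_of_ratios_normalize(z2)$size_factors,
               res_z$size_factors)
  expect_error(median_of_ratios_normalize(matrix(c(0, 1, 1, 0), 2)),
               "nonzero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  counts <- matrix(rnbinom(300, mu = 50, size = 5) + 1, 60, 5)
  rownames(counts) <- paste0("g", 1:60)
  colnames(counts) <- paste0("r", 1:5)
  ours <- median_of_ratios_normalize(counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("expressed-gene filter uses strict counts and region fraction", {
  counts <- rbind(
    kept = c(6, 6, rep(0, 8)),       # >5 in 2/10 regions
    strict = rep(5, 10),             # 5 is not > 5
    rare = c(6, rep(0, 9)))          # only 1/10 regions
  colnames(counts) <- paste0("r", 1:10)
  expect_equal(filter_expressed_genes(counts), "kept")
})

test_that("distance correlation matches the explicit-loop oracle", {
  expect_equal(distance_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               oracle_dcor(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(distance_correlation(x, y), oracle_dcor(x, y),
                 tolerance = 1e-12)
    expect_equal(distance_correlation(x, y), distance_correlation(y, x))
  }
  expect_equal(distance_correlation(1:5, 3 - 2 * (1:5)), 1)
  expect_equal(distance_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_true(is.na(distance_correlation(c(1, 1, 1), c(1, 2, 3))))
})

sim_expr <- function(seed = 4, ...) {
  co <- generate_cohort(cohort_config(n_tumours = 3,
                                      regions_per_tumour = 2,
                                      n_genes = 300, seed = seed))
  simulate_expression(co, ...)
}

test_that("identical regions give I-TED 0; two-region tumours are symmetric", {
  sim <- sim_expr()
  counts <- sim$counts
  # duplicate one region exactly: its tumour has I-TED 0
  counts2 <- cbind(counts[, 1], counts[, 1], counts[, 3:6])
  colnames(counts2) <- colnames(counts)
  info <- sim$region_info
  res <- ited(counts2, info, n_top = 100)
  t1 <- res[res$tumour_id == "T01", ]
  expect_equal(t1$ited_region, c(0, 0))
  expect_equal(t1$ited_tumour, c(0, 0))
  # two-region tumours: both regions share the same value = median
  res_full <- ited(counts, info, n_top = 100)
  for (tt in unique(res_full$tumour_id)) {
    rows <- res_full[res_full$tumour_id == tt, ]
    expect_equal(rows$ited_region[1], rows$ited_region[2])
    expect_equal(rows$ited_tumour[1], rows$ited_region[1])
  }
})

test_that("I-TED is invariant to region relabelling and post-hoc scaling", {
  sim <- sim_expr(seed = 5)
  info <- sim$region_info
  res <- ited(sim$counts, info, n_top = 100)
  # relabel (permute columns)
  perm <- sample(ncol(sim$counts))
  res_p <- ited(sim$counts[, perm], info, n_top = 100)
  merged <- dplyr::left_join(res, res_p, by = c("tumour_id", "region_id"))
  expect_equal(merged$ited_region.x, merged$ited_region.y,
               tolerance = 1e-12)
  # doubling one region's library is absorbed by normalization
  sc <- sim$counts
  sc[, 2] <- sc[, 2] * 2
  # scaling is absorbed by the size factors up to a cohort-wide
  # constant, which interacts only with the +1 pseudo-count
  res_s <- ited(sc, info, n_top = 100)
  expect_equal(res$ited_region, res_s$ited_region, tolerance = 1e-2)
})

test_that("single-region tumours are flagged, not computed", {
  sim <- sim_expr(seed = 6)
  info <- sim$region_info[-1, ]  # drop one region: T01 has 1 region left
  res <- ited(sim$counts[, -1], info, n_top = 100)
  t1 <- res[res$tumour_id == "T01", ]
  expect_false(t1$computed)
  expect_true(is.na(t1$ited_region))
})

test_that("transcript fraction: exact recovery, unidentifiable and null cases", {
  segs <- tibble::tibble(major_cn = rep(c(2, 3), each = 10),
                         minor_cn = 1)
  noiseless <- dplyr::mutate(segs,
                             baf = model_folded_baf(0.8, major_cn,
                                                    minor_cn))
  fit <- estimate_transcript_fraction(noiseless)
  expect_equal(fit$rho_rna, 0.8, tolerance = 1e-9)
  expect_true(fit$identifiable)
  # all segments balanced: constant model, flagged
  bal <- tibble::tibble(baf = c(0.5, 0.52), major_cn = 1, minor_cn = 1)
  expect_false(estimate_transcript_fraction(bal)$identifiable)
  # BAF 0.5 everywhere with imbalance present -> no tumour signal
  flat <- dplyr::mutate(segs, baf = 0.5)
  expect_equal(estimate_transcript_fraction(flat)$rho_rna, 0)
  expect_error(estimate_transcript_fraction(segs[0, ]), "no SNPs")
})

test_that("transcript fraction exceeds DNA purity when tumour cells
           transcribe more per copy", {
  # stated world: tumour cells produce 2x transcripts per chromosome copy;
  # the RNA admixture then behaves like an inflated effective fraction
  set.seed(7)
  purity <- 0.5
  boost <- 2
  rho_eff <- purity * boost / (purity * boost + (1 - purity))
  segs <- tibble::tibble(major_cn = rep(c(2, 3, 2), 20),
                         minor_cn = rep(c(1, 1, 0), 20))
  t <- 120
  m <- rbetabinom(nrow(segs), t,
                  model_folded_baf(rho_eff, segs$major_cn,
                                   segs$minor_cn), 0.02)
  fit <- estimate_transcript_fraction(dplyr::mutate(segs, baf = m / t))
  expect_gt(fit$rho_rna, purity)
})
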