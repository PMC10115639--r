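test_that("configuration invariants are enforced", {
  expect_error(cohort_config(purity_range = c(0, 0.5)), "purity")
  expect_error(cohort_config(purity_range = c(0.9, 0.5)), "purity")
  expect_error(cohort_config(rna_overdispersion = 1), "overdispersion")
  expect_error(cohort_config(n_genes = 0), "integers")
  expect_error(cohort_config(depth_mean = 0), "positive")
  expect_error(ase_truth_config(ase_allelic_ratio = 0.5), "allelic_ratio")
  expect_error(ase_truth_config(frac_cn_indep_ase = 1.5), "fractions")
  expect_error(generate_cohort(list()), "cohort_config")
})

test_that("cohort generation: determinism, purity bounds, bookkeeping", {
  cfg <- cohort_config(n_tumours = 5, regions_per_tumour = 3,
                       n_genes = 200, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$regions), 15)
  expect_equal(nrow(a$cn), 15 * 200)
  # every gene in every region has exactly one CN pair
  expect_equal(nrow(dplyr::distinct(a$cn, region_id, gene_id)),
               nrow(a$cn))
  expect_true(all(a$cn$major_cn >= a$cn$minor_cn))
  expect_true(all(a$cn$minor_cn >= 0))
  expect_true(all(a$cn$major_cn + a$cn$minor_cn > 0))
  # degenerate purity interval
  pure <- generate_cohort(cohort_config(purity_range = c(1, 1),
                                        seed = 2))
  expect_true(all(pure$regions$purity == 1))
  # range-valued regions per tumour
  rng <- generate_cohort(cohort_config(n_tumours = 20,
                                       regions_per_tumour = c(2, 4),
                                       n_genes = 10, seed = 3))
  per <- table(rng$regions$tumour_id)
  expect_true(all(per >= 2 & per <= 4))
})

test_that("ASE counts: seeded determinism and exhaustive truth labels", {
  co <- tiny_cohort(seed = 21)
  s1 <- simulate_ase_counts(co)
  s2 <- simulate_ase_counts(co)
  expect_identical(s1, s2)
  # one label per gene per tumour, from the fixed vocabulary
  expect_equal(nrow(s1$truth), 2 * 60)
  expect_true(all(s1$truth$true_class %in% c("none", "cn_dep",
                                             "cn_indep")))
  expect_true(all(s1$snps$rna_major_count + s1$snps$rna_minor_count > 0))
})

test_that("null truth config with balanced CN yields zero ASE genes", {
  co <- tiny_cohort(seed = 22)
  co$cn$major_cn <- 1
  co$cn$minor_cn <- 1
  sim <- simulate_ase_counts(co, ase_truth_config(
    frac_cn_indep_ase = 0, frac_imprinted = 0, frac_truncating_nmd = 0))
  expect_true(all(sim$truth$true_class == "none"))
  expect_true(all(sim$snps$expected_rna_ratio == 0.5))
})

test_that("sigma = 0 gives exactly binomial per-SNP variance", {
  co <- generate_cohort(cohort_config(n_tumours = 1,
                                      regions_per_tumour = 1,
                                      n_genes = 1, snps_per_gene = 1,
                                      purity_range = c(1, 1),
                                      rna_overdispersion = 0, seed = 4))
  co$cn$major_cn <- 1
  co$cn$minor_cn <- 1
  set.seed(23)
  t <- 40
  draws <- rbetabinom(1e4, t, 0.5, 0)
  expect_lt(abs(var(draws) - t * 0.25), 0.4)
  # and the generator respects the configured sigma = 0 pathway
  sim <- simulate_ase_counts(co)
  expect_equal(sim$snps$expected_rna_ratio, 0.5)
})

test_that("the labelled fraction of CN-independent genes matches the config", {
  co <- generate_cohort(cohort_config(n_tumours = 4,
                                      regions_per_tumour = 2,
                                      n_genes = 500, seed = 24))
  sim <- simulate_ase_counts(co, ase_truth_config(
    frac_cn_indep_ase = 0.1))
  frac <- mean(sim$truth$true_class == "cn_indep")
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.13)
  shifted <- dplyr::inner_join(
    sim$snps,
    dplyr::filter(sim$truth, true_class == "cn_indep"),
    by = c("tumour_id", "gene_id"))
  expect_true(all(shifted$expected_rna_ratio >= 0.9))
})

test_that("expression simulation: dimensions, limits, tumour structure", {
  co <- generate_cohort(cohort_config(n_tumours = 3,
                                      regions_per_tumour = 2,
                                      n_genes = 400, seed = 25))
  sim <- simulate_expression(co)
  expect_equal(dim(sim$counts), c(400, 6))
  expect_identical(simulate_expression(co)$counts, sim$counts)
  # within-tumour correlation exceeds between-tumour correlation
  cors <- cor(log1p(sim$counts))
  info <- sim$region_info
  same <- outer(info$tumour_id, info$tumour_id, "==") &
    upper.tri(cors)
  diff_t <- outer(info$tumour_id, info$tumour_id, "!=") &
    upper.tri(cors)
  expect_gt(mean(cors[same]), mean(cors[diff_t]))
  # zero region perturbation: regions of a tumour identical up to noise
  flat <- simulate_expression(co, frac_perturbed = 0,
                              region_effect_sd = 0)
  expect_length(flat$truth$perturbed[[1]], 0)
  # counting noise alone leaves a small residual distance, well below
  # the perturbed setting
  it_flat <- ited(flat$counts, flat$region_info, n_top = 100)
  it_pert <- ited(sim$counts, sim$region_info, n_top = 100)
  expect_lt(max(it_flat$ited_region), 0.2)
  expect_lt(mean(it_flat$ited_region), mean(it_pert$ited_region))
})

test_that("transcriptome generation covers all contexts and injects cassettes", {
  tx <- simulate_transcriptome(n_transcripts = 10,
                               transcript_length = 1200,
                               n_homopolymer_cassettes = 3, seed = 26)
  expect_equal(nrow(tx$transcripts), 10)
  expect_equal(nrow(tx$cassettes), 3)
  for (i in seq_len(3)) {
    s <- tx$transcripts$sequence[tx$transcripts$transcript_id ==
                                   tx$cassettes$transcript_id[i]]
    run <- substr(s, tx$cassettes$pos[i] - 4, tx$cassettes$pos[i] + 4)
    expect_equal(run, strrep(tx$cassettes$base[i], 9))
  }
  # all 64 mRNA-sense triplets available somewhere
  idx <- txevo:::context_index(tx$transcripts)
  expect_equal(length(unique(idx$key)), 64)
})

test_that("variant simulation: point-mass channel, decoy design, truth", {
  co <- generate_cohort(cohort_config(n_tumours = 1,
                                      regions_per_tumour = 2,
                                      n_genes = 10, seed = 27))
  txome <- simulate_transcriptome(seed = 27)
  channels <- spectrum_channels()
  point <- matrix(0, 192, 1,
                  dimnames = list(channels, "S1"))
  point["T[A>G]C", 1] <- 1
  sim <- simulate_rna_variants(co, point, c(S1 = 1), txome,
                               variants_per_region = 30)
  real <- dplyr::filter(sim$variants, !is_decoy)
  expect_true(all(real$channel_true == "T[A>G]C"))
  sp <- build_spectrum(real)
  expect_equal(unname(sp["T[A>G]C"]), nrow(real))
  # zero decoys: everything passes every filter
  expect_true(all(filter_variants(sim$variants)$pass))
  # decoys fail exactly their designed rule
  sim_d <- simulate_rna_variants(
    co, point, c(S1 = 1), txome, variants_per_region = 25,
    decoys = c(low_rna_coverage = 2, low_alt_support = 2, low_vaf = 2,
               low_germline_depth = 2, low_tumour_depth = 2,
               dna_support = 2, homopolymer_flank = 2, blacklist = 2))
  res <- filter_variants(sim_d$variants, blacklist = sim_d$blacklist)
  real_rows <- !res$is_decoy
  expect_true(all(res$pass[real_rows]))
  dec <- res[!real_rows, ]
  expect_true(all(!dec$pass))
  expect_true(all(dec$n_flags == 1))
  hit <- vapply(seq_len(nrow(dec)), function(i) {
    dec[[paste0("flag_", dec$decoy_rule[i])]][i]
  }, logical(1))
  expect_true(all(hit))
  # requesting an impossible channel errors with its name
  empty_tx <- list(transcripts = tibble::tibble(
    transcript_id = "TX001", strand = "+",
    sequence = strrep("A", 200)), cassettes = tibble::tibble())
  expect_error(simulate_rna_variants(co, point, c(S1 = 1), empty_tx,
                                     variants_per_region = 1),
               "T\\[A>G\\]C")
})

test_that("seeded variant simulation is reproducible end to end", {
  co <- tiny_cohort(seed = 28, n_genes = 10)
  txome <- simulate_transcriptome(seed = 28)
  sig <- toy_signatures()
  a <- simulate_rna_variants(co, sig, c(S1 = 0.5, S2 = 0.5), txome,
                             variants_per_region = 40)
  b <- simulate_rna_variants(co, sig, c(S1 = 0.5, S2 = 0.5), txome,
                             variants_per_region = 40)
  expect_identical(a$variants, b$variants)
  expect_equal(sum(a$exposures_truth$exposure),
               nrow(co$regions) * 1)
})
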