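test_that("independent filter reproduces binomial closed forms", {
  expect_true(independent_filter(10, 0.5))    # 0.5^10 = 0.0009765625
  expect_false(independent_filter(9, 0.5))    # 0.5^9  = 0.001953125
  expect_false(independent_filter(20, 0.9))   # 0.9^20 ~ 0.1216
  expect_false(independent_filter(50, 1))     # LOH: p = 1
  expect_false(independent_filter(50, 0))     # inconsistent with het
  expect_true(independent_filter(100, 0.9))   # 0.9^100 ~ 2.7e-5
})

make_snp <- function(m, minor, major_cn = 1, minor_cn = 1, ...) {
  tibble::tibble(snp_id = "s1", gene_id = "g1", tumour_id = "T1",
                 region_id = "T1_R1", rna_major_count = m,
                 rna_minor_count = minor, major_cn = major_cn,
                 minor_cn = minor_cn, ...)
}

test_that("per-SNP tests give exact binomial values at rho = 0", {
  res <- ase_test_snps(make_snp(5, 5), rho = 0)
  expect_equal(res$p_eq1, 0.623046875)  # P(Bin(10, 0.5) >= 5)
  expect_equal(res$p_eq3, 1 - 0.623046875)
  expect_equal(res$p_eq4, 0.623046875)  # cpn_ratio 0.5
})

test_that("per-SNP tails agree with the summation oracle", {
  res <- ase_test_snps(make_snp(10, 0), rho = 0.05)
  expect_equal(res$p_eq1, oracle_betabin_tail(10, 10, 0.5, 0.05),
               tolerance = 1e-12)
  expect_equal(res$p_eq3, 1 - oracle_betabin_tail(10, 10, 0.5, 0.05),
               tolerance = 1e-12)
  res2 <- ase_test_snps(make_snp(12, 3, major_cn = 2, minor_cn = 1),
                        rho = 0.05)
  expect_equal(res2$p_eq4, oracle_betabin_tail(12, 15, 2 / 3, 0.05),
               tolerance = 1e-12)
})

test_that("coverage threshold is strict and LOH yields NA eq4", {
  res <- ase_test_snps(make_snp(4, 4))  # t = 8: not evaluable
  expect_false(res$evaluable)
  expect_true(is.na(res$p_eq1))
  res9 <- ase_test_snps(make_snp(5, 4))  # t = 9 evaluable
  expect_true(res9$evaluable)
  loh <- ase_test_snps(make_snp(9, 1, major_cn = 2, minor_cn = 0))
  expect_true(is.na(loh$p_eq4))
  expect_false(loh$passes_independent_filter)
})

test_that("blacklisted SNPs are not evaluable", {
  snp <- make_snp(10, 2, chrom = "chr1", pos = 500L)
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 600))
  expect_false(ase_test_snps(snp, blacklist = bl)$evaluable)
  bl2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(600, 700))
  expect_true(ase_test_snps(snp, blacklist = bl2)$evaluable)
})

test_that("Fisher combination: identity, unity and oracle value", {
  expect_equal(fisher_combine(0.5), 0.5)
  expect_equal(fisher_combine(c(1, 1)), 1)
  # independent oracle: numerical chi-square survival integral on 4 df
  stat <- -2 * (log(0.01) + log(0.02))
  dens <- function(x) x * exp(-x / 2) / 4  # chi^2_4 density
  oracle <- integrate(dens, stat, Inf, rel.tol = 1e-12)$value
  expect_equal(stat, 17.034, tolerance = 1e-4)
  expect_equal(fisher_combine(c(0.01, 0.02)), oracle, tolerance = 1e-9)
})

test_that("gene combination uses only evaluable filter-passing SNPs", {
  snps <- dplyr::bind_rows(
    make_snp(9, 1),                 # t = 10, passes filter
    make_snp(30, 2),                # t = 32, passes
    make_snp(4, 4),                 # t = 8, not evaluable
    make_snp(6, 3))                 # t = 9, filter fails (0.5^9)
  res <- ase_test_snps(snps)
  comb <- ase_combine_genes(res)
  expect_equal(comb$n_snps_used, 2L)
  used <- res$evaluable & res$passes_independent_filter
  expect_equal(comb$p_combined_A, fisher_combine(res$p_eq1[used]))
  expect_equal(comb$p_combined_B,
               fisher_combine(pmin(res$p_eq3, res$p_eq4)[used]))
})

test_that("classification rule is applied per sample with BH", {
  gr <- tibble::tibble(
    tumour_id = "T1", region_id = "T1_R1",
    gene_id = paste0("g", 1:4), n_snps_used = c(2L, 2L, 2L, 0L),
    p_combined_A = c(1e-6, 1e-6, 0.8, NA),
    p_combined_B = c(0.9, 1e-6, 0.9, NA),
    ref_overexpressed = NA)
  cl <- ase_classify(gr)
  expect_equal(cl$label,
               c("cn_dependent_ase", "cn_independent_ase", "biallelic",
                 "not_evaluable"))
  # labels partition the gene set
  expect_true(all(table(cl$gene_id) == 1))
  expect_equal(nrow(ase_classify(gr[0, ])), 0)
})

test_that("enrichment odds ratios match cross-product arithmetic", {
  sym <- enrichment_odds_ratio(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  big <- enrichment_odds_ratio(matrix(c(10, 90, 1, 899), 2,
                                      byrow = TRUE))
  expect_equal(big$odds_ratio, 10 * 899 / (90 * 1))
  perfect <- enrichment_odds_ratio(matrix(c(10, 0, 0, 10), 2,
                                          byrow = TRUE),
                                   alternative = "greater")
  expect_equal(perfect$p_value, 1 / choose(20, 10))  # hypergeometric
  empty <- enrichment_odds_ratio(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_true(empty$degenerate)
})

test_that("CN-independent ASE ITH follows the homogeneous-fraction rule", {
  lab <- function(gene, regions, ci_in, eval_in = regions) {
    tidyr::expand_grid(gene_id = gene, region_id = eval_in) |>
      dplyr::mutate(tumour_id = "T1",
                    label = ifelse(region_id %in% ci_in,
                                   "cn_independent_ase", "biallelic"))
  }
  regions <- paste0("R", 1:3)
  # all CN-indep genes homogeneous -> ITH 0
  full <- dplyr::bind_rows(lab("g1", regions, regions),
                           lab("g2", regions, regions))
  expect_equal(cn_indep_ase_ith(full)$ith, 0)
  # 2 of 4 qualifying genes homogeneous -> ITH 0.5
  half <- dplyr::bind_rows(
    lab("g1", regions, regions), lab("g2", regions, regions),
    lab("g3", regions, regions[1:2]), lab("g4", regions, regions[1:2]))
  expect_equal(cn_indep_ase_ith(half)$ith, 0.5)
  # no gene recurrent -> denominator 0, flagged
  none <- dplyr::bind_rows(lab("g1", regions, regions[1]),
                           lab("g2", regions, regions[2]))
  res <- cn_indep_ase_ith(none)
  expect_false(res$defined)
  expect_true(is.na(res$ith))
  # a gene evaluable in only 1 region cannot count as homogeneous
  single <- lab("g1", regions, "R1", eval_in = "R1")
  expect_equal(cn_indep_ase_ith(single)$n_homogeneous, 0L)
})

test_that("reference bias ratio and degenerate flag", {
  mk <- function(n_ref, n_alt) {
    tibble::tibble(tumour_id = "T1", region_id = "R1",
                   gene_id = paste0("g", seq_len(n_ref + n_alt)),
                   label = "cn_independent_ase",
                   ref_overexpressed = rep(c(TRUE, FALSE),
                                           c(n_ref, n_alt)))
  }
  expect_equal(reference_bias(mk(10, 10))$bias_ratio, 1)
  expect_equal(reference_bias(mk(15, 5))$bias_ratio, 3)
  deg <- reference_bias(mk(4, 0))
  expect_false(deg$defined)
  expect_true(is.na(deg$bias_ratio))
})

test_that("promoter ASM requires three consecutive qualifying CpGs", {
  cpg <- function(m, lo = 0.3, hi = 0.6) {
    tibble::tibble(position = seq_along(m), m_t = m,
                   hdi_low = lo, hdi_high = hi)
  }
  expect_equal(classify_promoter_asm(cpg(c(0.5, 0.5, 0.5)))$class, "asm")
  expect_equal(classify_promoter_asm(cpg(c(0.5, 0.5)))$class, "not_asm")
  # a non-qualifying point estimate breaks the run
  broken <- classify_promoter_asm(cpg(c(0.5, 0.1, 0.5, 0.5)))
  expect_equal(broken$class, "not_asm")
  expect_equal(broken$max_run, 2L)
  # wide HDI disqualifies a locus even with a mid-range point estimate
  wide <- tibble::tibble(position = 1:3, m_t = 0.5,
                         hdi_low = c(0.1, 0.3, 0.3),
                         hdi_high = c(0.6, 0.6, 0.6))
  expect_equal(classify_promoter_asm(wide)$class, "not_asm")
  expect_equal(classify_promoter_asm(cpg(numeric(0)))$class, "not_asm")
})

msai_snp <- function(region, hap1_dna, hap2_dna, hap1_rna, hap2_rna,
                     gene = "g1") {
  tibble::tibble(
    snp_id = paste0(gene, "_", region), gene_id = gene,
    tumour_id = "T1", region_id = region, phase_block_id = gene,
    major_haplotype = 1L,
    dna_major_count = hap1_dna, dna_minor_count = hap2_dna,
    rna_major_count = hap1_rna, rna_minor_count = hap2_rna)
}

test_that("genomic MSAI flags opposite DNA-major haplotypes", {
  snps <- dplyr::bind_rows(
    msai_snp("R1", 90, 10, 50, 50),   # hap1 gained
    msai_snp("R2", 10, 90, 50, 50))   # hap2 gained
  cl <- tibble::tibble(tumour_id = "T1", region_id = c("R1", "R2"),
                       gene_id = "g1", label = "cn_dependent_ase")
  ev <- detect_msai(snps, cl)
  expect_equal(ev$type, "genomic")
  # single region: nothing to mirror
  expect_equal(nrow(detect_msai(snps[1, ], cl[1, ])), 0)
})

test_that("genomic-transcriptomic MSAI: balanced region silences the
           haplotype retained elsewhere", {
  snps <- dplyr::bind_rows(
    msai_snp("R1", 95, 5, 95, 5),    # LOH of hap2, CN-dep ASE
    msai_snp("R2", 95, 5, 95, 5),
    msai_snp("R3", 50, 50, 5, 95))   # balanced DNA, RNA favours hap2
  cl <- tibble::tibble(
    tumour_id = "T1", region_id = c("R1", "R2", "R3"), gene_id = "g1",
    label = c("cn_dependent_ase", "cn_dependent_ase",
              "cn_independent_ase"))
  ev <- detect_msai(snps, cl)
  expect_true("genomic_transcriptomic" %in% ev$type)
  gt <- ev[ev$type == "genomic_transcriptomic", ]
  expect_equal(gt$region_a, "R3")
  expect_true(gt$region_b %in% c("R1", "R2"))
})

test_that("unphased genes are skipped with a notice", {
  snps <- msai_snp("R1", 90, 10, 50, 50)
  snps$phase_block_id <- NA_character_
  cl <- tibble::tibble(tumour_id = "T1", region_id = "R1",
                       gene_id = "g1", label = "biallelic")
  expect_message(ev <- detect_msai(snps, cl), "unphased")
  expect_equal(nrow(ev), 0)
})
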