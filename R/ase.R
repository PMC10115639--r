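#' Independent filtering of heterozygous SNPs before ASE testing
#'
#' To ease the multiple-testing burden, a SNP is only carried into the ASE
#' tests when a binomial criterion shows it could in principle yield a
#' significant result: keep iff `P(X >= t | t, cpn_ratio) = cpn_ratio^t`
#' falls below `alpha`. This removes sites with low read counts and/or
#' extreme copy-number ratios (LOH, high-level allele-specific
#' amplification). A `cpn_ratio` of exactly 1 gives p = 1 and is removed;
#' a `cpn_ratio` of 0 is removed as inconsistent with expressed
#' heterozygosity.
#'
#' @param t Total RNA read count at the SNP (vectorised).
#' @param cpn_ratio Major-allele copy number over total copy number, in
#'   [0, 1] (vectorised).
#' @param alpha Filtering threshold (default 0.001).
#'
#' @return Logical vector: `TRUE` to keep the SNP.
#' @examples
#' independent_filter(10, 0.5)  # TRUE: 0.5^10 < 0.001
#' independent_filter(9, 0.5)   # FALSE: 0.5^9 = 0.00195
#' @export
independent_filter <- function(t, cpn_ratio, alpha = 0.001) {
  stopifnot(all(t >= 1), all(cpn_ratio >= 0), all(cpn_ratio <= 1))
  ifelse(cpn_ratio <= 0, FALSE, cpn_ratio^t < alpha)
}

#' Per-SNP copy-number-aware ASE tests
#'
#' Applies three one-tailed beta-binomial tests to every heterozygous SNP
#' record, with overdispersion `rho`:
#' * `p_eq1 = P(X >= m | t, 0.5)` — allelic imbalance against a balanced
#'   expectation;
#' * `p_eq3 = P(X <  m | t, 0.5)` — major-allele expression *below* balance
#'   (imbalance favouring the DNA-minor allele);
#' * `p_eq4 = P(X >= m | t, cpn_ratio)` — imbalance beyond that explained by
#'   the allele-specific DNA copy number.
#'
#' Because the bulk sample mixes tumour and non-tumour cells, the RNA
#' allelic ratio of a copy-number-imbalanced gene can take any value
#' between 0.5 and the copy-number ratio; a gene is only called
#' copy-number-independent when its imbalance exceeds both bounds (via the
#' smaller of `p_eq3`/`p_eq4` downstream).
#'
#' SNPs with total RNA coverage of `min_coverage` or fewer reads are marked
#' not evaluable rather than erroring. Records falling inside `blacklist`
#' intervals are marked not evaluable too. `p_eq4` is `NA` at
#' `cpn_ratio` of exactly 0 or 1, where the beta-binomial mean is
#' degenerate; such sites are always removed by the independent filter.
#'
#' @param snps Tibble of SNP allele records; required columns:
#'   `snp_id`, `gene_id`, `tumour_id`, `region_id`, `rna_major_count`,
#'   `rna_minor_count`, `major_cn`, `minor_cn`. Optional: `chrom`, `pos`
#'   (needed for blacklisting), `phase_block_id`, `major_haplotype`,
#'   `dna_major_count`, `dna_minor_count`, `major_is_reference`.
#' @param rho Beta-binomial overdispersion (default 0.05).
#' @param min_coverage SNPs need strictly more total RNA reads than this
#'   (default 8).
#' @param blacklist Optional `GRanges` (or `NULL`) of poor-mappability
#'   regions to exclude.
#'
#' @return The input tibble with columns `total_rna`, `cpn_ratio`,
#'   `evaluable`, `p_eq1`, `p_eq3`, `p_eq4`, `passes_independent_filter`.
#' @export
ase_test_snps <- function(snps, rho = 0.05, min_coverage = 8,
                          blacklist = NULL) {
  req <- c("snp_id", "gene_id", "tumour_id", "region_id",
           "rna_major_count", "rna_minor_count", "major_cn", "minor_cn")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0) {
    stop("ase_test_snps: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- dplyr::mutate(
    tibble::as_tibble(snps),
    total_rna = .data$rna_major_count + .data$rna_minor_count,
    cpn_ratio = ifelse(.data$major_cn + .data$minor_cn > 0,
                       .data$major_cn / (.data$major_cn + .data$minor_cn),
                       NA_real_),
    evaluable = .data$total_rna > min_coverage & !is.na(.data$cpn_ratio)
  )
  if (!is.null(blacklist)) {
    if (!all(c("chrom", "pos") %in% names(out))) {
      stop("ase_test_snps: blacklisting requires chrom and pos columns")
    }
    gr <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(out$pos, out$pos))
    hit <- suppressWarnings(IRanges::overlapsAny(gr, blacklist))
    out$evaluable <- out$evaluable & !hit
  }
  n <- nrow(out)
  p1 <- p3 <- p4 <- rep(NA_real_, n)
  keep <- rep(FALSE, n)
  ev <- which(out$evaluable)
  if (length(ev) > 0) {
    m <- out$rna_major_count[ev]
    t <- out$total_rna[ev]
    r <- out$cpn_ratio[ev]
    p1[ev] <- betabin_tail(m, t, 0.5, rho)
    p3[ev] <- 1 - p1[ev]
    inner <- r > 0 & r < 1
    p4[ev[inner]] <- betabin_tail(m[inner], t[inner], r[inner], rho)
    keep[ev] <- independent_filter(t, r)
  }
  out$p_eq1 <- p1
  out$p_eq3 <- p3
  out$p_eq4 <- p4
  out$passes_independent_filter <- keep
  out
}

#' Fisher's method for combining p-values
#'
#' `-2 * sum(log(p))` referred to a chi-squared distribution on `2k`
#' degrees of freedom. p-values are clipped at `1e-300` before the log as a
#' numerical floor that leaves the ranking untouched.
#'
#' @param p Numeric vector of p-values.
#' @return Combined p-value; `NA` for empty input.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  stat <- -2 * sum(log(pmax(p, 1e-300)))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Gene-level combination of per-SNP ASE tests
#'
#' For each gene in each tumour region, combines the evaluable,
#' filter-passing SNPs with Fisher's method into two p-values:
#' combination A of `p_eq1` (any allelic imbalance) and combination B of
#' `min(p_eq3, p_eq4)` per SNP (imbalance beyond copy number). Genes with
#' no usable SNP appear with `n_snps_used = 0` and `NA` p-values.
#'
#' @param snp_results Output of [ase_test_snps()].
#' @return Tibble with one row per `tumour_id` x `region_id` x `gene_id`:
#'   `n_snps_used`, `p_combined_A`, `p_combined_B`, and the
#'   majority `ref_overexpressed` vote across used SNPs (reference allele
#'   expressed above the alternative), when phase columns are present.
#' @export
ase_combine_genes <- function(snp_results) {
  has_ref <- "major_is_reference" %in% names(snp_results)
  dplyr::group_by(snp_results, .data$tumour_id, .data$region_id,
                  .data$gene_id) |>
    dplyr::summarise(
      n_snps_used = sum(.data$evaluable & .data$passes_independent_filter),
      p_combined_A = fisher_combine(
        .data$p_eq1[.data$evaluable & .data$passes_independent_filter]),
      p_combined_B = fisher_combine(
        pmin(.data$p_eq3, .data$p_eq4)[
          .data$evaluable & .data$passes_independent_filter]),
      ref_overexpressed = if (has_ref) {
        used <- .data$evaluable & .data$passes_independent_filter
        if (!any(used)) NA else {
          # overexpressed allele is the RNA-major; is it the reference?
          ref_major <- .data$major_is_reference[used] ==
            (.data$rna_major_count[used] >= .data$rna_minor_count[used])
          mean(ref_major) >= 0.5
        }
      } else NA,
      .groups = "drop"
    )
}

#' Classify genes as biallelic, CN-dependent or CN-independent ASE
#'
#' Benjamini-Hochberg correction is applied within each sample (tumour
#' region) across genes, separately for the A and B combinations. A gene is
#' labelled `cn_independent_ase` when `fdr_B < fdr_threshold`;
#' `cn_dependent_ase` when `fdr_A < fdr_threshold` but not B; otherwise
#' `biallelic`. Genes without usable SNPs are `not_evaluable`.
#'
#' @param gene_results Output of [ase_combine_genes()].
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @return Input tibble with `fdr_A`, `fdr_B` and `label` columns.
#' @export
ase_classify <- function(gene_results, fdr_threshold = 0.05) {
  if (nrow(gene_results) == 0) {
    return(dplyr::mutate(gene_results, fdr_A = numeric(0),
                         fdr_B = numeric(0), label = character(0)))
  }
  dplyr::group_by(gene_results, .data$tumour_id, .data$region_id) |>
    dplyr::mutate(
      fdr_A = stats::p.adjust(.data$p_combined_A, method = "BH"),
      fdr_B = stats::p.adjust(.data$p_combined_B, method = "BH")
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = dplyr::case_when(
      .data$n_snps_used == 0 ~ "not_evaluable",
      .data$fdr_B < fdr_threshold ~ "cn_independent_ase",
      .data$fdr_A < fdr_threshold ~ "cn_dependent_ase",
      TRUE ~ "biallelic"
    ))
}

#' Odds ratio of an annotation among ASE versus non-ASE genes
#'
#' Builds the 2x2 table of ASE status against a gene annotation (for
#' example imprinting status or the presence of a truncating mutation) over
#' the genes in which ASE was testable, and reports the sample
#' (cross-product) odds ratio with a Haldane correction of 0.5 on zero
#' cells plus the Fisher exact p-value.
#'
#' @param ase Logical vector: gene shows ASE. Alternatively a 2x2 matrix
#'   `[[ase&ann, ase&!ann], [!ase&ann, !ase&!ann]]` (then `annotation` is
#'   ignored).
#' @param annotation Logical vector: gene carries the annotation.
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return One-row tibble: `odds_ratio`, `p_value`, the four cell counts,
#'   and `degenerate` flag set when a margin is empty.
#' @export
enrichment_odds_ratio <- function(ase, annotation = NULL,
                                  alternative = "two.sided") {
  if (is.matrix(ase)) {
    tab <- ase
  } else {
    stopifnot(length(ase) == length(annotation))
    tab <- matrix(c(sum(ase & annotation), sum(ase & !annotation),
                    sum(!ase & annotation), sum(!ase & !annotation)),
                  nrow = 2, byrow = TRUE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  hald <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + hald) * (d + hald)) / ((b + hald) * (c + hald))
  pv <- if (degenerate) NA_real_ else {
    stats::fisher.test(tab, alternative = alternative)$p.value
  }
  tibble::tibble(odds_ratio = if (degenerate) NA_real_ else or,
                 p_value = pv, n_ase_annot = a, n_ase_other = b,
                 n_non_annot = c, n_non_other = d, degenerate = degenerate)
}

#' Intratumour heterogeneity of CN-independent ASE
#'
#' For each multiregion tumour, the homogeneous fraction is the number of
#' genes showing CN-independent ASE in *all* regions in which they were
#' evaluable (requiring at least two evaluable regions), divided by the
#' number of genes showing CN-independent ASE in at least two regions.
#' ITH is reported as one minus this fraction; tumours with an empty
#' denominator get `NA` with `defined = FALSE`.
#'
#' @param gene_labels Output of [ase_classify()] (rows are gene x region).
#' @return Tibble per tumour: `n_regions`, `n_recurrent` (denominator),
#'   `n_homogeneous`, `ith`, `defined`.
#' @export
cn_indep_ase_ith <- function(gene_labels) {
  dplyr::filter(gene_labels, .data$label != "not_evaluable") |>
    dplyr::group_by(.data$tumour_id, .data$gene_id) |>
    dplyr::summarise(
      n_eval = dplyr::n_distinct(.data$region_id),
      n_ci = sum(.data$label == "cn_independent_ase"),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$tumour_id) |>
    dplyr::summarise(
      n_regions = NA_integer_,
      n_recurrent = sum(.data$n_ci >= 2),
      n_homogeneous = sum(.data$n_ci >= 2 & .data$n_ci == .data$n_eval),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ith = ifelse(.data$n_recurrent > 0,
                   1 - .data$n_homogeneous / .data$n_recurrent, NA_real_),
      defined = .data$n_recurrent > 0
    ) |>
    dplyr::select(-"n_regions")
}

#' Per-sample reference bias of CN-independent ASE calls
#'
#' Misgenotyped homozygous sites on a generic reference genome inflate
#' apparent overexpression of the reference allele. As a per-sample
#' diagnostic, the number of CN-independent ASE events in which the
#' reference allele is overexpressed is divided by the number in which the
#' alternative allele is overexpressed.
#'
#' @param classified Output of [ase_classify()]; needs the
#'   `ref_overexpressed` column from [ase_combine_genes()].
#' @return Tibble per sample: `n_ref_over`, `n_alt_over`, `bias_ratio`
#'   (`NA` with `defined = FALSE` when no alternative-overexpressed event
#'   exists).
#' @export
reference_bias <- function(classified) {
  dplyr::filter(classified, .data$label == "cn_independent_ase",
                !is.na(.data$ref_overexpressed)) |>
    dplyr::group_by(.data$tumour_id, .data$region_id) |>
    dplyr::summarise(
      n_ref_over = sum(.data$ref_overexpressed),
      n_alt_over = sum(!.data$ref_overexpressed),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bias_ratio = ifelse(.data$n_alt_over > 0,
                          .data$n_ref_over / .data$n_alt_over, NA_real_),
      defined = .data$n_alt_over > 0
    )
}

#' Classify a gene promoter as allele-specifically methylated
#'
#' A CpG is an ASM locus when its 99% highest-density interval of the
#' tumour methylation rate lies within `[0.15, 0.75]` and the point
#' estimate within `[0.2, 0.7]` — intermediate methylation consistent with
#' one methylated and one unmethylated allele. A promoter is ASM when at
#' least three *consecutive* ASM loci occur along the position-sorted CpGs.
#'
#' @param cpgs Tibble with columns `position`, `m_t` (point methylation
#'   rate), `hdi_low`, `hdi_high`.
#' @param min_run Number of consecutive ASM loci required (default 3).
#' @return One-row tibble: `class` ("asm" / "not_asm"), `n_asm_loci`,
#'   `max_run`.
#' @export
classify_promoter_asm <- function(cpgs, min_run = 3) {
  cpgs <- dplyr::arrange(tibble::as_tibble(cpgs), .data$position)
  is_asm <- cpgs$hdi_low >= 0.15 & cpgs$hdi_high <= 0.75 &
    cpgs$m_t >= 0.2 & cpgs$m_t <= 0.7
  max_run <- if (length(is_asm) == 0) 0L else {
    r <- rle(is_asm)
    runs <- r$lengths[r$values]
    if (length(runs) == 0) 0L else max(runs)
  }
  tibble::tibble(
    class = if (max_run >= min_run) "asm" else "not_asm",
    n_asm_loci = sum(is_asm),
    max_run = as.integer(max_run)
  )
}

#' Detect mirrored subclonal allelic imbalance (MSAI)
#'
#' Using haplotype phase, flags two kinds of parallel allelic evolution
#' within a gene across tumour regions:
#' * **genomic** MSAI — two regions each show significant DNA allelic
#'   imbalance (binomial test on phased DNA counts) but favour *opposite*
#'   haplotypes;
#' * **genomic-transcriptomic** MSAI — a region without DNA imbalance
#'   shows CN-independent ASE whose overexpressed haplotype is the one
#'   lost or reduced (DNA-minor) in another, DNA-imbalanced region.
#'
#' Genes without phase information are skipped with a message.
#'
#' @param snp_results Output of [ase_test_snps()] including
#'   `phase_block_id`, `major_haplotype` (1 or 2: which phased haplotype
#'   carries the DNA-major allele at this SNP), `dna_major_count`,
#'   `dna_minor_count`.
#' @param classified Output of [ase_classify()].
#' @param dna_p Significance threshold for DNA allelic imbalance
#'   (default 0.05).
#' @return Tibble of events: `tumour_id`, `gene_id`, `phase_block_id`,
#'   `type` ("genomic" / "genomic_transcriptomic"), `region_a`, `region_b`.
#' @export
detect_msai <- function(snp_results, classified, dna_p = 0.05) {
  empty <- tibble::tibble(tumour_id = character(0), gene_id = character(0),
                          phase_block_id = character(0), type = character(0),
                          region_a = character(0), region_b = character(0))
  if (nrow(snp_results) == 0) return(empty)
  unphased <- is.na(snp_results$phase_block_id)
  if (any(unphased)) {
    message("detect_msai: skipping ", sum(unphased),
            " unphased SNP records")
    snp_results <- snp_results[!unphased, ]
  }
  if (nrow(snp_results) == 0) return(empty)

  per_region <- snp_results |>
    dplyr::mutate(
      hap1_dna = ifelse(.data$major_haplotype == 1,
                        .data$dna_major_count, .data$dna_minor_count),
      hap2_dna = ifelse(.data$major_haplotype == 1,
                        .data$dna_minor_count, .data$dna_major_count),
      hap1_rna = ifelse(.data$major_haplotype == 1,
                        .data$rna_major_count, .data$rna_minor_count),
      hap2_rna = ifelse(.data$major_haplotype == 1,
                        .data$rna_minor_count, .data$rna_major_count)
    ) |>
    dplyr::group_by(.data$tumour_id, .data$gene_id, .data$phase_block_id,
                    .data$region_id) |>
    dplyr::summarise(dplyr::across(c("hap1_dna", "hap2_dna",
                                     "hap1_rna", "hap2_rna"), sum),
                     .groups = "drop") |>
    dplyr::mutate(
      dna_p_value = purrr::map2_dbl(
        .data$hap1_dna, .data$hap1_dna + .data$hap2_dna,
        ~ if (.y == 0) 1 else stats::binom.test(.x, .y, 0.5)$p.value),
      dna_imbalanced = .data$dna_p_value < dna_p,
      dna_major_hap = ifelse(.data$hap1_dna >= .data$hap2_dna, 1L, 2L),
      rna_major_hap = ifelse(.data$hap1_rna >= .data$hap2_rna, 1L, 2L)
    ) |>
    dplyr::left_join(
      dplyr::select(classified, "tumour_id", "region_id", "gene_id",
                    "label"),
      by = c("tumour_id", "region_id", "gene_id"))

  events <- per_region |>
    dplyr::group_by(.data$tumour_id, .data$gene_id,
                    .data$phase_block_id) |>
    dplyr::group_map(function(g, key) {
      ev <- list()
      imb <- g[g$dna_imbalanced, ]
      # genomic: opposite DNA-major haplotypes in two imbalanced regions
      if (nrow(imb) >= 2 && dplyr::n_distinct(imb$dna_major_hap) > 1) {
        ra <- imb$region_id[imb$dna_major_hap == 1L][1]
        rb <- imb$region_id[imb$dna_major_hap == 2L][1]
        ev <- c(ev, list(tibble::tibble(type = "genomic",
                                        region_a = ra, region_b = rb)))
      }
      # genomic-transcriptomic: balanced region with CN-independent ASE
      # favouring the haplotype that is DNA-minor elsewhere
      bal <- g[!g$dna_imbalanced &
                 !is.na(g$label) & g$label == "cn_independent_ase", ]
      if (nrow(bal) > 0 && nrow(imb) > 0) {
        for (i in seq_len(nrow(bal))) {
          lost_in <- imb$region_id[imb$dna_major_hap !=
                                     bal$rna_major_hap[i]]
          if (length(lost_in) > 0) {
            ev <- c(ev, list(tibble::tibble(
              type = "genomic_transcriptomic",
              region_a = bal$region_id[i], region_b = lost_in[1])))
          }
        }
      }
      if (length(ev) == 0) return(NULL)
      dplyr::bind_rows(ev) |>
        dplyr::mutate(tumour_id = key$tumour_id, gene_id = key$gene_id,
                      phase_block_id = key$phase_block_id,
                      .before = 1)
    }) |>
    dplyr::bind_rows()
  if (nrow(events) == 0) empty else events
}
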