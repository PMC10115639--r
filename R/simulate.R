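#' Configuration of a synthetic multiregion cohort
#'
#' The generator emulates the statistical structure the downstream
#' analyses assume: multiregion tumours with per-region purity, integer
#' allele-specific copy-number states per gene, heterozygous SNPs with
#' beta-binomially overdispersed RNA allele counts (default sigma = 0.05),
#' negative-binomial expression with tumour-level random effects, and RNA
#' substitutions drawn from known 192-channel signature mixtures over a
#' synthetic transcriptome.
#'
#' @param n_tumours Number of tumours.
#' @param regions_per_tumour Single count or length-2 range.
#' @param n_genes Number of genes.
#' @param snps_per_gene Single count or length-2 range.
#' @param purity_range Length-2 interval within (0, 1].
#' @param rna_overdispersion Beta-binomial overdispersion sigma (default
#'   0.05).
#' @param depth_mean Mean RNA depth per SNP (negative binomial, truncated
#'   at 1; default 30).
#' @param dna_depth_mean Mean DNA depth per SNP (default 50).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated `txevo_cohort_config` list.
#' @export
cohort_config <- function(n_tumours = 5, regions_per_tumour = 3,
                          n_genes = 200, snps_per_gene = 2,
                          purity_range = c(0.3, 0.8),
                          rna_overdispersion = 0.05,
                          depth_mean = 30, dna_depth_mean = 50,
                          seed = 1) {
  cfg <- list(n_tumours = n_tumours,
              regions_per_tumour = regions_per_tumour,
              n_genes = n_genes, snps_per_gene = snps_per_gene,
              purity_range = purity_range,
              rna_overdispersion = rna_overdispersion,
              depth_mean = depth_mean, dna_depth_mean = dna_depth_mean,
              seed = as.integer(seed))
  ok <- function(x) length(x) %in% 1:2 && all(x >= 1) && all(x == floor(x))
  if (!ok(n_tumours) || length(n_tumours) != 1 || n_tumours < 1 ||
      !ok(regions_per_tumour) || !ok(n_genes) || length(n_genes) != 1 ||
      !ok(snps_per_gene)) {
    stop("cohort_config: counts must be integers >= 1")
  }
  if (length(purity_range) != 2 || purity_range[1] > purity_range[2] ||
      purity_range[1] <= 0 || purity_range[2] > 1) {
    stop("cohort_config: purity_range must be an interval within (0, 1]")
  }
  if (rna_overdispersion < 0 || rna_overdispersion >= 1) {
    stop("cohort_config: rna_overdispersion must lie in [0, 1)")
  }
  if (depth_mean <= 0 || dna_depth_mean <= 0) {
    stop("cohort_config: depth means must be positive")
  }
  structure(cfg, class = "txevo_cohort_config")
}

#' Ground-truth ASE configuration for the generator
#'
#' Fractions of genes (per tumour) with copy-number-independent ASE by
#' mechanism: cis-regulatory (`frac_cn_indep_ase`), genomic imprinting
#' (`frac_imprinted`, allelic ratio pushed to 0.95) and truncating
#' mutations triggering nonsense-mediated decay (`frac_truncating_nmd`).
#' All three produce true CN-independent ASE; the mechanism is recorded in
#' the truth table.
#'
#' @param frac_cn_indep_ase Fraction of regulatory CN-independent ASE
#'   genes (default 0.1).
#' @param frac_imprinted Fraction of imprinted genes (default 0).
#' @param frac_truncating_nmd Fraction of NMD-degraded genes (default 0).
#' @param ase_allelic_ratio True major-allele expression fraction for ASE
#'   genes, in (0.5, 1] (default 0.9).
#' @return A validated `txevo_ase_truth_config` list.
#' @export
ase_truth_config <- function(frac_cn_indep_ase = 0.1,
                             frac_imprinted = 0,
                             frac_truncating_nmd = 0,
                             ase_allelic_ratio = 0.9) {
  fr <- c(frac_cn_indep_ase, frac_imprinted, frac_truncating_nmd)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("ase_truth_config: fractions must be in [0, 1] and sum to <= 1")
  }
  if (ase_allelic_ratio <= 0.5 || ase_allelic_ratio > 1) {
    stop("ase_truth_config: ase_allelic_ratio must lie in (0.5, 1]")
  }
  structure(list(frac_cn_indep_ase = frac_cn_indep_ase,
                 frac_imprinted = frac_imprinted,
                 frac_truncating_nmd = frac_truncating_nmd,
                 ase_allelic_ratio = ase_allelic_ratio),
            class = "txevo_ase_truth_config")
}

draw_count <- function(spec, n) {
  if (length(spec) == 1) rep(as.integer(spec), n)
  else sample(seq(spec[1], spec[2]), n, replace = TRUE)
}

rdepth <- function(n, mean, size = 10) {
  pmax(1L, stats::rnbinom(n, mu = mean, size = size))
}

# Allele-specific copy-number states and clonal frequencies: a mostly
# diploid genome with common single-allele gains, occasional LOH and
# amplification.
CN_STATES <- list(c(1, 1), c(2, 1), c(2, 0), c(3, 1), c(2, 2), c(3, 2))
CN_PROBS <- c(0.60, 0.16, 0.08, 0.07, 0.05, 0.04)

#' Generate the scaffold of a synthetic multiregion cohort
#'
#' Draws tumours, regions with purities, genes laid out along a synthetic
#' chromosome, and one integer allele-specific copy-number pair per gene
#' per region (mostly clonal across a tumour, with a configurable fraction
#' of subclonal, region-specific states). `major >= minor >= 0` always
#' holds and no state is (0, 0).
#'
#' @param config A [cohort_config()].
#' @param subclonal_frac Fraction of genes per tumour with region-specific
#'   copy number (default 0.1).
#' @return List of class `txevo_cohort`: `config`, `regions` (tibble:
#'   `tumour_id`, `region_id`, `purity`), `genes` (tibble: `gene_id`,
#'   `chrom`, `start`), `cn` (tibble: `tumour_id`, `region_id`,
#'   `gene_id`, `major_cn`, `minor_cn`).
#' @export
generate_cohort <- function(config, subclonal_frac = 0.1) {
  if (!inherits(config, "txevo_cohort_config")) {
    stop("generate_cohort: config must come from cohort_config()")
  }
  with_local_seed(config$seed, {
    tumours <- sprintf("T%02d", seq_len(config$n_tumours))
    n_reg <- draw_count(config$regions_per_tumour, config$n_tumours)
    regions <- purrr::map2(tumours, n_reg, function(t, k) {
      tibble::tibble(tumour_id = t,
                     region_id = sprintf("%s_R%d", t, seq_len(k)),
                     purity = stats::runif(k, config$purity_range[1],
                                           config$purity_range[2]))
    }) |> dplyr::bind_rows()
    genes <- tibble::tibble(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = "chr1",
      start = 10000L * seq_len(config$n_genes))
    cn <- purrr::map(tumours, function(t) {
      reg <- regions$region_id[regions$tumour_id == t]
      clonal <- sample(seq_along(CN_STATES), config$n_genes,
                       replace = TRUE, prob = CN_PROBS)
      sub <- stats::runif(config$n_genes) < subclonal_frac
      purrr::map(reg, function(r) {
        state <- clonal
        if (any(sub)) {
          state[sub] <- sample(seq_along(CN_STATES), sum(sub),
                               replace = TRUE, prob = CN_PROBS)
        }
        tibble::tibble(tumour_id = t, region_id = r,
                       gene_id = genes$gene_id,
                       major_cn = vapply(CN_STATES[state], `[`,
                                         numeric(1), 1),
                       minor_cn = vapply(CN_STATES[state], `[`,
                                         numeric(1), 2))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    structure(list(config = config, regions = regions, genes = genes,
                   cn = cn),
              class = "txevo_cohort")
  })
}

#' @export
print.txevo_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$regions), "regions /",
      x$config$n_tumours, "tumours,", x$config$n_genes, "genes\n")
  invisible(x)
}

# expected DNA/RNA major-allele fraction in an admixed sample: tumour
# fraction rho with CN (nA, nB) against a diploid heterozygous normal
admixed_major_fraction <- function(rho, n_major, n_minor) {
  tot <- rho * (n_major + n_minor) + 2 * (1 - rho)
  ifelse(tot > 0, (rho * n_major + (1 - rho)) / tot, NA_real_)
}

#' Simulate per-SNP allele counts with known ASE truth
#'
#' For every gene in every region, draws heterozygous SNPs whose RNA
#' major-allele counts are beta-binomial with overdispersion sigma
#' (`config$rna_overdispersion`) around the admixture-weighted expected
#' allelic ratio: 0.5 for balanced non-ASE genes, the purity-weighted
#' copy-number ratio for imbalanced non-ASE genes, and a ratio shifted to
#' (at least) `ase_allelic_ratio` for true CN-independent ASE genes. DNA
#' counts are binomial around the admixture-weighted DNA allele fraction.
#' Every gene x tumour carries exactly one truth label in
#' `{none, cn_dep, cn_indep}`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param ase_cfg An [ase_truth_config()].
#' @param seed Optional seed; defaults to `config$seed + 1`.
#' @return List: `snps` (tibble of SNP allele records, pipeline input
#'   schema), `truth` (tibble: `tumour_id`, `gene_id`, `true_class`,
#'   `mechanism`, `ase_ratio`).
#' @export
simulate_ase_counts <- function(cohort, ase_cfg = ase_truth_config(),
                                seed = NULL) {
  stopifnot(inherits(cohort, "txevo_cohort"))
  cfg <- cohort$config
  if (cfg$depth_mean <= 0) stop("depth must be positive")
  seed <- seed %||% (cfg$seed + 1L)
  with_local_seed(seed, {
    rho <- cfg$rna_overdispersion
    truth <- purrr::map(unique(cohort$regions$tumour_id), function(t) {
      n <- cfg$n_genes
      mech <- rep("none", n)
      u <- stats::runif(n)
      c1 <- ase_cfg$frac_cn_indep_ase
      c2 <- c1 + ase_cfg$frac_imprinted
      c3 <- c2 + ase_cfg$frac_truncating_nmd
      mech[u < c1] <- "regulatory"
      mech[u >= c1 & u < c2] <- "imprinted"
      mech[u >= c2 & u < c3] <- "nmd"
      tibble::tibble(tumour_id = t, gene_id = cohort$genes$gene_id,
                     mechanism = mech,
                     ase_ratio = dplyr::case_when(
                       mech == "imprinted" ~ pmax(ase_cfg$ase_allelic_ratio,
                                                  0.95),
                       mech %in% c("regulatory", "nmd") ~
                         ase_cfg$ase_allelic_ratio,
                       TRUE ~ NA_real_))
    }) |> dplyr::bind_rows()

    n_snps_gene <- draw_count(cfg$snps_per_gene, cfg$n_genes)
    snp_offsets <- purrr::map(n_snps_gene,
                              ~ sort(sample(1:9999, .x)))

    snps <- cohort$cn |>
      dplyr::left_join(cohort$regions, by = c("tumour_id", "region_id")) |>
      dplyr::left_join(cohort$genes, by = "gene_id") |>
      dplyr::left_join(truth, by = c("tumour_id", "gene_id"))
    gene_idx <- match(snps$gene_id, cohort$genes$gene_id)
    snps <- snps[rep(seq_len(nrow(snps)), n_snps_gene[gene_idx]), ]
    off <- unlist(snp_offsets[gene_idx])
    snps$pos <- snps$start + off
    snps$snp_id <- paste0(snps$gene_id, "_", snps$pos)

    dna_frac <- admixed_major_fraction(snps$purity, snps$major_cn,
                                       snps$minor_cn)
    rna_null <- admixed_major_fraction(snps$purity, snps$major_cn,
                                       snps$minor_cn)
    p_rna <- ifelse(snps$mechanism == "none", rna_null,
                    pmax(rna_null, snps$ase_ratio))
    p_rna <- pmin(p_rna, 0.999)

    n <- nrow(snps)
    dna_depth <- rdepth(n, cfg$dna_depth_mean)
    snps$dna_major_count <- stats::rbinom(n, dna_depth, dna_frac)
    snps$dna_minor_count <- dna_depth - snps$dna_major_count
    t_rna <- rdepth(n, cfg$depth_mean)
    m <- integer(n)
    for (i in seq_len(n)) {
      m[i] <- rbetabinom(1, t_rna[i], p_rna[i], rho)
    }
    snps$rna_major_count <- m
    snps$rna_minor_count <- t_rna - m
    snps$phase_block_id <- snps$gene_id
    snps$major_haplotype <- 1L
    snps$major_is_reference <- sample(c(TRUE, FALSE), n, replace = TRUE)
    snps$expected_rna_ratio <- p_rna

    truth$true_class <- NA_character_
    cn_any_imb <- cohort$cn |>
      dplyr::group_by(.data$tumour_id, .data$gene_id) |>
      dplyr::summarise(imb = any(.data$major_cn != .data$minor_cn),
                       .groups = "drop")
    truth <- dplyr::left_join(truth, cn_any_imb,
                              by = c("tumour_id", "gene_id")) |>
      dplyr::mutate(true_class = dplyr::case_when(
        .data$mechanism != "none" ~ "cn_indep",
        .data$imb ~ "cn_dep",
        TRUE ~ "none")) |>
      dplyr::select(-"imb")

    keep <- c("snp_id", "gene_id", "tumour_id", "region_id", "chrom",
              "pos", "phase_block_id", "major_haplotype",
              "dna_major_count", "dna_minor_count", "rna_major_count",
              "rna_minor_count", "major_cn", "minor_cn",
              "major_is_reference", "purity", "expected_rna_ratio")
    list(snps = tibble::as_tibble(snps[keep]), truth = truth)
  })
}

#' Simulate a gene-by-region expression count matrix
#'
#' Counts are negative binomial around `baseline_g x tumour_effect(t, g) x
#' region_effect(r, g)`: gene baselines are log-normal, tumour effects are
#' per-gene log-normal random effects shared by all regions of a tumour
#' (making within-tumour regions more correlated than between-tumour
#' ones), and each region perturbs a random subset of genes by a further
#' log-normal factor.
#'
#' @param cohort A [generate_cohort()] result.
#' @param baseline_meanlog,baseline_sdlog Log-normal gene baseline
#'   (default meanlog 4, sdlog 1).
#' @param tumour_effect_sd Sd (log scale) of the per-tumour per-gene
#'   effect (default 0.5).
#' @param region_effect_sd Sd (log scale) of the per-region perturbation
#'   (default 0.5).
#' @param frac_perturbed Fraction of genes perturbed per region (default
#'   0.1).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion;
#'   default 0.1).
#' @param seed Optional seed; defaults to `config$seed + 2`.
#' @return List: `counts` (genes x regions matrix), `region_info`
#'   (tibble), `truth` (list: `tumour_effects` matrix, `perturbed` named
#'   list of gene sets per region).
#' @export
simulate_expression <- function(cohort, baseline_meanlog = 4,
                                baseline_sdlog = 1,
                                tumour_effect_sd = 0.5,
                                region_effect_sd = 0.5,
                                frac_perturbed = 0.1,
                                dispersion = 0.1, seed = NULL) {
  stopifnot(inherits(cohort, "txevo_cohort"))
  cfg <- cohort$config
  seed <- seed %||% (cfg$seed + 2L)
  with_local_seed(seed, {
    genes <- cohort$genes$gene_id
    regions <- cohort$regions
    ng <- length(genes); nr <- nrow(regions)
    base <- stats::rlnorm(ng, baseline_meanlog, baseline_sdlog)
    tumours <- unique(regions$tumour_id)
    tum_eff <- matrix(stats::rlnorm(ng * length(tumours), 0,
                                    tumour_effect_sd),
                      ng, length(tumours),
                      dimnames = list(genes, tumours))
    counts <- matrix(0L, ng, nr, dimnames = list(genes,
                                                 regions$region_id))
    perturbed <- vector("list", nr)
    names(perturbed) <- regions$region_id
    for (j in seq_len(nr)) {
      mu <- base * tum_eff[, regions$tumour_id[j]]
      pg <- if (frac_perturbed > 0 && region_effect_sd > 0) {
        sample(genes, round(frac_perturbed * ng))
      } else character(0)
      perturbed[[j]] <- pg
      if (length(pg) > 0) {
        mu[pg] <- mu[pg] * stats::rlnorm(length(pg), 0, region_effect_sd)
      }
      counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, region_info = regions,
         truth = list(tumour_effects = tum_eff, perturbed = perturbed))
  })
}

#' Simulate a synthetic transcriptome
#'
#' Random uniform-composition transcripts with per-transcript strand,
#' optional injected homopolymer cassettes (9-base runs used to build
#' flank-filter decoys) and a guarantee check that every trinucleotide
#' context is available for every substitution class.
#'
#' @param n_transcripts Number of transcripts (default 30).
#' @param transcript_length Bases per transcript (default 1500).
#' @param n_homopolymer_cassettes Injected 9-base homopolymer runs
#'   (default 2).
#' @param seed Seed (default 1).
#' @return List: `transcripts` (tibble: `transcript_id`, `strand`,
#'   `sequence`), `cassettes` (tibble: `transcript_id`, `pos`, `base` at
#'   the cassette centre).
#' @export
simulate_transcriptome <- function(n_transcripts = 30,
                                   transcript_length = 1500,
                                   n_homopolymer_cassettes = 2,
                                   seed = 1) {
  stopifnot(transcript_length >= 50)
  with_local_seed(seed, {
    tx <- tibble::tibble(
      transcript_id = sprintf("TX%03d", seq_len(n_transcripts)),
      strand = sample(c("+", "-"), n_transcripts, replace = TRUE),
      sequence = vapply(seq_len(n_transcripts), function(i) {
        paste(sample(BASES, transcript_length, replace = TRUE),
              collapse = "")
      }, character(1)))
    cassettes <- tibble::tibble(transcript_id = character(0),
                                pos = integer(0), base = character(0))
    if (n_homopolymer_cassettes > 0) {
      for (i in seq_len(n_homopolymer_cassettes)) {
        k <- sample(n_transcripts, 1)
        centre <- sample(seq(100, transcript_length - 100), 1)
        b <- sample(BASES, 1)
        s <- tx$sequence[k]
        substr(s, centre - 4, centre + 4) <- strrep(b, 9)
        tx$sequence[k] <- s
        cassettes <- dplyr::bind_rows(
          cassettes, tibble::tibble(transcript_id = tx$transcript_id[k],
                                    pos = centre, base = b))
      }
    }
    list(transcripts = tx, cassettes = cassettes)
  })
}

# index of usable positions: mRNA-sense trinucleotide key per genomic
# position (margin of 4 for the genomic 4-base flanks)
context_index <- function(transcripts) {
  purrr::pmap(transcripts, function(transcript_id, strand, sequence) {
    L <- nchar(sequence)
    pos <- seq(5L, L - 4L)
    chars <- strsplit(sequence, "")[[1]]
    up <- chars[pos - 1]; b <- chars[pos]; dn <- chars[pos + 1]
    if (strand == "-") {
      key <- paste0(chartr("ACGT", "TGCA", dn),
                    chartr("ACGT", "TGCA", b),
                    chartr("ACGT", "TGCA", up))
    } else {
      key <- paste0(up, b, dn)
    }
    tibble::tibble(transcript_id = transcript_id, strand = strand,
                   pos = pos, key = key)
  }) |> dplyr::bind_rows()
}

channel_parts <- function(channel) {
  tibble::tibble(channel = channel,
                 b5 = substr(channel, 1, 1),
                 ref = substr(channel, 3, 3),
                 alt = substr(channel, 5, 5),
                 b3 = substr(channel, 7, 7),
                 key = paste0(substr(channel, 1, 1),
                              substr(channel, 3, 3),
                              substr(channel, 7, 7)))
}

#' Simulate RNA substitutions from known signature mixtures
#'
#' Places variants at transcriptome positions whose strand-aware
#' (mRNA-sense) trinucleotide context matches the channel sampled from
#' each region's signature mixture, annotates full read-depth and DNA
#' support fields such that all true variants pass every post-caller
#' filter, and adds configurable numbers of decoys that each violate
#' exactly one filter rule (recorded in `decoy_rule`).
#'
#' @param cohort A [generate_cohort()] result (provides regions).
#' @param signature_matrix 192 x k column-stochastic matrix (rows in
#'   [spectrum_channels()] order).
#' @param exposures Either a k-vector shared by all regions or a matrix k
#'   x n_regions (columns named by `region_id`); each column sums to 1.
#' @param transcriptome A [simulate_transcriptome()] result.
#' @param variants_per_region True variants per region (default 100).
#' @param decoys Named integer vector of decoy counts per region; names
#'   among `low_rna_coverage`, `low_alt_support`, `low_vaf`,
#'   `low_germline_depth`, `low_tumour_depth`, `dna_support`,
#'   `homopolymer_flank`, `blacklist` (default none).
#' @param blacklist Optional `GRanges` over transcript coordinates; if
#'   `NULL` and blacklist decoys are requested, a two-interval blacklist
#'   is generated and returned.
#' @param seed Optional seed; defaults to `config$seed + 3`.
#' @return List: `variants` (tibble in the candidate-variant schema with
#'   `is_decoy`, `decoy_rule`, `channel_true`), `exposures_truth` (tibble
#'   per region x signature), `blacklist` (`GRanges` or `NULL`).
#' @export
simulate_rna_variants <- function(cohort, signature_matrix, exposures,
                                  transcriptome,
                                  variants_per_region = 100,
                                  decoys = integer(0),
                                  blacklist = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "txevo_cohort"))
  signature_matrix <- as.matrix(signature_matrix)
  stopifnot(nrow(signature_matrix) == 192)
  if (is.null(colnames(signature_matrix))) {
    colnames(signature_matrix) <- paste0("S",
                                         seq_len(ncol(signature_matrix)))
  }
  channels <- spectrum_channels()
  seed <- seed %||% (cohort$config$seed + 3L)
  regions <- cohort$regions$region_id
  expo_mat <- if (is.matrix(exposures)) {
    stopifnot(all(regions %in% colnames(exposures)))
    exposures[, regions, drop = FALSE]
  } else {
    matrix(exposures, ncol = length(regions),
           nrow = length(exposures),
           dimnames = list(names(exposures), regions))
  }

  with_local_seed(seed, {
    idx <- context_index(transcriptome$transcripts)
    if (is.null(blacklist) && ("blacklist" %in% names(decoys)) &&
        decoys[["blacklist"]] > 0) {
      tx <- transcriptome$transcripts
      picks <- sample(nrow(tx), 2, replace = nrow(tx) < 2)
      blacklist <- GenomicRanges::GRanges(
        tx$transcript_id[picks],
        IRanges::IRanges(start = c(200, 600), width = 100))
    }
    in_blacklist <- function(chrom, pos) {
      if (is.null(blacklist)) return(rep(FALSE, length(pos)))
      suppressWarnings(IRanges::overlapsAny(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
        blacklist))
    }
    seqs <- stats::setNames(transcriptome$transcripts$sequence,
                            transcriptome$transcripts$transcript_id)
    get_ctx <- function(chrom, pos) {
      s <- seqs[[chrom]]
      c(substr(s, pos - 4, pos - 1), substr(s, pos + 1, pos + 4))
    }
    idx_by_key <- split(seq_len(nrow(idx)), idx$key)
    place_channel <- function(channel, avoid_flags = TRUE) {
      parts <- channel_parts(channel)
      cand <- idx[idx_by_key[[parts$key]], ]
      if (is.null(idx_by_key[[parts$key]]) || nrow(cand) == 0) {
        stop("simulate_rna_variants: no transcriptome position offers ",
             "context for channel ", channel)
      }
      for (try in seq_len(50)) {
        i <- sample(nrow(cand), 1)
        chrom <- cand$transcript_id[i]; pos <- cand$pos[i]
        strand <- cand$strand[i]
        g_ref <- if (strand == "+") parts$ref else
          chartr("ACGT", "TGCA", parts$ref)
        g_alt <- if (strand == "+") parts$alt else
          chartr("ACGT", "TGCA", parts$alt)
        ctx <- get_ctx(chrom, pos)
        if (avoid_flags) {
          if (!flank_filter(g_ref, g_alt, ctx[1], ctx[2])) next
          if (in_blacklist(chrom, pos)) next
        }
        return(tibble::tibble(chrom = chrom, pos = pos,
                              transcript_strand = strand,
                              ref = g_ref, alt = g_alt,
                              context5 = ctx[1], context3 = ctx[2],
                              channel_true = channel))
      }
      stop("simulate_rna_variants: could not place channel ", channel,
           " clear of filter contexts")
    }
    base_fields <- function(v) {
      n <- nrow(v)
      v$rna_depth <- pmax(10L, stats::rnbinom(n, mu = 50, size = 10))
      v$rna_alt <- pmax(3L, stats::rbinom(n, v$rna_depth, 0.3))
      v$dna_germline_depth <- pmax(30L,
                                   stats::rnbinom(n, mu = 60, size = 10))
      v$dna_tumour_depth_total <- pmax(30L, stats::rnbinom(n, mu = 100,
                                                           size = 10))
      v$dna_alt_support <- 0L
      v$dna_error_support <- stats::rbinom(n, v$dna_tumour_depth_total,
                                           0.002)
      v
    }

    all_regions <- purrr::map(regions, function(r) {
      probs <- drop(signature_matrix %*% expo_mat[, r])
      ch <- sample(channels, variants_per_region, replace = TRUE,
                   prob = probs)
      v <- dplyr::bind_rows(purrr::map(ch, place_channel))
      v <- base_fields(v)
      v$is_decoy <- FALSE
      v$decoy_rule <- NA_character_

      dk <- decoys[decoys > 0]
      dv <- purrr::imap(as.list(dk), function(cnt, rule) {
        ch_d <- sample(channels, cnt, replace = TRUE, prob = probs)
        d <- dplyr::bind_rows(purrr::map(ch_d, function(cc) {
          if (rule == "homopolymer_flank") {
            cass <- transcriptome$cassettes
            if (nrow(cass) == 0) {
              stop("homopolymer decoys need cassettes in the ",
                   "transcriptome")
            }
            i <- sample(nrow(cass), 1)
            strand <- transcriptome$transcripts$strand[
              transcriptome$transcripts$transcript_id ==
                cass$transcript_id[i]]
            ctx <- get_ctx(cass$transcript_id[i], cass$pos[i])
            tibble::tibble(chrom = cass$transcript_id[i],
                           pos = cass$pos[i],
                           transcript_strand = strand,
                           ref = cass$base[i],
                           alt = sample(setdiff(BASES, cass$base[i]), 1),
                           context5 = ctx[1], context3 = ctx[2],
                           channel_true = NA_character_)
          } else if (rule == "blacklist") {
            place_channel(cc, avoid_flags = FALSE) |>
              dplyr::mutate(pos = {
                gr <- blacklist[1]
                sample(seq(GenomicRanges::start(gr),
                           GenomicRanges::end(gr)), 1)
              }, chrom = as.character(
                GenomicRanges::seqnames(blacklist[1])),
              context5 = get_ctx(.data$chrom, .data$pos)[1],
              context3 = get_ctx(.data$chrom, .data$pos)[2])
          } else {
            place_channel(cc)
          }
        }))
        d <- base_fields(d)
        if (rule == "low_rna_coverage") {
          d$rna_depth <- 9L; d$rna_alt <- 3L
        } else if (rule == "low_alt_support") {
          d$rna_depth <- 50L; d$rna_alt <- 2L
        } else if (rule == "low_vaf") {
          d$rna_depth <- 1000L; d$rna_alt <- 5L
        } else if (rule == "low_germline_depth") {
          d$dna_germline_depth <- 20L
        } else if (rule == "low_tumour_depth") {
          d$dna_tumour_depth_total <- 25L
          d$dna_error_support <- 0L
        } else if (rule == "dna_support") {
          d$dna_tumour_depth_total <- pmax(d$dna_tumour_depth_total,
                                           500L)
          d$dna_alt_support <- 12L
          d$dna_error_support <- 0L
        }
        d$is_decoy <- TRUE
        d$decoy_rule <- rule
        d
      })
      dplyr::bind_rows(c(list(v), dv)) |>
        dplyr::mutate(region_id = r,
                      tumour_id = cohort$regions$tumour_id[
                        match(r, cohort$regions$region_id)])
    }) |> dplyr::bind_rows()

    truth <- tibble::tibble(
      region_id = rep(regions, each = nrow(expo_mat)),
      signature = rep(rownames(expo_mat) %||%
                        colnames(signature_matrix),
                      times = length(regions)),
      exposure = as.numeric(expo_mat))
    list(variants = all_regions, exposures_truth = truth,
         blacklist = blacklist)
  })
}
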