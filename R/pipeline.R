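#' Default end-to-end run configuration
#'
#' All thresholds default to the framework's stated values: beta-binomial
#' overdispersion sigma 0.05, SNP coverage > 8 reads, independent-filter
#' alpha 0.001, FDR 0.05, variant filters (30/30/10/3 reads, 1% VAF,
#' noise p 0.1), top 500 variable genes for I-TED, transcript-fraction
#' grid step 0.001, exposure eligibility > 20 variants. Any override is
#' logged by [run_pipeline()].
#'
#' @param seed Master seed; each stage derives its own stream from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_tumours = 5, regions_per_tumour = 3, n_genes = 200,
      snps_per_gene = 2, purity_range = c(0.3, 0.8),
      rna_overdispersion = 0.05, depth_mean = 30, dna_depth_mean = 50,
      frac_cn_indep_ase = 0.1, ase_allelic_ratio = 0.9,
      n_transcripts = 30, transcript_length = 1500,
      variants_per_region = 100),
    ase = list(rho = 0.05, min_coverage = 8, fdr_threshold = 0.05),
    expression = list(n_top = 500, min_count = 5, min_frac = 0.2),
    rna = list(min_variants = 20, n_signatures = 2),
    transcript_fraction = list(grid_step = 0.001)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Values absent from the file fall back to [default_run_config()];
#' overrides are reported by [run_pipeline()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

two_signature_toy <- function() {
  # two well-separated editing-like signatures over the 192 channels:
  # an ADAR-like A>G(T>C) signature and an APOBEC-like C>T(G>A) one
  channels <- spectrum_channels()
  s1 <- as.numeric(grepl("\\[A>G\\]", channels) |
                     grepl("\\[T>C\\]", channels))
  s2 <- as.numeric(grepl("\\[C>T\\]", channels) |
                     grepl("\\[G>A\\]", channels))
  sig <- cbind(ADAR_like = s1 / sum(s1), APOBEC_like = s2 / sum(s2))
  rownames(sig) <- channels
  sig
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates simulate -> ASE -> expression -> RNA-substitution stages
#' with a single master seed, writes every artefact under `outdir` in the
#' documented text formats, and returns a manifest with per-stage record
#' counts and md5 checksums. Re-running with the same configuration and
#' seed reproduces identical files.
#'
#' @param config Configuration list from [default_run_config()] or
#'   [read_run_config()]; may be a partial override list.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisible list: `counts` (records per stage), `manifest`
#'   (tibble: file, md5), `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = tempfile("txevo_run_"),
                         quiet = FALSE) {
  config <- merge_config(default_run_config(), config)
  defaults <- default_run_config(config$seed)
  say <- function(...) if (!quiet) message(...)
  diffs <- setdiff(names(unlist(config)), names(unlist(defaults)))
  changed <- names(which(vapply(names(unlist(defaults)), function(nm) {
    !identical(unlist(config)[[nm]], unlist(defaults)[[nm]])
  }, logical(1))))
  for (nm in union(diffs, changed)) {
    say("config override: ", nm, " = ", unlist(config)[[nm]])
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scfg <- config$simulate
  say("stage simulate: cohort")
  cohort <- generate_cohort(cohort_config(
    n_tumours = scfg$n_tumours,
    regions_per_tumour = scfg$regions_per_tumour,
    n_genes = scfg$n_genes, snps_per_gene = scfg$snps_per_gene,
    purity_range = scfg$purity_range,
    rna_overdispersion = scfg$rna_overdispersion,
    depth_mean = scfg$depth_mean, dna_depth_mean = scfg$dna_depth_mean,
    seed = config$seed))
  ase_sim <- simulate_ase_counts(cohort, ase_truth_config(
    frac_cn_indep_ase = scfg$frac_cn_indep_ase,
    ase_allelic_ratio = scfg$ase_allelic_ratio))
  expr_sim <- simulate_expression(cohort)
  txome <- simulate_transcriptome(
    n_transcripts = scfg$n_transcripts,
    transcript_length = scfg$transcript_length,
    seed = config$seed + 4L)
  sig <- two_signature_toy()
  var_sim <- simulate_rna_variants(
    cohort, sig, c(ADAR_like = 0.6, APOBEC_like = 0.4), txome,
    variants_per_region = scfg$variants_per_region,
    decoys = c(low_rna_coverage = 2, low_alt_support = 2, low_vaf = 2,
               low_germline_depth = 2, low_tumour_depth = 2,
               dna_support = 2, homopolymer_flank = 2, blacklist = 2))
  write_snp_table(ase_sim$snps, file.path(outdir, "snp_counts.tsv"))
  readr::write_tsv(ase_sim$truth, file.path(outdir, "ase_truth.tsv"))
  write_counts_matrix(expr_sim$counts,
                      file.path(outdir, "expression_counts.tsv"))
  readr::write_tsv(expr_sim$region_info,
                   file.path(outdir, "region_info.tsv"))
  write_transcriptome(txome, file.path(outdir, "transcriptome.fa"),
                      file.path(outdir, "transcript_strands.tsv"))
  write_variants_vcf(var_sim$variants,
                     file.path(outdir, "candidate_variants.vcf"))
  if (!is.null(var_sim$blacklist)) {
    write_blacklist_bed(var_sim$blacklist,
                        file.path(outdir, "blacklist.bed"))
  }

  say("stage ase: ", nrow(ase_sim$snps), " SNP records")
  snp_res <- ase_test_snps(ase_sim$snps, rho = config$ase$rho,
                           min_coverage = config$ase$min_coverage)
  classified <- ase_classify(ase_combine_genes(snp_res),
                             fdr_threshold = config$ase$fdr_threshold)
  readr::write_tsv(classified, file.path(outdir, "gene_ase.tsv"))
  ith_ase <- cn_indep_ase_ith(classified)
  readr::write_tsv(ith_ase, file.path(outdir, "ase_ith.tsv"))
  msai <- detect_msai(snp_res, classified)
  readr::write_tsv(msai, file.path(outdir, "msai_events.tsv"))

  say("stage expression: I-TED and transcript fraction")
  ited_res <- ited(expr_sim$counts, expr_sim$region_info,
                   n_top = config$expression$n_top,
                   min_count = config$expression$min_count,
                   min_frac = config$expression$min_frac)
  readr::write_tsv(ited_res, file.path(outdir, "ited.tsv"))
  txfrac <- snp_res |>
    dplyr::filter(.data$evaluable) |>
    dplyr::group_by(.data$tumour_id, .data$region_id) |>
    dplyr::group_map(function(g, key) {
      fit <- estimate_transcript_fraction(
        tibble::tibble(baf = g$rna_major_count / g$total_rna,
                       major_cn = g$major_cn, minor_cn = g$minor_cn),
        grid_step = config$transcript_fraction$grid_step)
      dplyr::mutate(fit, tumour_id = key$tumour_id,
                    region_id = key$region_id, .before = 1)
    }) |> dplyr::bind_rows()
  readr::write_tsv(txfrac, file.path(outdir, "transcript_fraction.tsv"))

  say("stage rna: ", nrow(var_sim$variants), " candidate variants")
  filtered <- filter_variants(var_sim$variants,
                              blacklist = var_sim$blacklist)
  readr::write_tsv(
    dplyr::select(filtered, -dplyr::starts_with("is_decoy"),
                  -dplyr::any_of(c("decoy_rule", "channel_true"))),
    file.path(outdir, "variants_filtered.tsv"))
  passing <- dplyr::filter(filtered, .data$pass)
  fits <- passing |>
    dplyr::group_by(.data$tumour_id, .data$region_id) |>
    dplyr::group_map(function(g, key) {
      fit <- fit_exposures(build_spectrum(g), two_signature_toy(),
                           min_variants = config$rna$min_variants)
      dplyr::mutate(fit, tumour_id = key$tumour_id,
                    region_id = key$region_id, .before = 1)
    }) |> dplyr::bind_rows()
  readr::write_tsv(fits, file.path(outdir, "exposures.tsv"))
  cohort_spectrum <- build_spectrum(dedupe_per_patient(passing))
  write_spectrum(cohort_spectrum, file.path(outdir, "spectrum.tsv"))

  files <- list.files(outdir, full.names = TRUE)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  counts <- list(snp_records = nrow(ase_sim$snps),
                 genes_classified = nrow(classified),
                 msai_events = nrow(msai),
                 regions_ited = sum(ited_res$computed),
                 candidate_variants = nrow(filtered),
                 passing_variants = nrow(passing),
                 exposure_fits = nrow(fits))
  say("run complete: ", outdir)
  invisible(list(counts = counts, manifest = manifest,
                 results = list(cohort = cohort, classified = classified,
                                ase_truth = ase_sim$truth,
                                ited = ited_res,
                                transcript_fraction = txfrac,
                                filtered_variants = filtered,
                                exposures = fits,
                                msai = msai),
                 outdir = outdir))
}
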