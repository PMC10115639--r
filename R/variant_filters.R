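#' Fisher test distinguishing DNA support from sequencing noise
#'
#' At sites where the candidate RNA variant has one or more supporting
#' reads in the tumour DNA, the support may reflect sequencing error in a
#' high-coverage region rather than a true (expressed) DNA mutation. A
#' one-tailed Fisher exact test compares the DNA reads supporting the RNA
#' variant with the reads supporting any other non-reference base at the
#' same position, against the total coverage:
#' `[[alt_support, depth - alt_support], [error_support, depth - error_support]]`,
#' alternative "greater". Variants whose DNA support is distinguishable
#' from noise (p below the non-stringent threshold 0.1) are excluded as
#' likely genomically encoded.
#'
#' @param alt_support DNA reads supporting the RNA variant (vectorised).
#' @param error_support DNA reads supporting other non-reference bases.
#' @param depth Total DNA coverage at the site.
#' @param p_threshold Exclusion threshold (default 0.1).
#' @return Tibble with `p_value` and `exclude`; zero depth or zero alt
#'   support gives p = 1 (keep).
#' @export
dna_noise_test <- function(alt_support, error_support, depth,
                           p_threshold = 0.1) {
  n <- max(length(alt_support), length(error_support), length(depth))
  alt_support <- rep_len(alt_support, n)
  error_support <- rep_len(error_support, n)
  depth <- rep_len(depth, n)
  stopifnot(all(depth >= alt_support), all(depth >= error_support))
  p <- vapply(seq_len(n), function(i) {
    if (depth[i] == 0 || alt_support[i] == 0) return(1)
    tab <- matrix(c(alt_support[i], depth[i] - alt_support[i],
                    error_support[i], depth[i] - error_support[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  tibble::tibble(p_value = p, exclude = p < p_threshold)
}

#' Homopolymer flank filter
#'
#' Removes variants flanked by the same four nucleotides as either the
#' reference or alternative allele on either side — a classic alignment
#' artefact context.
#'
#' @param ref,alt Single bases (vectorised).
#' @param context5,context3 4-base genomic flanks 5' and 3' of the
#'   variant.
#' @return Logical vector: `TRUE` to keep.
#' @export
flank_filter <- function(ref, alt, context5, context3) {
  homo <- function(b) strrep(b, 4)
  !(context5 == homo(ref) | context5 == homo(alt) |
      context3 == homo(ref) | context3 == homo(alt))
}

#' Post-caller filtering of candidate RNA variants
#'
#' Applies the fixed post-caller rules for RNA-only substitutions, each
#' recorded as a named flag; a variant passes iff it triggers none:
#' * `low_germline_depth` — fewer than 30 reads in the germline DNA;
#' * `low_tumour_depth` — fewer than 30 reads in total across DNA tumour
#'   regions;
#' * `low_rna_coverage` — RNA coverage below 10 reads;
#' * `low_alt_support` — alternative base supported by fewer than 3 RNA
#'   reads;
#' * `low_vaf` — variant allele frequency below 1% (exactly 1% passes);
#' * `blacklist` — position inside a supplied poor-mappability interval;
#' * `dna_support` — DNA support distinguishable from sequencing noise
#'   ([dna_noise_test()], p < 0.1);
#' * `homopolymer_flank` — 4-base flank equal to ref or alt homopolymer
#'   ([flank_filter()]).
#'
#' The rules are independent, so the flag set does not depend on
#' evaluation order.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rna_depth`, `rna_alt`, `dna_germline_depth`,
#'   `dna_tumour_depth_total`, `dna_alt_support`, `dna_error_support`,
#'   `context5`, `context3`.
#' @param blacklist Optional `GRanges` of intervals to exclude.
#' @return Input tibble plus `vaf`, one logical `flag_*` column per rule,
#'   `n_flags` and `pass`.
#' @export
filter_variants <- function(variants, blacklist = NULL) {
  v <- tibble::as_tibble(variants)
  req <- c("chrom", "pos", "ref", "alt", "rna_depth", "rna_alt",
           "dna_germline_depth", "dna_tumour_depth_total",
           "dna_alt_support", "dna_error_support", "context5", "context3")
  missing_cols <- setdiff(req, names(v))
  if (length(missing_cols) > 0) {
    stop("filter_variants: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  v$vaf <- ifelse(v$rna_depth > 0, v$rna_alt / v$rna_depth, 0)
  v$flag_low_germline_depth <- v$dna_germline_depth < 30
  v$flag_low_tumour_depth <- v$dna_tumour_depth_total < 30
  v$flag_low_rna_coverage <- v$rna_depth < 10
  v$flag_low_alt_support <- v$rna_alt < 3
  v$flag_low_vaf <- v$vaf < 0.01
  if (is.null(blacklist)) {
    v$flag_blacklist <- FALSE
  } else {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    v$flag_blacklist <- suppressWarnings(IRanges::overlapsAny(gr, blacklist))
  }
  v$flag_dna_support <- dna_noise_test(
    v$dna_alt_support, v$dna_error_support,
    v$dna_tumour_depth_total)$exclude
  v$flag_homopolymer_flank <- !flank_filter(v$ref, v$alt,
                                            v$context5, v$context3)
  flag_cols <- grep("^flag_", names(v), value = TRUE)
  v$n_flags <- rowSums(as.matrix(v[flag_cols]))
  v$pass <- v$n_flags == 0
  v
}
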