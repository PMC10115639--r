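#' Read and write the pipeline's tabular interchange formats
#'
#' All tabular interfaces are tab-separated with a header row and 1-based
#' inclusive coordinates; BED blacklists are 0-based half-open as per the
#' BED convention. Writers and readers round-trip without loss.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name txevo_io
NULL

#' @rdname txevo_io
#' @export
write_snp_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname txevo_io
#' @export
read_snp_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    tumour_id = readr::col_character(),
                    region_id = readr::col_character()))
}

#' @rdname txevo_io
#' @param counts Genes x regions matrix.
#' @export
write_counts_matrix <- function(counts, path) {
  df <- tibble::as_tibble(as.data.frame(counts), rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname txevo_io
#' @export
read_counts_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  m
}

#' @rdname txevo_io
#' @param spectrum Named 192-vector from [build_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble::tibble(channel = names(spectrum),
                                  count = as.integer(spectrum)), path)
  invisible(path)
}

#' @rdname txevo_io
#' @export
read_spectrum <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(identical(df$channel, spectrum_channels()))
  structure(stats::setNames(as.integer(df$count), df$channel),
            n_skipped = 0L, class = "txevo_spectrum")
}

#' Write candidate RNA variants as minimal VCFv4.2
#'
#' One record per variant (single-base REF/ALT), with the pipeline's
#' depth, support, context and strand annotations carried in INFO fields
#' (documented in the header). Positions are 1-based as per VCF.
#'
#' @param variants Candidate-variant tibble (see [filter_variants()]).
#' @param path Output path.
#' @param contigs Optional tibble `transcript_id`/`length` for contig
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  info_defs <- c(
    "##INFO=<ID=RNAD,Number=1,Type=Integer,Description=\"RNA depth\">",
    "##INFO=<ID=RNAA,Number=1,Type=Integer,Description=\"RNA alt reads\">",
    "##INFO=<ID=DPG,Number=1,Type=Integer,Description=\"Germline DNA depth\">",
    "##INFO=<ID=DPT,Number=1,Type=Integer,Description=\"Total tumour DNA depth\">",
    "##INFO=<ID=ALTS,Number=1,Type=Integer,Description=\"Tumour DNA alt support\">",
    "##INFO=<ID=ERRS,Number=1,Type=Integer,Description=\"Tumour DNA other non-reference support\">",
    "##INFO=<ID=C5,Number=1,Type=String,Description=\"4-base 5-prime genomic flank\">",
    "##INFO=<ID=C3,Number=1,Type=String,Description=\"4-base 3-prime genomic flank\">",
    "##INFO=<ID=STR,Number=1,Type=String,Description=\"Transcript strand\">",
    "##INFO=<ID=TID,Number=1,Type=String,Description=\"Tumour id\">",
    "##INFO=<ID=RID,Number=1,Type=String,Description=\"Region id\">")
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(contigs)) {
                sprintf("##contig=<ID=%s,length=%d>",
                        contigs$transcript_id, contigs$length)
              },
              info_defs,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf(
    "RNAD=%d;RNAA=%d;DPG=%d;DPT=%d;ALTS=%d;ERRS=%d;C5=%s;C3=%s;STR=%s;TID=%s;RID=%s",
    variants$rna_depth, variants$rna_alt, variants$dna_germline_depth,
    variants$dna_tumour_depth_total, variants$dna_alt_support,
    variants$dna_error_support, variants$context5, variants$context3,
    variants$transcript_strand, variants$tumour_id, variants$region_id)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos, variants$ref,
                  variants$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a candidate-variant VCF back into the pipeline schema
#'
#' Parses with `VariantAnnotation::readVcf()` and restores the INFO
#' annotations written by [write_variants_vcf()].
#'
#' @param path VCF path.
#' @return Candidate-variant tibble.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_variants_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    rna_depth = as.integer(info$RNAD),
    rna_alt = as.integer(info$RNAA),
    dna_germline_depth = as.integer(info$DPG),
    dna_tumour_depth_total = as.integer(info$DPT),
    dna_alt_support = as.integer(info$ALTS),
    dna_error_support = as.integer(info$ERRS),
    context5 = as.character(info$C5),
    context3 = as.character(info$C3),
    transcript_strand = as.character(info$STR),
    tumour_id = as.character(info$TID),
    region_id = as.character(info$RID))
}

#' Write/read a transcriptome as FASTA plus strand sidecar TSV
#'
#' @param transcriptome A [simulate_transcriptome()] result (or a
#'   compatible `transcripts` tibble).
#' @param fasta_path,strand_path Output paths.
#' @return Paths, invisibly.
#' @export
write_transcriptome <- function(transcriptome, fasta_path, strand_path) {
  tx <- if (is.data.frame(transcriptome)) transcriptome else
    transcriptome$transcripts
  seqs <- Biostrings::DNAStringSet(stats::setNames(tx$sequence,
                                                   tx$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(tx[, c("transcript_id", "strand")], strand_path)
  invisible(c(fasta_path, strand_path))
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(fasta_path, strand_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  strands <- readr::read_tsv(strand_path, show_col_types = FALSE)
  tibble::tibble(transcript_id = names(seqs),
                 sequence = as.character(seqs)) |>
    dplyr::left_join(strands, by = "transcript_id") |>
    dplyr::select("transcript_id", "strand", "sequence")
}

#' Write/read a genomic blacklist as BED (0-based half-open)
#'
#' @param gr A `GRanges` of blacklist intervals (1-based internal
#'   representation).
#' @param path BED path.
#' @return `write_blacklist_bed()` the path; `read_blacklist_bed()` a
#'   `GRanges`.
#' @export
write_blacklist_bed <- function(gr, path) {
  df <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_blacklist_bed
#' @export
read_blacklist_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    rtracklayer::import(path, format = "BED")
  } else {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                          show_col_types = FALSE)
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end))
  }
}
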