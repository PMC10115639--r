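BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The 192 strand-aware substitution channels
#'
#' Channel names have the form `X[R>A]Y`: substitution `R>A` read on the
#' transcribed (mRNA-sense) strand, with 5' base `X` and 3' base `Y`.
#' All 12 substitution classes are kept separate (no pyrimidine folding),
#' giving 12 x 16 = 192 channels, ordered lexicographically by reference
#' base, alternative base, 5' base, 3' base. The order is fixed and
#' emitted in all spectrum outputs.
#'
#' @return Character vector of length 192.
#' @export
spectrum_channels <- function() {
  out <- character(0)
  for (ref in BASES) for (alt in setdiff(BASES, ref)) {
    for (b5 in BASES) for (b3 in BASES) {
      out <- c(out, paste0(b5, "[", ref, ">", alt, "]", b3))
    }
  }
  out
}

#' Map a channel to its reverse-complement channel
#'
#' The genomic event seen from the opposite strand: reference and
#' alternative bases are complemented and the flanking bases are swapped
#' and complemented. Applying the map twice returns the original channel
#' (involution).
#'
#' @param channel Character vector of channel names (`X[R>A]Y`).
#' @return Character vector of reverse-complement channel names.
#' @export
revcomp_channel <- function(channel) {
  b5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  b3 <- substr(channel, 7, 7)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  paste0(comp(b3), "[", comp(ref), ">", comp(alt), "]", comp(b5))
}

#' Build a strand-aware 192-channel substitution spectrum
#'
#' Assigns each variant to the channel of its substitution in transcribed
#' (mRNA-sense) orientation: variants on `-`-strand transcripts are
#' reverse-complemented (base and context) before channel assignment.
#' Variants with ambiguous bases in their immediate context are skipped
#' and counted.
#'
#' @param variants Tibble with columns `ref`, `alt`, `transcript_strand`
#'   (`"+"`/`"-"`), and either `ctx_up`/`ctx_down` (single immediate
#'   flanking bases, genomic orientation) or `context5`/`context3`
#'   (longer genomic flanks; the adjacent base is taken from each).
#' @return Named integer vector of length 192 (class `txevo_spectrum`);
#'   attribute `n_skipped` counts variants dropped for ambiguous context.
#' @export
build_spectrum <- function(variants) {
  channels <- spectrum_channels()
  counts <- stats::setNames(integer(length(channels)), channels)
  if (nrow(variants) == 0) {
    return(structure(counts, n_skipped = 0L, class = "txevo_spectrum"))
  }
  up <- if ("ctx_up" %in% names(variants)) variants$ctx_up else {
    substr(variants$context5, nchar(variants$context5),
           nchar(variants$context5))
  }
  down <- if ("ctx_down" %in% names(variants)) variants$ctx_down else {
    substr(variants$context3, 1, 1)
  }
  ref <- variants$ref
  alt <- variants$alt
  minus <- variants$transcript_strand == "-"
  ch <- paste0(up, "[", ref, ">", alt, "]", down)
  ch[minus] <- revcomp_channel(ch[minus])
  ok <- ch %in% channels
  tab <- table(factor(ch[ok], levels = channels))
  counts[] <- as.integer(tab)
  structure(counts, n_skipped = sum(!ok), class = "txevo_spectrum")
}

#' @export
print.txevo_spectrum <- function(x, ...) {
  cat("192-channel substitution spectrum:", sum(x), "variants",
      sprintf("(%d skipped)\n", attr(x, "n_skipped") %||% 0L))
  nz <- x[x > 0]
  if (length(nz) > 0) print(utils::head(sort(nz, decreasing = TRUE), 10))
  invisible(x)
}

#' Cosine similarity between two spectra
#'
#' @param a,b Nonnegative numeric vectors of equal length (e.g. two
#'   192-channel spectra); both must be nonzero.
#' @return Cosine of the angle, in [0, 1] for nonnegative inputs.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  sum(a * b) / (na * nb)
}

#' Collapse variant tables to unique variants per patient
#'
#' De-duplicates by genomic identity `(chrom, pos, ref, alt)` within each
#' patient/tumour so that recurrent variants in heavily sampled tumours
#' are not over-represented during signature extraction.
#'
#' @param variants Tibble with columns `tumour_id`, `chrom`, `pos`,
#'   `ref`, `alt` (other columns retained from the first occurrence).
#' @return De-duplicated tibble.
#' @export
dedupe_per_patient <- function(variants) {
  dplyr::distinct(variants, .data$tumour_id, .data$chrom, .data$pos,
                  .data$ref, .data$alt, .keep_all = TRUE)
}
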