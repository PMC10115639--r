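#' Detect a hairpin loop around an RNA variant
#'
#' RNA-editing enzymes such as APOBEC3A act preferentially on bases
#' presented in small stem-loops. A hairpin is called when some
#' `loop_len`-nucleotide window (3-5 nt) containing the variant has its
#' immediately flanking 5' and 3' stems complementary over at least
#' `min_stem` bases (the 5' stem equals the reverse complement of the 3'
#' stem).
#'
#' @param sequence Character scalar, the local reference window (mRNA
#'   sense).
#' @param variant_offset 1-based position of the variant within
#'   `sequence`.
#' @param loop_len Candidate loop lengths (default 3:5).
#' @param min_stem Minimum complementary stem length (default 3).
#' @return Logical: hairpin present. With `details = TRUE`, a tibble of
#'   all supporting loop placements (`loop_start`, `loop_len`, `stem5`,
#'   `stem3`).
#' @param details Return the supporting placements instead of a logical?
#' @examples
#' detect_hairpin("GCGACACGC", 5)  # TRUE: loop ACA, stems GCG/CGC
#' @export
detect_hairpin <- function(sequence, variant_offset, loop_len = 3:5,
                           min_stem = 3, details = FALSE) {
  stopifnot(length(sequence) == 1, variant_offset >= 1,
            variant_offset <= nchar(sequence))
  n <- nchar(sequence)
  hits <- list()
  for (L in loop_len) {
    starts <- seq(variant_offset - L + 1, variant_offset)
    for (s in starts) {
      if (s - min_stem < 1 || s + L - 1 + min_stem > n) next
      stem5 <- substr(sequence, s - min_stem, s - 1)
      stem3 <- substr(sequence, s + L, s + L + min_stem - 1)
      if (stem5 == revcomp(stem3)) {
        hits <- c(hits, list(tibble::tibble(
          loop_start = s, loop_len = L, stem5 = stem5, stem3 = stem3)))
      }
    }
  }
  if (details) {
    if (length(hits) == 0) {
      return(tibble::tibble(loop_start = integer(0), loop_len = integer(0),
                            stem5 = character(0), stem3 = character(0)))
    }
    return(dplyr::bind_rows(hits))
  }
  length(hits) > 0
}

# raw cross-product odds ratio; zero motif-context variants give 0
motif_or <- function(tab) {
  if (tab[1, 1] == 0) return(0)
  if (tab[1, 2] == 0 || tab[2, 1] == 0) return(Inf)
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

motif_positions <- function(seq_chr, motif = "CATC") {
  # positions of the edited C: last base of `motif` on '+', first base of
  # revcomp(motif) on '-'
  fwd <- gregexpr(motif, seq_chr, fixed = TRUE)[[1]]
  fwd <- if (fwd[1] == -1) integer(0) else as.integer(fwd) + nchar(motif) - 1L
  rcm <- revcomp(motif)
  rev_ <- gregexpr(rcm, seq_chr, fixed = TRUE)[[1]]
  rev_ <- if (rev_[1] == -1) integer(0) else as.integer(rev_)
  list(fwd = fwd, rev = rev_)
}

#' Local APOBEC motif enrichment of C>T RNA variants
#'
#' Tests, for each C>T variant site (read on either strand: genomic C>T
#' or G>A), whether the *other* C>T variants within `window` nucleotides
#' up- or downstream fall on the APOBEC3A-favoured `CAT[C>T]` motif more
#' often than expected from the motif content of the window. The per-site
#' 2x2 table is `[[motif C>T variants, non-motif C>T variants],
#' [motif-context C positions, non-motif C positions]]` with both strands
#' counted, tested one-tailed (enrichment). Sites whose window contains no
#' other C>T variant are skipped with p recorded as 1. A pooled
#' cohort-level table is also reported.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named character vector (or `DNAStringSet`) of
#'   reference sequences keyed by `chrom`.
#' @param window Number of nucleotides either side (default 20).
#' @param motif 4-mer whose final base is the edited C (default "CATC").
#' @return List with `sites` (per-site tibble: counts, `odds_ratio`,
#'   `p_value`, `skipped`) and `pooled` (one-row tibble from the summed
#'   table).
#' @export
apobec_motif_enrichment <- function(variants, reference, window = 20,
                                    motif = "CATC") {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference),
                                 names(reference))
  }
  v <- tibble::as_tibble(variants)
  is_ct <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
  ct <- v[is_ct, , drop = FALSE]
  if (nrow(ct) == 0) {
    return(list(sites = tibble::tibble(), pooled = tibble::tibble()))
  }
  site_is_motif <- function(chrom, pos) {
    s <- reference[[chrom]]
    base <- substr(s, pos, pos)
    if (base == "C" && pos >= nchar(motif)) {
      substr(s, pos - nchar(motif) + 1, pos) == motif
    } else if (base == "G" && pos + nchar(motif) - 1 <= nchar(s)) {
      substr(s, pos, pos + nchar(motif) - 1) == revcomp(motif)
    } else FALSE
  }
  ct$is_motif <- purrr::map2_lgl(ct$chrom, ct$pos, site_is_motif)

  rows <- purrr::map(seq_len(nrow(ct)), function(i) {
    chrom <- ct$chrom[i]; pos <- ct$pos[i]
    s <- reference[[chrom]]
    lo <- max(1, pos - window); hi <- min(nchar(s), pos + window)
    others <- ct[ct$chrom == chrom & ct$pos >= lo & ct$pos <= hi &
                   ct$pos != pos, , drop = FALSE]
    if (nrow(others) == 0) {
      return(tibble::tibble(chrom = chrom, pos = pos,
                            motif_var = 0L, nonmotif_var = 0L,
                            motif_bg = NA_integer_, nonmotif_bg = NA_integer_,
                            odds_ratio = NA_real_, p_value = 1,
                            skipped = TRUE))
    }
    # background opportunity: C positions (either strand) in the window
    win <- substr(s, lo, hi)
    chars <- strsplit(win, "")[[1]]
    n_c <- sum(chars %in% c("C", "G"))
    mp <- motif_positions(win, motif)
    n_motif_bg <- length(mp$fwd) + length(mp$rev)
    mv <- sum(others$is_motif); nv <- sum(!others$is_motif)
    tab <- matrix(c(mv, nv, n_motif_bg, n_c - n_motif_bg),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "greater")
    or <- motif_or(tab)
    tibble::tibble(chrom = chrom, pos = pos, motif_var = mv,
                   nonmotif_var = nv, motif_bg = n_motif_bg,
                   nonmotif_bg = n_c - n_motif_bg,
                   odds_ratio = or, p_value = ft$p.value, skipped = FALSE)
  })
  sites <- dplyr::bind_rows(rows)
  tested <- sites[!sites$skipped, , drop = FALSE]
  pooled <- if (nrow(tested) == 0) tibble::tibble() else {
    tab <- matrix(c(sum(tested$motif_var), sum(tested$nonmotif_var),
                    sum(tested$motif_bg), sum(tested$nonmotif_bg)),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "greater")
    tibble::tibble(
      motif_var = tab[1, 1], nonmotif_var = tab[1, 2],
      motif_bg = tab[2, 1], nonmotif_bg = tab[2, 2],
      odds_ratio = motif_or(tab), p_value = ft$p.value)
  }
  list(sites = sites, pooled = pooled)
}
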