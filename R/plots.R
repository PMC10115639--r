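#' Plot a 192-channel substitution spectrum
#'
#' Bars per channel, facetted by the 12 substitution classes in
#' transcribed orientation.
#'
#' @param spectrum Named 192-vector from [build_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- tibble::tibble(channel = names(spectrum),
                       count = as.numeric(spectrum)) |>
    dplyr::mutate(
      class = paste0(substr(.data$channel, 3, 3), ">",
                     substr(.data$channel, 5, 5)),
      context = paste0(substr(.data$channel, 1, 1), ".",
                       substr(.data$channel, 7, 7)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~class, nrow = 2, scales = "free_y") +
    ggplot2::labs(x = "trinucleotide context (5'.3')", y = "variants",
                  title = "RNA substitution spectrum (mRNA sense)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 5))
}

#' @export
autoplot.txevo_spectrum <- function(object, ...) plot_spectrum(object)

#' Plot signature exposures across tumour regions
#'
#' @param exposures Long tibble with `region_id`, `signature`,
#'   `exposure` (e.g. from [tidy.txevo_nmf()]).
#' @return A ggplot object.
#' @export
plot_exposures <- function(exposures) {
  ggplot2::ggplot(exposures,
                  ggplot2::aes(x = .data$region_id, y = .data$exposure,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "exposure") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5))
}

#' @export
autoplot.txevo_nmf <- function(object, ...) {
  plot_exposures(generics::tidy(object))
}

#' Plot per-region and per-tumour I-TED
#'
#' @param ited_result Output of [ited()].
#' @return A ggplot object.
#' @export
plot_ited <- function(ited_result) {
  df <- dplyr::filter(ited_result, .data$computed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tumour_id,
                                   y = .data$ited_region)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          colour = "red", shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "I-TED",
                  title = "Intratumour expression distance") +
    ggplot2::theme_bw()
}

#' Plot the distribution of ASE classes per region
#'
#' @param classified Output of [ase_classify()].
#' @return A ggplot object.
#' @export
plot_ase_classes <- function(classified) {
  df <- classified |>
    dplyr::filter(.data$label != "not_evaluable") |>
    dplyr::count(.data$tumour_id, .data$region_id, .data$label) |>
    dplyr::group_by(.data$tumour_id, .data$region_id) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_id, y = .data$frac,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of evaluable genes") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5))
}
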