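#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a de novo signature extraction
#'
#' @param x A `txevo_nmf` object from [extract_signatures()].
#' @param matrix Which component to return: `"exposures"` (long, per
#'   sample, normalized per-sample proportions) or `"signatures"` (long,
#'   per channel).
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.txevo_nmf <- function(x, matrix = "exposures", ...) {
  matrix <- match.arg(matrix, c("exposures", "signatures"))
  if (matrix == "exposures") {
    tibble::as_tibble(as.data.frame(x$exposures_norm),
                      rownames = "signature") |>
      tidyr::pivot_longer(-"signature", names_to = "region_id",
                          values_to = "exposure")
  } else {
    tibble::as_tibble(as.data.frame(x$signatures),
                      rownames = "channel") |>
      tidyr::pivot_longer(-"channel", names_to = "signature",
                          values_to = "weight")
  }
}

#' @rdname tidy.txevo_nmf
#' @export
glance.txevo_nmf <- function(x, ...) {
  tibble::tibble(k = ncol(x$signatures),
                 n_samples = ncol(x$exposures),
                 loss = x$loss)
}

#' Tidy an exposure fit
#'
#' @param x A `txevo_exposure_fit` from [fit_exposures()].
#' @param ... Unused.
#' @return Long tibble with one row per signature (`signature`,
#'   `exposure`), or zero rows for an ineligible fit.
#' @export
tidy.txevo_exposure_fit <- function(x, ...) {
  cols <- grep("^exposure_", names(x), value = TRUE)
  if (!x$eligible[1]) {
    return(tibble::tibble(signature = character(0),
                          exposure = numeric(0)))
  }
  tibble::tibble(signature = sub("^exposure_", "", cols),
                 exposure = as.numeric(x[1, cols]))
}

#' @rdname tidy.txevo_exposure_fit
#' @export
glance.txevo_exposure_fit <- function(x, ...) {
  tibble::tibble(eligible = x$eligible[1],
                 n_variants = x$n_variants[1],
                 residual_cosine = x$residual_cosine[1])
}
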