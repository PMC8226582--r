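#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a segregation test
#'
#' One row per phenotype class with observed and expected counts.
#'
#' @param x A `segregation_test` from [chi_square_segregation()].
#' @param ... Unused.
#' @return A tibble with columns `class`, `observed`, `expected`, `ratio`.
#' @method tidy segregation_test
#' @export
tidy.segregation_test <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    observed = x$observed,
    expected = x$expected,
    ratio = x$ratio
  )
}

#' Glance at a segregation test
#'
#' @param x A `segregation_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `ratio_text`.
#' @method glance segregation_test
#' @export
glance.segregation_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi_square,
    df = x$df,
    p.value = x$p_value,
    ratio_text = x$ratio_text
  )
}

#' Tidy an interval narrowing
#'
#' The per-marker report: position, marker index, recombinant plants.
#'
#' @param x An `interval_narrowing` from [narrow_interval()].
#' @param ... Unused.
#' @return Tibble with one row per marker.
#' @method tidy interval_narrowing
#' @export
tidy.interval_narrowing <- function(x, ...) {
  x$marker_report
}

#' Glance at an interval narrowing
#'
#' @param x An `interval_narrowing`.
#' @param ... Unused.
#' @return The candidate interval tibble with span in Mbp.
#' @method glance interval_narrowing
#' @export
glance.interval_narrowing <- function(x, ...) {
  dplyr::mutate(
    x$interval,
    span_mbp = ifelse(is.na(.data$end), NA_real_, interval_size_mbp(.data$start, .data$end))
  )
}
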