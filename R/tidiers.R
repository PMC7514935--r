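#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DAC result
#'
#' @param x A `dac_result` from [dac()] or [dac_result()].
#' @param ... Unused.
#' @return One-row tibble with the numerator and denominator distances, the
#'   ratio and the conflict flag.
#' @export
tidy.dac_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, numerator = x$numerator,
                 denominator = x$denominator, dac = x$dac,
                 conflict = x$conflict)
}

#' @rdname tidy.dac_result
#' @export
glance.dac_result <- function(x, ...) {
  tibble::tibble(dac = x$dac, conflict = x$conflict, threshold = x$threshold)
}

#' Tidy a surprise p-value result
#'
#' @param x A `nott_result` from [nott_p()].
#' @param ... Unused.
#' @return One-row tibble with the observed discrepancy, p-value, backend and
#'   conflict flag.
#' @export
tidy.nott_result <- function(x, ...) {
  tibble::tibble(observed_discrepancy = x$observed_discrepancy,
                 p_value = x$p_value, method = x$method, draws = x$draws,
                 conflict = x$conflict)
}

#' @rdname tidy.nott_result
#' @export
glance.nott_result <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, conflict = x$conflict,
                 threshold = x$threshold)
}
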