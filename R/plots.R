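#' Plot a decision grid
#'
#' Raster map of the conflict decision over the expert-prior grid
#' (concentration on the x axis, location on the y axis), one facet per
#' distance measure. The boundary between the two colors is the criterion's
#' decision contour (`dac = 1` or `p = 0.05`).
#'
#' @param object A `bbc_grid` from [run_fixed_sample_grid()].
#' @param criterion `"dac"` or `"nott"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bbc_grid <- function(object, criterion = c("dac", "nott"), ...) {
  criterion <- match.arg(criterion)
  df <- dplyr::filter(object, .data$criterion == !!criterion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                   y = .data$location,
                                   fill = .data$conflict)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8",
                                          `TRUE` = "#d95f0e"),
                               name = "conflict") +
    ggplot2::labs(x = "prior concentration (alpha + beta)",
                  y = "prior location (alpha / (alpha + beta))",
                  title = sprintf("%s decision grid (n = %g, s = %g)",
                                  toupper(criterion), df$n[1], df$cell_s[1]))
}

#' Plot replicate conflict rates
#'
#' Stacked bars of conflict vs no-conflict proportions per distance measure,
#' faceted by prior location (rows) and concentration (columns), for one
#' sample size and criterion.
#'
#' @param object A `bbc_replicates` from [run_replicates()].
#' @param criterion `"dac"` or `"nott"`.
#' @param n Sample size to display (default: the smallest in the result).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bbc_replicates <- function(object, criterion = c("dac", "nott"),
                                    n = NULL, ...) {
  criterion <- match.arg(criterion)
  if (is.null(n)) n <- min(object$n)
  df <- object |>
    dplyr::filter(.data$criterion == !!criterion, .data$n == !!n) |>
    dplyr::mutate(measure = factor(.data$measure,
                                   levels = study_measure_names())) |>
    tidyr::pivot_longer(c("no_conflict_rate"), values_to = "rate") |>
    dplyr::mutate(conflict_rate = 1 - .data$rate) |>
    tidyr::pivot_longer(c("rate", "conflict_rate"),
                        names_to = "verdict", values_to = "proportion") |>
    dplyr::mutate(verdict = ifelse(.data$verdict == "rate",
                                   "no conflict", "conflict"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure,
                                   y = .data$proportion,
                                   fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(location ~ concentration) +
    ggplot2::scale_fill_manual(values = c("conflict" = "#d95f0e",
                                          "no conflict" = "#31a354")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "proportion of replicate samples",
                  title = sprintf("%s conflict rates (n = %g)",
                                  toupper(criterion), n))
}

#' @importFrom rlang .data
NULL
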