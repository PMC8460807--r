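# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of polyA usage switches
#'
#' Median delta-PSI against -log10(q), coloured by direction call.
#'
#' @param object An `apa_switches` tibble from [test_switches()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.apa_switches <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median_delta_psi,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(shortened = "#c0392b",
                                            lengthened = "#2980b9",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = expression(median ~ Delta * PSI ~
                                   "(tumor - normal)"),
                  y = expression(-log[10] ~ q),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the PI risk groups
#'
#' @param object An `apa_risk_strata` from [stratify_and_logrank()].
#' @param ... Unused.
#' @return A ggplot of the two risk-group survival curves.
#' @exportS3Method ggplot2::autoplot
autoplot.apa_risk_strata <- function(object, ...) {
  sf <- object$survfit
  d <- tibble::tibble(
    time = sf$time, surv = sf$surv,
    risk = rep(sub("^risk=", "", names(sf$strata)),
               times = sf$strata))
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, risk = unique(d$risk)), d)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                  colour = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival fraction", colour = "risk",
                  subtitle = sprintf("log-rank p = %.2g", object$p)) +
    ggplot2::theme_minimal()
}

#' Distribution of PSI-load by group
#'
#' @param load Tibble `sample_id, psi_load` from [psi_load()].
#' @param metadata Sample table with `sample_id` and a grouping column.
#' @param group Name of the grouping column (default `tissue`).
#' @return A ggplot boxplot.
#' @export
plot_psi_load <- function(load, metadata, group = "tissue") {
  d <- dplyr::inner_join(load, metadata, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(.data[[group]], .data$psi_load,
                                  fill = .data[[group]])) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "PSI-load (median PSI)") +
    ggplot2::theme_minimal()
}
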