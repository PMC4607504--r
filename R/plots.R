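# ggplot2 graphics for trajectories, scans and state comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Concentration of each state metabolite against time.
#' @param object a `ccm_trajectory`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ccm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), -dplyr::any_of("biomass")),
    -"time", names_to = "metabolite", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                     colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)") +
    ggplot2::theme_minimal()
}

#' Plot the distinct states of a phase-space scan
#'
#' Concentration profile of every distinct steady state, coloured by
#' stability class, with basin counts in the strip labels.
#' @param object a `ccm_scan_result`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ccm_scan_result <- function(object, ...) {
  tb <- tidy(object)
  tb$label <- sprintf("state %d (%s, n=%d)", tb$state, tb$classification,
                      tb$basin_count)
  ggplot2::ggplot(tb, ggplot2::aes(.data$metabolite, .data$conc,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "concentration (mM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a two-state comparison
#'
#' Percent change in steady-state metabolite concentration between two
#' states (baseline to alternative), the standard view of a metabolic
#' phenotype shift.
#' @param comparison result of [compare_states()].
#' @export
plot_state_comparison <- function(comparison) {
  tb <- comparison$metabolites
  ggplot2::ggplot(tb[!tb$undefined, ],
                  ggplot2::aes(stats::reorder(.data$metabolite,
                                              .data$percent_change),
                               .data$percent_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% change vs baseline") +
    ggplot2::theme_minimal()
}
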