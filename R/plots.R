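#' Plot the incremental cost-effectiveness plane
#'
#' One point per PSA draw (AI minus no-AI); the lower-right quadrant is
#' cheaper and more effective.
#'
#' @param psa A `caries_psa`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  inc <- psa_increments(psa)
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::labs(x = "Incremental effectiveness (retention years)",
                  y = "Incremental cost (EUR)",
                  title = "Incremental cost-effectiveness, AI vs. no AI") +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ac A `caries_ceac` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ac) {
  ggplot2::ggplot(as.data.frame(ac),
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (EUR per retention year)",
                  y = "Probability cost-effective", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot EVPI/EVPPI curves over the willingness-to-pay grid
#'
#' @param voi A `caries_voi` data frame (rows for several parameters may be
#'   stacked; `parameter == "all"` is the overall EVPI).
#' @return A ggplot object.
#' @export
plot_voi <- function(voi) {
  d <- as.data.frame(voi)
  d$parameter <- ifelse(d$parameter == "all", "EVPI", paste0("EVPPI: ", d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$value,
                                  color = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (EUR per retention year)",
                  y = "Value of information (EUR per individual)",
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
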