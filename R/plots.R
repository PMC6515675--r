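# ggplot2 views of re-executions and operating characteristics.

#' Plot a re-execution's predictive probabilities against its boundaries
#'
#' Shows `P_max` (futility scale) and, where defined, `P_curr` (success
#' scale) at each interim together with the design's stopping boundaries;
#' an interim where `P_max` falls below the futility boundary stops the
#' trial.
#'
#' @param object A `reexecution` from [reexecute()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reexecution <- function(object, ...) {
  trail <- tidy(object)
  if (!nrow(trail)) {
    abort("Fixed design: no interim analyses to plot.")
  }
  long <- tidyr::pivot_longer(
    trail, cols = c("p_curr", "p_max"),
    names_to = "quantity", values_to = "probability"
  )
  long <- long[!is.na(long$probability), ]
  bounds <- dplyr::bind_rows(
    tibble::tibble(interim = seq_len(nrow(object$design$interims)),
                   quantity = "p_max",
                   boundary = object$design$interims$futility),
    tibble::tibble(interim = seq_len(nrow(object$design$interims)),
                   quantity = "p_curr",
                   boundary = object$design$interims$success)
  )
  bounds <- bounds[!is.na(bounds$boundary), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$interim, y = .data$probability)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$quantity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_step(data = bounds,
                       ggplot2::aes(y = .data$boundary),
                       linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(p_curr = "P_curr vs success boundary",
                            p_max = "P_max vs futility boundary"))) +
    ggplot2::scale_x_continuous(breaks = trail$interim) +
    ggplot2::labs(title = sprintf("%s: interim decision trail", object$design$name),
                  x = "interim analysis", y = "predictive probability") +
    ggplot2::theme_minimal()
}

#' Plot operating characteristics across scenarios
#'
#' Stacked early-stopping proportions and mean sample size by scenario, one
#' facet per design, from the combined OC tibble produced by
#' [run_simulate()] (or by row-binding [operating_characteristics()]
#' results).
#'
#' @param oc An OC tibble with columns `design`, `scenario`,
#'   `prop_stop_success`, `prop_stop_futility`, `mean_n`.
#' @return A ggplot object.
#' @export
plot_operating_characteristics <- function(oc) {
  oc <- tibble::as_tibble(oc)
  long <- tidyr::pivot_longer(
    oc, cols = c("prop_stop_success", "prop_stop_futility"),
    names_to = "stop", values_to = "proportion"
  )
  long$stop <- ifelse(long$stop == "prop_stop_success", "success stop", "futility stop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$proportion,
                                     fill = .data$stop)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~design) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "proportion of simulated trials stopped early", x = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_operating_characteristics
#' @param object An `oc_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.oc_table <- function(object, ...) {
  plot_operating_characteristics(object)
}
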