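#' Plot class-conditional item-response profiles
#'
#' One panel per indicator; bars give the probability of each response
#' category conditional on class, with Wald error bars where standard
#' errors are available.
#'
#' @param object An [fit_lca()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lca_fit <- function(object, ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$category,
                                         y = .data$estimate,
                                         fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$indicator)) +
    ggplot2::labs(x = NULL, y = "conditional response probability",
                  fill = "latent class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("std.error" %in% names(tab)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$estimate - 1.96 * .data$std.error, 0),
                   ymax = pmin(.data$estimate + 1.96 * .data$std.error, 1)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2)
  }
  p
}

#' Plot model comparison across candidate class counts
#'
#' @param object An [compare_class_solutions()] result.
#' @param ... Unused.
#' @export
autoplot.lca_comparison <- function(object, ...) {
  tab <- tidyr::pivot_longer(
    dplyr::select(object$table, "k", "bic", "rel_entropy"),
    cols = c("bic", "rel_entropy"), names_to = "metric")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$table$k) +
    ggplot2::labs(x = "number of classes", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of pooled odds ratios
#'
#' @param object A [pool_rubin()] result.
#' @param ... Unused.
#' @export
autoplot.pooled_result <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or.conf.low,
                                         xmax = .data$or.conf.high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
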