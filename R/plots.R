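#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a formal context as an incidence grid
#'
#' @param object A [formal_context()].
#' @param ... Unused.
#' @return A ggplot: objects on the y axis, attributes on the x axis,
#'   filled cells for incidence.
#' @export
autoplot.formal_context <- function(object, ...) {
  objs <- object$objects
  attrs <- object$attributes
  grid <- tidyr::expand_grid(object = objs, attribute = attrs)
  grid$incident <- paste(grid$object, grid$attribute) %in%
    paste(object$pairs$object, object$pairs$attribute)
  ggplot2::ggplot(grid, ggplot2::aes(
    x = factor(.data$attribute, levels = object$attributes),
    y = factor(.data$object, levels = rev(object$objects)),
    fill = .data$incident
  )) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "attribute", y = "object") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-example evaluation terms
#'
#' @param object An `ml_eval` ([evaluate_assignment()]).
#' @param ... Unused.
#' @return A ggplot of the per-example precision/recall/F1 terms with
#'   the macro-averages overlaid as dashed lines.
#' @export
autoplot.ml_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$examples[c("question_id", "precision", "recall", "f1")],
    -"question_id", names_to = "metric", values_to = "value"
  )
  means <- tibble::tibble(
    metric = c("precision", "recall", "f1"),
    value = c(object$example_based$precision,
              object$example_based$recall,
              object$example_based$f1)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$question_id,
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "example", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a concept-filtering trace
#'
#' @param result A `cui_filter_result` ([filter_cuis()]).
#' @return A ggplot of distinct surviving concepts per cascade step.
#' @export
plot_filter_trace <- function(result) {
  trace <- if (inherits(result, "cui_filter_result")) result$trace else result
  ggplot2::ggplot(trace, ggplot2::aes(
    x = factor(.data$step, levels = trace$step),
    y = .data$n_cuis, group = 1
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "filtering step", y = "distinct concepts") +
    ggplot2::theme_minimal()
}
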