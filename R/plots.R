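#' Plot a ROC curve
#'
#' @param object A [roc_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot: the ROC step curve with the chance diagonal.
#' @method autoplot wkelm_roc
#' @export
autoplot.wkelm_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  title = sprintf("ROC curve (AUC = %.4f)",
                                  roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves of an evaluated protocol
#'
#' One curve per split, with the mean AUC in the title.
#'
#' @param object A [run_protocol()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wkelm_eval
#' @export
autoplot.wkelm_eval <- function(object, ...) {
  roc <- purrr::map_dfr(object$reports, function(r) {
    dplyr::mutate(r$roc,
                  split = paste0("repeat ", r$repeat_id,
                                 ifelse(is.na(r$fold), "",
                                        paste0(" fold ", r$fold))))
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6, alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL,
                  title = sprintf("ROC across splits (mean AUC = %.4f)",
                                  object$aggregate$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the fitness history of a GA search
#'
#' Best and mean training-accuracy fitness per generation.
#'
#' @param object A [ga_optimize()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wkelm_ga
#' @export
autoplot.wkelm_ga <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best", "mean"),
                           names_to = "series", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(best = "#B2182B",
                                            mean = "#2166AC")) +
    ggplot2::labs(x = "Generation", y = "Training-accuracy fitness",
                  colour = NULL, title = "GA fitness history") +
    ggplot2::theme_minimal()
}
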