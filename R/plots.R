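#' Plot relative p-value errors of the correction methods
#'
#' Plots `log10(p_model / p_emp)` against the empirical p-value (log axis,
#' decreasing) for the old and new corrections; a perfect estimate lies on
#' the horizontal line 0. Points whose empirical standard is noisy (relative
#' SE > 30%) are hollow.
#'
#' @param object An [compare_corrections()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fsc_comparison <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("log10_new", "log10_old"),
                        names_to = "method", values_to = "log10_ratio") |>
    dplyr::mutate(method = dplyr::recode(.data$method,
                                         log10_new = "new correction",
                                         log10_old = "old correction"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$p_emp, y = .data$log10_ratio,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$noisy)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_colour_manual(values = c("new correction" = "red",
                                            "old correction" = "black")) +
    ggplot2::labs(x = "empirical p-value", y = "log10(p / p_emp)",
                  colour = NULL)
}

#' Plot a pooled ROC curve
#'
#' Cumulative true positives against false positives up to the truncation
#' point of the ROC_n statistic.
#'
#' @param object An [roc_n()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fp, y = .data$tp)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positives", y = "true positives",
                  title = sprintf("ROC_%d = %.4f", object$n_fp, object$score))
}

#' Gumbel fit diagnostic plot
#'
#' Empirical survival of the fitted score maxima overlaid with the fitted
#' Gumbel tail, on a log survival axis.
#'
#' @param object A [fit_gumbel()] result.
#' @param scores The score maxima used in the fit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gumbel_fit <- function(object, scores, ...) {
  tb <- tibble::tibble(y = sort(unique(scores)))
  tb$emp <- vapply(tb$y, function(t) mean(scores > t), numeric(1))
  tb$fit <- 1 - exp(-exp(-(tb$y - object$location) / object$scale))
  tb <- tb[tb$emp > 0, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$emp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "score", y = "P(M > y)")
}
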