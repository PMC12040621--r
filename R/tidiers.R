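#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted benchmark model
#'
#' For the logistic model, one row per coefficient (term, estimate,
#' std.error, statistic, p.value); for the other classifiers, a one-row
#' summary of the fitted object.
#'
#' @param x A `dce_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dce_model <- function(x, ...) {
  if (x$spec$name == "logistic") {
    cf <- summary(x$fit)$coefficients
    tibble::tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
                   statistic = cf[, 3], p.value = cf[, 4])
  } else {
    tibble::tibble(term = x$features, model = x$spec$name)
  }
}

#' One-row summary of a fitted benchmark model
#'
#' @param x A `dce_model`.
#' @param data Optional evaluation data; when supplied, AUC and accuracy on
#'   it are included (point estimates, no bootstrap).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dce_model <- function(x, data = NULL, ...) {
  out <- tibble::tibble(model = x$spec$name, n_features = length(x$features),
                        seed = x$spec$seed)
  if (!is.null(data)) {
    ev <- evaluate_model(x, data, ci = FALSE)
    out <- dplyr::bind_cols(out, ev[c("auc", "accuracy", "sensitivity", "specificity")])
  }
  out
}

#' Tidy a nomogram's point scales
#'
#' @param x A `dce_nomogram`.
#' @param ... Unused.
#' @return The `scales` tibble, one row per feature.
#' @export
tidy.dce_nomogram <- function(x, ...) x$scales

#' Plot ROC curves of a model benchmark
#'
#' @param object A `model_bench` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_bench <- function(object, ...) {
  d <- tidyr::unnest(dplyr::select(tibble::as_tibble(object), "model", "set", "roc"), "roc")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~set) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = "Model") +
    ggplot2::theme_minimal()
}

#' Plot a decision curve against the treat-all / treat-none references
#'
#' @param object A `decision_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decision_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "threshold", "net_benefit",
                  "treat_all", "treat_none"),
    -"threshold", names_to = "policy", values_to = "nb")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                  colour = .data$policy, linetype = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot nomogram point scales
#'
#' Horizontal bars showing each feature's maximum attainable points, with the
#' 0.5-probability total-point threshold in the subtitle.
#'
#' @param object A `dce_nomogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dce_nomogram <- function(object, ...) {
  d <- object$scales
  ggplot2::ggplot(d, ggplot2::aes(x = .data$max_points,
                                  y = stats::reorder(.data$feature, .data$max_points))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Maximum points", y = NULL,
                  subtitle = sprintf("0.5-probability threshold: %.1f total points",
                                     object$threshold_points)) +
    ggplot2::theme_minimal()
}

#' Plot the curve-type composition of lesions
#'
#' @param object A tibble of [analyze_lesion()] rows (optionally with an
#'   identifier column).
#' @param ... Unused.
#' @return A ggplot stacked-bar of P1/P2/P3 per lesion.
#' @export
plot_curve_proportions <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!"lesion" %in% names(d)) d$lesion <- factor(seq_len(nrow(d)))
  long <- tidyr::pivot_longer(d[c("lesion", "P1", "P2", "P3")], -"lesion",
                              names_to = "type", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lesion, y = .data$proportion,
                                     fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(P1 = "#1b9e77", P2 = "#7570b3", P3 = "#d95f02"),
                               labels = c("I (persistent)", "II (plateau)", "III (washout)")) +
    ggplot2::labs(x = "Lesion", y = "Proportion", fill = "Curve type") +
    ggplot2::theme_minimal()
}
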