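#' Build a nomogram from a fitted logistic model
#'
#' Standard point-scale construction: each feature's contribution is rendered
#' as points affine in the feature value, anchored so that the value
#' minimizing its contribution to risk (the low end for positive
#' coefficients, the high end for negative ones) scores 0 points, and scaled
#' so the feature with the largest `|beta| * range` spans exactly 0--100
#' points. Total points map monotonically to predicted probability through
#' the logistic function on the reconstructed linear score, so
#' points -> probability round-trips exactly with [predict_prob()].
#'
#' @param model A `dce_model` of type `"logistic"` with exposed coefficients.
#' @param data Training data frame supplying the feature ranges (defaults to
#'   the ranges stored at training time).
#' @return A `dce_nomogram`: `scales` tibble (`feature`, `beta`, `ref`,
#'   `points_per_unit`, `max_points`), the affine map `offset`/`slope` from
#'   total points to the linear score, and `threshold_points`, the total-point
#'   equivalent of probability 0.5.
#' @export
build_nomogram <- function(model, data = NULL) {
  stopifnot(inherits(model, "dce_model"))
  if (model$spec$name != "logistic") stop("nomograms are built from the logistic model")
  beta <- stats::coef(model$fit)
  b0 <- beta[1]; bs <- beta[-1]
  names(bs) <- model$features
  rng <- if (is.null(data)) {
    model$ranges
  } else {
    apply(as.matrix(tibble::as_tibble(data)[model$features]), 2, range)
  }
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) stop("zero-range feature(s): ",
                           paste(model$features[span == 0], collapse = ", "))
  scale_max <- max(abs(bs) * span)
  # reference (0-point) end: low end when beta > 0, high end when beta < 0
  ref <- ifelse(bs >= 0, rng[1, ], rng[2, ])
  scales <- tibble::tibble(
    feature = model$features,
    beta = unname(bs),
    ref = unname(ref),
    points_per_unit = unname(100 * abs(bs) / scale_max),
    max_points = unname(100 * abs(bs) * span / scale_max))
  offset <- unname(b0 + sum(bs * ref))
  slope <- scale_max / 100
  threshold_points <- -offset / slope  # total points where probability = 0.5
  structure(list(scales = scales, offset = offset, slope = slope,
                 threshold_points = threshold_points),
            class = "dce_nomogram")
}

#' @export
print.dce_nomogram <- function(x, ...) {
  cat("<dce_nomogram> ", nrow(x$scales), " features, 0.5-probability threshold at ",
      sprintf("%.1f", x$threshold_points), " total points\n", sep = "")
  print(x$scales)
  invisible(x)
}

#' Per-patient nomogram points and total
#'
#' @param nomogram A `dce_nomogram`.
#' @param data Data frame with the nomogram's feature columns.
#' @return A tibble with one `points_<feature>` column per feature,
#'   `total_points`, and the mapped `probability`.
#' @export
nomogram_points <- function(nomogram, data) {
  stopifnot(inherits(nomogram, "dce_nomogram"))
  sc <- nomogram$scales
  missing_ <- setdiff(sc$feature, names(data))
  if (length(missing_)) stop("missing feature value(s): ", paste(missing_, collapse = ", "))
  data <- tibble::as_tibble(data)
  pts <- purrr::map(seq_len(nrow(sc)), function(k) {
    x <- data[[sc$feature[k]]]
    sign(sc$beta[k]) * (x - sc$ref[k]) * sc$points_per_unit[k]
  })
  names(pts) <- paste0("points_", sc$feature)
  out <- tibble::as_tibble(pts)
  out$total_points <- Reduce(`+`, pts)
  out$probability <- points_to_probability(nomogram, out$total_points)
  out
}

#' Map total nomogram points to predicted probability
#'
#' @inheritParams nomogram_points
#' @param total_points Numeric vector of total points.
#' @return Probabilities via the logistic function of the reconstructed
#'   linear score.
#' @export
points_to_probability <- function(nomogram, total_points) {
  stats::plogis(nomogram$offset + nomogram$slope * total_points)
}

#' Classify patients by their nomogram total points
#'
#' High risk (non-luminal) when the total is strictly greater than the
#' threshold; a total exactly at the threshold is low risk. The default
#' threshold is the fitted scale's point-equivalent of probability 0.5; any
#' published cutoff is specific to its own fitted scales.
#'
#' @inheritParams nomogram_points
#' @param threshold_points Total-point cutoff (default: the nomogram's
#'   0.5-probability equivalent).
#' @return The tibble from [nomogram_points()] plus a `risk` column
#'   (`"low (luminal)"` / `"high (non-luminal)"`).
#' @export
classify_by_points <- function(nomogram, data, threshold_points = nomogram$threshold_points) {
  out <- nomogram_points(nomogram, data)
  out$risk <- ifelse(out$total_points > threshold_points,
                     "high (non-luminal)", "low (luminal)")
  out
}

#' Decision-curve (net-benefit) analysis
#'
#' Net benefit of acting on the model at threshold probability `t`:
#' \deqn{NB(t) = TP(t)/n - FP(t)/n \cdot t/(1 - t)}
#' where a patient is flagged when the predicted probability is at least `t`.
#' The treat-all policy has `NB = prevalence - (1 - prevalence) t/(1-t)` and
#' treat-none is 0 everywhere.
#'
#' @param prob Predicted probabilities.
#' @param y True 0/1 labels.
#' @param thresholds Threshold grid in (0, 1); default 0.01..0.99 by 0.01.
#' @return A `decision_curve` tibble: `threshold`, `net_benefit` (model),
#'   `treat_all`, `treat_none`, plus `tp`/`fp` counts per threshold.
#' @export
decision_curve <- function(prob, y, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must lie strictly in (0, 1)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  n <- length(y)
  prev <- mean(y)
  rows <- purrr::map_dfr(thresholds, function(t) {
    flag <- prob >= t
    tp <- sum(flag & y == 1); fp <- sum(flag & y == 0)
    tibble::tibble(threshold = t, tp = tp, fp = fp,
                   net_benefit = tp / n - fp / n * t / (1 - t),
                   treat_all = prev - (1 - prev) * t / (1 - t),
                   treat_none = 0)
  })
  class(rows) <- c("decision_curve", class(rows))
  rows
}

#' Write the full report bundle of a benchmark run
#'
#' Writes `roc.csv` (ROC points of every model/set), `nomogram.csv` (point
#' scales), `dca.csv` (decision-curve grid), `summary.json` (the metric
#' suite) and, when a plotting device is available, PNG renderings of the
#' ROC, decision-curve and nomogram-scale figures.
#'
#' @param bench A `model_bench` from [compare_models()].
#' @param nomogram A `dce_nomogram`.
#' @param dca A `decision_curve`.
#' @param out_dir Output directory (created if needed).
#' @param figures Also write PNG figures (default TRUE).
#' @return Invisibly, the named vector of written file paths.
#' @export
report_bundle <- function(bench, nomogram, dca, out_dir, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(roc = file.path(out_dir, "roc.csv"),
             nomogram = file.path(out_dir, "nomogram.csv"),
             dca = file.path(out_dir, "dca.csv"),
             summary = file.path(out_dir, "summary.json"))
  roc_tab <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(bench), "model", "set", "roc"), "roc")
  utils::write.csv(roc_tab, paths["roc"], row.names = FALSE)
  utils::write.csv(nomogram$scales, paths["nomogram"], row.names = FALSE)
  utils::write.csv(dplyr::select(tibble::as_tibble(dca), -dplyr::any_of(c("tp", "fp"))),
                   paths["dca"], row.names = FALSE)
  summary_tab <- dplyr::select(tibble::as_tibble(bench), -"roc")
  jsonlite::write_json(list(metrics = summary_tab,
                            best_model = attr(bench, "best"),
                            nomogram = list(offset = nomogram$offset,
                                            slope = nomogram$slope,
                                            threshold_points = nomogram$threshold_points)),
                       paths["summary"], digits = NA, auto_unbox = TRUE)
  if (figures && (capabilities("png") || capabilities("cairo"))) {
    figs <- c(roc_png = file.path(out_dir, "roc.png"),
              dca_png = file.path(out_dir, "dca.png"),
              nomogram_png = file.path(out_dir, "nomogram.png"))
    ggplot2::ggsave(figs["roc_png"], autoplot.model_bench(bench),
                    width = 8, height = 4, dpi = 120)
    ggplot2::ggsave(figs["dca_png"], autoplot.decision_curve(dca),
                    width = 6, height = 4, dpi = 120)
    ggplot2::ggsave(figs["nomogram_png"], autoplot.dce_nomogram(nomogram),
                    width = 6, height = 4, dpi = 120)
    paths <- c(paths, figs)
  }
  invisible(paths)
}
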