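# rank-based AUC = trapezoidal area under the empirical ROC (ties get 0.5)
auc_rank <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# empirical ROC curve points (threshold sweep over unique probabilities)
roc_points <- function(prob, y) {
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; yy <- y[ord]
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  keep <- c(p[-1] != p[-length(p)], TRUE)
  dplyr::bind_rows(
    tibble::tibble(threshold = Inf, tpr = 0, fpr = 0),
    tibble::tibble(threshold = p[keep],
                   tpr = tp[keep] / max(sum(y == 1), 1),
                   fpr = fp[keep] / max(sum(y == 0), 1)))
}

#' Specification of one benchmark classifier
#'
#' The five classifiers of the benchmark with their fixed, documented
#' hyperparameters (no tuning): logistic regression (unpenalized GLM), Gaussian
#' naive Bayes, k-nearest neighbours (k = 5, Euclidean), decision tree (Gini,
#' effectively unlimited depth) and XGBoost (depth 3, 100 rounds, learning
#' rate 0.1).
#'
#' @param name One of `"logistic"`, `"nb"`, `"knn"`, `"dt"`, `"xgboost"`.
#' @param seed Integer seed fixing all stochastic training.
#' @param ... Hyperparameter overrides (`k` for knn; `max_depth`, `nrounds`,
#'   `eta` for xgboost; `cp`, `minsplit`, `maxdepth` for dt).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name = c("logistic", "nb", "knn", "dt", "xgboost"),
                       seed = 1, ...) {
  name <- match.arg(name)
  hp <- utils::modifyList(switch(name,
    logistic = list(),
    nb = list(),
    knn = list(k = 5),
    dt = list(cp = 0, minsplit = 2, maxdepth = 30),
    xgboost = list(max_depth = 3, nrounds = 100, eta = 0.1)), list(...))
  structure(list(name = name, seed = as.integer(seed), hyper = hp), class = "model_spec")
}

#' Train one classifier on a feature table
#'
#' Fits the classifier named by `spec` on the given feature columns. Features
#' are assumed already standardized with the training-set scaler (see
#' [standard_scale()]). The positive class is non-luminal (label 1).
#'
#' @param spec A [model_spec] (or a model name, converted with defaults).
#' @param data Data frame holding features and the label.
#' @param label Name of the binary 0/1 label column.
#' @param features Character vector of feature columns (default: all numeric
#'   columns except the label).
#' @return A `dce_model`: the fitted object plus the spec, feature names and
#'   training feature ranges (used by the nomogram).
#' @export
train_model <- function(spec, data, label = "label", features = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  data <- tibble::as_tibble(data)
  y <- data[[label]]
  if (!all(y %in% c(0, 1))) stop("label column must be binary 0/1")
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label)
  }
  X <- as.matrix(data[features])
  set.seed(spec$seed)
  fit <- switch(spec$name,
    logistic = {
      df <- data.frame(y = y, X, check.names = FALSE)
      stats::glm(stats::reformulate(sprintf("`%s`", features), "y"),
                 data = df, family = stats::binomial())
    },
    nb = e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
    knn = list(X = X, y = factor(y, levels = c(0, 1)), k = spec$hyper$k),
    dt = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
      rpart::rpart(stats::reformulate(sprintf("`%s`", features), "y"), data = df,
                   method = "class",
                   control = rpart::rpart.control(cp = spec$hyper$cp,
                                                  minsplit = spec$hyper$minsplit,
                                                  maxdepth = spec$hyper$maxdepth,
                                                  xval = 0))
    },
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$hyper$max_depth,
                    learning_rate = spec$hyper$eta,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = spec$hyper$nrounds, verbose = 0)
  )
  structure(list(spec = spec, fit = fit, features = features, label = label,
                 ranges = apply(X, 2, range)),
            class = "dce_model")
}

#' @export
print.dce_model <- function(x, ...) {
  cat("<dce_model> ", x$spec$name, " on ", length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Predicted probability of the positive (non-luminal) class
#'
#' For the logistic model this is exactly the logistic function of the linear
#' score, \eqn{f(x) = 1 / (1 + e^{-(\beta_0 + \sum_i \beta_i x_i)})}.
#'
#' @param model A `dce_model` from [train_model()].
#' @param data Data frame containing the model's feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, data) {
  stopifnot(inherits(model, "dce_model"))
  missing_ <- setdiff(model$features, names(data))
  if (length(missing_)) stop("missing feature column(s): ", paste(missing_, collapse = ", "))
  X <- as.matrix(tibble::as_tibble(data)[model$features])
  switch(model$spec$name,
    logistic = {
      beta <- stats::coef(model$fit)
      stats::plogis(drop(cbind(1, X) %*% beta))
    },
    nb = {
      pr <- stats::predict(model$fit, X, type = "raw")
      unname(pr[, "1"])
    },
    knn = {
      set.seed(model$spec$seed)
      pred <- class::knn(model$fit$X, X, model$fit$y, k = model$fit$k, prob = TRUE)
      pw <- attr(pred, "prob")  # proportion of votes for the winning class
      ifelse(pred == "1", pw, 1 - pw)
    },
    dt = {
      pr <- stats::predict(model$fit, data.frame(X, check.names = FALSE), type = "prob")
      unname(pr[, "1"])
    },
    xgboost = {
      unname(stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
    })
}

# confusion-matrix metric suite at one probability threshold
metrics_at_threshold <- function(prob, y, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  sens <- tp / (tp + fn)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_ else 2 * prec * sens / (prec + sens)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(y),
       sensitivity = sens, specificity = tn / (tn + fp),
       precision = prec, recall = sens, f1 = f1)
}

#' Evaluate predicted probabilities against true labels
#'
#' Computes the full metric suite: confusion matrix at the probability
#' threshold (default 0.5, non-luminal positive), accuracy, sensitivity
#' (= recall), specificity, precision, F1, and the AUC of the trapezoidal ROC
#' with a stratified-bootstrap 95% confidence interval (resampling cases and
#' controls separately, 2000 resamples by default).
#'
#' @param model A `dce_model`, or `NULL` when `prob` is supplied directly.
#' @param data Data frame with features and label (when `model` is given).
#' @param prob Predicted probabilities (alternative to `model` + features).
#' @param y True 0/1 labels (required with `prob`).
#' @param threshold Decision threshold for the confusion matrix.
#' @param ci Compute the bootstrap AUC CI.
#' @param boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `auc`, `auc_low`, `auc_high`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `recall`, `f1`, confusion
#'   counts, plus the ROC points as a list-column `roc`.
#' @export
evaluate_model <- function(model = NULL, data = NULL, prob = NULL, y = NULL,
                           threshold = 0.5, ci = TRUE, boot = 2000, seed = 1) {
  if (!is.null(model)) {
    stopifnot(!is.null(data))
    y <- tibble::as_tibble(data)[[model$label]]
    prob <- predict_prob(model, data)
  }
  if (is.null(prob) || is.null(y)) stop("supply either model+data or prob+y")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  m <- metrics_at_threshold(prob, y, threshold)
  auc <- auc_rank(prob, y)
  lo <- hi <- NA_real_
  if (ci) {
    set.seed(seed)
    i1 <- which(y == 1); i0 <- which(y == 0)
    bs <- vapply(seq_len(boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      auc_rank(prob[idx], y[idx])
    }, numeric(1))
    q <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  tibble::tibble(auc = auc, auc_low = lo, auc_high = hi,
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, precision = m$precision,
                 recall = m$recall, f1 = m$f1,
                 tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
                 n = length(y), threshold = threshold,
                 roc = list(roc_points(prob, y)))
}

#' Benchmark several classifiers on a split cohort
#'
#' Standard-scales the features on the training rows, trains every requested
#' model, evaluates on both sets, and selects the best model by validation
#' accuracy (ties broken by validation AUC, then by name).
#'
#' @param data Feature table including a `split` column
#'   (see [split_cohort()]).
#' @param label,features As in [train_model()].
#' @param models Character vector of model names, or a list of [model_spec]s.
#' @param seed Seed applied to each model's training and bootstrap.
#' @param ci,boot Bootstrap CI settings forwarded to [evaluate_model()].
#' @param scale Standard-scale features on the training rows first (default
#'   TRUE).
#' @return A `model_bench` tibble with one row per model x set and the metric
#'   suite columns; the winning model name in `attr(, "best")` and the fitted
#'   models in `attr(, "models")`.
#' @export
compare_models <- function(data, label = "label", features = NULL,
                           models = c("logistic", "nb", "knn", "dt", "xgboost"),
                           seed = 1, ci = TRUE, boot = 2000, scale = TRUE) {
  data <- tibble::as_tibble(data)
  if (!"split" %in% names(data)) stop("data must carry a 'split' column; see split_cohort()")
  if (is.character(models)) models <- lapply(models, model_spec, seed = seed)
  if (length(models) < 1) stop("need at least one model spec")
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label)
  }
  tr_rows <- data$split == "train"
  if (scale) data <- standard_scale(data, fit_rows = tr_rows, columns = features)
  fits <- list()
  res <- purrr::map_dfr(models, function(sp) {
    fit <- train_model(sp, data[tr_rows, ], label = label, features = features)
    fits[[sp$name]] <<- fit
    purrr::map_dfr(c("train", "validation"), function(s) {
      rows <- data$split == s
      dplyr::bind_cols(tibble::tibble(model = sp$name, set = s),
                       evaluate_model(fit, data[rows, ], ci = ci, boot = boot,
                                      seed = sp$seed))
    })
  })
  val <- res[res$set == "validation", ]
  best <- val[order(-val$accuracy, -val$auc, val$model), ]$model[1]
  attr(res, "best") <- best
  attr(res, "models") <- fits
  class(res) <- c("model_bench", class(res))
  res
}
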