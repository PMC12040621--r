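#' Standard (z-score) scaling fitted on selected rows
#'
#' Standardizes each feature column to zero mean and unit SD over the fit
#' rows, \eqn{X^* = (X - \mu)/\sigma}; the fitted parameters are reapplied
#' unchanged to held-out rows. Constant columns map to 0 with a warning.
#'
#' @param table A data frame; non-numeric columns pass through.
#' @param fit_rows Row selector used to fit `(mu, sigma)` (default all rows).
#' @param columns Columns to scale (default all numeric columns).
#' @return The scaled tibble with fitted parameters in `attr(, "scaling")`
#'   (tibble `column`, `mean`, `sd`).
#' @export
standard_scale <- function(table, fit_rows = NULL, columns = NULL) {
  table <- tibble::as_tibble(table)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  if (is.null(columns)) columns <- names(table)[vapply(table, is.numeric, logical(1))]
  mu <- vapply(columns, function(cn) mean(table[[cn]][fit_rows]), numeric(1))
  sg <- vapply(columns, function(cn) stats::sd(table[[cn]][fit_rows]), numeric(1))
  out <- table
  for (k in seq_along(columns)) {
    cn <- columns[k]
    if (!is.finite(sg[k]) || sg[k] == 0) {
      warning("constant column '", cn, "' mapped to 0")
      out[[cn]] <- rep(0, nrow(table))
    } else {
      out[[cn]] <- (table[[cn]] - mu[k]) / sg[k]
    }
  }
  attr(out, "scaling") <- tibble::tibble(column = columns, mean = unname(mu), sd = unname(sg))
  out
}

# ridge-penalized logistic IRLS fallback for (quasi-)separated fits;
# returns coef, se, p for the single-predictor model (intercept + x)
ridge_logistic_wald <- function(x, y, lambda = 1e-4, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + 2 * pen
    g <- crossprod(X, y - p) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * stats::plogis(drop(X %*% beta)) *
                                    (1 - stats::plogis(drop(X %*% beta)))) + 2 * pen)))
  z <- beta[2] / se[2]
  list(coef = beta[2], se = se[2], p = 2 * stats::pnorm(-abs(z)))
}

#' Screen features against a binary label by logistic regression
#'
#' Univariate mode fits one single-predictor logistic model per feature and
#' keeps features whose Wald P-value falls below the cutoff (no multiplicity
#' correction by default — set `adjust = "BH"` for Benjamini-Hochberg).
#' Two-stage mode follows the univariate screen with a joint multivariable
#' logistic model on the survivors, pruned backward until every remaining
#' coefficient has P below the cutoff. Features with (quasi-)complete
#' separation are flagged and refit with a lightly ridge-penalized logistic
#' model so their P-value stays finite.
#'
#' @param data Data frame with the label and feature columns.
#' @param label Name of the binary 0/1 label column.
#' @param features Character vector of feature columns (default: every
#'   numeric column except the label).
#' @param cutoff Retention threshold on P (default 0.05).
#' @param mode `"univariate"` or `"two-stage"`.
#' @param adjust P-value adjustment method (`"none"` default, or any
#'   [stats::p.adjust()] method).
#' @return A `screening_result` tibble: `feature`, `estimate`, `std.error`,
#'   `p.value`, `separation`, `retained`, ordered by P ascending (ties by
#'   name). Two-stage results carry the joint-model survivors in
#'   `attr(, "joint")`.
#' @export
screen_features <- function(data, label = "label", features = NULL, cutoff = 0.05,
                            mode = c("univariate", "two-stage"), adjust = "none") {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  y <- data[[label]]
  if (is.null(y) || !all(y %in% c(0, 1))) stop("label column must be binary 0/1")
  if (length(unique(y)) < 2) stop("label must contain both classes")
  if (nrow(data) <= 10) stop("need more than 10 rows to screen")
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label)
  }
  rows <- purrr::map(features, function(fn) {
    x <- data[[fn]]
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    sep <- !fit$converged || max(abs(stats::coef(fit)), na.rm = TRUE) > 20 ||
      any(!is.finite(summary(fit)$coefficients[, 2]))
    if (sep) {
      # Wald inference collapses under (quasi-)separation; report the ridge
      # coefficient with a likelihood-ratio P, which stays valid there
      rw <- ridge_logistic_wald(x, y)
      p_lrt <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                             lower.tail = FALSE)
      tibble::tibble(feature = fn, estimate = rw$coef, std.error = rw$se,
                     p.value = p_lrt, separation = TRUE)
    } else {
      cf <- summary(fit)$coefficients
      tibble::tibble(feature = fn, estimate = cf["x", 1], std.error = cf["x", 2],
                     p.value = cf["x", 4], separation = FALSE)
    }
  })
  res <- dplyr::bind_rows(rows)
  if (any(res$separation)) {
    warning("perfect separation detected for: ",
            paste(res$feature[res$separation], collapse = ", "),
            " (ridge-penalized fallback used)")
  }
  res$p.value <- stats::p.adjust(res$p.value, method = adjust)
  res$retained <- res$p.value < cutoff
  res <- dplyr::arrange(res, .data$p.value, .data$feature)

  if (mode == "two-stage") {
    keep <- res$feature[res$retained]
    while (length(keep) > 0) {
      fml <- stats::reformulate(sprintf("`%s`", keep), response = "y")
      dat <- cbind(data.frame(y = y), data[keep])
      names(dat) <- c("y", keep)
      fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      pv <- cf[-1, 4]
      if (all(pv < cutoff)) break
      keep <- setdiff(keep, keep[which.max(pv)])
    }
    res$retained <- res$feature %in% keep
    attr(res, "joint") <- keep
  }
  class(res) <- c("screening_result", class(res))
  res
}

#' Point-biserial correlation of a feature with a binary label
#'
#' Numerically the Pearson correlation of the feature with the label coded
#' 0/1; used as a linearity check between each signature feature and the
#' subtype target.
#'
#' @param feature Numeric vector (non-constant).
#' @param y Binary 0/1 vector of the same length.
#' @return Correlation in `[-1, 1]`.
#' @export
pointbiserial <- function(feature, y) {
  if (length(feature) != length(y)) stop("mismatched lengths")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) stop("y must be binary with both classes")
  if (stats::sd(feature) == 0) stop("constant feature")
  stats::cor(feature, as.numeric(y))
}

#' Two-reader intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — the
#' standard choice for inter-reader reliability of radiomics features —
#' computed from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects and `k = 2` raters. The reliability band follows the
#' usual thresholds: poor < 0.5, moderate 0.5--0.75, good 0.75--0.9,
#' excellent > 0.9.
#'
#' @param reader1,reader2 Paired numeric vectors of one feature measured by
#'   two readers over the same lesions (n >= 3).
#' @return A one-row tibble: `icc`, `band`, `n`.
#' @export
icc_two_reader <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) stop("mismatched lengths")
  n <- length(reader1)
  if (n < 3) stop("need at least 3 paired measurements")
  x <- cbind(reader1, reader2)
  k <- 2
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- (sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g)^2)) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  band <- cut(icc, c(-Inf, 0.5, 0.75, 0.9, Inf),
              labels = c("poor", "moderate", "good", "excellent"), right = FALSE)
  tibble::tibble(icc = icc, band = as.character(band), n = n)
}

#' Group comparison of cohort covariates
#'
#' Builds a clinical-characteristics comparison of the two subtype groups:
#' continuous covariates by Student's two-sample t-test (reported as
#' mean +/- SD per group), categorical covariates by the chi-square test on
#' the contingency table (no continuity correction; Fisher's exact test is
#' substituted automatically when any expected cell count is below 5).
#' P-values are two-sided.
#'
#' @param table Data frame with a grouping column and covariates.
#' @param group Name of the grouping column (2 levels).
#' @param continuous,categorical Covariate column names; by default numeric
#'   columns with > 5 distinct values are treated as continuous and the rest
#'   as categorical.
#' @return A tibble: `variable`, `type`, `test`, group summaries,
#'   `statistic`, `p.value`.
#' @export
cohort_stats <- function(table, group = "group", continuous = NULL, categorical = NULL) {
  table <- tibble::as_tibble(table)
  gl <- table[[group]]
  lev <- sort(unique(gl))
  if (length(lev) != 2) stop("grouping column must have exactly 2 levels")
  if (any(table(gl) == 0)) stop("empty group")
  if (is.null(continuous) && is.null(categorical)) {
    cand <- setdiff(names(table), group)
    num <- cand[vapply(table[cand], is.numeric, logical(1))]
    nd <- vapply(num, function(cn) length(unique(table[[cn]])), integer(1))
    continuous <- num[nd > 5]
    categorical <- c(num[nd <= 5],
                     cand[vapply(table[cand], function(x)
                       is.character(x) || is.factor(x) || is.logical(x), logical(1))])
  }
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  rows <- list()
  for (cn in continuous) {
    x1 <- table[[cn]][gl == lev[1]]; x2 <- table[[cn]][gl == lev[2]]
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = cn, type = "continuous", test = "t",
      group1 = fmt(x1), group2 = fmt(x2),
      statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  for (cn in categorical) {
    tab <- table(table[[cn]], gl)
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_ < 5)) {
      ft <- stats::fisher.test(tab)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = cn, type = "categorical", test = "fisher",
        group1 = paste(tab[, 1], collapse = "/"), group2 = paste(tab[, 2], collapse = "/"),
        statistic = NA_real_, p.value = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = cn, type = "categorical", test = "chisq",
        group1 = paste(tab[, 1], collapse = "/"), group2 = paste(tab[, 2], collapse = "/"),
        statistic = unname(ct$statistic), p.value = ct$p.value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Stratified train/validation split
#'
#' Assigns each patient to the training or validation set at the requested
#' ratio, stratified by label so each class's training share matches the
#' ratio within one patient; the overall training size is exactly
#' `round(ratio * n)`. The assignment is a pure function of
#' `(seed, patient order, labels)`.
#'
#' @param table Feature table (one row per patient).
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param label Label column used for stratification, or `NULL` for an
#'   unstratified split.
#' @return The table with a `split` column (`"train"`/`"validation"`).
#' @export
split_cohort <- function(table, ratio = 0.7, seed = 1, label = "label") {
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  if (n < 10) stop("need at least 10 patients to split")
  n_train <- round(ratio * n)
  set.seed(seed)
  split <- rep("validation", n)
  if (is.null(label)) {
    split[sample.int(n, n_train)] <- "train"
  } else {
    y <- table[[label]]
    cls <- split(seq_len(n), y)
    if (any(lengths(cls) < 2)) stop("each class needs at least 2 members")
    # per-class targets by largest remainder, constrained to sum to n_train
    raw <- lengths(cls) * ratio
    tc <- floor(raw)
    rem <- n_train - sum(tc)
    if (rem > 0) {
      ord <- order(raw - tc, decreasing = TRUE)
      tc[ord[seq_len(rem)]] <- tc[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(raw - tc)
      tc[ord[seq_len(-rem)]] <- tc[ord[seq_len(-rem)]] - 1L
    }
    for (k in seq_along(cls)) {
      split[sample(cls[[k]], tc[k])] <- "train"
    }
  }
  table$split <- split
  table
}
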