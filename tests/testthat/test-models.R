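test_that("logistic training recovers a separable signal with the right sign", {
  set.seed(1)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(label = y, x = y + rnorm(n, sd = 0.4))
  fit <- train_model("logistic", d)
  expect_gt(stats::coef(fit$fit)[["x"]], 0)
  expect_gt(evaluate_model(fit, d, ci = FALSE)$auc, 0.9)
  # determinism: same spec + seed + data -> identical predictions
  for (m in c("logistic", "nb", "knn", "dt", "xgboost")) {
    f1 <- train_model(model_spec(m, seed = 3), d)
    f2 <- train_model(model_spec(m, seed = 3), d)
    expect_identical(predict_prob(f1, d), predict_prob(f2, d))
  }
  expect_error(train_model("logistic", d[d$label == 1, ]), "both classes")
})

test_that("logistic probabilities are exactly the logistic function of the linear score", {
  set.seed(2)
  d <- tibble::tibble(label = rep(c(0, 1), 30), x = rnorm(60), z = rnorm(60))
  fit <- train_model("logistic", d)
  beta <- stats::coef(fit$fit)
  lin <- beta[1] + beta[2] * d$x + beta[3] * d$z
  expect_lt(max(abs(predict_prob(fit, d) - 1 / (1 + exp(-lin)))), 1e-12)
  # direct evaluation of the link: score 0 -> 0.5; score 1 -> 0.7310586
  expect_equal(stats::plogis(0), 0.5)
  expect_equal(stats::plogis(1), 0.7310585786300049, tolerance = 1e-12)
  expect_gte(stats::plogis(50), 1 - 1e-15)  # saturated beyond double resolution
  expect_error(predict_prob(fit, d["x"]), "missing feature")
})

test_that("the metric suite matches the hand-computed confusion arithmetic", {
  # printed-style counts TP=9 FP=1 FN=2 TN=8 at threshold 0.5
  y <- rep(c(1, 0), c(11, 9))
  prob <- c(rep(0.9, 9), rep(0.1, 2), rep(0.9, 1), rep(0.1, 8))
  ev <- evaluate_model(prob = prob, y = y, ci = FALSE)
  expect_identical(c(ev$tp, ev$fp, ev$fn, ev$tn), c(9L, 1L, 2L, 8L))
  expect_equal(ev$sensitivity, 9 / 11, tolerance = 1e-12)
  expect_equal(ev$specificity, 8 / 9, tolerance = 1e-12)
  expect_equal(ev$precision, 0.9, tolerance = 1e-12)
  expect_equal(ev$f1, 2 * (0.9 * 9 / 11) / (0.9 + 9 / 11), tolerance = 1e-12)
  expect_equal(ev$accuracy, 17 / 20, tolerance = 1e-12)
  expect_identical(ev$recall, ev$sensitivity)
  # perfect probabilities give a perfect report
  evp <- evaluate_model(prob = as.numeric(y), y = y, ci = FALSE)
  expect_equal(evp$auc, 1)
  expect_equal(evp$accuracy, 1)
  # metrics consistent with the report's own confusion matrix
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / ev$n)
})

test_that("AUC is rank-based: monotone-transform invariant, null-centred, pROC-concordant", {
  set.seed(33)
  y <- rep(c(0, 1), 100)
  prob <- stats::plogis(y + rnorm(200))
  a1 <- evaluate_model(prob = prob, y = y, ci = FALSE)$auc
  a2 <- evaluate_model(prob = prob^3, y = y, ci = FALSE)$auc  # strictly monotone map
  expect_equal(a1, a2, tolerance = 1e-12)
  # independent cross-check against pROC on the same data
  skip_if_not_installed("pROC")
  a_oracle <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                             direction = "<", levels = c(0, 1))))
  expect_equal(a1, a_oracle, tolerance = 1e-10)
  # probabilities independent of y: AUC near 0.5
  set.seed(34)
  y2 <- rep(c(0, 1), 1000)
  anull <- evaluate_model(prob = runif(2000), y = y2, ci = FALSE)$auc
  expect_gt(anull, 0.45); expect_lt(anull, 0.55)
})

test_that("bootstrap CI brackets the point AUC and narrows with sample size", {
  set.seed(44)
  mk <- function(n) {
    y <- rep(c(0, 1), n / 2)
    evaluate_model(prob = stats::plogis(2 * y + rnorm(n)), y = y, boot = 400, seed = 9)
  }
  small <- mk(100); big <- mk(1000)
  expect_true(small$auc_low <= small$auc && small$auc <= small$auc_high)
  expect_lt(big$auc_high - big$auc_low, small$auc_high - small$auc_low)
})

test_that("model comparison reports both sets, selects by validation accuracy, breaks ties by name", {
  ft <- bench_cohort(seed = 21)
  feats <- signature_features(ft)
  bench <- compare_models(ft, features = feats, ci = FALSE, seed = 21)
  expect_identical(nrow(tibble::as_tibble(bench)), 10L)
  expect_setequal(unique(bench$model), c("logistic", "nb", "knn", "dt", "xgboost"))
  val <- bench[bench$set == "validation", ]
  best <- attr(bench, "best")
  expect_identical(best, val$model[order(-val$accuracy, -val$auc, val$model)][1])
  # single spec: one model, trivially best
  solo <- compare_models(ft, features = feats, models = "nb", ci = FALSE)
  expect_identical(attr(solo, "best"), "nb")
  # identical duplicated specs tie and break by name
  two <- compare_models(ft, features = feats,
                        models = list(model_spec("logistic", seed = 2),
                                      model_spec("logistic", seed = 2)),
                        ci = FALSE)
  expect_identical(attr(two, "best"), "logistic")
})

test_that("flexible learners overfit the training set relative to validation", {
  hits <- vapply(1:10, function(s) {
    ft <- bench_cohort(seed = 300 + s)
    b <- compare_models(ft, features = signature_features(ft), models = "xgboost",
                        ci = FALSE, seed = s)
    b$auc[b$set == "train"] >= b$auc[b$set == "validation"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance expose the fitted logistic model", {
  ft <- bench_cohort(seed = 31)
  fit <- train_model("logistic", ft[ft$split == "train", ],
                     features = c("Heterogeneity", "Washout"))
  td <- generics::tidy(fit)
  expect_identical(td$term[1], "(Intercept)")
  expect_true(all(c("estimate", "p.value") %in% names(td)))
  gl <- generics::glance(fit, data = ft[ft$split == "validation", ])
  expect_identical(gl$model, "logistic")
  expect_true(gl$auc > 0 && gl$auc <= 1)
})
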