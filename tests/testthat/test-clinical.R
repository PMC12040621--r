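fit_small_logistic <- function(seed = 51, features = c("Heterogeneity", "Washout",
                                                       "Correlation_angle90_offset1")) {
  ft <- bench_cohort(seed = seed)
  tr <- ft[ft$split == "train", ]
  list(fit = train_model("logistic", tr, features = features), train = tr, all = ft)
}

test_that("nomogram scales are normalized to the dominant feature and reconstruct the model", {
  env <- fit_small_logistic()
  nom <- build_nomogram(env$fit, env$train)
  expect_equal(max(nom$scales$max_points), 100, tolerance = 1e-9)
  # round trip: total points -> probability equals direct logistic prediction
  pts <- nomogram_points(nom, env$all)
  direct <- predict_prob(env$fit, env$all)
  expect_lt(max(abs(pts$probability - direct)), 1e-9)
  # per-feature points non-negative, total = sum
  expect_true(all(as.matrix(pts[grep("^points_", names(pts))]) >= -1e-9))
  expect_equal(rowSums(pts[grep("^points_", names(pts))]), pts$total_points,
               tolerance = 1e-9)
  # probability is monotone in total points
  ord <- order(pts$total_points)
  expect_true(!is.unsorted(pts$probability[ord]))
})

test_that("a single-feature nomogram spans exactly 0-100 points", {
  set.seed(3)
  d <- tibble::tibble(label = rep(c(0, 1), 40), x = rnorm(80) + rep(c(0, 1), 40))
  fit <- train_model("logistic", d, features = "x")
  nom <- build_nomogram(fit, d)
  pts <- nomogram_points(nom, d)
  expect_equal(min(pts$points_x), 0, tolerance = 1e-9)
  expect_equal(max(pts$points_x), 100, tolerance = 1e-9)
})

test_that("two features with a 2:1 coefficient ratio and equal ranges score 100 and 50 points", {
  # build a synthetic fitted model by hand: beta = (0, 2, 1), ranges [0,1] each
  d <- tibble::tibble(label = rep(c(0, 1), 60), a = runif(120), b = runif(120))
  fit <- train_model("logistic", d, features = c("a", "b"))
  fit$fit$coefficients <- c("(Intercept)" = 0, a = 2, b = 1)
  rng <- rbind(c(0, 0), c(1, 1)); colnames(rng) <- c("a", "b")
  fit$ranges <- rng
  nom <- build_nomogram(fit)
  expect_equal(nom$scales$max_points, c(100, 50), tolerance = 1e-9)
})

test_that("point classification is strict at the threshold and matches probability thresholding", {
  env <- fit_small_logistic(seed = 52)
  nom <- build_nomogram(env$fit, env$train)
  cls <- classify_by_points(nom, env$all)
  # exact threshold -> low risk (strict inequality)
  at <- tibble::tibble(total_points = nom$threshold_points)
  expect_identical(ifelse(at$total_points > nom$threshold_points,
                          "high (non-luminal)", "low (luminal)"), "low (luminal)")
  # agreement with thresholding the direct probability at 0.5
  direct <- predict_prob(env$fit, env$all) > 0.5
  expect_identical(cls$risk == "high (non-luminal)", unname(direct))
  # all features at their minimum-contribution ends -> 0 points, low risk
  sc <- nom$scales
  ref_row <- tibble::as_tibble(as.list(stats::setNames(sc$ref, sc$feature)))
  pts0 <- nomogram_points(nom, ref_row)
  expect_equal(pts0$total_points, 0, tolerance = 1e-9)
})

test_that("decision curves obey the analytic treat-all/none references and a recount oracle", {
  set.seed(61)
  n <- 400
  y <- rep(c(0, 1), c(250, 150))
  prob <- stats::plogis(stats::qlogis(0.375) + 1.5 * (y - mean(y)) + rnorm(n, sd = 0.8))
  thr <- seq(0.01, 0.99, by = 0.01)
  dc <- decision_curve(prob, y, thr)
  prev <- mean(y)
  expect_true(all(dc$treat_none == 0))
  expect_lt(max(abs(dc$treat_all - (prev - (1 - prev) * thr / (1 - thr)))), 1e-12)
  expect_true(all(dc$net_benefit <= prev + 1e-12))
  # brute-force recount at every threshold
  for (k in seq_along(thr)) {
    flag <- prob >= thr[k]
    nb <- sum(flag & y == 1) / n - sum(flag & y == 0) / n * thr[k] / (1 - thr[k])
    expect_equal(dc$net_benefit[k], nb, tolerance = 1e-15)
  }
  expect_error(decision_curve(prob, y, numeric(0)), "empty")
  expect_error(decision_curve(prob, y, c(0, 0.5)), "strictly")
})

test_that("a perfect classifier attains the treat-all limit below every positive's probability", {
  y <- rep(c(0, 1), each = 50)
  prob <- ifelse(y == 1, 0.9, 0.05)
  dc <- decision_curve(prob, y, seq(0.1, 0.85, by = 0.05))
  expect_true(all(abs(dc$net_benefit - 0.5) < 1e-12))
})

test_that("an informative model's curve beats both references on a contiguous interval", {
  env <- fit_small_logistic(seed = 53,
                            features = c("Heterogeneity", "Washout",
                                         "Correlation_angle90_offset1",
                                         "HaralickCorrelation_angle0_offset1"))
  val <- env$all[env$all$split == "validation", ]
  dc <- decision_curve(predict_prob(env$fit, val), val$label)
  above <- dc$net_benefit > pmax(dc$treat_all, 0) + 1e-12
  runs <- rle(above)
  expect_gte(max(runs$lengths[runs$values]), 20)  # >= 0.20-wide interval
})

test_that("the report bundle writes parseable artifacts that round-trip the metrics", {
  env <- fit_small_logistic(seed = 54)
  bench <- compare_models(env$all, features = c("Heterogeneity", "Washout",
                                                "Correlation_angle90_offset1"),
                          models = c("logistic", "nb"), ci = FALSE)
  nom <- build_nomogram(attr(bench, "models")$logistic, env$train)
  val <- env$all[env$all$split == "validation", ]
  dc <- decision_curve(predict_prob(attr(bench, "models")$logistic, val), val$label)
  out <- withr::local_tempdir()
  paths <- report_bundle(bench, nom, dc, out)
  expect_true(all(file.exists(paths[c("roc", "nomogram", "dca", "summary")])))
  dca_csv <- utils::read.csv(paths[["dca"]])
  expect_identical(nrow(dca_csv), nrow(dc))
  js <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  expect_equal(js$metrics$auc[js$metrics$model == "logistic" &
                                js$metrics$set == "validation"],
               bench$auc[bench$model == "logistic" & bench$set == "validation"],
               tolerance = 1e-9)
  expect_identical(js$best_model, attr(bench, "best"))
})
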