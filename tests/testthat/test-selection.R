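test_that("standard scaling centres and scales fit rows and is idempotent on refit", {
  tb <- tibble::tibble(a = c(1, 2, 3), b = c(10, 20, 60))
  out <- standard_scale(tb)
  expect_lt(max(abs(vapply(out, mean, numeric(1)))), 1e-12)
  expect_lt(max(abs(vapply(out, stats::sd, numeric(1)) - 1)), 1e-12)
  again <- standard_scale(out)
  expect_equal(again$a, out$a, tolerance = 1e-12)
  expect_equal(again$b, out$b, tolerance = 1e-12)
  # held-out value mu + 2 sigma maps to 2
  tb2 <- tibble::tibble(a = c(1, 2, 3, 2 + 2 * stats::sd(c(1, 2, 3))))
  out2 <- standard_scale(tb2, fit_rows = 1:3)
  expect_equal(out2$a[4], 2, tolerance = 1e-12)
  expect_warning(standard_scale(tibble::tibble(k = rep(1, 3))), "constant")
})

test_that("screening flags strong signal and calibrates on pure noise", {
  set.seed(314)
  n <- 500
  y <- rep(c(0, 1), each = n / 2)
  strong <- y + rnorm(n, sd = 0.1)
  expect_warning(
    res <- screen_features(tibble::tibble(label = y, strong = strong, junk = rnorm(n))),
    "separation")
  expect_true(res$retained[res$feature == "strong"])
  expect_lt(res$p.value[res$feature == "strong"], 1e-3)
  # type-I calibration: a noise feature is retained at ~the nominal 5% rate
  hits <- vapply(1:50, function(i) {
    d <- tibble::tibble(label = y, x = rnorm(n))
    screen_features(d)$retained[1]
  }, logical(1))
  rate <- mean(hits)
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 50))
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 50))
})

test_that("two-stage screening prunes to a jointly significant panel", {
  ft <- bench_cohort(seed = 11)
  tr <- ft[ft$split == "train", ]
  feats <- c(signature_features(ft), grep("^noise", names(ft), value = TRUE))
  res_uni <- screen_features(tr, features = feats, mode = "univariate")
  res <- screen_features(tr, features = feats, mode = "two-stage")
  kept <- res$feature[res$retained]
  # the joint stage only prunes, never adds
  expect_true(all(kept %in% res_uni$feature[res_uni$retained]))
  expect_gt(length(kept), 0)
  expect_false(any(grepl("^noise", kept)))
  # every survivor is jointly significant
  y <- tr$label
  joint <- stats::glm(stats::reformulate(sprintf("`%s`", kept), "y"),
                      data = cbind(data.frame(y = y), tr[kept]),
                      family = stats::binomial())
  expect_true(all(summary(joint)$coefficients[-1, 4] < 0.05))
  # ordering is deterministic: P ascending
  expect_true(!is.unsorted(res$p.value))
})

test_that("separated features fall back to a penalized fit with finite inference", {
  y <- rep(c(0, 1), each = 20)
  x <- y * 2 - 1  # perfect separation
  expect_warning(res <- screen_features(tibble::tibble(label = y, x = x, z = rnorm(40)),
                                        features = c("x", "z")),
                 "separation")
  expect_true(res$separation[res$feature == "x"])
  expect_true(is.finite(res$p.value[res$feature == "x"]))
  expect_lt(res$p.value[res$feature == "x"], 0.05)
})

test_that("point-biserial equals Pearson on 0/1 coding with the expected signs", {
  y <- rep(c(0, 1), 50)
  expect_equal(pointbiserial(as.numeric(y), y), 1)
  set.seed(5)
  expect_equal(pointbiserial(-y + rnorm(100, sd = 0.01), y), -1, tolerance = 0.01)
  x <- rnorm(10000); yy <- rep(c(0, 1), 5000)
  expect_lt(abs(pointbiserial(x, yy)), 0.05)
  expect_error(pointbiserial(rep(1, 10), rep(c(0, 1), 5)), "constant")
})

test_that("ICC(2,1) honours its algebraic contracts and a variance-components oracle", {
  set.seed(6)
  x <- rnorm(50, 10, 3)
  perfect <- icc_two_reader(x, x)
  expect_equal(perfect$icc, 1, tolerance = 1e-12)
  expect_identical(perfect$band, "excellent")
  # invariance to a common affine transform
  y <- x + rnorm(50, sd = 0.5)
  expect_equal(icc_two_reader(2 * x + 3, 2 * y + 3)$icc, icc_two_reader(x, y)$icc,
               tolerance = 1e-9)
  # independent readers: ICC near zero
  icc0 <- icc_two_reader(rnorm(200), rnorm(200))$icc
  expect_lt(abs(icc0), 0.15)
  # two-variance-components generating model: subject sd 2, error sd 1
  # closed-form ICC = 4 / (4 + 1) = 0.8
  n <- 500
  subj <- rnorm(n, sd = 2)
  r1 <- subj + rnorm(n); r2 <- subj + rnorm(n)
  est <- icc_two_reader(r1, r2)
  expect_lt(abs(est$icc - 0.8), 0.05)
  expect_identical(est$band, "good")
  expect_error(icc_two_reader(1:3, 1:4), "mismatch")
})

test_that("cohort statistics use the right test per variable type", {
  set.seed(8)
  tb <- tibble::tibble(
    group = rep(c("luminal", "nonluminal"), c(133, 139)),
    age = c(rnorm(133, 45.6, 9.0), rnorm(139, 47.7, 10.2)),
    lesions = c(rep(c(0, 1), c(110, 23)), rep(c(0, 1), c(105, 34))))
  res <- cohort_stats(tb)
  expect_identical(res$test[res$variable == "age"], "t")
  expect_identical(res$test[res$variable == "lesions"], "chisq")
  # the multifocality contingency of the emulated cohort is non-significant
  chi_p <- res$p.value[res$variable == "lesions"]
  expect_gt(chi_p, 0.05)
  expect_equal(chi_p,
               stats::chisq.test(matrix(c(110, 23, 105, 34), 2), correct = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("null continuous covariates give uniform p-values and 1-SD shifts are powered", {
  pv <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    tb <- tibble::tibble(group = rep(c("a", "b"), each = 40),
                         v = rnorm(80))
    cohort_stats(tb, continuous = "v", categorical = character())$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  power <- mean(vapply(1:40, function(s) {
    set.seed(2000 + s)
    tb <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                         v = c(rnorm(50), rnorm(50, mean = 1)))
    cohort_stats(tb, continuous = "v", categorical = character())$p.value < 0.01
  }, logical(1)))
  expect_gte(power, 0.95)
})

test_that("the 7:3 split is stratified, exact, and reproducible", {
  ft <- simulate_feature_table(cohort_config(), seed = 3)
  sp <- split_cohort(ft, seed = 4)
  expect_identical(sum(sp$split == "train"), 272L)
  expect_identical(sum(sp$split == "validation"), 116L)
  # stratification within 1 patient per class
  for (cl in 0:1) {
    n_cl <- sum(sp$label == cl)
    n_tr <- sum(sp$label == cl & sp$split == "train")
    expect_lte(abs(n_tr - 0.7 * n_cl), 1)
  }
  expect_identical(split_cohort(ft, seed = 4)$split, sp$split)
  expect_false(identical(split_cohort(ft, seed = 5)$split, sp$split))
  # small-n arithmetic
  tb10 <- tibble::tibble(label = rep(c(0, 1), 5), x = rnorm(10))
  s10 <- split_cohort(tb10, seed = 1)
  expect_identical(sum(s10$split == "train"), 7L)
})
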