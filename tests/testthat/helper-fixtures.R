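# Small deterministic fixtures used across test files.

# 1x1x4 column volume with explicit intensities (z axis)
column_volume <- function(values, spacing = c(1, 1, 1)) {
  vol_image(array(values, dim = c(1, 1, length(values))), spacing = spacing)
}

# random masked volume for GLCM oracle checks: n^3 grid, ~70% mask coverage
random_masked_volume <- function(n = 4, n_levels = 4, p_mask = 0.7) {
  vol <- vol_image(array(runif(n^3), dim = c(n, n, n)))
  m <- array(0L, dim = c(n, n, n))
  m[runif(n^3) < p_mask] <- 1L
  if (sum(m) < 2) m[1:2] <- 1L
  list(vol = vol, mask = lesion_mask(m))
}

# brute-force GLCM by explicit double loop over all in-mask voxel pairs
brute_glcm <- function(qvol, direction, offset) {
  ng <- attr(qvol, "n_levels")
  d <- dim(qvol)
  counts <- matrix(0, ng, ng)
  sh <- direction * offset
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- qvol[i, j, k]
    if (is.na(a)) next
    ii <- i + sh[1]; jj <- j + sh[2]; kk <- k + sh[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    b <- qvol[ii, jj, kk]
    if (is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
  }
  if (sum(counts) == 0) return(NULL)
  m <- counts + t(counts)
  m / sum(m)
}

# brute-force statistic evaluation straight from the textbook formulas
brute_statistic <- function(glcm, statistic, entropy_base = 2) {
  if (is.null(glcm)) return(NA_real_)
  ng <- nrow(glcm)
  tot <- 0
  px <- rowSums(glcm); py <- colSums(glcm)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px)); sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  if (statistic == "Correlation") {
    if (sx == 0 || sy == 0) return(NA_real_)
    for (i in 1:ng) for (j in 1:ng) tot <- tot + (i - mux) * (j - muy) * glcm[i, j]
    return(tot / (sx * sy))
  }
  if (statistic == "HaralickCorrelation") {
    mu_t <- mean(px)
    s_t2 <- mean((px - mu_t)^2)
    if (s_t2 == 0) return(NA_real_)
    for (i in 1:ng) for (j in 1:ng) tot <- tot + i * j * glcm[i, j]
    return((tot - mu_t^2) / s_t2)
  }
  if (statistic == "GLCMEntropy") {
    for (i in 1:ng) for (j in 1:ng) if (glcm[i, j] > 0) {
      tot <- tot - glcm[i, j] * log(glcm[i, j], base = entropy_base)
    }
    return(tot)
  }
  if (statistic == "ClusterShade") {
    for (i in 1:ng) for (j in 1:ng) tot <- tot + (i + j - mux - muy)^3 * glcm[i, j]
    return(tot)
  }
  stop("unknown statistic")
}

# tiny noiseless phantom for recovery tests
tiny_phantom <- function(mixture = c(0.2, 0.5, 0.3), seed = 42, semi = c(6, 6, 6),
                         noise_sd = 0) {
  simulate_lesion(lesion_spec(semi_axes = semi, curve_mixture = mixture,
                              noise_sd = noise_sd), seed = seed)
}

# small benchmark cohort (tabular generator, split attached)
bench_cohort <- function(seed = 1, ...) {
  ft <- simulate_feature_table(cohort_config(...), seed = seed)
  split_cohort(ft, seed = seed)
}

signature_features <- function(ft) {
  c("Heterogeneity", "Washout", grep("offset", names(ft), value = TRUE))
}
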