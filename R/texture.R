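#' Quantize in-mask intensities to discrete gray levels
#'
#' Equal-width binning of the in-mask intensity range onto levels `1..n_levels`;
#' the in-mask maximum maps to `n_levels`. Quantization depends only on the
#' in-mask min/max, so features downstream are invariant to adding a constant
#' to the whole image and to any change outside the mask.
#'
#' @param vol A [vol_image].
#' @param mask A [lesion_mask] on the same grid.
#' @param n_levels Number of gray levels Ng (default 32; typical radiomics
#'   settings run 8--256).
#' @return A `quantized_volume`: integer array (`NA` outside the mask) with
#'   attributes `n_levels` and `range` (the in-mask min/max used).
#' @export
quantize_volume <- function(vol, mask, n_levels = 32) {
  stopifnot(inherits(vol, "vol_image"), inherits(mask, "vol_image"))
  if (!identical(dim(vol$data), dim(mask$data))) stop("volume/mask dimension mismatch")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("n_levels must be at least 2")
  inm <- mask$data > 0
  x <- vol$data[inm]
  rng <- range(x)
  if (diff(rng) == 0) stop("constant in-mask image: texture is degenerate (zero variance)")
  lev <- pmin(floor((x - rng[1]) / diff(rng) * n_levels) + 1L, n_levels)
  out <- array(NA_integer_, dim = dim(vol$data))
  out[inm] <- lev
  structure(out, class = "quantized_volume", n_levels = n_levels, range = rng)
}

#' The 13 unique 3D co-occurrence directions
#'
#' Displacement vectors `(dx, dy, dz)` covering every 3D direction once (the
#' opposite vector is implied by GLCM symmetrization). The first four, with
#' `dz = 0`, are the in-plane axial directions named `angle0` (x), `angle45`,
#' `angle90` (y) and `angle135` in the AK-style feature grammar.
#'
#' @return A 13 x 3 integer matrix with informative rownames.
#' @export
glcm_directions <- function() {
  m <- rbind(
    angle0   = c(1, 0, 0),
    angle45  = c(1, 1, 0),
    angle90  = c(0, 1, 0),
    angle135 = c(-1, 1, 0),
    z        = c(0, 0, 1),
    xz_p     = c(1, 0, 1),
    xz_m     = c(1, 0, -1),
    yz_p     = c(0, 1, 1),
    yz_m     = c(0, 1, -1),
    xyz_ppp  = c(1, 1, 1),
    xyz_mpp  = c(-1, 1, 1),
    xyz_pmp  = c(1, -1, 1),
    xyz_ppm  = c(1, 1, -1))
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix for one direction and offset
#'
#' Counts ordered in-mask voxel pairs `(v, v + offset * direction)`,
#' symmetrizes (each pair counted in both orders) and normalizes to sum 1.
#'
#' @param qvol A `quantized_volume` from [quantize_volume()].
#' @param direction Integer displacement vector of length 3 (components in
#'   -1/0/1), e.g. a row of [glcm_directions()].
#' @param offset Step length in voxels (>= 1).
#' @return An Ng x Ng matrix summing to 1, or `NULL` when the displacement
#'   yields no valid in-mask pair (feature treated as missing).
#' @export
compute_glcm <- function(qvol, direction, offset = 1) {
  stopifnot(inherits(qvol, "quantized_volume"))
  direction <- as.integer(direction)
  offset <- as.integer(offset)
  if (length(direction) != 3L || all(direction == 0L)) stop("direction must be a non-zero length-3 integer vector")
  if (offset < 1L) stop("offset must be >= 1")
  ng <- attr(qvol, "n_levels")
  d <- dim(qvol)
  sh <- direction * offset

  # index windows such that both voxel and its displaced partner are in-volume
  rng <- function(n, s) {
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) NULL else lo:hi
  }
  ix <- rng(d[1], sh[1]); iy <- rng(d[2], sh[2]); iz <- rng(d[3], sh[3])
  if (is.null(ix) || is.null(iy) || is.null(iz)) return(NULL)
  a <- qvol[ix, iy, iz, drop = FALSE]
  b <- qvol[ix + sh[1], iy + sh[2], iz + sh[3], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  counts <- table(factor(a[keep], levels = 1:ng), factor(b[keep], levels = 1:ng))
  m <- unclass(counts) + t(unclass(counts))
  m / sum(m)
}

#' Scalar texture statistic of a GLCM
#'
#' With entries \eqn{p(i,j)} over level indices and marginal mean/SD
#' \eqn{\mu, \sigma} (x and y marginals coincide on a symmetrized GLCM):
#' \describe{
#'   \item{Correlation}{\eqn{\sum_{ij} (i-\mu)(j-\mu) p(i,j) / \sigma^2}
#'     (Pearson correlation of the level pair; in `[-1, 1]`).}
#'   \item{HaralickCorrelation}{\eqn{(\sum_{ij} i j\, p(i,j) - \mu_t^2)/\sigma_t^2}
#'     in the ITK convention, where \eqn{\mu_t, \sigma_t} are the mean and SD
#'     of the Ng entries of the marginal probability vector itself — the
#'     reading under which this feature is distinct from `Correlation` and
#'     takes the large magnitudes familiar from AK/ITK output.}
#'   \item{GLCMEntropy}{\eqn{-\sum_{p>0} p \log_2 p} (base configurable).}
#'   \item{ClusterShade}{\eqn{\sum_{ij} (i + j - 2\mu)^3 p(i,j)}, the third
#'     central cross-moment (sign carries the asymmetry).}
#' }
#'
#' @param glcm Matrix from [compute_glcm()].
#' @param statistic One of `"Correlation"`, `"HaralickCorrelation"`,
#'   `"GLCMEntropy"`, `"ClusterShade"`.
#' @param entropy_base Log base for `GLCMEntropy` (default 2, i.e. bits).
#' @return The statistic value, or `NA` when undefined (zero marginal
#'   variance for the correlation statistics).
#' @export
glcm_statistic <- function(glcm, statistic = c("Correlation", "HaralickCorrelation",
                                               "GLCMEntropy", "ClusterShade"),
                           entropy_base = 2) {
  statistic <- match.arg(statistic)
  if (is.null(glcm)) return(NA_real_)
  ng <- nrow(glcm)
  i <- seq_len(ng)
  px <- rowSums(glcm)            # == colSums for a symmetrized GLCM
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  switch(statistic,
    Correlation = {
      if (sig2 <= 0) return(NA_real_)
      sum(outer(i - mu, i - mu) * glcm) / sig2
    },
    HaralickCorrelation = {
      mu_t <- mean(px)
      sig_t2 <- sum((px - mu_t)^2) / ng
      if (sig_t2 <= 0) return(NA_real_)
      (sum(outer(i, i) * glcm) - mu_t^2) / sig_t2
    },
    GLCMEntropy = {
      p <- glcm[glcm > 0]
      -sum(p * log(p, base = entropy_base))
    },
    ClusterShade = sum(outer(i, i, function(a, b) (a + b - 2 * mu)^3) * glcm)
  )
}

#' Aggregate a per-direction statistic into AllDirection mean and SD
#'
#' The AK-style `AllDirection` value is the arithmetic mean of a statistic
#' over the 13 unique 3D directions, and the `_SD` suffix its population
#' standard deviation over the same set. Directions where the statistic is
#' undefined are dropped with a warning.
#'
#' @param values Numeric vector of per-direction values (possibly with `NA`).
#' @return `c(mean =, sd =)`; both `NA` when fewer than 2 directions are
#'   defined.
#' @export
aggregate_directions <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < length(values)) warning(sum(!ok), " direction(s) undefined; dropped from AllDirection aggregate")
  v <- values[ok]
  if (length(v) < 2) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Extract a named GLCM texture panel from one phase
#'
#' Computes every feature of the AK-style grammar
#' `<Statistic>_<angle0|angle45|angle90|angle135|AllDirection>_offset<d>[_SD]`:
#' planar angles are single axial-plane directions; `AllDirection` is the
#' mean over the 13 unique 3D directions and `AllDirection..._SD` their
#' population SD. The default panel crosses the four co-occurrence statistics
#' with the four planar angles plus the AllDirection mean/SD at offsets 1, 4
#' and 7 voxels (= mm on the 1 mm isotropic grid), 72 features, a superset of
#' the eight-feature signature used for subtype prediction.
#'
#' @param vol A [vol_image] — conventionally the initial post-contrast phase,
#'   the most intensely enhancing one.
#' @param mask A [lesion_mask].
#' @param statistics Character vector of statistics (see [glcm_statistic()]).
#' @param angles Planar angle names among `angle0/angle45/angle90/angle135`.
#' @param offsets Integer offsets in voxels.
#' @param n_levels Quantization levels (see [quantize_volume()]).
#' @param entropy_base Log base for `GLCMEntropy`.
#' @param all_direction Include the `AllDirection` mean and `_SD` aggregates.
#' @return A one-row wide tibble, one column per feature name; undefined
#'   features are `NA`.
#' @export
extract_features <- function(vol, mask,
                             statistics = c("Correlation", "HaralickCorrelation",
                                            "GLCMEntropy", "ClusterShade"),
                             angles = c("angle0", "angle45", "angle90", "angle135"),
                             offsets = c(1, 4, 7),
                             n_levels = 32, entropy_base = 2,
                             all_direction = TRUE) {
  dirs <- glcm_directions()
  bad <- setdiff(angles, rownames(dirs)[1:4])
  if (length(bad)) stop("unknown angle(s): ", paste(bad, collapse = ", "))
  qv <- quantize_volume(vol, mask, n_levels = n_levels)
  out <- list()
  for (off in offsets) {
    glcms <- lapply(seq_len(nrow(dirs)), function(k) compute_glcm(qv, dirs[k, ], off))
    names(glcms) <- rownames(dirs)
    for (st in statistics) {
      vals <- vapply(glcms, glcm_statistic, numeric(1), statistic = st,
                     entropy_base = entropy_base)
      for (an in angles) {
        out[[sprintf("%s_%s_offset%d", st, an, off)]] <- unname(vals[an])
      }
      if (all_direction) {
        agg <- suppressWarnings(aggregate_directions(vals))
        out[[sprintf("%s_AllDirection_offset%d", st, off)]] <- unname(agg["mean"])
        out[[sprintf("%s_AllDirection_offset%d_SD", st, off)]] <- unname(agg["sd"])
      }
    }
  }
  tibble::as_tibble(out)
}

#' Parse an AK-style feature name
#'
#' @param name Character vector of feature names such as
#'   `"HaralickCorrelation_AllDirection_offset7_SD"`.
#' @return A tibble with columns `name`, `statistic`, `angle`, `offset`,
#'   `aggregate` (`"value"` or `"SD"`).
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexec(
    "^([A-Za-z]+)_(angle0|angle45|angle90|angle135|AllDirection)_offset([0-9]+)(_SD)?$", name))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("feature name does not parse: ", paste(name[bad], collapse = ", "))
  tibble::tibble(
    name = name,
    statistic = vapply(m, `[`, character(1), 2),
    angle = vapply(m, `[`, character(1), 3),
    offset = as.integer(vapply(m, `[`, character(1), 4)),
    aggregate = ifelse(vapply(m, `[`, character(1), 5) == "_SD", "SD", "value"))
}

#' Min-max normalization fitted on selected rows
#'
#' Affine rescale of each feature column to `[0, 1]` over the fit rows; the
#' fitted (min, max) are reapplied unchanged to held-out rows, which may
#' therefore fall outside `[0, 1]` (no clipping). Constant columns map to 0
#' with a warning.
#'
#' @param table A data frame of numeric feature columns (non-numeric columns
#'   pass through untouched).
#' @param fit_rows Logical or integer row selector used to fit the ranges
#'   (default: all rows).
#' @param columns Columns to normalize (default: all numeric columns).
#' @return The normalized tibble, with the fitted parameters in
#'   `attr(, "ranges")` (tibble `column`, `min`, `max`).
#' @export
minmax_normalize <- function(table, fit_rows = NULL, columns = NULL) {
  table <- tibble::as_tibble(table)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  if (is.null(columns)) columns <- names(table)[vapply(table, is.numeric, logical(1))]
  rng <- purrr::map(columns, function(cn) range(table[[cn]][fit_rows]))
  out <- table
  for (k in seq_along(columns)) {
    cn <- columns[k]; r <- rng[[k]]
    if (diff(r) == 0) {
      warning("constant column '", cn, "' mapped to 0")
      out[[cn]] <- rep(0, nrow(table))
    } else {
      out[[cn]] <- (table[[cn]] - r[1]) / diff(r)
    }
  }
  attr(out, "ranges") <- tibble::tibble(column = columns,
                                        min = vapply(rng, `[`, numeric(1), 1),
                                        max = vapply(rng, `[`, numeric(1), 2))
  out
}
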