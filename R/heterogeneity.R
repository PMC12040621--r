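#' Classify one voxel's enhancement curve
#'
#' Three-phase kinetic typing used throughout breast DCE-MRI reading: with
#' relative late change \eqn{r = (s_{delayed} - s_{initial}) / s_{initial}},
#' a voxel is *persistent* (type I) when `r > tau`, *washout* (type III) when
#' `r < -tau` and *plateau* (type II) otherwise. Voxels whose initial uptake
#' `(s_initial - s_pre)/s_pre` falls below `min_enhancement` are excluded as
#' non-enhancing (necrosis/cysts that slipped into a manual mask); set
#' `min_enhancement = 0` to classify everything. `reference = "pre"` switches
#' the late-change denominator to the pre-contrast signal for software
#' conventions that measure washout against baseline.
#'
#' @param s_pre,s_initial,s_delayed Signal at the pre-contrast, initial
#'   (~90 s) and delayed phases. Vectorized.
#' @param tau Plateau half-width on the relative late change (default 0.10).
#' @param min_enhancement Minimum initial uptake fraction (default 0.10).
#' @param reference Denominator of the late change: `"initial"` (default) or
#'   `"pre"`.
#' @return Integer vector: 1, 2, 3 for curve types I/II/III, `NA` for
#'   excluded voxels.
#' @export
classify_voxel_curve <- function(s_pre, s_initial, s_delayed, tau = 0.10,
                                 min_enhancement = 0.10,
                                 reference = c("initial", "pre")) {
  reference <- match.arg(reference)
  if (any(!is.finite(s_pre)) || any(!is.finite(s_initial)) || any(!is.finite(s_delayed))) {
    stop("signals must be finite")
  }
  if (any(s_pre <= 0)) stop("pre-contrast signal must be positive")
  if (tau < 0) stop("tau must be non-negative")
  enh <- (s_initial - s_pre) / s_pre
  denom <- if (reference == "initial") s_initial else s_pre
  r <- (s_delayed - s_initial) / denom
  lab <- ifelse(r > tau, 1L, ifelse(r < -tau, 3L, 2L))
  lab[enh < min_enhancement] <- NA_integer_
  lab
}

#' Voxel-wise curve-type map of a lesion
#'
#' Applies [classify_voxel_curve()] to every in-mask voxel of a three-phase
#' series.
#'
#' @param series A [dce_series] (geometry assumed validated, see
#'   [validate_series()]).
#' @param mask A [lesion_mask] on the same grid.
#' @inheritParams classify_voxel_curve
#' @return A `curve_type_map`: integer array matching the volume, with 1/2/3
#'   inside the mask (`NA` for excluded voxels) and `NA` outside.
#' @export
curve_type_map <- function(series, mask, tau = 0.10, min_enhancement = 0.10,
                           reference = c("initial", "pre")) {
  rep_ <- validate_series(series, mask)
  if (!attr(rep_, "passed")) stop("series/mask geometry mismatch:\n", paste(rep_$message, collapse = "\n"))
  inm <- mask$data > 0
  if (!any(inm)) stop("empty mask")
  out <- array(NA_integer_, dim = dim(mask$data))
  out[inm] <- classify_voxel_curve(series$pre$data[inm], series$initial$data[inm],
                                   series$delayed$data[inm], tau = tau,
                                   min_enhancement = min_enhancement,
                                   reference = reference)
  structure(out, class = "curve_type_map", mask = which(inm))
}

#' Curve-type proportions of a lesion
#'
#' Counts classified (non-excluded) in-mask voxels of each kinetic type and
#' returns their proportions, computed on integer counts so they sum to 1
#' exactly up to float division.
#'
#' @param map A `curve_type_map` from [curve_type_map()], or an integer
#'   vector/array of labels 1/2/3 with `NA` for excluded.
#' @return Named numeric vector `c(P1 =, P2 =, P3 =)` with attributes
#'   `n_voxels` (classified) and `n_excluded`.
#' @export
curve_proportions <- function(map) {
  lab <- if (inherits(map, "curve_type_map")) unclass(map)[attr(map, "mask")] else as.integer(map)
  n_exc <- sum(is.na(lab))
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) stop("no classifiable voxels (all excluded as non-enhancing)")
  counts <- tabulate(lab, nbins = 3L)
  p <- counts / sum(counts)
  structure(stats::setNames(p, c("P1", "P2", "P3")),
            counts = counts, n_voxels = sum(counts), n_excluded = n_exc)
}

#' Entropy heterogeneity index of curve-type proportions
#'
#' Shannon entropy of the lesion's curve-type distribution,
#' \eqn{H = -\sum_k P_k \log P_k}, with \eqn{0 \log 0 := 0}. Natural log by
#' default (so \eqn{0 \le H \le \ln 3}); the base only rescales the index.
#'
#' @param p Numeric vector of proportions summing to 1 (any length; the
#'   three-curve-type case has length 3). Alternatively three scalars
#'   `heterogeneity_index(P1, P2, P3)`.
#' @param ... Further proportion components.
#' @param base Logarithm base; `exp(1)` (default) or e.g. `2`.
#' @param tol Tolerance on `sum(p) == 1`.
#' @return The entropy index, a single number.
#' @export
heterogeneity_index <- function(p, ..., base = exp(1), tol = 1e-9) {
  p <- c(p, ...)
  if (any(!is.finite(p)) || any(p < 0)) stop("proportions must be finite and non-negative")
  if (abs(sum(p) - 1) > tol) stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Full heterogeneity analysis of one lesion
#'
#' Voxel-wise curve typing followed by the four heterogeneity parameters:
#' the three curve-type proportions and the entropy index.
#'
#' @inheritParams curve_type_map
#' @param base Logarithm base for the entropy index.
#' @return A one-row tibble: `P1`, `P2`, `P3`, `H`, `n_voxels`, `n_excluded`.
#' @export
analyze_lesion <- function(series, mask, tau = 0.10, min_enhancement = 0.10,
                           reference = c("initial", "pre"), base = exp(1)) {
  map <- curve_type_map(series, mask, tau = tau, min_enhancement = min_enhancement,
                        reference = reference)
  p <- curve_proportions(map)
  tibble::tibble(P1 = p[["P1"]], P2 = p[["P2"]], P3 = p[["P3"]],
                 H = heterogeneity_index(as.numeric(p), base = base),
                 n_voxels = attr(p, "n_voxels"), n_excluded = attr(p, "n_excluded"))
}
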