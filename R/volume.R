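#' Volumetric image container
#'
#' A `vol_image` holds one 3D scalar grid together with its voxel spacing and
#' world origin, the minimal geometry needed for resampling and for checking
#' that dynamic phases and lesion masks live on the same grid. Arrays are
#' indexed `[x, y, z]` with `z` the slice axis; voxel indices are 0-based in
#' world-coordinate formulas (`world = origin + index * spacing`).
#'
#' @param data Numeric 3D array.
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @param origin World coordinate of voxel (0,0,0) in mm, length 3.
#'
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("non-3D image: expected a 3D array, got ", length(dim(data)), "D")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) stop("origin must be 3 finite numbers (mm)")
  if (any(!is.finite(data))) stop("image intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin), class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  cat("<vol_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 6), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.vol_image <- function(x) dim(x$data)

#' Read a 3D volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim` and the origin from the
#' translation column of the stored affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [vol_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D image: ", path, " has ", length(d), " dimensions")
  xf <- RNifti::xform(img)
  vol_image(array(as.numeric(img), dim = d),
            spacing = RNifti::pixdim(img)[1:3],
            origin = xf[1:3, 4])
}

#' Write a 3D volume to a NIfTI file
#'
#' @param vol A [vol_image].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol_image"))
  affine <- diag(4)
  diag(affine)[1:3] <- vol$spacing
  affine[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Bundle the three dynamic phases of a DCE acquisition
#'
#' The three phases (pre-contrast, initial ~90 s post-contrast, delayed/final)
#' must be co-registered on an identical grid; this is checked at construction
#' within a small geometric tolerance.
#'
#' @param pre,initial,delayed [vol_image] objects for the three phases.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(pre, initial, delayed) {
  vols <- list(pre = pre, initial = initial, delayed = delayed)
  stopifnot(all(vapply(vols, inherits, logical(1), "vol_image")))
  rep_ <- geometry_report(vols)
  if (nrow(rep_) > 0) {
    stop("dynamic phases are not on a common grid:\n",
         paste(rep_$message, collapse = "\n"))
  }
  structure(vols, class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat("<dce_series> 3 phases, ", paste(dim(x$pre$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$pre$spacing, 6), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Lesion mask on the grid of a dynamic series
#'
#' @param data 3D array of 0/1 values with at least one foreground voxel.
#' @inheritParams vol_image
#' @return An object of class `lesion_mask` (also a `vol_image`).
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- vol_image(data, spacing, origin)
  if (!all(v$data %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (sum(v$data) < 1) stop("mask has no foreground voxels")
  class(v) <- c("lesion_mask", class(v))
  v
}

#' Read a lesion mask from NIfTI
#'
#' @inheritParams read_volume
#' @return A [lesion_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lesion_mask(v$data, v$spacing, v$origin)
}

# One row per geometry mismatch across a named list of vol_images.
geometry_report <- function(vols, tol = 1e-6) {
  nm <- names(vols)
  ref <- vols[[1]]
  out <- list()
  for (i in seq_along(vols)[-1]) {
    v <- vols[[i]]
    if (!identical(dim(v$data), dim(ref$data))) {
      out[[length(out) + 1L]] <- tibble::tibble(
        field = "dim", a = nm[1], b = nm[i],
        message = sprintf("dimension mismatch %s (%s) vs %s (%s)", nm[1],
                          paste(dim(ref$data), collapse = "x"), nm[i],
                          paste(dim(v$data), collapse = "x")))
    }
    if (max(abs(v$spacing - ref$spacing)) > tol) {
      out[[length(out) + 1L]] <- tibble::tibble(
        field = "spacing", a = nm[1], b = nm[i],
        message = sprintf("spacing mismatch %s vs %s", nm[1], nm[i]))
    }
    if (max(abs(v$origin - ref$origin)) > tol) {
      out[[length(out) + 1L]] <- tibble::tibble(
        field = "origin", a = nm[1], b = nm[i],
        message = sprintf("origin mismatch %s vs %s", nm[1], nm[i]))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(field = character(), a = character(), b = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Check that a dynamic series and mask share one grid
#'
#' Compares dimensions, spacing and origin of all four grids (three phases
#' plus the mask) within a tolerance of 1e-6 mm and reports every mismatch
#' rather than stopping at the first.
#'
#' @param series A [dce_series].
#' @param mask A [lesion_mask].
#' @param tol Geometric tolerance in mm.
#' @return A tibble with one row per mismatch (`field`, `a`, `b`, `message`);
#'   zero rows means the geometry is consistent. The `passed` attribute holds
#'   the overall verdict.
#' @export
validate_series <- function(series, mask, tol = 1e-6) {
  stopifnot(inherits(series, "dce_series"), inherits(mask, "vol_image"))
  rep_ <- geometry_report(list(pre = series$pre, initial = series$initial,
                               delayed = series$delayed, mask = mask), tol = tol)
  attr(rep_, "passed") <- nrow(rep_) == 0
  rep_
}

#' Resample a volume to an isotropic grid
#'
#' Produces a grid with the requested isotropic spacing covering the same
#' physical extent (the output grid never extrapolates beyond the input's
#' outermost voxel centres, so extent is preserved to within one voxel).
#' Images are interpolated trilinearly; masks must use nearest-neighbour so
#' values stay binary.
#'
#' @param vol A [vol_image] (or [lesion_mask]).
#' @param target_spacing Isotropic output spacing in mm (default 1).
#' @param interpolation `"linear"` or `"nearest"`; defaults to `"nearest"`
#'   for masks, `"linear"` otherwise.
#' @return A resampled [vol_image] (class preserved for masks).
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               interpolation = if (inherits(vol, "lesion_mask")) "nearest" else "linear") {
  stopifnot(inherits(vol, "vol_image"))
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("target_spacing must be a single positive number")
  d <- dim(vol$data)
  if (max(abs(vol$spacing - t)) < 1e-12) return(vol)  # already on the target grid

  # output voxel-centre positions, in input index units, per axis
  ax <- lapply(1:3, function(k) {
    n_out <- floor((d[k] - 1) * vol$spacing[k] / t) + 1L
    (seq_len(n_out) - 1) * t / vol$spacing[k]
  })

  if (interpolation == "nearest") {
    idx <- lapply(1:3, function(k) pmin(pmax(round(ax[[k]]) + 1L, 1L), d[k]))
    out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(k) pmin(floor(ax[[k]]), d[k] - 1 - (d[k] > 1)) + 1L)
    # fraction within the cell; degenerate axes (length 1) get weight 0
    fr <- lapply(1:3, function(k) if (d[k] > 1) ax[[k]] - (i0[[k]] - 1) else rep(0, length(ax[[k]])))
    n_out <- vapply(ax, length, integer(1))
    out <- array(0, dim = n_out)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- outer(outer(if (dx) fr[[1]] else 1 - fr[[1]],
                       if (dy) fr[[2]] else 1 - fr[[2]]),
                 if (dz) fr[[3]] else 1 - fr[[3]])
      if (all(w == 0)) next
      ii <- pmin(i0[[1]] + dx, d[1]); jj <- pmin(i0[[2]] + dy, d[2]); kk <- pmin(i0[[3]] + dz, d[3])
      out <- out + w * vol$data[ii, jj, kk, drop = FALSE]
    }
  }
  res <- vol_image(out, spacing = rep(t, 3), origin = vol$origin)
  if (inherits(vol, "lesion_mask")) {
    res$data <- round(res$data)
    class(res) <- class(vol)
  }
  res
}

#' Resample a whole dynamic series and its mask
#'
#' Convenience wrapper applying [resample_isotropic()] to all three phases
#' (trilinear) and the mask (nearest-neighbour).
#'
#' @inheritParams validate_series
#' @inheritParams resample_isotropic
#' @return A list with elements `series` and `mask` on the isotropic grid.
#' @export
resample_case <- function(series, mask, target_spacing = 1) {
  list(series = dce_series(resample_isotropic(series$pre, target_spacing),
                           resample_isotropic(series$initial, target_spacing),
                           resample_isotropic(series$delayed, target_spacing)),
       mask = resample_isotropic(mask, target_spacing, "nearest"))
}
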