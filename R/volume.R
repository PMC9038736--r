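# Volume containers and the two standardisation steps every radiomics run
# starts with: resampling to a common voxel spacing and fixed-bin-number
# intensity discretisation over mean +/- k * SD inside the mask.

#' Create a 3-D intensity volume
#'
#' A `volume_grid` holds a 3-D array of scalar intensities (Hounsfield units
#' for CT) together with its anisotropic voxel spacing and world origin.
#' Voxel centres sit at `origin + (index - 1) * spacing` (1-based R indices),
#' with axes ordered (x, y, z) and z the cranio-caudal direction.
#'
#' @param intensities numeric 3-D array.
#' @param spacing_mm positive numeric of length 3, voxel spacing in mm.
#' @param origin_mm numeric of length 3, world position of the first voxel
#'   centre in mm.
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive finite numbers")
  }
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(
    list(intensities = intensities,
         spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "volume_grid"
  )
}

#' Create a binary mask on a voxel grid
#'
#' @param labels logical or 0/1 numeric 3-D array.
#' @inheritParams volume_grid
#' @return object of class `mask_volume`.
#' @export
mask_volume <- function(labels, spacing_mm, origin_mm = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("mask values must be 0 or 1")
    labels <- array(labels == 1, dim(labels))
  }
  if (!is.logical(labels)) stop("mask must be logical or 0/1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive numbers")
  }
  structure(
    list(labels = labels,
         spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "mask_volume"
  )
}

#' @exportS3Method base::print
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$intensities), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "), " mm\n",
      "  intensity range: [", signif(min(x$intensities), 5), ", ",
      signif(max(x$intensities), 5), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "), " mm; ",
      sum(x$labels), " foreground voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "volume_grid")) dim(a$intensities) else dim(a$labels)
  db <- if (inherits(b, "volume_grid")) dim(b$intensities) else dim(b$labels)
  identical(da, db) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

# ---- NIfTI I/O ------------------------------------------------------------

#' Read / write volumes and masks as NIfTI
#'
#' Spacing is stored in `pixdim` and the origin in the sform translation.
#' Masks are written as uint8 and read back by thresholding at 0.5.
#'
#' @param x a `volume_grid` or `mask_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `volume_grid`; `read_mask` a `mask_volume`;
#'   the writers return `path` invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("volume_grid", "mask_volume")))
  arr <- if (inherits(x, "volume_grid")) x$intensities else array(as.integer(x$labels), dim(x$labels))
  img <- RNifti::asNifti(arr, datatype = if (inherits(x, "mask_volume")) "uint8" else "double")
  xform <- diag(c(x$spacing_mm, 1))
  xform[1:3, 4] <- x$origin_mm
  RNifti::sform(img) <- structure(xform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

.read_nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  spacing <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
  if (any(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(xf[1:3, 4])
  list(spacing = spacing, origin = origin)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .read_nifti_geometry(img)
  volume_grid(array(as.numeric(img), dim(img)[1:3]), g$spacing, g$origin)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  g <- .read_nifti_geometry(img)
  mask_volume(array(as.numeric(img) > 0.5, dim(img)[1:3]), g$spacing, g$origin)
}

# ---- Resampling -----------------------------------------------------------

#' Resample a volume or mask to a target voxel spacing
#'
#' Intensities are interpolated trilinearly; masks use nearest-neighbour
#' sampling so labels stay binary. The physical extent of the grid is
#' preserved to within one voxel per axis: the output has
#' `round(n * spacing / target)` voxels per axis and keeps the input origin.
#'
#' @param x `volume_grid` or `mask_volume`.
#' @param target_spacing_mm positive numeric of length 3.
#' @return resampled object of the same class.
#' @export
resample_to_spacing <- function(x, target_spacing_mm) {
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L || any(!is.finite(target_spacing_mm)) ||
      any(target_spacing_mm <= 0)) {
    stop("target spacing must be 3 positive numbers")
  }
  is_mask <- inherits(x, "mask_volume")
  arr <- if (is_mask) x$labels else x$intensities
  dm <- dim(arr)
  if (all(abs(x$spacing_mm - target_spacing_mm) < 1e-12)) return(x)
  n_out <- pmax(1L, as.integer(round(dm * x$spacing_mm / target_spacing_mm)))
  # sample coordinates of output voxel centres, in input index space (1-based)
  coord <- lapply(1:3, function(k) {
    1 + (seq_len(n_out[k]) - 1) * target_spacing_mm[k] / x$spacing_mm[k]
  })
  if (is_mask) {
    # floor(x + 0.5), not round(): half-to-even rounding would duplicate
    # some source voxels and skip others
    idx <- lapply(1:3, function(k) pmin(pmax(floor(coord[[k]] + 0.5), 1L), dm[k]))
    out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- n_out
    return(mask_volume(out, target_spacing_mm, x$origin_mm))
  }
  i0 <- lapply(1:3, function(k) pmin(pmax(floor(coord[[k]]), 1L), dm[k]))
  i1 <- lapply(1:3, function(k) pmin(i0[[k]] + 1L, dm[k]))
  w <- lapply(1:3, function(k) pmin(pmax(coord[[k]] - i0[[k]], 0), 1))
  wa <- function(k, hi) {
    v <- if (hi) w[[k]] else 1 - w[[k]]
    if (k == 1) array(v, n_out)
    else if (k == 2) array(rep(v, each = n_out[1]), n_out)
    else array(rep(v, each = n_out[1] * n_out[2]), n_out)
  }
  out <- array(0, n_out)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) i1[[1]] else i0[[1]]
    iy <- if (cy) i1[[2]] else i0[[2]]
    iz <- if (cz) i1[[3]] else i0[[3]]
    wgt <- wa(1, cx) * wa(2, cy) * wa(3, cz)
    out <- out + wgt * arr[ix, iy, iz, drop = FALSE]
  }
  volume_grid(out, target_spacing_mm, x$origin_mm)
}

# ---- Intensity quantisation -----------------------------------------------

#' Discretise masked intensities into fixed bins over mean +/- k * SD
#'
#' Computes the mean and standard deviation of the intensities inside the
#' mask, splits the range `[mu - k*sd, mu + k*sd]` into `n_bins` equal-width
#' bins (half-open, last bin right-closed) and assigns every masked voxel an
#' integer level in `1..n_bins`; values outside the range are clipped to the
#' first/last bin. If the masked region is constant (`sd == 0`) all voxels
#' are assigned the middle bin.
#'
#' @param volume `volume_grid`.
#' @param mask `mask_volume` on the same grid.
#' @param n_bins number of grey levels (default 64).
#' @param k_sd half-width of the quantisation range in standard deviations
#'   (default 3).
#' @return list with `levels` (integer array, `NA` outside the mask),
#'   `edges` (bin edges, length `n_bins + 1`), `n_bins`, `mu`, `sigma`.
#' @export
quantize_intensities <- function(volume, mask, n_bins = 64L, k_sd = 3) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "mask_volume"))
  if (!same_grid(volume, mask)) stop("volume and mask are on different grids")
  if (!any(mask$labels)) stop("empty mask")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  vals <- volume$intensities[mask$labels]
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  levels <- array(NA_integer_, dim(volume$intensities))
  if (!is.finite(sigma) || sigma == 0) {
    levels[mask$labels] <- (n_bins + 1L) %/% 2L
    return(list(levels = levels, edges = rep(mu, n_bins + 1L),
                n_bins = n_bins, mu = mu, sigma = 0))
  }
  edges <- seq(mu - k_sd * sigma, mu + k_sd * sigma, length.out = n_bins + 1L)
  lev <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  levels[mask$labels] <- as.integer(lev)
  list(levels = levels, edges = edges, n_bins = n_bins, mu = mu, sigma = sigma)
}
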