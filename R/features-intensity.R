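# Morphological, local-intensity, intensity-statistics and
# intensity-histogram feature families (IBSI definitions). Each family
# function returns a named numeric vector; names are bare feature names,
# prefixed with source/family by the extractor.

#' Morphological features of a binary mask
#'
#' Voxel-based IBSI morphology: approximate volume (voxel count times voxel
#' volume), surface area from exposed voxel faces, the derived shape ratios,
#' axis lengths `4 * sqrt(lambda)` from the principal-component eigenvalues
#' of the voxel-centre coordinates (population covariance), and the
#' axis-aligned bounding-box volume density. The maximum 3-D diameter is
#' computed over the surface voxels that are extremal along the 13 unique
#' grid directions (a deterministic approximation exact for convex bodies
#' aligned with those directions).
#'
#' @param mask nonempty `mask_volume`.
#' @return named numeric vector of 15 features.
#' @export
morphological_features <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- mask$labels
  if (!any(m)) stop("empty mask")
  sp <- mask$spacing_mm
  n <- sum(m)
  V <- n * prod(sp)

  # surface area: faces between mask and background (or grid edge)
  A <- 0
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L)
      d[axis] <- s
      nbv <- shift_array(m, d, fill = FALSE)
      A <- A + sum(m & !nbv) * face_area[axis]
    }
  }

  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx, 2, c(1, 1, 1)) %*% diag(sp)  # mm, 0-based
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  C <- crossprod(cc) / n                            # population covariance
  ev <- sort(pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axis_len <- 4 * sqrt(ev)

  # extremal surface points along the 13 unique directions -> diameter
  surf <- surface_voxels(m)
  sidx <- which(surf, arr.ind = TRUE)
  scoord <- sweep(sidx, 2, c(1, 1, 1)) %*% diag(sp)
  dirs <- unique_offsets_26()
  cand <- unique(unlist(lapply(seq_len(nrow(dirs)), function(r) {
    pr <- scoord %*% dirs[r, ]
    c(which.max(pr), which.min(pr))
  })))
  pc <- scoord[cand, , drop = FALSE]
  dmax <- if (nrow(pc) > 1) sqrt(max(as.vector(stats::dist(pc))^2)) else 0

  ext <- vapply(1:3, function(k) diff(range(idx[, k])) + 1, numeric(1)) * sp
  k36 <- (36 * pi * V^2)^(1 / 3)

  c(approximate_volume = V,
    surface_area = A,
    surface_to_volume_ratio = A / V,
    compactness_1 = V / (sqrt(pi) * A^1.5),
    compactness_2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / k36,
    sphericity = k36 / A,
    asphericity = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
    maximum_3d_diameter = dmax,
    major_axis_length = axis_len[1],
    minor_axis_length = axis_len[2],
    least_axis_length = axis_len[3],
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    volume_density_aabb = V / prod(ext))
}

# spherical 0/1 kernel of physical radius r_mm on the given spacing
.sphere_kernel <- function(r_mm, spacing_mm) {
  rv <- pmax(1L, ceiling(r_mm / spacing_mm))
  cx <- (-rv[1]:rv[1]) * spacing_mm[1]
  cy <- (-rv[2]:rv[2]) * spacing_mm[2]
  cz <- (-rv[3]:rv[3]) * spacing_mm[3]
  dm <- c(length(cx), length(cy), length(cz))
  d2 <- array(cx^2, dm) +
    array(rep(cy^2, each = dm[1]), dm) +
    array(rep(cz^2, each = dm[1] * dm[2]), dm)
  array(as.numeric(d2 <= r_mm^2), dm)
}

#' Local and global intensity peak
#'
#' The spherical mean of the image in a 1 cm^3 sphere (radius ~6.2 mm):
#' the local peak is that mean centred at a maximum-intensity masked voxel
#' (highest mean over ties), the global peak is the maximum spherical mean
#' over all masked voxels. Sphere voxels outside the image are excluded from
#' the mean; voxels outside the mask but inside the image contribute.
#'
#' @param volume `volume_grid`.
#' @param mask nonempty `mask_volume` on the same grid.
#' @param volume_cm3 sphere volume in cm^3 (default 1).
#' @return named numeric vector: `local_intensity_peak`,
#'   `global_intensity_peak`.
#' @export
intensity_peak_features <- function(volume, mask, volume_cm3 = 1) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "mask_volume"))
  if (!same_grid(volume, mask)) stop("volume and mask are on different grids")
  if (!any(mask$labels)) stop("empty mask")
  r_mm <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  K <- .sphere_kernel(r_mm, volume$spacing_mm)
  num <- fft_convolve(volume$intensities, K)
  den <- fft_convolve(array(1, dim(volume$intensities)), K)
  mean_map <- num / pmax(den, 0.5)
  inmask <- mean_map[mask$labels]
  vals <- volume$intensities[mask$labels]
  loc <- max(inmask[vals == max(vals)])
  glob <- max(inmask)
  c(local_intensity_peak = loc, global_intensity_peak = glob)
}

# quantile shorthand (linear interpolation, type 7)
.q <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)

#' Intensity-based statistical features
#'
#' IBSI statistical family on the raw masked intensities, with population
#' (1/n) moments; kurtosis is excess kurtosis. Degenerate denominators
#' (zero variance or zero mean) yield 0 so every feature stays finite.
#'
#' @param values numeric vector of masked intensities (or a `volume_grid`
#'   plus `mask`).
#' @param mask optional `mask_volume` when `values` is a `volume_grid`.
#' @return named numeric vector of 22 features.
#' @export
intensity_statistics <- function(values, mask = NULL) {
  if (inherits(values, "volume_grid")) {
    stopifnot(inherits(mask, "mask_volume"))
    if (!same_grid(values, mask)) stop("volume and mask are on different grids")
    values <- values$intensities[mask$labels]
  }
  x <- as.numeric(values)
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  sdv <- sqrt(v)
  skew <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((x - m)^4) / v^2 - 3 else 0
  p <- .q(x, c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  rob <- x[x >= p[2] & x <= p[6]]
  c(mean = m,
    variance = v,
    skewness = skew,
    kurtosis = kurt,
    median = p[4],
    minimum = min(x),
    p5 = p[1], p10 = p[2], p25 = p[3], p75 = p[5], p90 = p[6], p95 = p[7],
    maximum = max(x),
    interquartile_range = p[5] - p[3],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - m)),
    robust_mean_absolute_deviation =
      if (length(rob) > 0) mean(abs(rob - mean(rob))) else 0,
    median_absolute_deviation = mean(abs(x - p[4])),
    coefficient_of_variation = if (m != 0) sdv / m else 0,
    quartile_coefficient_of_dispersion =
      if ((p[5] + p[3]) != 0) (p[5] - p[3]) / (p[5] + p[3]) else 0,
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2)))
}

#' Intensity-histogram features
#'
#' IBSI histogram family on discretised grey levels `1..n_bins` (output of
#' [quantize_intensities()]): moments of the level distribution, mode
#' (closest to the mean among ties, then lowest), entropy/uniformity, and
#' the histogram-gradient features computed by central differences over the
#' per-bin counts (one-sided at the ends).
#'
#' @param levels integer vector of grey levels in `1..n_bins`, or the list
#'   returned by [quantize_intensities()].
#' @param n_bins number of grey levels (taken from the quantisation result
#'   when `levels` is one).
#' @return named numeric vector of 23 features.
#' @export
intensity_histogram_features <- function(levels, n_bins = 64L) {
  if (is.list(levels) && !is.null(levels$levels)) {
    n_bins <- levels$n_bins
    levels <- levels$levels[!is.na(levels$levels)]
  }
  g <- as.integer(levels[!is.na(levels)])
  if (length(g) == 0) stop("empty mask")
  if (any(g < 1L | g > n_bins)) stop("levels must lie in 1..n_bins")
  n <- length(g)
  cnt <- tabulate(g, n_bins)
  pr <- cnt / n
  m <- mean(g)
  v <- mean((g - m)^2)
  skew <- if (v > 0) mean((g - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((g - m)^4) / v^2 - 3 else 0
  p <- .q(g, c(0.10, 0.25, 0.50, 0.75, 0.90))
  modes <- which(cnt == max(cnt))
  mode <- modes[order(abs(modes - m), modes)][1]
  rob <- g[g >= p[1] & g <= p[5]]
  grad <- numeric(n_bins)
  if (n_bins >= 2L) {
    grad[1] <- cnt[2] - cnt[1]
    grad[n_bins] <- cnt[n_bins] - cnt[n_bins - 1L]
    if (n_bins >= 3L) {
      mid <- 2:(n_bins - 1L)
      grad[mid] <- (cnt[mid + 1L] - cnt[mid - 1L]) / 2
    }
  }
  pos <- pr[pr > 0]
  c(mean = m,
    variance = v,
    skewness = skew,
    kurtosis = kurt,
    median = p[3],
    minimum = min(g),
    p10 = p[1], p90 = p[5],
    maximum = max(g),
    mode = mode,
    interquartile_range = p[4] - p[2],
    range = max(g) - min(g),
    mean_absolute_deviation = mean(abs(g - m)),
    robust_mean_absolute_deviation =
      if (length(rob) > 0) mean(abs(rob - mean(rob))) else 0,
    median_absolute_deviation = mean(abs(g - p[3])),
    coefficient_of_variation = if (m != 0) sqrt(v) / m else 0,
    quartile_coefficient_of_dispersion =
      if ((p[4] + p[2]) != 0) (p[4] - p[2]) / (p[4] + p[2]) else 0,
    entropy = -sum(pos * log2(pos)),
    uniformity = sum(pr^2),
    max_gradient = max(grad),
    max_gradient_level = which.max(grad),
    min_gradient = min(grad),
    min_gradient_level = which.min(grad))
}
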