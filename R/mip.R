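# Deterministic preprocessing for the vertebral detection / segmentation
# stages: bone extraction (Otsu threshold, region growing, morphological
# filtering, histogram equalisation), full and thin-slab maximum intensity
# projections, fixed-size cropping, cutout augmentation, two-plane VOI
# assembly, and propagation-label construction. Network inference itself is
# out of scope; these operations produce the inputs and targets such a
# network consumes.

#' Otsu threshold of a numeric vector
#'
#' Exhaustively maximises the between-class variance over a histogram of
#' `n_levels` candidate cut points.
#'
#' @param values numeric vector.
#' @param n_levels histogram resolution (default 256).
#' @return threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(values, n_levels = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) stop("degenerate histogram")
  edges <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), n_levels)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_levels]
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, n_levels)
  sb2[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  edges[which.max(sb2) + 1L]
}

#' Bone-enhancing preprocessing for MIP generation
#'
#' Sequentially applies Otsu thresholding, region growing (supra-threshold
#' connected components of at least `min_region_voxels` voxels),
#' morphological filtering (closing then opening with a 3^3 element) and
#' global histogram equalisation of the retained intensities. Background is
#' set to the volume minimum.
#'
#' @param volume `volume_grid`.
#' @param min_region_voxels smallest supra-threshold component kept
#'   (default 27, one structuring element).
#' @return list with `volume` (the equalised bone-enhanced `volume_grid`),
#'   `bone_mask` (`mask_volume` of retained voxels) and `threshold`.
#' @export
preprocess_for_mip <- function(volume, min_region_voxels = 27L) {
  stopifnot(inherits(volume, "volume_grid"))
  thr <- otsu_threshold(as.vector(volume$intensities))
  supra <- volume$intensities > thr
  if (!any(supra)) stop("no voxels above the Otsu threshold")
  lab <- label_components(supra, connectivity = 26)
  sizes <- tabulate(lab[lab > 0L])
  keep_ids <- which(sizes >= min_region_voxels)
  grown <- array(lab %in% keep_ids & lab > 0L, dim(lab))
  if (!any(grown)) grown <- supra  # all components tiny: keep them all
  filtered <- binary_open(binary_close(grown, 1L), 1L)
  if (!any(filtered)) filtered <- grown
  lo <- min(volume$intensities)
  hi <- max(volume$intensities)
  out <- array(lo, dim(volume$intensities))
  vals <- volume$intensities[filtered]
  # global histogram equalisation: map retained intensities through their
  # empirical CDF onto the original intensity range
  r <- (rank(vals, ties.method = "average") - 0.5) / length(vals)
  out[filtered] <- lo + r * (hi - lo)
  list(volume = volume_grid(out, volume$spacing_mm, volume$origin_mm),
       bone_mask = mask_volume(filtered, volume$spacing_mm, volume$origin_mm),
       threshold = thr)
}

#' Maximum intensity projection
#'
#' Coronal projections collapse the y axis (pixels indexed x, z); sagittal
#' projections collapse the x axis (pixels indexed y, z). An optional slab
#' restricts the projection to a contiguous index range along the collapsed
#' axis (thin-slab MIP).
#'
#' @param volume `volume_grid`.
#' @param plane `"coronal"` or `"sagittal"`.
#' @param slab optional integer range `c(from, to)` (1-based, inclusive)
#'   along the projected axis.
#' @return list of class `mip_image`: `pixels` (2-D matrix), `plane`,
#'   `source_extent`, `offset` (crop offset, for coordinate back-mapping).
#' @export
project_mip <- function(volume, plane = c("coronal", "sagittal"), slab = NULL) {
  stopifnot(inherits(volume, "volume_grid"))
  plane <- match.arg(plane)
  axis <- if (plane == "coronal") 2L else 1L
  dm <- dim(volume$intensities)
  rng <- c(1L, dm[axis])
  if (!is.null(slab)) {
    slab <- as.integer(slab)
    if (length(slab) != 2L || slab[1] > slab[2] ||
        slab[1] < 1L || slab[2] > dm[axis]) {
      stop("empty or out-of-bounds slab")
    }
    rng <- slab
  }
  sub <- if (axis == 2L) {
    volume$intensities[, rng[1]:rng[2], , drop = FALSE]
  } else {
    volume$intensities[rng[1]:rng[2], , , drop = FALSE]
  }
  px <- apply(sub, setdiff(1:3, axis), max)
  structure(list(pixels = px, plane = plane, source_extent = rng,
                 offset = c(0L, 0L)),
            class = "mip_image")
}

#' Crop or pad a MIP image to a fixed size
#'
#' Content is centred (or placed at `center`); padding uses the image
#' minimum. The applied offset (output index of input pixel (1,1), which may
#' be negative when cropping) is recorded for coordinate back-mapping.
#'
#' @param image `mip_image`.
#' @param size target `c(rows, cols)` (default `c(416, 416)`).
#' @param center optional input-pixel coordinate to place at the output
#'   centre (defaults to the image centre).
#' @return `mip_image` of exactly `size` with an updated `offset`.
#' @export
crop_pad_to <- function(image, size = c(416L, 416L), center = NULL) {
  stopifnot(inherits(image, "mip_image"))
  size <- as.integer(size)
  px <- image$pixels
  dm <- dim(px)
  if (is.null(center)) center <- (dm + 1) / 2
  fill <- min(px)
  out <- matrix(fill, size[1], size[2])
  # offset: position of input pixel (1,1) in output coordinates
  off <- floor((size + 1) / 2 - center)
  src1 <- pmax(1L, 1L - off)
  src2 <- pmin(dm, size - off)
  if (all(src2 >= src1)) {
    out[(src1[1]:src2[1]) + off[1], (src1[2]:src2[2]) + off[2]] <-
      px[src1[1]:src2[1], src1[2]:src2[2]]
  }
  structure(list(pixels = out, plane = image$plane,
                 source_extent = image$source_extent,
                 offset = as.integer(off)),
            class = "mip_image")
}

#' Cutout augmentation
#'
#' Sets `n_holes` square regions of side `hole_size` to the image minimum at
#' seeded-random positions (clipped at the borders), emulating bone
#' destroyed by fracture or obscured by metal.
#'
#' @param image `mip_image`.
#' @param n_holes number of holes (0 returns the input unchanged).
#' @param hole_size side length in pixels (>= 1).
#' @param seed integer seed.
#' @return augmented `mip_image`.
#' @export
cutout_augment <- function(image, n_holes, hole_size, seed = 1L) {
  stopifnot(inherits(image, "mip_image"), hole_size >= 1)
  if (n_holes == 0) return(image)
  px <- image$pixels
  dm <- dim(px)
  fill <- min(px)
  with_seed(seed, {
    for (i in seq_len(n_holes)) {
      r0 <- sample.int(dm[1], 1L)
      c0 <- sample.int(dm[2], 1L)
      rr <- r0:min(dm[1], r0 + hole_size - 1L)
      cc <- c0:min(dm[2], c0 + hole_size - 1L)
      px[rr, cc] <- fill
    }
  })
  structure(list(pixels = px, plane = image$plane,
                 source_extent = image$source_extent, offset = image$offset),
            class = "mip_image")
}

#' Assemble a 3-D VOI from coronal and sagittal ROIs
#'
#' x bounds come from the coronal ROI, y bounds from the sagittal ROI, and z
#' bounds from the intersection of the two planes' z ranges. ROIs are
#' half-open 0-based index intervals, `list(u = c(min, max), z = c(min,
#' max))` with `u` the in-plane horizontal axis (x for coronal, y for
#' sagittal).
#'
#' @param coronal_roi,sagittal_roi ROIs as above.
#' @return list of class `voi_3d` with half-open 0-based `x`, `y`, `z`
#'   bounds.
#' @export
assemble_voi <- function(coronal_roi, sagittal_roi) {
  chk <- function(r, nm) {
    if (!is.list(r) || !all(c("u", "z") %in% names(r)) ||
        r$u[1] >= r$u[2] || r$z[1] >= r$z[2]) {
      stop("invalid ", nm, " ROI: bounds must satisfy min < max")
    }
  }
  chk(coronal_roi, "coronal")
  chk(sagittal_roi, "sagittal")
  z <- c(max(coronal_roi$z[1], sagittal_roi$z[1]),
         min(coronal_roi$z[2], sagittal_roi$z[2]))
  if (z[1] >= z[2]) stop("inconsistent ROIs: disjoint z ranges")
  structure(list(x = as.integer(coronal_roi$u),
                 y = as.integer(sagittal_roi$u),
                 z = as.integer(z)),
            class = "voi_3d")
}

#' Build a propagation label for one slice from its neighbours
#'
#' The propagation label is the union of the neighbouring slices' masks
#' within `+/- window`, morphologically eroded toward the current slice
#' extent: the union is eroded (2-D, 8-connected) once per slice of distance
#' from the nearest nonempty neighbour, so labels propagated from far away
#' commit to less. It is nonempty whenever any neighbour in the window is
#' nonempty, and reduces to the slice itself when all neighbours equal it.
#'
#' @param mask_slices list of 2-D logical matrices (a z-stack of masks).
#' @param index slice whose label is built (1-based).
#' @param window neighbourhood half-width in slices (>= 1).
#' @return 2-D logical matrix.
#' @export
make_propagation_label <- function(mask_slices, index, window = 1L) {
  stopifnot(window >= 1L, index >= 1L, index <= length(mask_slices))
  dm <- dim(mask_slices[[index]])
  nbr <- setdiff(seq.int(max(1L, index - window),
                         min(length(mask_slices), index + window)), index)
  nbr <- nbr[vapply(nbr, function(i) any(mask_slices[[i]]), logical(1))]
  if (length(nbr) == 0L) return(matrix(FALSE, dm[1], dm[2]))
  u <- Reduce(`|`, mask_slices[nbr])
  dist <- min(abs(nbr - index))
  if (dist > 1L) {
    for (i in seq_len(dist - 1L)) {
      er <- .erode2d(u)
      if (!any(er)) break
      u <- er
    }
  }
  u
}

.erode2d <- function(m) {
  dm <- dim(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, dm[1], dm[2])
    rs <- max(1, 1 + dr):min(dm[1], dm[1] + dr)
    cs <- max(1, 1 + dc):min(dm[2], dm[2] + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- out & sh
  }
  out
}
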