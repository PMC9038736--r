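# Low-level 3-D array helpers shared by the phantom generator, the MIP
# pipeline, the surface-distance metrics and the texture-matrix builders.
# All functions treat arrays as (x, y, z) with 1-based R indexing; physical
# coordinates follow world = origin + (index - 1) * spacing.

#' Shift a 3-D array by an integer voxel offset
#'
#' Voxels shifted in from outside the grid take the value `fill`.
#'
#' @param a 3-D array.
#' @param d integer offset of length 3 (positive moves content toward higher
#'   indices).
#' @param fill value used for voxels with no source (default `NA`).
#' @return array of the same dimension as `a`.
#' @keywords internal
shift_array <- function(a, d, fill = NA) {
  dm <- dim(a)
  stopifnot(length(dm) == 3L, length(d) == 3L)
  d <- as.integer(d)
  out <- array(fill, dm)
  dst <- src <- vector("list", 3L)
  for (k in 1:3) {
    n <- dm[k]
    if (abs(d[k]) >= n) return(out)
    if (d[k] >= 0) {
      dst[[k]] <- seq.int(d[k] + 1L, n)
      src[[k]] <- seq.int(1L, n - d[k])
    } else {
      dst[[k]] <- seq.int(1L, n + d[k])
      src[[k]] <- seq.int(1L - d[k], n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique direction offsets of the 26-neighbourhood (one per
# antipodal pair), used by GLCM/GLRLM and for building adjacency edges.
unique_offsets_26 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  # keep one representative per antipodal pair: first nonzero component > 0
  keep <- apply(offs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

all_offsets_26 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE])
}

offsets_6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

#' Convolve a 3-D array with a 1-D kernel along one axis
#'
#' Uses replicate (nearest) boundary handling so that a kernel summing to one
#' leaves constant arrays unchanged.
#'
#' @keywords internal
conv_axis <- function(a, kernel, axis) {
  dm <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dmp <- dim(ap)
  n <- dmp[1]
  m <- matrix(ap, nrow = n)
  r <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  idx_base <- seq_len(n)
  for (j in seq_along(kernel)) {
    if (kernel[j] == 0) next
    off <- j - r - 1L
    idx <- pmin(pmax(idx_base + off, 1L), n)
    out <- out + kernel[j] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dmp), order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g / sum(g)
}

#' Separable Gaussian smoothing with per-axis sigma in voxels
#' @keywords internal
gaussian_smooth <- function(a, sigma_vox) {
  out <- a
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      out <- conv_axis(out, gaussian_kernel(sigma_vox[axis]), axis)
    }
  }
  out
}

# ---- Euclidean distance transform -----------------------------------------

# One parabola-envelope pass (Felzenszwalb & Huttenlocher) along `axis`,
# with sample step in mm so anisotropic spacing is exact.
.dt_line <- function(f, step) {
  n <- length(f)
  if (n == 1L) return(f)
  INF <- 1e30
  v <- integer(n)
  z <- numeric(n + 1L)
  x <- (seq_len(n) - 1) * step
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -INF
  z[2L] <- INF
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- INF
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

.dt_axis <- function(d, step, axis) {
  dm <- dim(d)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(d, perm)
  dmp <- dim(ap)
  m <- matrix(ap, nrow = dmp[1])
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col >= 1e30) || all(col == 0)) next
    m[, j] <- .dt_line(col, step)
  }
  aperm(array(m, dmp), order(perm))
}

#' Exact squared Euclidean distance transform to a voxel set
#'
#' Returns, for every voxel, the squared distance in mm^2 from its centre to
#' the nearest centre of a voxel where `mask` is `TRUE`.
#'
#' @param mask logical 3-D array (the feature set).
#' @param spacing_mm voxel spacing per axis in mm.
#' @keywords internal
squared_edt <- function(mask, spacing_mm) {
  if (!any(mask)) stop("distance transform of an empty set is undefined")
  d <- array(0, dim(mask))
  d[!mask] <- 1e30
  for (axis in 1:3) d <- .dt_axis(d, spacing_mm[axis], axis)
  d
}

#' Signed distance (mm) to the boundary of a binary mask
#'
#' Negative inside the mask, positive outside; magnitude is the distance to
#' the nearest voxel centre on the opposite side.
#' @keywords internal
signed_distance <- function(mask, spacing_mm) {
  if (!any(mask) || all(mask)) stop("signed distance needs both phases present")
  d_out <- sqrt(squared_edt(mask, spacing_mm))      # distance to foreground
  d_in <- sqrt(squared_edt(!mask, spacing_mm))      # distance to background
  ifelse(mask, -d_in, d_out)
}

# ---- Connected components -------------------------------------------------

#' Label connected components of a logical 3-D array
#'
#' @param mask logical array.
#' @param connectivity 6 or 26.
#' @param values optional array; when given, voxels are connected only if
#'   they share the same value (used for size-zone extraction).
#' @return integer array, 0 outside the mask, component labels 1..k inside.
#' @keywords internal
label_components <- function(mask, connectivity = 26, values = NULL) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nv <- sum(mask)
  if (nv == 0L) return(lab)
  ids <- array(0L, dm)
  ids[mask] <- seq_len(nv)
  offs <- if (connectivity == 26) unique_offsets_26() else offsets_6()[c(1, 3, 5), , drop = FALSE]
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    s <- shift_array(ids, offs[r, ], fill = 0L)
    cond <- ids > 0L & s > 0L
    if (!is.null(values)) {
      sv <- shift_array(values, offs[r, ], fill = NA)
      cond <- cond & !is.na(sv) & !is.na(values) & sv == values
    }
    if (any(cond)) {
      from <- c(from, ids[cond])
      to <- c(to, s[cond])
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = nv, directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[mask] <- as.integer(comp)
  lab
}

# ---- Binary morphology ----------------------------------------------------

#' Dilate/erode a logical array with a cubic structuring element
#' @keywords internal
binary_dilate <- function(mask, radius = 1L, connectivity = 26) {
  offs <- if (connectivity == 26) all_offsets_26() else offsets_6()
  out <- mask
  for (i in seq_len(radius)) {
    acc <- out
    for (r in seq_len(nrow(offs))) {
      acc <- acc | shift_array(out, offs[r, ], fill = FALSE)
    }
    out <- acc
  }
  out
}

#' @rdname binary_dilate
#' @keywords internal
binary_erode <- function(mask, radius = 1L, connectivity = 26) {
  !binary_dilate(!mask, radius = radius, connectivity = connectivity)
}

#' @rdname binary_dilate
#' @keywords internal
binary_close <- function(mask, radius = 1L) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' @rdname binary_dilate
#' @keywords internal
binary_open <- function(mask, radius = 1L) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' Surface voxels: mask voxels with at least one face-adjacent background
#' neighbour (voxels outside the grid count as background).
#' @keywords internal
surface_voxels <- function(mask) {
  offs <- offsets_6()
  surf <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(mask, offs[r, ], fill = FALSE)
    surf <- surf | (mask & !nb)
  }
  surf
}

# ---- FFT convolution (for spherical-mean intensity peaks) -----------------

# Zero-padded circular FFT convolution of `a` with a centred kernel `k`
# (both 3-D arrays); returns the "same"-size result.
fft_convolve <- function(a, k) {
  da <- dim(a)
  dk <- dim(k)
  dp <- vapply(da + dk, function(n) stats::nextn(n, c(2, 3, 5)), numeric(1))
  pa <- array(0, dp)
  pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  conv <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / prod(dp)
  ctr <- (dk + 1L) %/% 2L
  conv[ctr[1] + seq_len(da[1]) - 1L,
       ctr[2] + seq_len(da[2]) - 1L,
       ctr[3] + seq_len(da[3]) - 1L]
}
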