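# 3-D texture-matrix families on discretised grey levels: grey-level
# co-occurrence (GLCM, 13 unique directions at distance 1, symmetrised,
# matrices averaged), run-length (GLRLM, counts merged over the 13
# directions), size-zone (GLSZM, 26-connected zones) and neighbouring
# grey-level dependence (NGLDM, 26-neighbourhood, coarseness alpha = 0).
# `levels` is the integer level array from quantize_intensities() (NA
# outside the mask).

.levels_array <- function(levels) {
  if (is.list(levels) && !is.null(levels$levels)) levels <- levels$levels
  if (is.null(dim(levels)) || length(dim(levels)) != 3L) {
    stop("levels must be a 3-D array (see quantize_intensities)")
  }
  levels
}

#' Grey-level co-occurrence matrix
#'
#' @param levels level array (`NA` outside the mask) or a
#'   [quantize_intensities()] result.
#' @param n_bins number of grey levels.
#' @return `n_bins x n_bins` matrix: the symmetrised co-occurrence
#'   probabilities averaged over the 13 unique distance-1 directions
#'   (directions with no valid voxel pair are skipped).
#' @export
glcm_matrix <- function(levels, n_bins = 64L) {
  lev <- .levels_array(levels)
  if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
  offs <- unique_offsets_26()
  acc <- matrix(0, n_bins, n_bins)
  used <- 0L
  for (r in seq_len(nrow(offs))) {
    s <- shift_array(lev, offs[r, ], fill = NA)
    ok <- !is.na(lev) & !is.na(s)
    if (!any(ok)) next
    code <- lev[ok] + (s[ok] - 1L) * n_bins
    m <- matrix(tabulate(code, n_bins * n_bins), n_bins, n_bins)
    m <- m + t(m)
    acc <- acc + m / sum(m)
    used <- used + 1L
  }
  if (used == 0L) stop("no co-occurring voxel pairs in the mask")
  acc / used
}

#' GLCM features (IBSI set of 25)
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
glcm_features <- function(levels, n_bins = 64L) {
  if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
  P <- if (is.matrix(levels)) levels else glcm_matrix(levels, n_bins)
  ng <- nrow(P)
  i <- matrix(rep(seq_len(ng), ng), ng)       # row index
  j <- t(i)
  pij <- P
  pi_ <- rowSums(P)
  mu <- sum(i * pij)
  joint_var <- sum((i - mu)^2 * pij)
  pos <- pij[pij > 0]
  joint_entropy <- -sum(pos * log2(pos))

  dmat <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(pij[dmat == k]), numeric(1))
  kd <- 0:(ng - 1)
  da <- sum(kd * pd)
  pdp <- pd[pd > 0]

  smat <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(pij[smat == k]), numeric(1))
  ks <- 2:(2 * ng)
  sa <- sum(ks * ps)
  psp <- ps[ps > 0]

  mu_i <- sum(seq_len(ng) * pi_)
  var_i <- sum((seq_len(ng) - mu_i)^2 * pi_)
  corr <- if (var_i > 0) (sum(i * j * pij) - mu_i^2) / var_i else 1

  hx <- {
    pp <- pi_[pi_ > 0]
    -sum(pp * log2(pp))
  }
  pipj <- pi_[row(P)] * pi_[col(P)]
  okk <- pij > 0 & pipj > 0
  hxy1 <- -sum(pij[okk] * log2(pipj[okk]))
  ok2 <- pipj > 0
  hxy2 <- -sum(pipj[ok2] * log2(pipj[ok2]))
  ic1 <- if (hx > 0) (joint_entropy - hxy1) / hx else 0
  ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - joint_entropy))))

  off_diag <- dmat > 0
  c(joint_maximum = max(pij),
    joint_average = mu,
    joint_variance = joint_var,
    joint_entropy = joint_entropy,
    difference_average = da,
    difference_variance = sum((kd - da)^2 * pd),
    difference_entropy = -sum(pdp * log2(pdp)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * ps),
    sum_entropy = -sum(psp * log2(psp)),
    angular_second_moment = sum(pij^2),
    contrast = sum((i - j)^2 * pij),
    dissimilarity = sum(dmat * pij),
    inverse_difference = sum(pij / (1 + dmat)),
    inverse_difference_normalised = sum(pij / (1 + dmat / ng)),
    inverse_difference_moment = sum(pij / (1 + dmat^2)),
    inverse_difference_moment_normalised = sum(pij / (1 + dmat^2 / ng^2)),
    inverse_variance = sum(pij[off_diag] / dmat[off_diag]^2),
    correlation = corr,
    autocorrelation = sum(i * j * pij),
    cluster_tendency = sum((i + j - 2 * mu_i)^2 * pij),
    cluster_shade = sum((i + j - 2 * mu_i)^3 * pij),
    cluster_prominence = sum((i + j - 2 * mu_i)^4 * pij),
    information_correlation_1 = ic1,
    information_correlation_2 = ic2)
}

# Enumerate runs for one direction; returns counts matrix [level, length].
.runs_one_direction <- function(lev, d, n_bins, max_len) {
  dm <- dim(lev)
  prev <- shift_array(lev, d, fill = NA)
  start <- !is.na(lev) & (is.na(prev) | prev != lev)
  sidx <- which(start, arr.ind = TRUE)
  if (nrow(sidx) == 0L) return(matrix(0, n_bins, max_len))
  run_lev <- lev[start]
  len <- rep(1L, nrow(sidx))
  cur <- sidx
  active <- seq_len(nrow(sidx))
  while (length(active) > 0L) {
    nxt <- cur[active, , drop = FALSE] +
      matrix(d, nrow = length(active), ncol = 3, byrow = TRUE)
    inb <- nxt[, 1] >= 1 & nxt[, 1] <= dm[1] &
      nxt[, 2] >= 1 & nxt[, 2] <= dm[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dm[3]
    cont <- logical(length(active))
    if (any(inb)) {
      nv <- lev[nxt[inb, , drop = FALSE]]
      cont[inb] <- !is.na(nv) & nv == run_lev[active[inb]]
    }
    keep <- active[cont]
    if (length(keep) == 0L) break
    len[keep] <- len[keep] + 1L
    cur[keep, ] <- nxt[cont, , drop = FALSE]
    active <- keep
  }
  len <- pmin(len, max_len)
  matrix(tabulate(run_lev + (len - 1L) * n_bins, n_bins * max_len),
         n_bins, max_len)
}

#' Grey-level run-length matrix and features (IBSI set of 16)
#'
#' Run counts are merged (summed) over the 13 unique directions before
#' feature computation; run percentage uses `n_runs / (n_voxels * 13)`.
#'
#' @inheritParams glcm_matrix
#' @return `glrlm_matrix`: counts matrix (level x run length);
#'   `glrlm_features`: named numeric vector.
#' @export
glrlm_matrix <- function(levels, n_bins = 64L) {
  lev <- .levels_array(levels)
  if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
  max_len <- max(dim(lev))
  offs <- unique_offsets_26()
  R <- matrix(0, n_bins, max_len)
  for (r in seq_len(nrow(offs))) {
    R <- R + .runs_one_direction(lev, offs[r, ], n_bins, max_len)
  }
  R
}

#' @rdname glrlm_matrix
#' @param n_voxels number of masked voxels (inferred when `levels` is an
#'   array or quantisation result).
#' @export
glrlm_features <- function(levels, n_bins = 64L, n_voxels = NULL) {
  if (is.matrix(levels)) {
    R <- levels
    if (is.null(n_voxels)) stop("n_voxels required with a precomputed matrix")
  } else {
    lev <- .levels_array(levels)
    if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
    n_voxels <- sum(!is.na(lev))
    R <- glrlm_matrix(levels, n_bins)
  }
  .rl_type_features(R, n_voxels, n_dir = 13L,
                    size_name = "run_length", prefix = "run",
                    extra = c(percentage = "run_percentage",
                              entropy = "run_entropy"))
}

# Shared feature set for run-length-like matrices (GLRLM / GLSZM): counts
# matrix M[level, size]; returns the 16 standard features with `size`
# interpreted as run length or zone size.
.rl_type_features <- function(M, n_voxels, n_dir, size_name, prefix, extra) {
  Ns <- sum(M)
  if (Ns == 0) stop("empty texture matrix")
  ng <- nrow(M)
  nl <- ncol(M)
  g <- seq_len(ng)
  s <- seq_len(nl)
  mg <- rowSums(M)
  ms <- colSums(M)
  p <- M / Ns
  gmat <- matrix(g, ng, nl)
  smat <- matrix(s, ng, nl, byrow = TRUE)
  mu_g <- sum(gmat * p)
  mu_s <- sum(smat * p)
  pos <- p[p > 0]
  out <- c(
    sum(ms / s^2) / Ns,                       # small/short emphasis
    sum(ms * s^2) / Ns,                       # large/long emphasis
    sum(mg / g^2) / Ns,                       # low grey level
    sum(mg * g^2) / Ns,                       # high grey level
    sum(M / (gmat^2 * smat^2)) / Ns,          # small + low
    sum(M * gmat^2 / smat^2) / Ns,            # small + high
    sum(M * smat^2 / gmat^2) / Ns,            # large + low
    sum(M * gmat^2 * smat^2) / Ns,            # large + high
    sum(mg^2) / Ns,                           # grey level non-uniformity
    sum(mg^2) / Ns^2,                         # ... normalised
    sum(ms^2) / Ns,                           # size non-uniformity
    sum(ms^2) / Ns^2,                         # ... normalised
    Ns / (n_voxels * n_dir),                  # percentage
    sum((gmat - mu_g)^2 * p),                 # grey level variance
    sum((smat - mu_s)^2 * p),                 # size variance
    -sum(pos * log2(pos))                     # entropy
  )
  names(out) <- switch(prefix,
    run = c("short_runs_emphasis", "long_runs_emphasis",
            "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
            "short_run_low_grey_level_emphasis",
            "short_run_high_grey_level_emphasis",
            "long_run_low_grey_level_emphasis",
            "long_run_high_grey_level_emphasis",
            "grey_level_non_uniformity",
            "grey_level_non_uniformity_normalised",
            "run_length_non_uniformity",
            "run_length_non_uniformity_normalised",
            "run_percentage", "grey_level_variance",
            "run_length_variance", "run_entropy"),
    zone = c("small_zone_emphasis", "large_zone_emphasis",
             "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
             "small_zone_low_grey_level_emphasis",
             "small_zone_high_grey_level_emphasis",
             "large_zone_low_grey_level_emphasis",
             "large_zone_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalised",
             "zone_size_non_uniformity",
             "zone_size_non_uniformity_normalised",
             "zone_percentage", "grey_level_variance",
             "zone_size_variance", "zone_size_entropy"))
  out
}

#' Grey-level size-zone matrix and features (IBSI set of 16)
#'
#' Zones are 26-connected components of equal grey level; the matrix is
#' indexed (level, zone size). Zone percentage uses `n_zones / n_voxels`.
#'
#' @inheritParams glcm_matrix
#' @export
glszm_matrix <- function(levels, n_bins = 64L) {
  lev <- .levels_array(levels)
  if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
  mask <- !is.na(lev)
  lab <- label_components(mask, connectivity = 26, values = lev)
  nz <- max(lab)
  zsize <- tabulate(lab[lab > 0L], nz)
  zlev <- integer(nz)
  zlev[lab[mask]] <- lev[mask]
  max_size <- max(zsize)
  matrix(tabulate(zlev + (zsize - 1L) * n_bins, n_bins * max_size),
         n_bins, max_size)
}

#' @rdname glszm_matrix
#' @param n_voxels number of masked voxels (inferred when `levels` is an
#'   array or quantisation result).
#' @export
glszm_features <- function(levels, n_bins = 64L, n_voxels = NULL) {
  if (is.matrix(levels)) {
    S <- levels
    if (is.null(n_voxels)) stop("n_voxels required with a precomputed matrix")
  } else {
    lev <- .levels_array(levels)
    if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
    n_voxels <- sum(!is.na(lev))
    S <- glszm_matrix(levels, n_bins)
  }
  .rl_type_features(S, n_voxels, n_dir = 1L,
                    size_name = "zone_size", prefix = "zone",
                    extra = NULL)
}

#' Neighbouring grey-level dependence matrix and features (IBSI set of 17)
#'
#' The dependence count of a voxel is the number of its 26-neighbours
#' (inside the mask) sharing its grey level exactly (coarseness alpha = 0);
#' the matrix is indexed (level, k + 1).
#'
#' @inheritParams glcm_matrix
#' @export
ngldm_matrix <- function(levels, n_bins = 64L) {
  lev <- .levels_array(levels)
  if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
  mask <- !is.na(lev)
  offs <- all_offsets_26()
  k <- array(0L, dim(lev))
  for (r in seq_len(nrow(offs))) {
    s <- shift_array(lev, offs[r, ], fill = NA)
    k <- k + (!is.na(s) & !is.na(lev) & s == lev)
  }
  g <- lev[mask]
  j <- k[mask] + 1L
  matrix(tabulate(g + (j - 1L) * n_bins, n_bins * 27L), n_bins, 27L)
}

#' @rdname ngldm_matrix
#' @export
ngldm_features <- function(levels, n_bins = 64L) {
  if (is.matrix(levels)) S <- levels
  else {
    if (is.list(levels) && !is.null(levels$n_bins)) n_bins <- levels$n_bins
    S <- ngldm_matrix(levels, n_bins)
  }
  Ns <- sum(S)
  if (Ns == 0) stop("empty dependence matrix")
  ng <- nrow(S)
  nk <- ncol(S)
  g <- seq_len(ng)
  j <- seq_len(nk)
  mg <- rowSums(S)
  mj <- colSums(S)
  p <- S / Ns
  gmat <- matrix(g, ng, nk)
  jmat <- matrix(j, ng, nk, byrow = TRUE)
  mu_g <- sum(gmat * p)
  mu_j <- sum(jmat * p)
  pos <- p[p > 0]
  c(low_dependence_emphasis = sum(mj / j^2) / Ns,
    high_dependence_emphasis = sum(mj * j^2) / Ns,
    low_grey_level_count_emphasis = sum(mg / g^2) / Ns,
    high_grey_level_count_emphasis = sum(mg * g^2) / Ns,
    low_dependence_low_grey_level_emphasis = sum(S / (gmat^2 * jmat^2)) / Ns,
    low_dependence_high_grey_level_emphasis = sum(S * gmat^2 / jmat^2) / Ns,
    high_dependence_low_grey_level_emphasis = sum(S * jmat^2 / gmat^2) / Ns,
    high_dependence_high_grey_level_emphasis = sum(S * gmat^2 * jmat^2) / Ns,
    grey_level_non_uniformity = sum(mg^2) / Ns,
    grey_level_non_uniformity_normalised = sum(mg^2) / Ns^2,
    dependence_count_non_uniformity = sum(mj^2) / Ns,
    dependence_count_non_uniformity_normalised = sum(mj^2) / Ns^2,
    dependence_count_percentage = 1,
    grey_level_variance = sum((gmat - mu_g)^2 * p),
    dependence_count_variance = sum((jmat - mu_j)^2 * p),
    dependence_count_entropy = -sum(pos * log2(pos)),
    dependence_count_energy = sum(p^2))
}
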