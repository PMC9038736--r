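# Independent brute-force oracles used to verify the texture matrices and
# ranking statistics. These deliberately use naive enumeration (explicit
# loops over voxels / pairs) rather than the package's vectorised paths.

# all 26 neighbour offsets as a list
.oracle_offsets <- local({
  o <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    o[[length(o) + 1]] <- c(dx, dy, dz)
  }
  o
})

.in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

# GLCM: per unique direction, count ordered pairs, symmetrise, normalise,
# average over directions with at least one pair.
oracle_glcm <- function(lev, nb) {
  dm <- dim(lev)
  dirs <- .oracle_offsets[sapply(.oracle_offsets, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })]
  acc <- matrix(0, nb, nb)
  used <- 0
  for (d in dirs) {
    m <- matrix(0, nb, nb)
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      g1 <- lev[x, y, z]
      if (is.na(g1)) next
      p2 <- c(x, y, z) + d
      if (!.in_bounds(p2, dm)) next
      g2 <- lev[p2[1], p2[2], p2[3]]
      if (is.na(g2)) next
      m[g1, g2] <- m[g1, g2] + 1
    }
    m <- m + t(m)
    if (sum(m) > 0) {
      acc <- acc + m / sum(m)
      used <- used + 1
    }
  }
  acc / used
}

# GLSZM: recursive flood fill over 26-connected equal-level zones.
oracle_glszm <- function(lev, nb) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    g <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (d in .oracle_offsets) {
        q <- p + d
        if (!.in_bounds(q, dm)) next
        if (seen[q[1], q[2], q[3]]) next
        gq <- lev[q[1], q[2], q[3]]
        if (!is.na(gq) && gq == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  if (length(zones) == 0) return(matrix(0, nb, 1))
  zs <- do.call(rbind, zones)
  S <- matrix(0, nb, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) S[zs[r, 1], zs[r, 2]] <- S[zs[r, 1], zs[r, 2]] + 1
  S
}

# NGLDM: per-voxel count of equal-level 26-neighbours (alpha = 0).
oracle_ngldm <- function(lev, nb) {
  dm <- dim(lev)
  S <- matrix(0, nb, 27)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    k <- 0
    for (d in .oracle_offsets) {
      q <- c(x, y, z) + d
      if (!.in_bounds(q, dm)) next
      gq <- lev[q[1], q[2], q[3]]
      if (!is.na(gq) && gq == g) k <- k + 1
    }
    S[g, k + 1] <- S[g, k + 1] + 1
  }
  S
}

# AUC as explicit all-pairs concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  y <- as.integer(labels %in% c(1, TRUE, "malignant"))
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# pairwise Hausdorff distance between the surface point sets of two masks
oracle_hausdorff <- function(a, b, spacing) {
  pa <- which(vertrad:::surface_voxels(a), arr.ind = TRUE)
  pb <- which(vertrad:::surface_voxels(b), arr.ind = TRUE)
  pa <- sweep(pa, 2, c(1, 1, 1)) %*% diag(spacing)
  pb <- sweep(pb, 2, c(1, 1, 1)) %*% diag(spacing)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

# small random discretised mask on a grid of at most 5^3 voxels
random_small_levels <- function(seed, nb = 4) {
  set.seed(seed)
  dm <- sample(2:5, 3, replace = TRUE)
  lev <- array(sample.int(nb, prod(dm), replace = TRUE), dm)
  drop_frac <- runif(1, 0, 0.5)
  lev[runif(prod(dm)) < drop_frac] <- NA
  if (all(is.na(lev))) lev[1, 1, 1] <- 1L
  lev
}

# compact phantom parameters for fast tests
p_small <- function(...) {
  defaults <- list(grid_shape = c(40L, 40L, 26L),
                   voxel_spacing_mm = c(1, 1, 1.5),
                   body_semi_axes_mm = c(13, 10, 22),
                   lesion_radius_mm = 5)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}
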