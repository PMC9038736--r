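# Intensity/morphology feature families, the LoG filter, and the
# 280-feature extractor contract.

test_that("morphological features match closed forms", {
  # 100 voxels at 1 mm -> approximate volume 100 mm^3
  dm <- c(10, 10, 5)
  a <- array(FALSE, dm); a[1:4, 1:5, 1:5] <- TRUE
  f <- morphological_features(mask_volume(a, c(1, 1, 1)))
  expect_equal(unname(f["approximate_volume"]), 100)
  # a box of 4 x 5 x 5 voxels has known exposed-face area
  expect_equal(unname(f["surface_area"]), 2 * (4 * 5 + 4 * 5 + 5 * 5))
  expect_equal(unname(f["volume_density_aabb"]), 1)

  # single voxel: zero covariance -> zero axis lengths
  s <- array(FALSE, c(3, 3, 3)); s[2, 2, 2] <- TRUE
  fs <- morphological_features(mask_volume(s, c(1, 1, 1)))
  expect_equal(unname(fs[c("major_axis_length", "minor_axis_length",
                           "least_axis_length")]), c(0, 0, 0))

  # ball of radius 10 mm on a fine grid: major axis ~ 4 * sqrt(r^2 / 5)
  r <- 10
  n <- 27L
  cc <- (seq_len(n) - (n + 1) / 2) * (2.2 * r / n)
  d2 <- array(cc^2, c(n, n, n)) +
    array(rep(cc^2, each = n), c(n, n, n)) +
    array(rep(cc^2, each = n * n), c(n, n, n))
  ball <- mask_volume(d2 <= r^2, rep(2.2 * r / n, 3))
  fb <- morphological_features(ball)
  expect_equal(unname(fb["major_axis_length"]), 4 * sqrt(r^2 / 5),
               tolerance = 0.05)
  # voxel-face surface area overestimates a smooth sphere's area (staircase
  # effect), so sphericity sits well below 1 but above a loose floor
  expect_gt(unname(fb["sphericity"]), 0.55)
  expect_lt(unname(fb["sphericity"]), 1)
  expect_equal(unname(fb["maximum_3d_diameter"]), 2 * r, tolerance = 0.1)
})

test_that("intensity peaks are spherical means", {
  dm <- c(21, 21, 21)
  sp <- c(1, 1, 1)
  arr <- array(0, dm)
  arr[11, 11, 11] <- 1000
  mk <- mask_volume(array(TRUE, dm), sp)
  pk <- intensity_peak_features(volume_grid(arr, sp), mk)
  # sphere of 1 cm^3 at 1 mm spacing covers a known voxel count
  n_sphere <- sum(vertrad:::.sphere_kernel((3000 / (4 * pi))^(1 / 3), sp))
  expect_equal(unname(pk["local_intensity_peak"]), 1000 / n_sphere,
               tolerance = 1e-6)
  expect_gte(pk["global_intensity_peak"], pk["local_intensity_peak"] - 1e-9)

  const <- volume_grid(array(42, dm), sp)
  pc <- intensity_peak_features(const, mk)
  expect_equal(unname(pc), c(42, 42), tolerance = 1e-9)
})

test_that("intensity statistics use population moments and stated rules", {
  f <- intensity_statistics(c(1, 2, 3))
  expect_equal(unname(f["minimum"]), 1)
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["variance"]), 2 / 3)        # population
  expect_equal(unname(f["median"]), 2)
  expect_equal(unname(f["energy"]), 14)
  expect_equal(unname(f["root_mean_square"]), sqrt(14 / 3))
  # constant vector: degenerate moments are zero, not NaN
  fc <- intensity_statistics(rep(5, 10))
  expect_equal(unname(fc["skewness"]), 0)
  expect_equal(unname(fc["kurtosis"]), 0)
  expect_true(all(is.finite(fc)))
})

test_that("histogram features follow the level-distribution definitions", {
  # constant region: entropy 0, uniformity 1
  f <- intensity_histogram_features(rep(7L, 20), 64)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["mode"]), 7)

  # two occupied bins at the extremes: the extremal gradients sit at the
  # transitions adjacent to the occupied bins
  lev <- c(rep(1L, 50), rep(64L, 50))
  f2 <- intensity_histogram_features(lev, 64)
  expect_true(f2["max_gradient_level"] %in% c(63, 64))  # rising into bin 64
  expect_true(f2["min_gradient_level"] %in% c(1, 2))    # falling off bin 1
  expect_gt(f2["max_gradient"], 0)
  expect_lt(f2["min_gradient"], 0)
  expect_equal(unname(f2["mean"]), 32.5)
})

test_that("LoG filter is zero on constants, linear, and scale-selective", {
  dm <- c(24, 24, 24)
  sp <- c(1, 1, 1)
  const <- volume_grid(array(3, dm), sp)
  expect_true(all(abs(log_filter(const, 2)$intensities) < 1e-10))

  set.seed(4)
  v <- volume_grid(array(rnorm(prod(dm)), dm), sp)
  l1 <- log_filter(v, 1.5)$intensities
  v3 <- volume_grid(3 * v$intensities, sp)
  expect_equal(log_filter(v3, 1.5)$intensities, 3 * l1, tolerance = 1e-10)

  # Gaussian blob of scale s: response magnitude at the centre is extremal
  # near sigma = s among the tested scales
  s <- 2
  cc <- seq_len(dm[1]) - (dm[1] + 1) / 2
  d2 <- array(cc^2, dm) + array(rep(cc^2, each = dm[1]), dm) +
    array(rep(cc^2, each = dm[1]^2), dm)
  blob <- volume_grid(exp(-d2 / (2 * s^2)), sp)
  ctr <- (dm + 1) / 2
  resp <- vapply(c(1, 2, 4), function(sg) {
    abs(log_filter(blob, sg)$intensities[ctr[1], ctr[2], ctr[3]])
  }, numeric(1))
  expect_equal(which.max(resp), 2L)
})

test_that("the extractor emits exactly the 280-feature catalogue", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 280L)
  expect_false(any(duplicated(cat$id)))
  expect_setequal(unique(cat$source), c("original", "log_1", "log_2"))

  cs <- make_vertebra_phantom(p_small(), "malignant")
  cfg <- extraction_config(resample = FALSE)
  f1 <- extract_features(cs$volume, cs$truth_mask, cfg)
  f2 <- extract_features(cs$volume, cs$truth_mask, cfg)
  expect_identical(f1, f2)
  expect_length(f1, 280L)
  expect_identical(names(f1), cat$id)
  expect_true(all(is.finite(f1)))

  # every published-model feature resolves to a catalogue entry
  pm <- published_model()
  expect_true(all(pm$features %in% cat$id))

  # +100 HU shifts the statistics mean, leaves morphology unchanged
  v2 <- volume_grid(cs$volume$intensities + 100, cs$volume$spacing_mm)
  f3 <- extract_features(v2, cs$truth_mask, cfg)
  expect_equal(unname(f3["original__statistics__mean"] -
                        f1["original__statistics__mean"]), 100,
               tolerance = 1e-9)
  morph_ids <- cat$id[cat$family == "morphological"]
  expect_equal(f3[morph_ids], f1[morph_ids])
})
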