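# Phantom generator: determinism, anatomy, class contrast, observer
# perturbation bounds, cohort assembly and per-patient selection.

test_that("phantom generation is deterministic and anatomically sensible", {
  p <- p_small()
  a <- make_vertebra_phantom(p, "malignant")
  b <- make_vertebra_phantom(p, "malignant")
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth_mask$labels, b$truth_mask$labels)

  # truth mask is a single connected body containing the interior
  lab <- vertrad:::label_components(a$truth_mask$labels)
  expect_equal(max(lab), 1L)
  expect_gt(sum(a$truth_mask$labels), 500)
})

test_that("noise-free benign phantom has constant trabecular interior", {
  p <- p_small(fracture_compression_frac = 0, noise_sd_hu = 0,
               trabecular_sd_hu = 0, sclerosis_band_hu = 0)
  cs <- make_vertebra_phantom(p, "benign_acute")
  vol <- cs$volume$intensities
  interior_vals <- vol[cs$truth_mask$labels & vol < p$cortical_mean_hu]
  expect_true(all(interior_vals == p$trabecular_mean_hu))
})

test_that("malignant phantoms are darker than acute benign by the lesion deficit", {
  p <- p_small()
  mal <- make_vertebra_phantom(p, "malignant")
  ben <- make_vertebra_phantom(p, "benign_acute")
  mean_mal <- mean(mal$volume$intensities[mal$truth_mask$labels])
  mean_ben <- mean(ben$volume$intensities[ben$truth_mask$labels])
  v_lesion <- 4 / 3 * pi * p$lesion_radius_mm^3
  v_body <- sum(mal$truth_mask$labels) * prod(p$voxel_spacing_mm)
  bound <- (p$trabecular_mean_hu - p$lesion_mean_hu) * (v_lesion / v_body) / 2
  expect_gt(mean_ben - mean_mal, bound)
})

test_that("oversized lesions and bad parameters are rejected", {
  expect_error(make_vertebra_phantom(p_small(lesion_radius_mm = 50), "malignant"),
               "lesion exceeds body")
  expect_error(phantom_params(voxel_spacing_mm = c(0, 1, 1)), "positive")
  expect_error(phantom_params(fracture_compression_frac = 1), "compression")
})

test_that("observer masks respect the displacement bound and stay connected", {
  p <- p_small()
  cs <- make_vertebra_phantom(p, "benign_chronic")
  m <- cs$truth_mask

  expect_identical(simulate_observer_mask(m, 0, seed = 1), m)

  o1 <- simulate_observer_mask(m, 1, seed = 1)
  o2 <- simulate_observer_mask(m, 1, seed = 2)
  expect_false(identical(o1$labels, o2$labels))
  expect_gt(dsc(o1, m), 0.8)
  expect_gt(dsc(o2, m), 0.8)
  expect_lte(asd(o1, m, symmetric = TRUE), 1)

  # single connected component preserved
  expect_equal(max(vertrad:::label_components(o1$labels)), 1L)

  # Hausdorff bound: no boundary point moves farther than the displacement
  # (plus one voxel diagonal of discretisation slack)
  d <- 3
  o3 <- simulate_observer_mask(m, d, seed = 3)
  hd <- oracle_hausdorff(o3$labels, m$labels, m$spacing_mm)
  expect_lte(hd, d + sqrt(sum(m$spacing_mm^2)))

  expect_error(simulate_observer_mask(mask_volume(array(FALSE, c(4, 4, 4)),
                                                  c(1, 1, 1)), 1),
               "empty")
})

test_that("cohorts are deterministic, labelled as requested, and jittered", {
  expect_identical(make_cohort(0, 0), list())
  p <- p_small()
  c1 <- make_cohort(4, 3, base_params = p, seed = 11)
  c2 <- make_cohort(4, 3, base_params = p, seed = 11)
  expect_equal(length(c1), 7L)
  expect_identical(vapply(c1, `[[`, "", "label"),
                   c(rep("benign_acute", 4), rep("malignant", 3)))
  expect_identical(c1[[3]]$volume$intensities, c2[[3]]$volume$intensities)
  # anatomy jitter: volumes differ across cases of the same class
  expect_false(identical(sum(c1[[1]]$truth_mask$labels),
                         sum(c1[[2]]$truth_mask$labels)))
  # patients never mix classes
  for (pid in unique(vapply(c1, `[[`, "", "patient_id"))) {
    labs <- unique(vapply(Filter(function(x) x$patient_id == pid, c1),
                          `[[`, "", "label"))
    expect_length(labs, 1L)
  }
})

test_that("one vertebra per patient is selected uniformly", {
  stub <- function(pid, vid) list(patient_id = pid, vertebra_id = vid)
  cases <- list(stub("A", 1), stub("A", 2), stub("B", 1),
                stub("C", 1), stub("C", 2))
  out <- select_one_vertebra_per_patient(cases, seed = 5)
  expect_length(out, 3L)
  expect_identical(sort(vapply(out, `[[`, "", "patient_id")), c("A", "B", "C"))

  # identity when every patient owns one vertebra
  singles <- list(stub("A", 1), stub("B", 1))
  expect_identical(select_one_vertebra_per_patient(singles, seed = 1), singles)

  # uniformity over seeds for a two-vertebra patient
  two <- list(stub("P", 1), stub("P", 2))
  picks <- vapply(1:10000, function(s) {
    select_one_vertebra_per_patient(two, seed = s)[[1]]$vertebra_id
  }, numeric(1))
  expect_lt(abs(mean(picks == 1) - 0.5), 0.02)
})

test_that("cohorts round-trip through NIfTI files and a manifest", {
  p <- phantom_params(grid_shape = c(24L, 24L, 16L),
                      voxel_spacing_mm = c(1.5, 1.5, 2),
                      body_semi_axes_mm = c(12, 9, 18), lesion_radius_mm = 4)
  cases <- make_cohort(1, 1, base_params = p, seed = 3)
  td <- withr::local_tempdir()
  man <- write_cohort(cases, td)
  expect_equal(nrow(man), 2L)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  v <- read_volume(man$volume[1])
  m <- read_mask(man$mask[1])
  expect_equal(v$intensities, cases[[1]]$volume$intensities)
  expect_identical(m$labels, cases[[1]]$truth_mask$labels)
  expect_equal(v$spacing_mm, p$voxel_spacing_mm, tolerance = 1e-6)
})
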