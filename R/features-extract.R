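# The 280-feature catalogue and the per-case extractor. Families on the
# original image: morphology (15), local intensity (2), intensity
# statistics (22), intensity histogram (23), GLCM (25), GLRLM (16), GLSZM
# (16), NGLDM (17). On each of two Laplacian-of-Gaussian filtered images
# (sigma 1 mm and 2 mm): local intensity, statistics, histogram and GLCM
# (72 each). 136 + 2 * 72 = 280.

#' Laplacian-of-Gaussian filter
#'
#' Spacing-aware band-pass filter emphasising blob-like structure at scale
#' `sigma_mm`: the volume is smoothed with a separable Gaussian of physical
#' width `sigma_mm`, the Laplacian is taken by second central differences
#' per axis (in 1/mm^2), and the response is scale-normalised by
#' `sigma_mm^2` so the response to a blob is extremal when the filter scale
#' matches the blob scale. Zero on any constant input; linear.
#'
#' @param volume `volume_grid`.
#' @param sigma_mm filter scale in mm (> 0).
#' @return filtered `volume_grid`.
#' @export
log_filter <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "volume_grid"))
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  sp <- volume$spacing_mm
  sm <- gaussian_smooth(volume$intensities, sigma_mm / sp)
  lap <- array(0, dim(sm))
  for (axis in 1:3) {
    lap <- lap + conv_axis(sm, c(1, -2, 1) / sp[axis]^2, axis)
  }
  volume_grid(sigma_mm^2 * lap, sp, volume$origin_mm)
}

.family_feature_names <- function(family) {
  switch(family,
    morphological = c("approximate_volume", "surface_area",
      "surface_to_volume_ratio", "compactness_1", "compactness_2",
      "spherical_disproportion", "sphericity", "asphericity",
      "maximum_3d_diameter", "major_axis_length", "minor_axis_length",
      "least_axis_length", "elongation", "flatness", "volume_density_aabb"),
    local_intensity = c("local_intensity_peak", "global_intensity_peak"),
    statistics = c("mean", "variance", "skewness", "kurtosis", "median",
      "minimum", "p5", "p10", "p25", "p75", "p90", "p95", "maximum",
      "interquartile_range", "range", "mean_absolute_deviation",
      "robust_mean_absolute_deviation", "median_absolute_deviation",
      "coefficient_of_variation", "quartile_coefficient_of_dispersion",
      "energy", "root_mean_square"),
    histogram = c("mean", "variance", "skewness", "kurtosis", "median",
      "minimum", "p10", "p90", "maximum", "mode", "interquartile_range",
      "range", "mean_absolute_deviation", "robust_mean_absolute_deviation",
      "median_absolute_deviation", "coefficient_of_variation",
      "quartile_coefficient_of_dispersion", "entropy", "uniformity",
      "max_gradient", "max_gradient_level", "min_gradient",
      "min_gradient_level"),
    glcm = c("joint_maximum", "joint_average", "joint_variance",
      "joint_entropy", "difference_average", "difference_variance",
      "difference_entropy", "sum_average", "sum_variance", "sum_entropy",
      "angular_second_moment", "contrast", "dissimilarity",
      "inverse_difference", "inverse_difference_normalised",
      "inverse_difference_moment", "inverse_difference_moment_normalised",
      "inverse_variance", "correlation", "autocorrelation",
      "cluster_tendency", "cluster_shade", "cluster_prominence",
      "information_correlation_1", "information_correlation_2"),
    glrlm = c("short_runs_emphasis", "long_runs_emphasis",
      "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
      "short_run_low_grey_level_emphasis",
      "short_run_high_grey_level_emphasis",
      "long_run_low_grey_level_emphasis",
      "long_run_high_grey_level_emphasis", "grey_level_non_uniformity",
      "grey_level_non_uniformity_normalised", "run_length_non_uniformity",
      "run_length_non_uniformity_normalised", "run_percentage",
      "grey_level_variance", "run_length_variance", "run_entropy"),
    glszm = c("small_zone_emphasis", "large_zone_emphasis",
      "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
      "small_zone_low_grey_level_emphasis",
      "small_zone_high_grey_level_emphasis",
      "large_zone_low_grey_level_emphasis",
      "large_zone_high_grey_level_emphasis", "grey_level_non_uniformity",
      "grey_level_non_uniformity_normalised", "zone_size_non_uniformity",
      "zone_size_non_uniformity_normalised", "zone_percentage",
      "grey_level_variance", "zone_size_variance", "zone_size_entropy"),
    ngldm = c("low_dependence_emphasis", "high_dependence_emphasis",
      "low_grey_level_count_emphasis", "high_grey_level_count_emphasis",
      "low_dependence_low_grey_level_emphasis",
      "low_dependence_high_grey_level_emphasis",
      "high_dependence_low_grey_level_emphasis",
      "high_dependence_high_grey_level_emphasis",
      "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
      "dependence_count_non_uniformity",
      "dependence_count_non_uniformity_normalised",
      "dependence_count_percentage", "grey_level_variance",
      "dependence_count_variance", "dependence_count_entropy",
      "dependence_count_energy"),
    stop("unknown family: ", family))
}

#' The 280-feature catalogue
#'
#' Ordered manifest of every feature the extractor emits: feature `id`
#' (`source__family__name`, the column name in feature tables), `source`
#' (`original`, `log_1`, `log_2`), `family` and bare `name`.
#'
#' @return data.frame with 280 rows.
#' @export
feature_catalog <- function() {
  fam_orig <- c("morphological", "local_intensity", "statistics",
                "histogram", "glcm", "glrlm", "glszm", "ngldm")
  fam_log <- c("local_intensity", "statistics", "histogram", "glcm")
  rows <- list()
  add <- function(source, family) {
    nms <- .family_feature_names(family)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = paste(source, family, nms, sep = "__"),
      source = source, family = family, name = nms,
      stringsAsFactors = FALSE)
  }
  for (f in fam_orig) add("original", f)
  for (s in c("log_1", "log_2")) for (f in fam_log) add(s, f)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extraction configuration
#'
#' @param target_spacing_mm common voxel spacing features are computed at
#'   (default `c(0.29, 0.29, 0.70)` mm).
#' @param resample resample volume and mask to `target_spacing_mm` before
#'   extraction (set `FALSE` to extract at native spacing, e.g. in fast
#'   tests).
#' @param n_bins,k_sd discretisation parameters (see
#'   [quantize_intensities()]).
#' @param log_sigmas_mm the two Laplacian-of-Gaussian scales in mm.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(target_spacing_mm = c(0.29, 0.29, 0.70),
                              resample = TRUE, n_bins = 64L, k_sd = 3,
                              log_sigmas_mm = c(1, 2)) {
  stopifnot(length(log_sigmas_mm) == 2L, all(log_sigmas_mm > 0))
  structure(list(target_spacing_mm = target_spacing_mm, resample = resample,
                 n_bins = as.integer(n_bins), k_sd = k_sd,
                 log_sigmas_mm = as.numeric(log_sigmas_mm)),
            class = "extraction_config")
}

.intensity_family_block <- function(volume, mask, config, source, with_texture) {
  out <- list()
  pk <- intensity_peak_features(volume, mask)
  names(pk) <- paste(source, "local_intensity", names(pk), sep = "__")
  out$li <- pk
  st <- intensity_statistics(volume, mask)
  names(st) <- paste(source, "statistics", names(st), sep = "__")
  out$st <- st
  q <- quantize_intensities(volume, mask, n_bins = config$n_bins,
                            k_sd = config$k_sd)
  hi <- intensity_histogram_features(q)
  names(hi) <- paste(source, "histogram", names(hi), sep = "__")
  out$hi <- hi
  gl <- glcm_features(q)
  names(gl) <- paste(source, "glcm", names(gl), sep = "__")
  out$gl <- gl
  if (with_texture) {
    rl <- glrlm_features(q)
    names(rl) <- paste(source, "glrlm", names(rl), sep = "__")
    out$rl <- rl
    sz <- glszm_features(q)
    names(sz) <- paste(source, "glszm", names(sz), sep = "__")
    out$sz <- sz
    nd <- ngldm_features(q)
    names(nd) <- paste(source, "ngldm", names(nd), sep = "__")
    out$nd <- nd
  }
  unlist(out, use.names = TRUE)
}

#' Extract the full 280-feature radiomics vector
#'
#' Applies the standardisation pipeline (resampling to the target spacing,
#' then per image source the LoG filter or identity, mask-restricted
#' mean +/- k*SD discretisation) and computes every catalogue feature.
#' Deterministic: two calls on the same input give identical vectors.
#'
#' @param volume `volume_grid`.
#' @param mask `mask_volume` on the same grid.
#' @param config [extraction_config()].
#' @return named numeric vector of length 280 in [feature_catalog()] order.
#' @export
extract_features <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "mask_volume"))
  if (!same_grid(volume, mask)) stop("volume and mask are on different grids")
  if (!any(mask$labels)) stop("empty mask")
  if (isTRUE(config$resample)) {
    volume <- resample_to_spacing(volume, config$target_spacing_mm)
    mask <- resample_to_spacing(mask, config$target_spacing_mm)
    if (!any(mask$labels)) stop("mask vanished under resampling")
  }
  mo <- morphological_features(mask)
  names(mo) <- paste("original", "morphological", names(mo), sep = "__")
  vals <- c(mo, .intensity_family_block(volume, mask, config, "original", TRUE))
  for (k in 1:2) {
    lg <- log_filter(volume, config$log_sigmas_mm[k])
    vals <- c(vals, .intensity_family_block(lg, mask, config,
                                            paste0("log_", k), FALSE))
  }
  # unlist() concatenates list element names; strip the block prefixes
  cat_ids <- feature_catalog()$id
  names(vals) <- sub("^(li|st|hi|gl|rl|sz|nd)\\.", "", names(vals))
  if (!identical(names(vals), cat_ids)) {
    vals <- vals[cat_ids]
    if (any(is.na(names(vals)))) stop("feature/catalogue mismatch")
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    stop("non-finite feature value(s): ",
         paste(names(vals)[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  vals
}

#' Extract a feature table for a cohort of phantom cases
#'
#' @param cases list of `phantom_case`.
#' @param config [extraction_config()].
#' @param mask_source `"truth"` or `"observer"`; observer masks use
#'   `observer_index`.
#' @param observer_index which observer mask to use (default 1).
#' @param masks optional list of `mask_volume`s overriding the case masks
#'   (e.g. externally perturbed segmentations), one per case.
#' @return data.frame: `case_id`, `patient_id`, `label`, then the 280
#'   feature columns.
#' @export
extract_cohort_features <- function(cases, config = extraction_config(),
                                    mask_source = c("truth", "observer"),
                                    observer_index = 1L, masks = NULL) {
  mask_source <- match.arg(mask_source)
  rows <- lapply(seq_along(cases), function(i) {
    cc <- cases[[i]]
    mk <- if (!is.null(masks)) masks[[i]]
    else if (mask_source == "truth") cc$truth_mask
    else {
      if (length(cc$observer_masks) < observer_index) {
        stop("case ", cc$vertebra_id, " has no observer mask ", observer_index)
      }
      cc$observer_masks[[observer_index]]
    }
    fv <- extract_features(cc$volume, mk, config)
    cbind(data.frame(case_id = paste(cc$patient_id, cc$vertebra_id, sep = "_"),
                     patient_id = cc$patient_id, label = cc$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Columns of a feature table that hold features
#' @param table feature table data.frame.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("case_id", "patient_id", "label"))
}
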