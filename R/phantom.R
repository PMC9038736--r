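# Synthetic vertebra phantoms: an elliptic-cylinder vertebral body with a
# bright cortical shell and textured trabecular interior, plus the three
# fracture appearances used throughout the package -- acute benign
# (height loss + sclerotic band), chronic benign (height loss only) and
# malignant (lytic low-attenuation lesion breaching the cortex).
# Observer re-segmentations are emulated by displacing the mask boundary
# with a smooth random field on the signed-distance function.

#' Parameters of a synthetic vertebra phantom
#'
#' Defaults give a thoracolumbar-sized vertebral body whose benign and
#' malignant appearances are separable by attenuation-based features:
#' trabecular bone 150 HU, cortex 800 HU, lytic lesion -20 HU, sclerotic
#' band +250 HU, additive noise SD 20 HU.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_spacing_mm voxel spacing in mm.
#' @param body_semi_axes_mm c(a, b, h): ellipse semi-axes of the body in x
#'   and y, and full body height along z, in mm.
#' @param cortical_thickness_mm thickness of the cortical shell.
#' @param trabecular_mean_hu,trabecular_sd_hu mean and texture SD of the
#'   trabecular interior (the texture is a correlated Gaussian field).
#' @param cortical_mean_hu attenuation of the cortical shell.
#' @param fracture_compression_frac fractional height loss in `[0, 1)`.
#' @param lesion_radius_mm,lesion_mean_hu radius and attenuation of the
#'   malignant lytic lesion.
#' @param sclerosis_band_hu attenuation increment of the acute-benign
#'   sclerotic band.
#' @param noise_sd_hu SD of additive white noise over the whole volume.
#' @param seed integer seed; the generator is a pure function of
#'   (params, seed, label).
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 64L),
                           voxel_spacing_mm = c(0.5, 0.5, 1),
                           body_semi_axes_mm = c(16, 12, 26),
                           cortical_thickness_mm = 1.5,
                           trabecular_mean_hu = 150,
                           trabecular_sd_hu = 20,
                           cortical_mean_hu = 800,
                           fracture_compression_frac = 0.2,
                           lesion_radius_mm = 6,
                           lesion_mean_hu = -20,
                           sclerosis_band_hu = 250,
                           noise_sd_hu = 20,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_spacing_mm = as.numeric(voxel_spacing_mm),
            body_semi_axes_mm = as.numeric(body_semi_axes_mm),
            cortical_thickness_mm = cortical_thickness_mm,
            trabecular_mean_hu = trabecular_mean_hu,
            trabecular_sd_hu = trabecular_sd_hu,
            cortical_mean_hu = cortical_mean_hu,
            fracture_compression_frac = fracture_compression_frac,
            lesion_radius_mm = lesion_radius_mm,
            lesion_mean_hu = lesion_mean_hu,
            sclerosis_band_hu = sclerosis_band_hu,
            noise_sd_hu = noise_sd_hu,
            seed = as.integer(seed))
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 4L)) {
    stop("grid_shape must be 3 integers >= 4")
  }
  if (any(p$voxel_spacing_mm <= 0)) stop("voxel spacing must be positive")
  if (length(p$body_semi_axes_mm) != 3L || any(p$body_semi_axes_mm <= 0)) {
    stop("body_semi_axes_mm must be 3 positive numbers")
  }
  if (p$fracture_compression_frac < 0 || p$fracture_compression_frac >= 1) {
    stop("fracture_compression_frac must be in [0, 1)")
  }
  if (p$cortical_thickness_mm < 0) stop("cortical thickness must be >= 0")
  if (p$noise_sd_hu < 0 || p$trabecular_sd_hu < 0) stop("noise SDs must be >= 0")
  invisible(p)
}

fracture_labels <- function() c("benign_acute", "benign_chronic", "malignant")

# Evaluate RNG-dependent code under a local, seeded RNG stream without
# disturbing the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# world coordinates of voxel centres, relative to the grid centre (mm)
.grid_coords <- function(grid_shape, spacing) {
  lapply(1:3, function(k) {
    (seq_len(grid_shape[k]) - (grid_shape[k] + 1) / 2) * spacing[k]
  })
}

.coord_arrays <- function(grid_shape, spacing) {
  cc <- .grid_coords(grid_shape, spacing)
  list(
    x = array(cc[[1]], grid_shape),
    y = array(rep(cc[[2]], each = grid_shape[1]), grid_shape),
    z = array(rep(cc[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

#' Generate one synthetic vertebra phantom
#'
#' Builds the CT-like volume, its ground-truth body mask, and (optionally)
#' observer-perturbed re-segmentations. The body is an elliptic cylinder;
#' fractures compress its height; the malignant appearance inserts a lytic
#' sphere whose centre sits on the lateral cortex so the lesion breaches it;
#' the acute benign appearance adds a high-attenuation band across the
#' mid-body.
#'
#' @param params `phantom_params`.
#' @param label one of `"benign_acute"`, `"benign_chronic"`, `"malignant"`.
#' @param n_observers number of observer-perturbed masks to simulate
#'   (default 0; see [simulate_observer_mask()]).
#' @param observer_displacement_mm maximum boundary displacement of the
#'   observer masks.
#' @param patient_id,vertebra_id identifiers carried into the case.
#' @return list of class `phantom_case` with elements `volume`,
#'   `truth_mask`, `observer_masks`, `label`, `patient_id`, `vertebra_id`.
#' @export
make_vertebra_phantom <- function(params, label,
                                  n_observers = 0L,
                                  observer_displacement_mm = 0.5,
                                  patient_id = "P1", vertebra_id = "V1") {
  validate_phantom_params(params)
  label <- match.arg(label, fracture_labels())
  a <- params$body_semi_axes_mm[1]
  b <- params$body_semi_axes_mm[2]
  h <- params$body_semi_axes_mm[3]
  if (label %in% c("benign_acute", "benign_chronic", "malignant")) {
    h <- h * (1 - params$fracture_compression_frac)
  }
  if (label == "malignant" && params$lesion_radius_mm >= min(a, b, h / 2)) {
    stop("lesion exceeds body")
  }
  sp <- params$voxel_spacing_mm
  gs <- params$grid_shape
  co <- .coord_arrays(gs, sp)

  q <- sqrt((co$x / a)^2 + (co$y / b)^2)
  body <- q <= 1 & abs(co$z) <= h / 2
  if (!any(body)) stop("body does not intersect the grid; enlarge grid_shape")
  t_mm <- params$cortical_thickness_mm
  interior <- sqrt((co$x / max(a - t_mm, 1e-6))^2 +
                   (co$y / max(b - t_mm, 1e-6))^2) <= 1 &
    abs(co$z) <= pmax(h / 2 - t_mm, 1e-6)
  shell <- body & !interior

  vol <- array(0, gs)
  vol[interior] <- params$trabecular_mean_hu
  vol[shell] <- params$cortical_mean_hu

  with_seed(params$seed, {
    if (params$trabecular_sd_hu > 0 && any(interior)) {
      # correlated texture: white noise smoothed at ~1 mm, rescaled to the
      # requested SD inside the interior
      field <- array(stats::rnorm(prod(gs)), gs)
      field <- gaussian_smooth(field, pmax(1 / sp, 0.5))
      fs <- stats::sd(field[interior])
      if (fs > 0) vol[interior] <- vol[interior] +
          params$trabecular_sd_hu * field[interior] / fs
    }
    if (label == "benign_acute" && params$sclerosis_band_hu != 0) {
      band <- interior & abs(co$z) <= 0.15 * h
      vol[band] <- vol[band] + params$sclerosis_band_hu
    }
    if (label == "malignant") {
      # lesion centred on the lateral cortex at mid-height: breaches the shell
      ctr <- c(a - params$lesion_radius_mm / 2, 0, 0)
      les <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2) <=
        params$lesion_radius_mm
      les <- les & body
      vol[les] <- params$lesion_mean_hu
    }
    if (params$noise_sd_hu > 0) {
      vol <- vol + array(stats::rnorm(prod(gs), sd = params$noise_sd_hu), gs)
    }
    volume <- volume_grid(vol, sp)
    truth <- mask_volume(body, sp)
    observers <- list()
    if (n_observers > 0L) {
      obs_seeds <- sample.int(.Machine$integer.max - 1L, n_observers)
      observers <- lapply(obs_seeds, function(s) {
        simulate_observer_mask(truth, observer_displacement_mm, seed = s)
      })
    }
    structure(
      list(volume = volume, truth_mask = truth, observer_masks = observers,
           label = label, patient_id = patient_id, vertebra_id = vertebra_id),
      class = "phantom_case"
    )
  })
}

#' @exportS3Method base::print
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", x$patient_id, "/", x$vertebra_id, " [", x$label, "] ",
      paste(dim(x$volume$intensities), collapse = "x"), " voxels, ",
      length(x$observer_masks), " observer mask(s)\n", sep = "")
  invisible(x)
}

#' Simulate an observer re-segmentation of a mask
#'
#' Displaces the mask boundary with a smooth random field applied to the
#' signed-distance function: the perturbed mask is
#' `{x : sdf(x) <= f(x)}` where `f` is a low-frequency Gaussian random
#' field scaled to SD `displacement_mm / 2` and hard-clamped at
#' `+/- displacement_mm`. The displacement along the boundary normal
#' therefore never exceeds `displacement_mm`; displacements smaller than
#' half a voxel cannot flip a voxel, so on coarse grids small
#' `displacement_mm` changes little. Only the largest connected component
#' is kept so the mask stays a single body.
#'
#' @param mask `mask_volume`, nonempty.
#' @param displacement_mm maximum boundary displacement (>= 0); 0 returns
#'   the input unchanged.
#' @param seed integer seed.
#' @return perturbed `mask_volume` on the same grid.
#' @export
simulate_observer_mask <- function(mask, displacement_mm, seed = 1L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!any(mask$labels)) stop("empty mask")
  if (displacement_mm < 0) stop("displacement_mm must be >= 0")
  if (displacement_mm == 0) return(mask)
  # voxel-centre signed distance to the continuum boundary: the surface lies
  # half a voxel beyond the last foreground centre, so both one-sided
  # distances are shifted by half the finest spacing
  h <- min(mask$spacing_mm)
  d_fg <- sqrt(squared_edt(mask$labels, mask$spacing_mm))
  d_bg <- sqrt(squared_edt(!mask$labels, mask$spacing_mm))
  sdf <- ifelse(mask$labels, -(d_bg - h / 2), d_fg - h / 2)
  gs <- dim(mask$labels)
  out <- with_seed(seed, {
    field <- array(stats::rnorm(prod(gs)), gs)
    # ~4 mm correlation length: smooth with sigma 4 mm per axis (in voxels)
    field <- gaussian_smooth(field, 4 / mask$spacing_mm)
    # scale to SD displacement/2, hard-clamped at +/- displacement so the
    # normal displacement never exceeds the bound
    field <- field / stats::sd(field) * (displacement_mm / 2)
    field <- pmin(pmax(field, -displacement_mm), displacement_mm)
    sdf <= field
  })
  lab <- label_components(out, connectivity = 26)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    out <- lab == which.max(sizes)
  }
  if (!any(out)) stop("perturbation removed the mask entirely")
  mask_volume(out, mask$spacing_mm, mask$origin_mm)
}

#' Generate a labelled cohort of phantom cases
#'
#' Benign cases carry the acute-benign appearance, matching the
#' classification task (acute benign vs malignant compression fracture).
#' Per-case anatomy is jittered around `base_params` (semi-axes +/- 10 %,
#' compression +/- 0.05, trabecular mean +/- 10 HU) and patients own 1--3
#' vertebrae so per-patient selection is exercised.
#'
#' @param n_benign,n_malignant class counts (>= 0).
#' @param base_params `phantom_params` around which cases are jittered.
#' @param seed integer seed for the whole cohort.
#' @param n_observers,observer_displacement_mm forwarded to
#'   [make_vertebra_phantom()].
#' @return list of `phantom_case` objects.
#' @export
make_cohort <- function(n_benign, n_malignant, base_params = phantom_params(),
                        seed = 1L, n_observers = 0L,
                        observer_displacement_mm = 0.5) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  n <- n_benign + n_malignant
  if (n == 0L) return(list())
  labels <- c(rep("benign_acute", n_benign), rep("malignant", n_malignant))
  with_seed(seed, {
    # patients own 1-3 vertebrae, never mixing classes within a patient
    patient_of <- character(n)
    pid <- 0L
    i <- 1L
    while (i <= n) {
      pid <- pid + 1L
      k <- sample(1:3, 1L)
      k <- min(k, n - i + 1L)
      # keep a patient within one class
      k <- min(k, sum(labels[i:n] == labels[i]))
      patient_of[i:(i + k - 1L)] <- sprintf("P%03d", pid)
      i <- i + k
    }
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    jit <- function(v, frac) v * stats::runif(1, 1 - frac, 1 + frac)
    lapply(seq_len(n), function(j) {
      p <- base_params
      p$body_semi_axes_mm <- c(jit(p$body_semi_axes_mm[1], 0.1),
                               jit(p$body_semi_axes_mm[2], 0.1),
                               jit(p$body_semi_axes_mm[3], 0.1))
      p$fracture_compression_frac <-
        min(0.95, max(0, p$fracture_compression_frac + stats::runif(1, -0.05, 0.05)))
      p$trabecular_mean_hu <- p$trabecular_mean_hu + stats::runif(1, -10, 10)
      p$seed <- case_seeds[j]
      make_vertebra_phantom(p, labels[j],
                            n_observers = n_observers,
                            observer_displacement_mm = observer_displacement_mm,
                            patient_id = patient_of[j],
                            vertebra_id = sprintf("V%03d", j))
    })
  })
}

#' Keep one randomly chosen vertebra per patient
#'
#' For patients with several fractured vertebrae, one is selected uniformly
#' at random (seeded); output preserves the input order of the chosen cases.
#'
#' @param cases list of `phantom_case` objects (any list whose elements carry
#'   a `patient_id` field works, e.g. a cohort manifest split by row).
#' @param seed integer seed.
#' @return sub-list of `cases` with exactly one element per `patient_id`.
#' @export
select_one_vertebra_per_patient <- function(cases, seed = 1L) {
  if (length(cases) == 0L) return(cases)
  pids <- vapply(cases, function(cc) as.character(cc$patient_id), character(1))
  with_seed(seed, {
    keep <- logical(length(cases))
    for (p in unique(pids)) {
      idx <- which(pids == p)
      keep[if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]] <- TRUE
    }
    cases[keep]
  })
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cases list of `phantom_case`.
#' @param outdir output directory (created if missing).
#' @return data.frame manifest (also written to `manifest.csv`).
#' @export
write_cohort <- function(cases, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cc) {
    stem <- paste0(cc$patient_id, "_", cc$vertebra_id)
    vpath <- file.path(outdir, paste0(stem, "_ct.nii.gz"))
    mpath <- file.path(outdir, paste0(stem, "_mask.nii.gz"))
    write_volume(cc$volume, vpath)
    write_mask(cc$truth_mask, mpath)
    opaths <- character(0)
    if (length(cc$observer_masks) > 0) {
      opaths <- vapply(seq_along(cc$observer_masks), function(i) {
        op <- file.path(outdir, sprintf("%s_obs%d.nii.gz", stem, i))
        write_mask(cc$observer_masks[[i]], op)
        op
      }, character(1))
    }
    data.frame(patient_id = cc$patient_id, vertebra_id = cc$vertebra_id,
               label = cc$label, volume = vpath, mask = mpath,
               observer_masks = paste(opaths, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  manifest
}
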