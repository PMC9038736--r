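# Segmentation agreement metrics: Dice similarity coefficient (DSC),
# signed cross-sectional-area (CSA) error, and average surface distance
# (ASD), plus the median [IQR] cohort summary table.

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between an automatic segmentation `A`
#' and a reference `B` on the same grid.
#'
#' @param auto,truth `mask_volume`s on the same grid.
#' @return value in `[0, 1]`.
#' @export
dsc <- function(auto, truth) {
  stopifnot(inherits(auto, "mask_volume"), inherits(truth, "mask_volume"))
  if (!same_grid(auto, truth)) stop("masks are on different grids")
  na <- sum(auto$labels)
  nb <- sum(truth$labels)
  if (na + nb == 0) stop("undefined DSC: both masks empty")
  2 * sum(auto$labels & truth$labels) / (na + nb)
}

#' Signed cross-sectional-area error (percent)
#'
#' `(B_CSA - A_CSA) / B_CSA * 100`, positive when the automatic
#' segmentation under-segments. The per-case CSA is the total
#' cross-sectional area summed over axial slices (voxel count times in-plane
#' voxel area); a per-slice breakdown is available with
#' `per_slice = TRUE`.
#'
#' @param auto,truth `mask_volume`s on the same grid.
#' @param per_slice return a vector of per-axial-slice errors instead of the
#'   single per-case value (slices where the reference is empty are `NA`).
#' @return signed percentage (or vector when `per_slice`).
#' @export
csa_error <- function(auto, truth, per_slice = FALSE) {
  stopifnot(inherits(auto, "mask_volume"), inherits(truth, "mask_volume"))
  if (!same_grid(auto, truth)) stop("masks are on different grids")
  pix <- auto$spacing_mm[1] * auto$spacing_mm[2]
  if (per_slice) {
    a <- apply(auto$labels, 3, sum) * pix
    b <- apply(truth$labels, 3, sum) * pix
    return(ifelse(b > 0, (b - a) / b * 100, NA_real_))
  }
  a <- sum(auto$labels) * pix
  b <- sum(truth$labels) * pix
  if (b == 0) stop("reference area is zero")
  (b - a) / b * 100
}

#' Average surface distance (mm)
#'
#' Surface voxels are mask voxels with at least one face-adjacent background
#' neighbour. The one-sided ASD averages, over the surface voxels of `auto`,
#' the Euclidean distance (spacing-aware, via an exact distance transform)
#' to the nearest surface voxel of `truth`; `symmetric = TRUE` averages the
#' two one-sided values.
#'
#' @param auto,truth nonempty `mask_volume`s on the same grid.
#' @param symmetric average both directions (default `FALSE`: `auto` to
#'   `truth`).
#' @return nonnegative distance in mm.
#' @export
asd <- function(auto, truth, symmetric = FALSE) {
  stopifnot(inherits(auto, "mask_volume"), inherits(truth, "mask_volume"))
  if (!same_grid(auto, truth)) stop("masks are on different grids")
  if (!any(auto$labels) || !any(truth$labels)) stop("empty mask")
  sa <- surface_voxels(auto$labels)
  sb <- surface_voxels(truth$labels)
  d_to_b <- sqrt(squared_edt(sb, truth$spacing_mm))
  one_sided <- mean(d_to_b[sa])
  if (!symmetric) return(one_sided)
  d_to_a <- sqrt(squared_edt(sa, auto$spacing_mm))
  (one_sided + mean(d_to_a[sb])) / 2
}

#' Evaluate one automatic segmentation against its reference
#'
#' @param auto,truth `mask_volume`s.
#' @param case_id,label identifiers carried into the result row.
#' @param symmetric passed to [asd()].
#' @return one-row data.frame with `case_id`, `label`, `dsc`,
#'   `csa_error_pct`, `asd_mm`.
#' @export
evaluate_segmentation <- function(auto, truth, case_id = NA_character_,
                                  label = NA_character_, symmetric = FALSE) {
  data.frame(case_id = case_id, label = label,
             dsc = dsc(auto, truth),
             csa_error_pct = csa_error(auto, truth),
             asd_mm = asd(auto, truth, symmetric = symmetric),
             stringsAsFactors = FALSE)
}

#' Median [IQR] summary of segmentation metrics, overall and per group
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param results data.frame as returned by rbind-ing
#'   [evaluate_segmentation()] rows.
#' @param group_key column name to group by (default `"label"`).
#' @return data.frame with one row per (group, metric): `median`, `q1`,
#'   `q3`, `n`, and a formatted `"median [q1, q3]"` string.
#' @export
summarize_by_group <- function(results, group_key = "label") {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  metrics <- intersect(c("dsc", "csa_error_pct", "asd_mm"), names(results))
  groups <- c(list(Overall = results),
              split(results, results[[group_key]]))
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(metrics, function(m) {
      qs <- stats::quantile(df[[m]], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group = g, metric = m, n = nrow(df),
                 median = qs[2], q1 = qs[1], q3 = qs[3],
                 formatted = sprintf("%.2f [%.2f, %.2f]", qs[2], qs[1], qs[3]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
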