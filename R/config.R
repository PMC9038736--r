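# Run configuration and seed fan-out for the command-line workflows.

#' Default run configuration
#'
#' One validated list holding every tunable the workflows use; defaults
#' mirror the standard analysis constants (0.29 x 0.29 x 0.70 mm target
#' spacing, 64 bins over mean +/- 3 SD, LoG sigmas 1 and 2 mm, CCC and
#' correlation thresholds 0.90, 5 CV folds).
#'
#' @param seed global seed fanned out to per-stage seeds via
#'   [derive_seed()].
#' @param target_spacing_mm,n_bins,k_sd,log_sigmas_mm see
#'   [extraction_config()].
#' @param ccc_threshold,r_threshold,n_folds see [fracture_signature()].
#' @param phantom [phantom_params()] for simulation.
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       target_spacing_mm = c(0.29, 0.29, 0.70),
                       n_bins = 64L, k_sd = 3, log_sigmas_mm = c(1, 2),
                       ccc_threshold = 0.90, r_threshold = 0.90,
                       n_folds = 5L,
                       phantom = phantom_params(),
                       outdir = ".") {
  cfg <- list(seed = as.integer(seed),
              target_spacing_mm = as.numeric(target_spacing_mm),
              n_bins = as.integer(n_bins), k_sd = k_sd,
              log_sigmas_mm = as.numeric(log_sigmas_mm),
              ccc_threshold = ccc_threshold, r_threshold = r_threshold,
              n_folds = as.integer(n_folds),
              phantom = phantom, outdir = outdir)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg configuration list.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (any(cfg$target_spacing_mm <= 0)) stop("target spacing must be positive")
  if (cfg$n_bins < 2L) stop("n_bins must be >= 2")
  if (any(cfg$log_sigmas_mm <= 0)) stop("LoG sigmas must be positive")
  if (cfg$ccc_threshold > 1) stop("ccc_threshold must be <= 1")
  if (cfg$r_threshold <= 0 || cfg$r_threshold > 1) stop("r_threshold in (0, 1]")
  if (cfg$n_folds < 2L) stop("n_folds must be >= 2")
  validate_phantom_params(cfg$phantom)
  invisible(cfg)
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic splitmix-style derivation so each pipeline stage gets an
#' independent, reproducible RNG stream; the result is always a positive
#' integer below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name (character) or index.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  sidx <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_len(nchar(stage)))
          else as.integer(stage)
  h <- (as.numeric(seed) * 2654435761 + sidx * 40503 + 12345) %% 2147483647
  as.integer(max(1, h))
}

#' Hash of a configuration (embedded in output artifacts)
#'
#' MD5 of the canonical JSON serialisation; any changed threshold changes
#' the hash.
#'
#' @param cfg `run_config` (or any serialisable list).
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
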