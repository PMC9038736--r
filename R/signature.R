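# One fitting function tying the cascade together: feature table in,
# classed model object out, with the usual print/summary/coef/predict
# methods.

#' Fit a radiomics malignancy signature
#'
#' Runs the full model-construction cascade on a feature table: (1) drop
#' zero-variance features, (2) standardize to zero mean / unit SD, (3)
#' optionally keep only features whose concordance correlation with every
#' observer re-segmentation table exceeds `ccc_threshold`, (4) prune
#' correlated pairs by univariable association, (5) logistic LASSO with
#' stratified cross-validation. The decision cutoff is set by the Youden
#' index on the training scores.
#'
#' @param table feature table (`case_id`, `label`, feature columns).
#' @param labels binary labels; defaults to `table$label`.
#' @param repeats optional list of feature tables extracted from observer
#'   segmentations of a case subset (enables the stability filter).
#' @param ccc_threshold CCC stability threshold (default 0.90).
#' @param r_threshold correlation-pruning threshold (default 0.90).
#' @param n_folds CV folds (default 5).
#' @param seed integer seed (fold assignment).
#' @return object of class `fracture_signature`: `model` (a [model_spec()]
#'   carrying the standardizer, usable on raw feature tables), `report`
#'   (per-stage feature counts), `ccc`, `dropped`, `seed`.
#' @export
fracture_signature <- function(table, labels = NULL, repeats = NULL,
                               ccc_threshold = 0.90, r_threshold = 0.90,
                               n_folds = 5L, seed = 1L) {
  if (is.null(labels)) {
    if (is.null(table$label)) stop("labels missing and table has no label column")
    labels <- table$label
  }
  n0 <- length(feature_columns(table))
  zv <- drop_zero_variance(table)
  std <- fit_standardizer(zv$table)
  tab <- apply_standardizer(zv$table, std)
  dropped <- list(zero_variance = zv$dropped)
  ccc <- NULL
  if (!is.null(repeats)) {
    reps_std <- lapply(repeats, function(r) {
      keep <- intersect(names(r), names(zv$table))
      apply_standardizer(r[, keep, drop = FALSE], std)
    })
    st <- stability_filter(tab, reps_std, threshold = ccc_threshold)
    tab <- st$table
    ccc <- st$ccc
    dropped$unstable <- st$dropped
  }
  cp <- correlation_prune(tab, labels, r_threshold = r_threshold)
  tab <- cp$table
  dropped$correlated <- names(cp$dropped)
  spec <- lasso_cv_fit(tab, labels, n_folds = n_folds, seed = seed)
  dropped$lasso_zeroed <- setdiff(feature_columns(tab), spec$features)
  # attach the standardizer restricted to the model's features so the
  # returned model scores raw feature tables directly
  spec$standardizer <- structure(
    list(mean = std$mean[spec$features], sd = std$sd[spec$features],
         features = spec$features),
    class = "standardizer")
  report <- data.frame(
    stage = c("initial", "zero_variance", "stability", "correlation", "lasso"),
    n_features = c(n0,
                   n0 - length(dropped$zero_variance),
                   n0 - length(dropped$zero_variance) -
                     length(dropped$unstable %||% character(0)),
                   length(feature_columns(tab)),
                   length(spec$features)))
  structure(list(model = spec, report = report, ccc = ccc,
                 dropped = dropped, seed = seed,
                 call = match.call()),
            class = "fracture_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.fracture_signature <- function(x, ...) {
  cat("Radiomics malignancy signature\n")
  cat("  features:", length(x$model$features),
      " | intercept:", signif(x$model$intercept, 4),
      " | cutoff:", signif(x$model$cutoff, 4), "\n")
  cat("  cascade: ", paste(sprintf("%s=%d", x$report$stage, x$report$n_features),
                           collapse = " -> "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.fracture_signature <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(data.frame(feature = object$model$features,
                   beta = object$model$coefficients), row.names = FALSE)
  invisible(object)
}

#' @exportS3Method
coef.fracture_signature <- function(object, ...) coef(object$model)

#' @exportS3Method
predict.fracture_signature <- function(object, newdata,
                                       type = c("score", "class"), ...) {
  predict(object$model, newdata, type = match.arg(type))
}
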