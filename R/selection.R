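# The four-step model-construction cascade: zero-variance filter,
# standardisation, concordance-correlation stability filter against
# observer re-segmentations, correlation pruning by univariable
# association, and logistic LASSO with stratified 5-fold cross-validation.

#' Drop features with zero variance across cases
#'
#' Variance is tested exactly after rounding values to 12 significant
#' digits, so features constant up to representation noise are removed.
#'
#' @param table feature table (data.frame; non-feature columns `case_id`,
#'   `patient_id`, `label` are preserved).
#' @return list: `table` (filtered), `dropped` (character), `report`.
#' @export
drop_zero_variance <- function(table) {
  fc <- feature_columns(table)
  if (nrow(table) < 2L) stop("need at least 2 cases")
  is_const <- vapply(fc, function(f) {
    v <- signif(table[[f]], 12)
    length(unique(v)) == 1L
  }, logical(1))
  dropped <- fc[is_const]
  list(table = table[, setdiff(names(table), dropped), drop = FALSE],
       dropped = dropped,
       report = data.frame(stage = "zero_variance",
                           n_in = length(fc), n_out = sum(!is_const)))
}

#' Fit / apply per-feature standardisation (zero mean, unit SD)
#'
#' Means and standard deviations (sample SD, `n - 1` denominator) are
#' learned on the training table and re-used unchanged on test tables.
#'
#' @param table feature table.
#' @return `fit_standardizer`: list of class `standardizer` with `mean`,
#'   `sd` per feature; `apply_standardizer`: the transformed table.
#' @export
fit_standardizer <- function(table) {
  fc <- feature_columns(table)
  mu <- vapply(fc, function(f) mean(table[[f]]), numeric(1))
  sd_ <- vapply(fc, function(f) stats::sd(table[[f]]), numeric(1))
  if (any(sd_ == 0 | !is.finite(sd_))) {
    stop("zero-variance feature(s) present; run drop_zero_variance first: ",
         paste(fc[sd_ == 0 | !is.finite(sd_)][1:min(3, sum(sd_ == 0))],
               collapse = ", "))
  }
  structure(list(mean = mu, sd = sd_, features = fc), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a `standardizer` fitted on training data.
#' @export
apply_standardizer <- function(table, params) {
  stopifnot(inherits(params, "standardizer"))
  missing <- setdiff(params$features, names(table))
  if (length(missing) > 0) {
    stop("table lacks standardized feature(s): ",
         paste(missing[1:min(3, length(missing))], collapse = ", "))
  }
  for (f in params$features) {
    table[[f]] <- (table[[f]] - params$mean[[f]]) / params$sd[[f]]
  }
  table
}

#' Lin's concordance correlation coefficient
#'
#' `2 * s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with population (1/n)
#' moments. Degenerate inputs: both constant with equal means gives 1;
#' any other constant input gives 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return value in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) return(if (mx == my) 1 else 0)
  if (vx == 0 || vy == 0) return(0)
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Retain features stable under observer re-segmentation
#'
#' A feature is kept iff its minimum CCC between the primary (ground-truth
#' segmentation) values and every repeat table exceeds `threshold`
#' (strictly). Repeat tables hold the same features extracted from observer
#' segmentations of a case subset; cases are matched by `case_id`.
#'
#' @param primary feature table from ground-truth masks.
#' @param repeats list of feature tables from observer masks; their
#'   `case_id`s must all be present in `primary`.
#' @param threshold CCC threshold (default 0.90).
#' @return list: `table` (filtered primary), `ccc` (feature x repeat
#'   matrix of CCC values), `dropped`, `report`.
#' @export
stability_filter <- function(primary, repeats, threshold = 0.90) {
  if (!is.list(repeats) || length(repeats) == 0) stop("repeats must be a nonempty list")
  fc <- feature_columns(primary)
  ccc <- matrix(NA_real_, length(fc), length(repeats),
                dimnames = list(fc, NULL))
  for (r in seq_along(repeats)) {
    rep_tab <- repeats[[r]]
    if (!all(rep_tab$case_id %in% primary$case_id)) {
      stop("repeat table ", r, " contains case_ids absent from the primary table")
    }
    idx <- match(rep_tab$case_id, primary$case_id)
    for (f in fc) {
      if (!f %in% names(rep_tab)) stop("repeat table ", r, " lacks feature ", f)
      ccc[f, r] <- lin_ccc(primary[[f]][idx], rep_tab[[f]])
    }
  }
  keep <- apply(ccc, 1, min) > threshold
  dropped <- fc[!keep]
  list(table = primary[, setdiff(names(primary), dropped), drop = FALSE],
       ccc = ccc, dropped = dropped,
       report = data.frame(stage = "stability", n_in = length(fc),
                           n_out = sum(keep)))
}

# univariable association p-value of a feature with the binary label:
# two-sided Mann-Whitney / Wilcoxon rank-sum test
.univariable_p <- function(x, labels) {
  g1 <- unique(labels)[1]
  suppressWarnings(
    stats::wilcox.test(x[labels == g1], x[labels != g1], exact = FALSE)$p.value
  )
}

#' Prune highly correlated feature pairs
#'
#' Pairs with `|Pearson r| > r_threshold` are visited in descending `|r|`;
#' for each pair still fully retained, the feature with the larger
#' univariable association p-value (two-sided Mann-Whitney test against the
#' binary label) is dropped. The result contains no retained pair above the
#' threshold.
#'
#' @param table feature table.
#' @param labels binary label vector (one per row of `table`).
#' @param r_threshold correlation threshold (default 0.90).
#' @return list: `table`, `dropped` (with reasons), `report`.
#' @export
correlation_prune <- function(table, labels, r_threshold = 0.90) {
  fc <- feature_columns(table)
  if (length(unique(labels)) != 2L) stop("labels must be binary")
  X <- as.matrix(table[, fc, drop = FALSE])
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  pairs <- which(abs(cm) > r_threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(list(table = table, dropped = character(0),
                report = data.frame(stage = "correlation", n_in = length(fc),
                                    n_out = length(fc))))
  }
  ord <- order(-abs(cm[pairs]))
  pairs <- pairs[ord, , drop = FALSE]
  pcache <- rep(NA_real_, length(fc))
  getp <- function(k) {
    if (is.na(pcache[k])) pcache[k] <<- .univariable_p(X[, k], labels)
    pcache[k]
  }
  retained <- rep(TRUE, length(fc))
  reason <- character(0)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]
    b <- pairs[r, 2]
    if (!retained[a] || !retained[b]) next
    drop_idx <- if (getp(a) >= getp(b)) a else b
    retained[drop_idx] <- FALSE
    reason <- c(reason, sprintf("%s: |r|=%.3f with %s, larger p (%.3g vs %.3g)",
                                fc[drop_idx], abs(cm[a, b]),
                                fc[if (drop_idx == a) b else a],
                                getp(drop_idx), getp(if (drop_idx == a) b else a)))
  }
  dropped <- fc[!retained]
  list(table = table[, setdiff(names(table), dropped), drop = FALSE],
       dropped = stats::setNames(reason, dropped),
       report = data.frame(stage = "correlation", n_in = length(fc),
                           n_out = sum(retained)))
}

#' Logistic LASSO with stratified cross-validation
#'
#' Fits an L1-penalised logistic regression over a 100-value log-spaced
#' lambda grid (from just above the smallest lambda zeroing all
#' coefficients down four decades), choosing the lambda minimising mean
#' cross-validated binomial deviance over seeded, class-stratified folds.
#' Because the CV deviance is itself a noisy estimate, deviances within one
#' cross-validation standard error of the minimum are treated as tied, and
#' ties are broken toward the larger lambda (the sparser model) -- the
#' usual one-standard-error rule. The model is refit on all data at the
#' chosen lambda. Inputs are expected standardized; glmnet's internal
#' standardisation is disabled.
#'
#' @param table standardized feature table.
#' @param labels binary labels; the positive (malignant) class is the
#'   level given by `positive`.
#' @param positive value of `labels` treated as the positive class
#'   (default `"malignant"` if present, else the larger level).
#' @param n_folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param lambda optional fixed lambda (skips CV; used for the null-model
#'   limit).
#' @return `model_spec` (see [model_spec()]) with the selected features and
#'   the training-score Youden cutoff, plus attributes `lambda`, `cv`.
#' @export
lasso_cv_fit <- function(table, labels, positive = NULL, n_folds = 5L,
                         seed = 1L, lambda = NULL) {
  fc <- feature_columns(table)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (is.null(positive)) {
    positive <- if ("malignant" %in% labels) "malignant" else max(as.character(labels))
  }
  y <- as.integer(labels == positive)
  X <- as.matrix(table[, fc, drop = FALSE])
  n <- nrow(X)
  if (min(table(y)) < n_folds) stop("need at least n_folds cases per class")
  # lambda grid: lambda_max zeroes every coefficient for the null intercept
  ybar <- mean(y)
  lambda_max <- 1.01 * max(abs(crossprod(X, y - ybar))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))
  if (is.null(lambda)) {
    foldid <- integer(n)
    with_seed(seed, {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    })
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", lambda = grid,
                               foldid = foldid, type.measure = "deviance",
                               standardize = FALSE)
    cvm <- cvfit$cvm
    # deviances within one CV standard error of the minimum are ties;
    # ties resolve toward the larger lambda (the sparser model), i.e. the
    # first qualifying entry of the decreasing grid
    tol <- cvfit$cvsd[which.min(cvm)]
    best <- which(cvm <= min(cvm) + tol)[1]
    lambda_star <- cvfit$lambda[best]
    cv <- data.frame(lambda = cvfit$lambda, deviance = cvm, sd = cvfit$cvsd)
  } else {
    lambda_star <- lambda
    cv <- NULL
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = grid,
                        standardize = FALSE)
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda_star, exact = FALSE))
  names(beta) <- c("(Intercept)", fc)
  nz <- beta[-1][beta[-1] != 0]
  spec <- model_spec(features = names(nz), coefficients = unname(nz),
                     intercept = beta[1], cutoff = NA_real_,
                     positive = positive)
  scores <- score(spec, table)
  if (length(spec$features) > 0 && length(unique(scores)) > 1) {
    spec$cutoff <- youden_cutoff(scores, y)$cutoff
  } else {
    spec$cutoff <- 0
  }
  attr(spec, "lambda") <- lambda_star
  attr(spec, "cv") <- cv
  spec
}
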