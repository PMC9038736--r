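# The radiomics malignancy signature: a sparse linear combination of
# standardized features, the published 12-feature instance of it, and the
# diagnostic statistics used to compare segmentations (ROC/AUC, DeLong,
# Youden cutoff, exact McNemar, Wilson confidence intervals).

#' Construct a model specification
#'
#' A `model_spec` scores a case as `intercept + sum(beta_i * z_i)` over
#' standardized feature values `z`, and calls it positive (malignant) when
#' the score is at or above `cutoff`.
#'
#' @param features ordered feature names (catalogue ids or any column names
#'   present in the tables to score).
#' @param coefficients numeric, one per feature.
#' @param intercept scalar.
#' @param cutoff decision cutoff on the linear score.
#' @param standardizer optional [fit_standardizer()] result applied before
#'   scoring; when `NULL` the inputs must already be standardized.
#' @param positive label of the positive class (default `"malignant"`).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(features, coefficients, intercept, cutoff,
                       standardizer = NULL, positive = "malignant") {
  if (length(features) != length(coefficients)) {
    stop("coefficient count must equal feature count")
  }
  structure(list(features = as.character(features),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 cutoff = as.numeric(cutoff),
                 standardizer = standardizer,
                 positive = positive),
            class = "model_spec")
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", length(x$features), " features, intercept ",
      signif(x$intercept, 4), ", cutoff ", signif(x$cutoff, 4), "\n", sep = "")
  if (length(x$features) > 0) {
    df <- data.frame(feature = x$features, beta = x$coefficients)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method
coef.model_spec <- function(object, ...) {
  stats::setNames(c(object$intercept, object$coefficients),
                  c("(Intercept)", object$features))
}

#' The published 12-feature malignancy signature
#'
#' Returns the released model specification: 12 features spanning the
#' morphology, local-intensity, statistics, histogram, GLCM, GLSZM, NGLDM
#' and LoG-filtered families, with intercept -0.176 and decision cutoff
#' 0.328 on the linear score. The standardisation means/SDs of the original
#' training cohort were never released, so the spec carries no
#' standardizer: [score()] expects pre-standardized inputs, and applying
#' the published coefficients to new raw data is not reproducible.
#'
#' @return `model_spec` with 12 features.
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_model.json", package = "vertrad",
                      mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(features = j$features$id,
             coefficients = j$features$beta,
             intercept = j$intercept,
             cutoff = j$cutoff)
}

#' Score cases with a model specification
#'
#' @param model `model_spec`.
#' @param features named numeric vector, or a feature table (data.frame)
#'   with one row per case. Values must be standardized unless the model
#'   carries a standardizer.
#' @return numeric score(s): `intercept + sum(beta * z)`.
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "model_spec"))
  if (is.data.frame(features)) {
    if (!is.null(model$standardizer)) {
      features <- apply_standardizer(features, model$standardizer)
    }
    missing <- setdiff(model$features, names(features))
    if (length(missing) > 0) {
      stop("missing feature: ", paste(missing, collapse = ", "))
    }
    X <- as.matrix(features[, model$features, drop = FALSE])
    return(as.numeric(model$intercept + X %*% model$coefficients))
  }
  missing <- setdiff(model$features, names(features))
  if (length(missing) > 0) {
    stop("missing feature: ", paste(missing, collapse = ", "))
  }
  z <- as.numeric(features[model$features])
  if (!is.null(model$standardizer)) {
    z <- (z - model$standardizer$mean[model$features]) /
      model$standardizer$sd[model$features]
  }
  model$intercept + sum(model$coefficients * z)
}

#' Classify cases with a model specification
#'
#' Positive (malignant) iff `score >= cutoff`; the tie at the cutoff goes
#' to the positive class.
#'
#' @inheritParams score
#' @return character vector of `"malignant"` / `"benign"` (using the
#'   model's `positive` label).
#' @export
classify <- function(model, features) {
  s <- score(model, features)
  ifelse(s >= model$cutoff, model$positive, "benign")
}

#' @exportS3Method
predict.model_spec <- function(object, newdata,
                               type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (type == "score") score(object, newdata) else classify(object, newdata)
}

# ---- diagnostic statistics ------------------------------------------------

#' Confusion counts
#'
#' @param tp,fp,tn,fn nonnegative integers.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || sum(v) == 0) stop("counts must be nonnegative, total > 0")
  structure(as.list(v), class = "confusion_counts")
}

# Wilson 95% score interval for a binomial proportion
.wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Diagnostic performance from confusion counts
#'
#' Accuracy, sensitivity, specificity, PPV and NPV with Wilson 95%
#' confidence intervals; metrics with a zero denominator are reported as
#' `NA`.
#'
#' @param counts `confusion_counts` (or the four counts via `tp=`, ...).
#' @param ... used to pass `tp`, `fp`, `tn`, `fn` directly.
#' @return data.frame with `metric`, `numerator`, `denominator`,
#'   `estimate` (proportion), `pct`, `ci_lo`, `ci_hi`.
#' @export
diagnostic_metrics <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- confusion_counts(...)
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  defs <- list(accuracy = c(tp + tn, n),
               sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn))
  rows <- lapply(names(defs), function(m) {
    k <- defs[[m]][1]
    d <- defs[[m]][2]
    est <- if (d > 0) k / d else NA_real_
    ci <- .wilson_ci(k, d)
    data.frame(metric = m, numerator = k, denominator = d, estimate = est,
               pct = 100 * est, ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance probability (ties get half credit),
#' which equals the trapezoidal area under the empirical ROC. The 95% CI
#' uses the DeLong structural-component variance.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels (0/1, logical, or two-level; the larger /
#'   `TRUE` / `"malignant"` level is positive).
#' @return list of class `roc_result`: `curve` (data.frame of threshold,
#'   sensitivity, specificity), `auc`, `auc_ci`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               sensitivity = mean(pos >= t),
               specificity = mean(neg < t))
  }))
  v <- .delong_components(scores, y)
  se <- sqrt(stats::var(v$v10) / length(pos) + stats::var(v$v01) / length(neg))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(curve = curve, auc = auc, auc_ci = ci), class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", sprintf("%.3f", x$auc), " (95% CI ",
      sprintf("%.3f", x$auc_ci[1]), "-", sprintf("%.3f", x$auc_ci[2]), ")\n",
      sep = "")
  invisible(x)
}

.binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  lv <- sort(unique(as.character(labels)))
  if (length(lv) > 2L) stop("labels must be binary")
  pos <- if ("malignant" %in% lv) "malignant" else lv[length(lv)]
  as.integer(as.character(labels) == pos)
}

# DeLong structural components: v10 per positive, v01 per negative
.delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided z-test of the paired AUC difference using the DeLong
#' structural-component covariance; both score vectors must refer to the
#' same cases in the same order.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (see [roc_auc()]).
#' @return list: `auc_a`, `auc_b`, `diff`, `se`, `z`, `p_value`,
#'   `diff_ci` (95%).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) stop("paired scores required")
  y <- .binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ca <- .delong_components(scores_a, y)
  cb <- .delong_components(scores_b, y)
  auc_a <- mean(ca$v10)
  auc_b <- mean(cb$v10)
  m <- sum(y == 1)
  n <- sum(y == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- auc_a - auc_b
  if (var_diff <= 0) {
    if (abs(d) > 0) warning("degenerate DeLong variance with unequal AUCs")
    return(list(auc_a = auc_a, auc_b = auc_b, diff = d, se = 0, z = 0,
                p_value = 1, diff_ci = c(d, d)))
  }
  se <- sqrt(var_diff)
  z <- d / se
  list(auc_a = auc_a, auc_b = auc_b, diff = d, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       diff_ci = d + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Cutoff maximising the Youden index
#'
#' Scans midpoints between adjacent distinct scores (plus sentinels below
#' and above all scores), classifying `score >= cutoff` as positive;
#' returns the cutoff with maximal `J = sensitivity + specificity - 1`,
#' ties resolved toward the lowest cutoff.
#'
#' @inheritParams roc_auc
#' @return list: `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- .binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) s else c(s[1] - 1, (s[-1] + s[-length(s)]) / 2,
                                        s[length(s)] + 1)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  best <- list(cutoff = cand[1], j = -Inf, sensitivity = NA, specificity = NA)
  for (ct in cand) {
    sens <- mean(pos >= ct)
    spec <- mean(neg < ct)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      best <- list(cutoff = ct, j = j, sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' Exact McNemar test for paired classifier accuracy
#'
#' With discordant counts `b` (A correct, B wrong) and `c` (B correct, A
#' wrong), the two-sided exact p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`,
#' and 1 when `b + c = 0`.
#'
#' @param correct_a,correct_b logical (or 0/1) vectors marking which cases
#'   each classifier got right, paired by position.
#' @return list: `b`, `c`, `p_value`.
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) stop("paired vectors required")
  a <- as.logical(correct_a)
  b_ <- as.logical(correct_b)
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  n <- b + cc
  p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
  list(b = b, c = cc, p_value = p)
}
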