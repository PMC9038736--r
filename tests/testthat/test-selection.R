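# The feature-selection cascade: variance filter, standardisation, CCC,
# correlation pruning and the cross-validated LASSO.

make_table <- function(X, labels = NULL, ids = NULL) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  cbind(data.frame(case_id = ids %||% paste0("c", seq_len(nrow(X))),
                   label = labels %||% rep("benign_acute", nrow(X)),
                   stringsAsFactors = FALSE),
        df)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("zero-variance features are dropped exactly", {
  set.seed(1)
  X <- matrix(rnorm(20 * 20), 20)
  X[, 1:5] <- matrix(rep(c(3, -1, 0, 1e5, 1e-7), each = 20), 20)
  tab <- make_table(X)
  out <- drop_zero_variance(tab)
  expect_length(out$dropped, 5L)
  expect_equal(out$report$n_out, 15L)
  # no constants -> identity
  out2 <- drop_zero_variance(out$table)
  expect_length(out2$dropped, 0L)
  expect_identical(out2$table, out$table)
})

test_that("standardisation learns on training data and reuses parameters", {
  tab <- make_table(matrix(c(1, 2, 3, 10, 20, 30), 3))
  std <- fit_standardizer(tab)
  fitted <- apply_standardizer(tab, std)
  for (f in c("f1", "f2")) {
    expect_lt(abs(mean(fitted[[f]])), 1e-12)
    expect_equal(stats::sd(fitted[[f]]), 1)
  }
  # test value 4 under training {1, 2, 3}: (4 - 2) / 1 = 2 (sample SD)
  test_tab <- make_table(matrix(c(4, 20), 1))
  mapped <- apply_standardizer(test_tab, std)
  expect_equal(mapped$f1, 2)
  expect_equal(mapped$f2, 0)
  # standardising a constant feature is refused
  expect_error(fit_standardizer(make_table(matrix(1, 4, 1))), "zero-variance")
})

test_that("Lin's CCC matches the population-moment closed form", {
  x <- c(1, 5, 2, 8, 4)
  expect_equal(lin_ccc(x, x), 1)
  y <- c(-2, 0, 2)
  expect_equal(lin_ccc(y, -y), -1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)),
               2 * (2 / 3) / ((2 / 3) + (2 / 3) + 1), tolerance = 1e-12)
  # degenerate rules
  expect_equal(lin_ccc(rep(2, 5), rep(2, 5)), 1)
  expect_equal(lin_ccc(rep(2, 5), rep(3, 5)), 0)
  expect_equal(lin_ccc(rep(2, 5), c(1, 2, 3, 4, 5)), 0)
  expect_error(lin_ccc(1:2, 1:2), "at least 3")
  # |CCC| never exceeds |Pearson r|
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- 2 * a + rnorm(30)
    expect_lte(abs(lin_ccc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
})

test_that("the stability filter keeps features concordant across repeats", {
  set.seed(3)
  n <- 35
  X <- matrix(rnorm(n * 6), n)
  prim <- make_table(X, ids = sprintf("c%02d", 1:n))
  # repeats: tiny perturbations, except feature 4 replaced by noise in one
  mk_rep <- function(noise_col = NULL) {
    Xr <- X + matrix(rnorm(n * 6, sd = 0.02), n)
    if (!is.null(noise_col)) Xr[, noise_col] <- rnorm(n)
    make_table(Xr, ids = sprintf("c%02d", 1:n))
  }
  reps <- list(mk_rep(), mk_rep(), mk_rep(noise_col = 4))
  out <- stability_filter(prim, reps, threshold = 0.90)
  expect_true("f4" %in% out$dropped)
  expect_false(any(c("f1", "f2", "f3", "f5", "f6") %in% out$dropped))

  # identical repeats retain everything; threshold -1 is vacuous
  out_id <- stability_filter(prim, list(prim, prim))
  expect_length(out_id$dropped, 0L)
  out_vac <- stability_filter(prim, reps, threshold = -1)
  expect_length(out_vac$dropped, 0L)

  bad <- mk_rep()
  bad$case_id[1] <- "zzz"
  expect_error(stability_filter(prim, list(bad)), "absent")
})

test_that("correlation pruning drops the weaker of near-duplicate features", {
  set.seed(4)
  n <- 60
  labels <- rep(c("benign_acute", "malignant"), each = n / 2)
  signal <- ifelse(labels == "malignant", 1.5, 0) + rnorm(n, sd = 0.7)
  A <- signal
  B <- A + rnorm(n, sd = 0.05)       # near-duplicate, slightly noisier
  C <- rnorm(n)                      # independent
  tab <- make_table(cbind(A, B, C), labels)
  out <- correlation_prune(tab, labels, r_threshold = 0.90)
  expect_identical(unname(names(out$dropped)), "f2")
  expect_true(all(c("f1", "f3") %in% feature_columns(out$table)))
  # post-condition: no retained pair above the threshold (brute force)
  cm <- stats::cor(as.matrix(out$table[, feature_columns(out$table)]))
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.90))

  # exact duplicates: exactly one survives
  dup <- make_table(cbind(A, A, C), labels)
  out2 <- correlation_prune(dup, labels)
  expect_length(out2$dropped, 1L)

  # nothing above threshold -> identity
  ind <- make_table(matrix(rnorm(n * 3), n), labels)
  expect_length(correlation_prune(ind, labels)$dropped, 0L)
})

test_that("the LASSO recovers planted signal and has the null-model limit", {
  # two informative features with a 2-SD class shift among 20 decoys
  set.seed(5)
  n <- 150
  p <- 22
  X <- matrix(rnorm(n * p), n)
  y <- rep(c(0L, 1L), length.out = n)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  X[y == 1, 2] <- X[y == 1, 2] - 2
  labels <- ifelse(y == 1, "malignant", "benign_acute")
  X <- scale(X)
  tab <- make_table(X, labels)

  fit <- lasso_cv_fit(tab, labels, seed = 7)
  expect_true(all(c("f1", "f2") %in% fit$features))
  decoys <- setdiff(paste0("f", 1:p), c("f1", "f2"))
  expect_gte(sum(!decoys %in% fit$features), 0.8 * length(decoys))

  # determinism under the seed
  fit2 <- lasso_cv_fit(tab, labels, seed = 7)
  expect_identical(fit$features, fit2$features)
  expect_equal(fit$coefficients, fit2$coefficients)
  expect_equal(attr(fit, "lambda"), attr(fit2, "lambda"))

  # infinite-penalty endpoint: all coefficients zero, intercept = logit(prev)
  null_fit <- lasso_cv_fit(tab, labels, lambda = 1e6)
  expect_length(null_fit$features, 0L)
  expect_equal(null_fit$intercept, stats::qlogis(mean(y)), tolerance = 1e-4)

  expect_error(lasso_cv_fit(tab, rep("malignant", n)), "both classes")
})

test_that("the composed cascade removes planted defects in stage order", {
  set.seed(6)
  n <- 40
  labels <- rep(c("benign_acute", "malignant"), each = n / 2)
  sig <- ifelse(labels == "malignant", 2, 0) + rnorm(n, sd = 0.8)
  X <- cbind(const = rep(1, n),
             sig = sig,
             dup = sig + rnorm(n, sd = 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n),
             unstable = rnorm(n))
  tab <- make_table(X, labels, ids = sprintf("c%02d", 1:n))
  reps <- lapply(1:3, function(i) {
    Xr <- X + matrix(rnorm(length(X), sd = 0.01), n)
    Xr[, "unstable"] <- rnorm(n)
    make_table(Xr, labels, ids = sprintf("c%02d", 1:n))
  })
  sig_fit <- fracture_signature(tab, repeats = reps, seed = 9)
  expect_true("f1" %in% sig_fit$dropped$zero_variance)       # const
  expect_true("f6" %in% sig_fit$dropped$unstable)            # unstable
  expect_true(any(c("f2", "f3") %in% sig_fit$dropped$correlated))
  expect_true(all(diff(sig_fit$report$n_features) <= 0))
  # the signal survives to the final model
  expect_true(any(c("f2", "f3") %in% sig_fit$model$features))
  # the fitted model scores raw tables through its standardizer
  sc <- predict(sig_fit, tab)
  expect_length(sc, n)
  expect_true(all(is.finite(sc)))
})
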