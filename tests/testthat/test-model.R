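# Published signature arithmetic and the diagnostic statistics.

test_that("the published model reproduces its printed coefficients", {
  pm <- published_model()
  expect_length(pm$features, 12L)
  expect_equal(pm$intercept, -0.176)
  expect_equal(pm$cutoff, 0.328)
  cf <- coef(pm)
  expect_equal(unname(cf["original__glszm__small_zone_low_grey_level_emphasis"]),
               -0.994)
  expect_equal(unname(cf["original__morphological__approximate_volume"]),
               -0.483)
  expect_true(all(pm$coefficients != 0))
})

test_that("scoring is the linear combination with the stated tie rule", {
  pm <- published_model()
  z0 <- stats::setNames(rep(0, 12), pm$features)
  expect_equal(score(pm, z0), -0.176)
  expect_equal(classify(pm, z0), "benign")

  z1 <- z0
  z1["original__morphological__approximate_volume"] <- 1
  expect_equal(score(pm, z1), -0.176 - 0.483)

  # linearity: score(2z) - score(z) = score(z) - score(0)
  z <- stats::setNames(rnorm(12), pm$features)
  z2 <- 2 * z
  expect_equal(score(pm, z2) - score(pm, z), score(pm, z) - score(pm, z0),
               tolerance = 1e-12)

  # ties at the cutoff are malignant; a clear positive is malignant
  zc <- z0
  zc["original__local_intensity__global_intensity_peak"] <-
    (0.328 + 0.176) / 0.837
  expect_equal(score(pm, zc), 0.328, tolerance = 1e-12)
  expect_equal(classify(pm, zc), "malignant")

  expect_error(score(pm, z0[-1]), "missing feature")
})

test_that("model specs survive a JSON round-trip", {
  pm <- published_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_spec(pm, f)
  pm2 <- read_model_spec(f)
  expect_equal(pm2$features, pm$features)
  expect_equal(pm2$coefficients, pm$coefficients)
  expect_equal(pm2$intercept, pm$intercept)
  expect_equal(pm2$cutoff, pm$cutoff)
})

test_that("diagnostic metrics reproduce closed-form proportions", {
  dm <- diagnostic_metrics(tp = 69, fn = 5, fp = 19, tn = 65)
  get <- function(m) dm$pct[dm$metric == m]
  expect_equal(get("accuracy"), 100 * 134 / 158)
  expect_equal(get("sensitivity"), 100 * 69 / 74)
  expect_equal(get("specificity"), 100 * 65 / 84)
  expect_equal(get("ppv"), 100 * 69 / 88)
  expect_equal(get("npv"), 100 * 65 / 70)
  expect_true(all(dm$ci_lo <= dm$estimate & dm$estimate <= dm$ci_hi))

  perfect <- diagnostic_metrics(tp = 10, fn = 0, fp = 0, tn = 10)
  expect_true(all(perfect$pct == 100))
  even <- diagnostic_metrics(tp = 25, fn = 25, fp = 25, tn = 25)
  expect_true(all(even$pct == 50))
})

test_that("AUC equals all-pairs concordance and flips with labels", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  r <- roc_auc(c(0.1, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0.1, 0.6, 0.4, 0.9), c(1, 1, 0, 0))$auc, 0.25)

  set.seed(12)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- round(rnorm(n), 1)           # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, y)$auc, oracle_auc(sc, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(80)
  y <- rbinom(80, 1, stats::plogis(sc))
  ours <- roc_auc(sc, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the DeLong test is null for identical models and antisymmetric", {
  set.seed(14)
  y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  same <- delong_test(s, s, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  s2 <- rnorm(60)
  ab <- delong_test(s, s2, y)
  ba <- delong_test(s2, s, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  # a perfect model against noise at n = 200/class is overwhelmingly distinct
  yy <- rep(c(0, 1), each = 200)
  sa <- yy + 0.01 * rnorm(400)
  sb <- rnorm(400)
  expect_lt(delong_test(sa, sb, yy)$p_value, 0.001)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(100, 1, 0.5)
  y[1:2] <- c(0, 1)
  sa <- rnorm(100) + 0.8 * y
  sb <- rnorm(100) + 0.3 * y
  ours <- delong_test(sa, sb, y)
  ra <- pROC::roc(y, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("the Youden cutoff matches an exhaustive scan", {
  out <- youden_cutoff(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(out$cutoff, 0.5)
  expect_equal(out$j, 1)

  # degenerate: identical scores give J = 0
  expect_equal(youden_cutoff(rep(0.3, 6), c(0, 0, 0, 1, 1, 1))$j, 0)

  # shift equivariance
  sc <- c(0.2, 0.5, 0.3, 0.8, 0.9, 0.1)
  y <- c(0, 1, 0, 1, 1, 0)
  a <- youden_cutoff(sc, y)
  b <- youden_cutoff(sc + 10, y)
  expect_equal(b$cutoff, a$cutoff + 10)
  expect_equal(b$j, a$j)

  # exhaustive oracle over a fine grid of cutoffs
  set.seed(16)
  sc2 <- rnorm(40)
  y2 <- rbinom(40, 1, 0.5)
  y2[1:2] <- c(0, 1)
  got <- youden_cutoff(sc2, y2)
  grid <- seq(min(sc2) - 1, max(sc2) + 1, length.out = 2000)
  js <- vapply(grid, function(ct) {
    mean(sc2[y2 == 1] >= ct) + mean(sc2[y2 == 0] < ct) - 1
  }, numeric(1))
  expect_equal(got$j, max(js), tolerance = 1e-9)
  # the metrics at the chosen cutoff achieve the maximal J
  expect_equal(got$sensitivity + got$specificity - 1, got$j)
})

test_that("exact McNemar matches binomial tail enumeration", {
  expect_equal(mcnemar_exact(c(TRUE, TRUE), c(TRUE, TRUE))$p_value, 1)

  # b = 2, c = 8: two-sided exact p = 2 * (1 + 10 + 45) / 1024
  ca <- c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 5))
  cb <- c(rep(FALSE, 2), rep(TRUE, 8), rep(TRUE, 5))
  out <- mcnemar_exact(ca, cb)
  expect_equal(out$b, 2)
  expect_equal(out$c, 8)
  expect_equal(out$p_value, 2 * (choose(10, 0) + choose(10, 1) +
                                   choose(10, 2)) / 2^10)
  expect_equal(out$p_value, 0.109375)

  # b = c: the capped two-sided p is 1 (or just above, capped)
  cc <- mcnemar_exact(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(cc$p_value, 1)
})
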