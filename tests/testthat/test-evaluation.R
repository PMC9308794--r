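test_that("virtual plugs realize the target mass and average the map", {
  arr <- array(FALSE, c(30, 30, 30)); arr[2:29, 2:29, 2:29] <- TRUE
  myo <- new_mask(arr, c(1, 1, 1))
  map <- array(2.0, c(30, 30, 30))
  plug <- extract_plug(map, myo, c(15, 15, 15), target_mass_g = 10, rho = 1.053)
  expect_equal(as.numeric(plug), 2.0)
  expect_equal(attr(plug, "n_voxels"), 9497L)  # ceiling(10 / 1.053 / 0.001)
  expect_lt(abs(attr(plug, "mass_g") - 10) / 10, 0.02)

  # boundary plug averaging values split across two halves
  map2 <- map; map2[1:15, , ] <- 1; map2[16:30, , ] <- 3
  arr2 <- array(TRUE, c(30, 30, 30))
  plug2 <- extract_plug(map2, new_mask(arr2, c(1, 1, 1)), c(15, 15, 15),
                        target_mass_g = 2, rho = 1)
  expect_lt(abs(as.numeric(plug2) - 2.0), 0.15)

  expect_error(extract_plug(map, myo, c(15, 15, 15), target_mass_g = 1e4),
               "insufficient")
})

test_that("OLS regression recovers exact lines and hand-solved fits", {
  p <- data.frame(ref_perfusion = c(0.5, 1, 1.5, 2, 3),
                  ct_perfusion = 2 * c(0.5, 1, 1.5, 2, 3) + 1)
  f <- ols_fit(p)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$slope_ci[1], f$slope_ci[2], tolerance = 1e-8)

  # y = x with one outlier: solve the 2x2 normal equations directly
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 10)
  n <- 5
  sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  ic <- mean(y) - sl * mean(x)
  f2 <- ols_fit(data.frame(ref_perfusion = x, ct_perfusion = y))
  expect_equal(f2$slope, sl, tolerance = 1e-12)
  expect_equal(f2$intercept, ic, tolerance = 1e-12)

  expect_error(ols_fit(data.frame(ref_perfusion = c(1, 1, 1),
                                  ct_perfusion = 1:3)), "degenerate")
})

test_that("Pearson and Lin's concordance match their defining formulas", {
  p <- data.frame(ref_perfusion = c(1, 2, 3), ct_perfusion = c(2, 4, 6))
  expect_equal(pearson_r(p)$r, 1)
  expect_equal(lin_ccc(p)$ccc, 8 / 22)   # population moments by hand
  pid <- data.frame(ref_perfusion = 1:5, ct_perfusion = 1:5)
  expect_equal(pearson_r(pid)$r, 1)
  expect_equal(lin_ccc(pid)$ccc, 1)
  pc <- data.frame(ref_perfusion = 1:5, ct_perfusion = rep(2, 5))
  expect_equal(lin_ccc(pc)$ccc, 0)       # zero covariance
  expect_error(pearson_r(pc), "zero variance")
})

test_that("RMSE is about the identity line, RMSD about the regression line", {
  pid <- data.frame(ref_perfusion = c(1, 2, 3, 4), ct_perfusion = c(1, 2, 3, 4))
  expect_equal(rmse_identity(pid), 0)
  expect_equal(rmsd_regression(pid), 0)
  pb <- data.frame(ref_perfusion = c(1, 2, 3, 4),
                   ct_perfusion = c(1, 2, 3, 4) + 1)
  expect_equal(rmse_identity(pb), 1)                 # pure bias
  expect_equal(rmsd_regression(pb), 0, tolerance = 1e-12)
  p5 <- data.frame(ref_perfusion = c(0.5, 1.2, 1.9, 2.4, 3.1),
                   ct_perfusion = c(0.7, 1.0, 2.2, 2.1, 3.4))
  expect_equal(rmse_identity(p5),
               sqrt(mean((p5$ct_perfusion - p5$ref_perfusion)^2)))
  fit <- lm(ct_perfusion ~ ref_perfusion, p5)
  expect_equal(rmsd_regression(p5), sqrt(mean(residuals(fit)^2)))
})

test_that("Bland-Altman bias and limits of agreement", {
  pid <- data.frame(ref_perfusion = c(1, 2, 3), ct_perfusion = c(1, 2, 3))
  ba0 <- bland_altman(pid)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa, c(0, 0))
  p <- data.frame(ref_perfusion = c(2, 2, 2), ct_perfusion = c(1, 2, 3))
  ba <- bland_altman(p)   # differences (-1, 0, 1)
  expect_equal(ba$bias, 0); expect_equal(ba$sd, 1)
  expect_equal(ba$loa, c(-1.96, 1.96))
  pshift <- p; pshift$ct_perfusion <- p$ct_perfusion + 0.5
  bas <- bland_altman(pshift)
  expect_equal(bas$bias, ba$bias + 0.5)
  expect_equal(diff(bas$loa), diff(ba$loa))
})

test_that("ROC AUC equals the concordant-pair fraction", {
  r1 <- roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)    # 3 concordant of 4 pairs
  r3 <- roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(r3$auc, 0.5)     # all tied
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both")
})

test_that("one-way ICC reproduces hand-worked ANOVA cases", {
  expect_equal(icc_oneway(c(0, 0, 1, 1), c("a", "a", "b", "b")), 1)
  expect_equal(icc_oneway(c(0, 1, 0, 1), c("a", "a", "b", "b")), -1)
  set.seed(2)
  v <- rnorm(12); g <- rep(1:3, each = 4)
  i1 <- icc_oneway(v, g)
  vshuf <- ave(v, g, FUN = sample)   # shuffle within clusters
  expect_equal(icc_oneway(vshuf, g), i1, tolerance = 1e-12)
  expect_error(icc_oneway(1:3, c("a", "b", "c")), "singleton")
})

test_that("diagnostic report reproduces printed confusion decompositions", {
  # high-specificity pattern: 12/15, 39/40, 12/13, 39/42, 51/55
  r <- diagnostic_report(tp = 12, fn = 3, fp = 1, tn = 39)
  pct <- setNames(r$metrics$percent, r$metrics$metric)
  expect_identical(pct, c(sensitivity = 80, specificity = 98, ppv = 92,
                          npv = 93, accuracy = 93))
  # high-sensitivity pattern: 14/15, 32/40, 14/22, 32/33, 46/55
  r2 <- diagnostic_report(tp = 14, fn = 1, fp = 8, tn = 32)
  pct2 <- setNames(r2$metrics$percent, r2$metrics$metric)
  expect_identical(pct2, c(sensitivity = 93, specificity = 80, ppv = 64,
                           npv = 97, accuracy = 84))
  # perfect prediction
  r3 <- diagnostic_report(tp = 5, fn = 0, fp = 0, tn = 10)
  expect_true(all(r3$metrics$percent == 100))
  expect_equal(r$n, 55)
  expect_equal(with(r, tp + fp + tn + fn), r$n)
  expect_equal(r$metrics$proportion,
               r$metrics$numerator / r$metrics$denominator)
})

test_that("threshold-based diagnostic performance counts and flags classes", {
  p <- data.frame(ref_perfusion = c(0.5, 0.6, 1.5, 2.0, 0.8),
                  ct_perfusion  = c(0.4, 1.2, 1.8, 0.9, 0.7))
  dp <- diagnostic_performance(p, 1.0, 1.0)
  expect_equal(c(dp$tp, dp$fn, dp$fp, dp$tn), c(2, 1, 1, 1))
  expect_true(is.finite(dp$auc))
  pneg <- data.frame(ref_perfusion = c(2, 3, 2.5), ct_perfusion = c(2, 3, 2.5))
  dp2 <- diagnostic_performance(pneg, 1.0, 1.0)
  expect_true(is.na(dp2$auc))
  expect_match(dp2$auc_flag, "single-class")
})

test_that("all statistics match brute-force references on random datasets", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    p <- random_pairs(n)
    x <- p$ref_perfusion; y <- p$ct_perfusion
    expect_equal(pearson_r(p)$r, brute_pearson(x, y), tolerance = 1e-12)
    expect_equal(lin_ccc(p)$ccc, brute_ccc(x, y), tolerance = 1e-12)
    expect_equal(rmse_identity(p), sqrt(sum((y - x)^2) / n), tolerance = 1e-12)
    lab <- x < stats::median(x)
    if (any(lab) && any(!lab))
      expect_equal(roc_auc(-y, lab)$auc, brute_auc(-y, lab), tolerance = 1e-12)
    g <- sample(1:3, n, replace = TRUE)
    if (length(unique(g)) >= 2 && any(table(g) >= 2))
      expect_equal(icc_oneway(y, g), brute_icc(y, g), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:20) {
    y <- runif(30); lab <- runif(30) < 0.4
    if (!any(lab) || all(lab)) next
    ours <- roc_auc(y, lab)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, y, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("RMSE never falls below RMSD", {
  set.seed(31)
  for (i in 1:50) {
    p <- random_pairs(sample(5:20, 1))
    expect_gte(rmse_identity(p) + 1e-12, rmsd_regression(p))
  }
})

test_that("evaluate_pairs assembles the full per-method report", {
  set.seed(17)
  terr <- rep(c("proximal LAD", "distal LAD", "LCx"), times = 10)
  ref <- ifelse(terr == "LCx", runif(30, 0.6, 1.1), runif(30, 0.4, 3.5))
  pairs <- rbind(
    data.frame(subject = rep(1:5, each = 6), territory = terr, method = "MI",
               ct_perfusion = ref * 1.02 + rnorm(30, 0, 0.05),
               ref_perfusion = ref),
    data.frame(subject = rep(1:5, each = 6), territory = terr, method = "MS",
               ct_perfusion = ref * 0.6 + rnorm(30, 0, 0.3),
               ref_perfusion = ref))
  ev <- evaluate_pairs(pairs)
  expect_s3_class(ev, "fpa_evaluation")
  expect_named(ev$methods, c("MI", "MS"))
  expect_equal(ev$methods$MI$agreement$`LAD+LCx`$n, 30)
  expect_equal(ev$methods$MI$agreement$LAD$n, 20)
  expect_gt(ev$methods$MI$agreement$`LAD+LCx`$ccc$ccc,
            ev$methods$MS$agreement$`LAD+LCx`$ccc$ccc)
  expect_s3_class(ev$methods$MI$diagnostics, "diagnostic_report")
  expect_true(is.finite(ev$methods$MI$icc))
  expect_output(print(ev), "paired measurements")
})
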