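# ROI-level associations, LOOCV prediction and structural summaries.

test_that("ROI means skip flagged voxels and match direct summation", {
  m <- array(seq_len(4 * 4 * 3), c(4, 4, 3))
  roi <- array(FALSE, c(4, 4, 3)); roi[1:2, 1, 1] <- TRUE
  expect_equal(as.numeric(roi_mean(m, roi)), mean(c(1, 2)))
  uni <- array(7, c(4, 4, 3))
  expect_equal(as.numeric(roi_mean(uni, array(TRUE, c(4, 4, 3)))), 7)
  set.seed(12)
  rm3 <- array(runif(48) < 0.4, c(4, 4, 3))
  expect_equal(as.numeric(roi_mean(m, rm3)), sum(m[rm3]) / sum(rm3))
  expect_error(roi_mean(m, array(FALSE, c(4, 4, 3))), "empty")
  # undefined voxels carry no weight and are counted
  s <- random_series(c(4, 4, 3), t = 30, seed = 2)
  s$data[1, 1, 1, ] <- 5
  bm <- ben_map(s, array(TRUE, c(4, 4, 3)))
  roi2 <- array(FALSE, c(4, 4, 3)); roi2[1:2, 1, 1] <- TRUE
  got <- roi_mean(bm, roi2)
  expect_equal(attr(got, "n_skipped"), 1)
  expect_equal(as.numeric(got), bm$values[2, 1, 1])
})

test_that("simple regression reports the standardized slope with its exact
          relation to R-squared", {
  x <- seq_len(20)
  fit <- simple_regression(x, 2 * x + 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$beta_std, 1)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(simple_regression(x, -x)$beta_std, -1)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    f <- simple_regression(rnorm(n), rnorm(n))
    expect_equal(abs(f$beta_std), sqrt(f$r_squared), tolerance = 1e-10)
    # p value agrees with the stock linear model
    xx <- rnorm(n); yy <- rnorm(n)
    f2 <- simple_regression(xx, yy)
    p_lm <- summary(lm(yy ~ xx))$coefficients[2, 4]
    expect_equal(f2$p_value, p_lm, tolerance = 1e-10)
  }
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(simple_regression(rnorm(2), rnorm(2)), "at least 3")
})

test_that("Bonferroni correction applies alpha over the declared family", {
  got <- bonferroni_adjust(c(0.01, 0.04), alpha = 0.05)
  expect_equal(got$threshold, 0.025)
  expect_equal(got$significant, c(TRUE, FALSE))
  expect_equal(bonferroni_adjust(0.04)$significant, TRUE)   # k = 1
  set.seed(15)
  p <- runif(7)
  got2 <- bonferroni_adjust(p, alpha = 0.05,
                            family = paste0("roi", 1:7))
  expect_equal(got2$significant, p < 0.05 / 7)
  expect_equal(got2$k, 7)
  expect_equal(got2$family, paste0("roi", 1:7))
  expect_error(bonferroni_adjust(numeric()), "empty")
})

test_that("LOOCV recovers an exact line and each fold is honest", {
  x <- seq_len(10)
  res <- loocv_predict(x, 3 * x)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_equal(res$predicted, 3 * x, tolerance = 1e-8)
  # corrupting one observation changes only that fold's prediction
  set.seed(16)
  x <- rnorm(12); y <- rnorm(12)
  base <- loocv_predict(x, y)
  y2 <- y; y2[5] <- y2[5] + 100
  pert <- loocv_predict(x, y2)
  # fold 5 excludes observation 5, so its prediction is unchanged;
  # every other fold trains on the corrupted value
  expect_equal(pert$predicted[5], base$predicted[5], tolerance = 1e-10)
  expect_true(all(abs(pert$predicted[-5] - base$predicted[-5]) > 1e-8))
})

test_that("LOOCV exhibits the leave-one-out anticorrelation under the null
          and shrinks an R^2 of 0.15", {
  # under a zero slope the held-out prediction is essentially the
  # leave-one-out mean, which is exactly anticorrelated with the held-out
  # value, so the null distribution of r is centred well below 0 and the
  # two-sided t-test on r is anticonservative -- a real property of the
  # correlation-as-accuracy procedure, documented in the vignette
  set.seed(17)
  r <- p <- numeric(200)
  for (s in 1:200) {
    x <- rnorm(34); y <- rnorm(34)
    res <- loocv_predict(x, y)
    r[s] <- res$r; p[s] <- res$p_value
  }
  expect_lt(mean(r), -0.1)
  expect_gt(mean(p < 0.05), 0.2)
  # shrinkage at a planted in-sample R^2 of ~0.15 (n = 34)
  set.seed(18)
  gap <- vapply(1:100, function(s) {
    x <- rnorm(34)
    y <- sqrt(0.15) * x + sqrt(0.85) * rnorm(34)
    simple_regression(x, y)$r_squared - loocv_predict(x, y)$r_squared
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("BPF and lesion volume match their closed forms", {
  expect_equal(brain_parenchymal_fraction(0.4, 0.4, 0.2), 0.8)
  expect_equal(brain_parenchymal_fraction(0.4, 0.4, 0), 1)
  expect_error(brain_parenchymal_fraction(0, 0, 0), "zero")
  # discretized ellipsoid phantom vs analytic shell volumes
  d <- c(40, 40, 32)
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / semi[a])^2)
  rho <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  par_frac <- 0.85
  gm_wm <- array(as.numeric(rho <= par_frac), d)
  csf <- array(as.numeric(rho > par_frac & rho <= 1), d)
  bpf <- brain_parenchymal_fraction(gm_wm, array(0, d), csf, voxel_size_mm = 3)
  expect_equal(bpf, par_frac^3, tolerance = 0.02)

  lm3 <- array(0L, c(20, 20, 10)); lm3[seq_len(1000)] <- 1L
  expect_equal(lesion_volume_ml(lm3, 3), 27)
  expect_equal(lesion_volume_ml(array(0L, c(5, 5, 5)), 3), 0)
  expect_error(lesion_volume_ml(array(0.5, c(2, 2, 2)), 3), "binary")
  set.seed(19)
  r3 <- array(rbinom(600, 1, 0.3), c(10, 10, 6))
  expect_equal(lesion_volume_ml(r3, c(2, 2, 2.5)), sum(r3) * 10 / 1000)
})

test_that("the ROI association scan ties regressions to one Bonferroni
          family", {
  set.seed(20)
  rois <- data.frame(a = rnorm(30), b = rnorm(30))
  meas <- data.frame(edss = rnorm(30), mfis = rnorm(30), pasat = rnorm(30))
  tab <- associate_rois(rois, meas)
  expect_equal(nrow(tab), 6)
  expect_equal(attr(tab, "family_size"), 6)
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / 6)
  expect_equal(tab$significant_bonferroni, tab$p_value < 0.05 / 6)
  expect_equal(abs(tab$beta_std), sqrt(tab$r_squared), tolerance = 1e-10)
})

test_that("the full chain recovers a planted clinical link through measured
          entropy", {
  # scores planted on *measured* ROI entropy means with R^2 0.3, then
  # recovered by the cluster -> ROI-mean -> regression chain
  hits <- 0L
  for (s in 1:10) {
    coh <- tiny_cohort(seed = 1200 + s, n_per_group = 17, grid = c(10, 10, 8),
                       t = 60)
    pat <- which(coh$manifest$group == "patient")
    ben <- vapply(pat, function(i) {
      b <- simulate_bold(coh, i)
      pp <- preprocess_bold(b, coh$motion[[i]], discard_k = 5,
                            mask = coh$mask, alff = FALSE)
      as.numeric(roi_mean(ben_map(pp$ben_input, coh$mask)$values,
                          coh$roi_masks$SMA))
    }, numeric(1))
    sd_b <- sd(ben)
    set.seed(3100 + s)
    score <- 2 + 1 * ben + rnorm(length(ben), 0, sd_b * sqrt(0.7 / 0.3))
    fit <- simple_regression(ben, score)
    hits <- hits + (fit$beta_std > 0)
  }
  expect_gte(hits, 9)
})
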