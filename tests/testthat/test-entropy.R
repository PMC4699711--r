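# Sample entropy and map-level operations.

test_that("all-match series gives SampEn 0 in standard mode and the printed
          asymmetric normalizers reproduce their algebraic value", {
  # constant plus tiny jitter: every template pair matches at both lengths
  n <- 20
  x <- 5 + seq_len(n) * 1e-9
  expect_equal(sample_entropy(x, sampen_params(m = 3, r_frac = 0.6)), 0)
  # the asymmetric normalizers give -ln[(N-m+1)/(N-m-1)] = -ln(18/16) < 0
  # on the same input, which is why they are not the default
  lit <- sample_entropy(x, sampen_params(m = 3, r_frac = 0.6,
                                         normalization = "literal"))
  expect_equal(lit, -log(18 / 16), tolerance = 1e-12)
})

test_that("degenerate series are flagged, not returned as infinities", {
  expect_true(is.na(sample_entropy(rep(3, 30))))        # constant: sd = 0
  expect_error(sample_entropy(rnorm(4), sampen_params(m = 3)), "too short")
  set.seed(1)
  # far-apart spikes: no m-length template matches at tiny r
  x <- rnorm(12)
  v <- sample_entropy(x, sampen_params(m = 3, r_frac = 1e-6))
  expect_true(is.na(v) || is.finite(v))
})

test_that("white noise has higher SampEn than strongly autocorrelated AR(1)
          at the mapping parameters", {
  p <- sampen_params(m = 3, r_frac = 0.6)
  d <- vapply(1:50, function(s) {
    sample_entropy(synth_voxel_signal(1, 0.9, 230, seed = 9000 + s), p) -
      sample_entropy(synth_voxel_signal(0, 0.9, 230, seed = 9000 + s), p)
  }, numeric(1))
  expect_gt(mean(d), 0)
  expect_gt(mean(d > 0), 0.95)
})

test_that("ben_map applies SampEn per voxel, zeroes the background and flags
          undefined voxels", {
  s <- random_series(c(5, 4, 4), t = 30, seed = 2)
  mask <- array(FALSE, c(5, 4, 4)); mask[2:4, 2:3, 2:3] <- TRUE
  # one constant voxel inside the mask
  s$data[2, 2, 2, ] <- 7
  bm <- ben_map(s, mask)
  expect_true(bm$undefined[2, 2, 2])
  expect_equal(sum(bm$undefined), 1)
  expect_true(all(bm$values[!mask] == 0))
  # per-voxel independence: values equal the scalar operation
  expect_equal(bm$values[3, 2, 2],
               sample_entropy(s$data[3, 2, 2, ]))
  expect_equal(bm$values[4, 3, 3],
               sample_entropy(s$data[4, 3, 3, ]))
  expect_error(ben_map(s, array(TRUE, c(4, 4, 4))), "mask")
})

test_that("a series of identical volumes yields an all-undefined map", {
  arr <- array(rep(as.numeric(1:60), times = 60), c(5, 4, 3, 60))
  s <- bold_series(arr, 3, 2)
  mask <- array(TRUE, c(5, 4, 3))
  bm <- ben_map(s, mask)
  expect_true(all(bm$undefined[mask]))
})

test_that("map standardization obeys its contracts", {
  s <- random_series(c(6, 6, 5), t = 40, seed = 3)
  mask <- synth_brain_geometry(c(6, 6, 5))$mask
  bm <- ben_map(s, mask)
  z <- smooth_and_standardize_ben(bm, fwhm_mm = 6)
  expect_lt(abs(mean(z$values[z$mask])), 1e-8)
  expect_lt(abs(sd(z$values[z$mask]) - 1), 1e-8)
  expect_true(z$standardized)
  expect_error(smooth_and_standardize_ben(z), "already")
  # fwhm = 0, zscore: affine transform of the input (correlation 1);
  # undefined voxels are dropped from the standardized mask
  z0 <- smooth_and_standardize_ben(bm, fwhm_mm = 0)
  expect_equal(cor(z0$values[z0$mask], bm$values[z0$mask]), 1)
  # artanh is refused when any in-mask value is >= 1 (typical for SampEn)
  bm2 <- bm
  bm2$values[which(mask)[1]] <- 1.2
  expect_error(smooth_and_standardize_ben(bm2, fwhm_mm = 0, mode = "artanh"),
               "artanh")
  # artanh accepted when all values are inside (-1, 1)
  bm3 <- bm
  bm3$values[mask] <- tanh(bm3$values[mask] - mean(bm3$values[mask]))
  z3 <- smooth_and_standardize_ben(bm3, fwhm_mm = 0, mode = "artanh")
  expect_equal(z3$values[z3$mask], atanh(bm3$values[z3$mask]))
})

test_that("ALFF equals the closed-form spectral sum", {
  dims <- c(4, 3, 3); t <- 230; tr <- 2
  mask <- array(TRUE, dims)
  # zero series -> ALFF 0 (mask voxel set to zero)
  arr <- array(0, c(dims, t))
  tt <- seq_len(t) - 1
  # bin k = 23: f = 23 / (230 * 2) = 0.05 Hz, inside the band
  arr[1, 1, 1, ] <- sin(2 * pi * 23 * tt / t)
  arr[2, 1, 1, ] <- rnorm(t)
  s <- bold_series(arr + 0, 3, tr)
  am <- alff_map(s, mask, band = c(0.01, 0.08))
  expect_equal(am$values[3, 3, 3], 0)
  expect_equal(am$values[1, 1, 1], t / 2, tolerance = 1e-9)
  # Parseval bound: in-band power cannot exceed total power
  x <- arr[2, 1, 1, ]
  expect_lte(am$values[2, 1, 1]^2, sum(Mod(fft(x))^2) / 2)
  expect_error(alff_map(s, mask, band = c(0.0301, 0.0302)), "no DFT bins")
})

test_that("the planted group contrast keeps its sign across match tolerances", {
  # r sweep at the cohort's design scale: the patient-minus-control ROI
  # difference planted via the mixing weights must not flip sign with the
  # tolerance choice; preprocessing is shared across tolerances, only the
  # entropy mapping is repeated. Smaller grids dilute the 6 mm-smoothed ROI
  # contrast into subject-sampling noise, so the full grid is used here.
  coh <- generate_cohort(cohort_config(seed = 21))
  rfs <- c(0.3, 0.45, 0.6, 0.75)
  pat <- coh$manifest$group == "patient"
  n <- nrow(coh$manifest)
  sma <- ph <- matrix(0, n, length(rfs))
  for (i in seq_len(n)) {
    b <- simulate_bold(coh, i)
    pp <- preprocess_bold(b, coh$motion[[i]], coh$tissue$wm,
                          coh$tissue$csf, mask = coh$mask, alff = FALSE)
    for (k in seq_along(rfs)) {
      bm <- ben_map(pp$ben_input, coh$mask, sampen_params(3, rfs[k]))
      sma[i, k] <- as.numeric(roi_mean(bm$values, coh$roi_masks$SMA))
      ph[i, k] <- as.numeric(roi_mean(bm$values, coh$roi_masks$pHIPP))
    }
  }
  for (k in seq_along(rfs)) {
    expect_gt(mean(sma[pat, k]) - mean(sma[!pat, k]), 0)
    expect_lt(mean(ph[pat, k]) - mean(ph[!pat, k]), 0)
  }
})

test_that("a compartment with higher mixing weight shows higher mean entropy", {
  # GM/WM contrast analogue: assign the GM shell a higher w than the WM core
  grid <- c(12, 12, 10)
  geom <- synth_brain_geometry(grid)
  gm_vox <- which(geom$gm == 1, arr.ind = TRUE)
  cfg <- cohort_config(n_patients = 2, n_controls = 0, grid_shape = grid,
                       n_timepoints = 240, baseline_w = 0.2,
                       roi_specs = list(roi_spec("GMshell", gm_vox, 0.9, 0.9)),
                       clinical_link = link_params(
                         edss = list(intercept = 2, slopes = numeric(),
                                     noise_sd = 0.5),
                         mfis5 = list(intercept = 11, slopes = numeric(),
                                      noise_sd = 1)),
                       seed = 31)
  coh <- generate_cohort(cfg)
  b <- simulate_bold(coh, 1)
  pp <- preprocess_bold(b, coh$motion[[1]], discard_k = 10, mask = coh$mask,
                        alff = FALSE)
  bm <- ben_map(pp$ben_input, coh$mask)
  gm_mean <- roi_mean(bm, geom$gm == 1)
  wm_mean <- roi_mean(bm, geom$wm == 1)
  expect_gt(gm_mean, wm_mean)
})
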