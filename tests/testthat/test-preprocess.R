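# Temporal/spatial preprocessing operators.

test_that("volume discard drops exactly the first k volumes", {
  s <- random_series(c(4, 4, 3), t = 240, seed = 1)
  out <- discard_initial_volumes(s, 10)
  expect_equal(dim(out)[4], 230)
  expect_equal(out$data[, , , 1], s$data[, , , 11])
  expect_match(tail(out$provenance, 1), "discard:10")
  # k = 0 is the identity but still recorded
  id <- discard_initial_volumes(s, 0)
  expect_equal(id$data, s$data)
  expect_match(tail(id$provenance, 1), "discard:0")
  short <- random_series(c(2, 2, 2), t = 5)
  expect_error(discard_initial_volumes(short, 10), "discard")
})

test_that("linear detrending removes ramps exactly and matches the OLS oracle", {
  dims <- c(3, 3, 2); t <- 25
  tt <- seq_len(t)
  arr <- array(0, c(dims, t))
  arr[1, 1, 1, ] <- 3 + 0.5 * tt       # exact ramp
  arr[2, 1, 1, ] <- 42                 # constant
  set.seed(4)
  arr[3, 2, 2, ] <- rnorm(t)
  s <- detrend_linear(bold_series(arr, 3, 2))
  expect_equal(max(abs(s$data[1, 1, 1, ])), 0, tolerance = 1e-10)
  expect_equal(max(abs(s$data[2, 1, 1, ])), 0, tolerance = 1e-10)
  # closed-form two-parameter OLS residual per voxel
  y <- arr[3, 2, 2, ]
  fit <- lm(y ~ tt)
  expect_equal(s$data[3, 2, 2, ], unname(resid(fit)), tolerance = 1e-10)
  # residuals orthogonal to intercept and ramp
  r <- s$data[3, 2, 2, ]
  expect_lt(abs(sum(r)), 1e-6 * sqrt(t) * sqrt(sum(r^2)) + 1e-12)
  expect_lt(abs(sum(r * tt)), 1e-6 * sqrt(sum(tt^2)) * sqrt(sum(r^2)) + 1e-12)
})

test_that("the ideal band-pass keeps in-band sines, rejects out-of-band sines
          and satisfies Parseval", {
  dims <- c(2, 2, 1); t <- 230; tr <- 2
  tt <- seq_len(t) - 1
  arr <- array(0, c(dims, t))
  arr[1, 1, 1, ] <- sin(2 * pi * 0.05 * tt * tr)   # in band
  arr[2, 1, 1, ] <- sin(2 * pi * 0.15 * tt * tr)   # out of band
  set.seed(5)
  arr[1, 2, 1, ] <- rnorm(t)
  s <- bandpass_filter(bold_series(arr, 3, tr), 0.01, 0.08)
  x_in <- arr[1, 1, 1, ]
  expect_lt(sqrt(sum((s$data[1, 1, 1, ] - (x_in - mean(x_in)))^2)) /
              sqrt(sum((x_in - mean(x_in))^2)), 0.05)
  expect_lt(sqrt(sum(s$data[2, 1, 1, ]^2)) /
              sqrt(sum(arr[2, 1, 1, ]^2)), 0.05)
  # Parseval: output power equals the retained in-band input power
  y <- s$data[1, 2, 1, ]
  f <- seq.int(0, t - 1) / (t * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f >= 0.01 - 1e-12 & f <= 0.08 + 1e-12
  power_in_band <- sum(Mod(fft(arr[1, 2, 1, ])[keep])^2) / t
  expect_equal(sum(y^2), power_in_band, tolerance = 1e-8)
  expect_error(bandpass_filter(bold_series(arr, 3, tr), 0.01, 0.3), "Nyquist")
})

test_that("nuisance regression residualizes exactly and matches the
          normal-equations oracle", {
  dims <- c(3, 2, 2); t <- 40
  set.seed(6)
  motion <- matrix(rnorm(t * 6), t, 6)
  wm <- rnorm(t); csf <- rnorm(t)
  nuis <- nuisance_set(motion, wm, csf)
  X <- cbind(1, motion, wm, csf)
  arr <- array(rnorm(prod(dims) * t), c(dims, t))
  # one voxel that is an exact linear combination of the regressors
  arr[1, 1, 1, ] <- X %*% c(2, rnorm(6), -1, 0.5)
  s <- regress_nuisance(bold_series(arr, 3, 2), nuis)
  expect_lt(max(abs(s$data[1, 1, 1, ])), 1e-8)
  # pseudoinverse oracle on a random voxel
  y <- arr[3, 2, 2, ]
  r_oracle <- y - X %*% (solve(crossprod(X)) %*% crossprod(X, y))
  expect_equal(s$data[3, 2, 2, ], as.numeric(r_oracle), tolerance = 1e-8)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(X, s$data[3, 2, 2, ]))), 1e-6)
  # collinear design is refused with the offending columns named
  bad <- nuisance_set(cbind(motion[, 1:5], motion[, 5]), wm, csf)
  expect_error(regress_nuisance(bold_series(arr, 3, 2), bad),
               "rank deficient")
})

test_that("Gaussian smoothing preserves mass, normalizes the kernel and
          honours the FWHM-to-sigma conversion", {
  expect_equal(fwhm_to_sigma_vox(6, 3), 6 / (2 * sqrt(2 * log(2))) / 3,
               tolerance = 1e-12)
  expect_equal(fwhm_to_sigma_vox(6, 3), 0.8493218, tolerance = 1e-6)
  vol <- array(rnorm(16 * 14 * 12), c(16, 14, 12))
  expect_identical(smooth_gaussian(vol, 0, 3), vol)
  sm <- smooth_gaussian(vol, 6, 3)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-6)
  delta <- array(0, c(16, 14, 12)); delta[8, 7, 6] <- 1
  k <- smooth_gaussian(delta, 6, 3)
  expect_equal(sum(k), 1, tolerance = 1e-6)
  expect_lt(max(k), 1)
  expect_error(smooth_gaussian(vol, -1, 3), "non-negative")
})

test_that("motion QC excludes on either mean translation or mean rotation", {
  t <- 50
  zeros <- matrix(0, t, 6)
  expect_true(qc_motion_exclude(zeros)$keep)
  m <- zeros; m[, 3] <- 2.5                      # mean |z translation| 2.5 mm
  q <- qc_motion_exclude(m)
  expect_false(q$keep)
  expect_equal(q$reasons, "z-translation")
  m <- zeros; m[, 6] <- 2.4                      # mean |z rotation| 2.4 deg
  q <- qc_motion_exclude(m)
  expect_false(q$keep)
  expect_equal(q$reasons, "z-rotation")
  expect_error(qc_motion_exclude(zeros[, 1:5]), "6 columns")
})

test_that("the combined preprocessing stream equals the sequence of public
          operators", {
  coh <- tiny_cohort(seed = 8, n_per_group = 1, grid = c(10, 10, 8), t = 50)
  b <- simulate_bold(coh, 1)
  motion <- coh$motion[[1]]
  pp <- preprocess_bold(b, motion, coh$tissue$wm, coh$tissue$csf,
                        discard_k = 5, mask = coh$mask)
  # manual chain with the public operators
  s <- discard_initial_volumes(b, 5)
  mo <- motion[-(1:5), ]
  s <- smooth_gaussian(s, 6)
  s <- detrend_linear(s)
  bp <- bandpass_filter(s, 0.01, 0.08)
  wm <- benmap:::tissue_signal(bp, coh$tissue$wm)
  csf <- benmap:::tissue_signal(bp, coh$tissue$csf)
  ben_manual <- regress_nuisance(bp, nuisance_set(mo, wm, csf))
  inm <- as.vector(coh$mask)
  M1 <- matrix(pp$ben_input$data, ncol = dim(pp$ben_input$data)[4])
  M2 <- matrix(ben_manual$data, ncol = dim(ben_manual$data)[4])
  expect_equal(M1[inm, ], M2[inm, ], tolerance = 1e-10)
  # masked fast path zeroes the background
  expect_true(all(M1[!inm, ] == 0))
  # un-band-passed branch: same chain without the band-pass
  wm2 <- benmap:::tissue_signal(s, coh$tissue$wm)
  csf2 <- benmap:::tissue_signal(s, coh$tissue$csf)
  alff_manual <- regress_nuisance(s, nuisance_set(mo, wm2, csf2))
  Ma <- matrix(pp$alff_input$data, ncol = dim(pp$alff_input$data)[4])
  Mb <- matrix(alff_manual$data, ncol = dim(alff_manual$data)[4])
  expect_equal(Ma[inm, ], Mb[inm, ], tolerance = 1e-10)
})

test_that("motion files in the SPM dialect are converted to degrees", {
  f <- tempfile(fileext = ".txt")
  m <- cbind(matrix(0.5, 4, 3), matrix(pi / 180, 4, 3))  # 1 degree in radians
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  got <- read_motion_params(f)
  expect_equal(got[, 4:6], matrix(1, 4, 3), tolerance = 1e-10)
  got_deg <- read_motion_params(f, rotations = "degrees")
  expect_equal(got_deg[, 4:6], matrix(pi / 180, 4, 3), tolerance = 1e-10)
})
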