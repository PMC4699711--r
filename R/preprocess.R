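# Temporal and spatial preprocessing of 4D BOLD data.
#
# Conventions: the pipeline order follows the common resting-state stream --
# discard initial volumes, spatial smoothing, linear detrend, temporal
# band-pass, nuisance regression -- and each step appends to the series
# provenance so the order can be audited downstream.

#' Discard initial volumes
#'
#' Drops the first `k` volumes of a BOLD series so the signal analysed starts
#' after longitudinal magnetisation has reached steady state.
#'
#' @param series A [bold_series].
#' @param k Number of leading volumes to drop (default 10); must be smaller
#'   than the number of timepoints.
#' @return The shortened [bold_series].
#' @export
discard_initial_volumes <- function(series, k = 10L) {
  stopifnot(inherits(series, "bold_series"))
  t <- n_timepoints(series)
  k <- as.integer(k)
  if (k < 0) stopf("k must be non-negative")
  if (k >= t) stopf("cannot discard %d of %d volumes", k, t)
  if (k > 0) series$data <- series$data[, , , -seq_len(k), drop = FALSE]
  add_provenance(series, sprintf("discard:%d", k))
}

# reshape helpers between 4D array and time-by-voxel matrix
as_tv_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, prod(d[1:3]), d[4]))
}

from_tv_matrix <- function(series, m, step) {
  d <- dim(series$data)
  series$data <- array(t(m), d)
  add_provenance(series, step)
}

#' Voxel-wise linear detrending
#'
#' Removes, per voxel, the ordinary least-squares fit of the signal on an
#' intercept and a linear time ramp, leaving residuals orthogonal to both.
#'
#' @param series A [bold_series] with at least 3 timepoints.
#' @return The detrended [bold_series].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  t <- n_timepoints(series)
  if (t < 3) stopf("need at least 3 timepoints to detrend")
  if (!all(is.finite(series$data))) stopf("non-finite values in series")
  X <- cbind(1, seq_len(t))
  M <- as_tv_matrix(series)
  resid <- M - X %*% qr.coef(qr(X), M)
  from_tv_matrix(series, resid, "detrend")
}

#' Temporal band-pass filter
#'
#' Ideal (brick-wall) frequency-domain filter: per voxel, discrete Fourier
#' transform, zeroing of all bins whose frequency lies strictly below `f_lo`
#' or strictly above `f_hi` (the DC bin is removed whenever `f_lo > 0`), and
#' inverse transform. This reproduces the REST/DPARSF convention; see
#' [butterworth_bandpass()] for an IIR alternative.
#'
#' @param series A [bold_series].
#' @param f_lo,f_hi Pass-band edges in Hz; `0 <= f_lo < f_hi <= ` Nyquist.
#' @return The filtered [bold_series].
#' @export
bandpass_filter <- function(series, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(series, "bold_series"))
  t <- n_timepoints(series)
  nyq <- 1 / (2 * series$tr_s)
  if (f_lo < 0 || f_lo >= f_hi) stopf("need 0 <= f_lo < f_hi")
  if (f_hi > nyq + 1e-12) stopf("f_hi (%g Hz) above Nyquist (%g Hz)", f_hi, nyq)
  freq <- seq.int(0, t - 1) / (t * series$tr_s)
  freq <- pmin(freq, 1 / series$tr_s - freq)  # fold to physical frequency
  keep <- freq >= f_lo - 1e-12 & freq <= f_hi + 1e-12
  M <- as_tv_matrix(series)
  F <- mvfft(M)
  F[!keep, ] <- 0
  out <- Re(mvfft(F, inverse = TRUE)) / t
  from_tv_matrix(series, out, sprintf("bandpass:%g-%g", f_lo, f_hi))
}

#' Butterworth band-pass filter (IIR alternative)
#'
#' Forward-backward (zero-phase) Butterworth band-pass of the stated order,
#' offered as an alternative to the ideal filter in [bandpass_filter()].
#'
#' @inheritParams bandpass_filter
#' @param order Filter order (default 2).
#' @return The filtered [bold_series].
#' @export
butterworth_bandpass <- function(series, f_lo = 0.01, f_hi = 0.08, order = 2L) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr_s)
  if (f_lo <= 0 || f_lo >= f_hi) stopf("need 0 < f_lo < f_hi")
  if (f_hi > nyq + 1e-12) stopf("f_hi above Nyquist")
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  M <- as_tv_matrix(series)
  out <- apply(M, 2, function(x) signal::filtfilt(bf, x))
  from_tv_matrix(series, out, sprintf("butterworth:%g-%g", f_lo, f_hi))
}

#' Nuisance regressor set
#'
#' Bundles the six head-motion parameters with mean white-matter and CSF
#' signals; every regressor must have the series' temporal length.
#'
#' @param motion t x 6 matrix of motion parameters.
#' @param wm_signal,csf_signal Numeric vectors of length t.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(motion, wm_signal, csf_signal) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion must have 6 columns")
  t <- nrow(motion)
  if (length(wm_signal) != t || length(csf_signal) != t)
    stopf("wm/csf signal lengths must match motion rows (%d)", t)
  structure(list(motion = motion, wm_signal = as.numeric(wm_signal),
                 csf_signal = as.numeric(csf_signal)),
            class = "nuisance_set")
}

nuisance_design <- function(nuis, t) {
  if (nrow(nuis$motion) != t)
    stopf("nuisance length (%d) does not match series (%d)",
          nrow(nuis$motion), t)
  X <- cbind(intercept = 1, nuis$motion, wm = nuis$wm_signal,
             csf = nuis$csf_signal)
  colnames(X) <- c("intercept", paste0("motion", 1:6), "wm", "csf")
  X
}

#' Nuisance regression
#'
#' Per voxel, replaces the signal by the OLS residual after regressing on an
#' intercept plus all nuisance columns (6 motion, WM, CSF); residuals are
#' orthogonal to every regressor.
#'
#' @param series A [bold_series].
#' @param nuisance A [nuisance_set] with regressor length matching the series.
#' @return The residualised [bold_series].
#' @export
regress_nuisance <- function(series, nuisance) {
  stopifnot(inherits(series, "bold_series"), inherits(nuisance, "nuisance_set"))
  t <- n_timepoints(series)
  X <- nuisance_design(nuisance, t)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])]
    stopf("nuisance design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  M <- as_tv_matrix(series)
  resid <- M - X %*% qr.coef(q, M)
  from_tv_matrix(series, resid, "nuisance")
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution (applied per volume for 4D input) with
#' per-axis sigma equal to `fwhm_mm / (2 sqrt(2 ln 2)) / voxel size`. The
#' kernel is unit-sum and applied with circular (wrap-around) boundaries, so
#' the total image sum is preserved exactly; with the zero background used
#' throughout the package the wrap-around has no practical effect.
#'
#' @param x A [bold_series], or a 3D/4D numeric array.
#' @param fwhm_mm Kernel FWHM in mm (0 = identity).
#' @param voxel_size_mm Voxel size, required when `x` is a bare array.
#' @return Same type and shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stopf("fwhm_mm must be non-negative")
  if (inherits(x, "bold_series")) {
    if (fwhm_mm == 0) return(add_provenance(x, "smooth:0"))
    sig <- fwhm_to_sigma_vox(fwhm_mm, x$voxel_size_mm)
    x$data <- smooth3d(x$data, sig)
    return(add_provenance(x, sprintf("smooth:%g", fwhm_mm)))
  }
  if (fwhm_mm == 0) return(x)
  if (is.null(voxel_size_mm)) stopf("voxel_size_mm required for array input")
  sig <- fwhm_to_sigma_vox(fwhm_mm, rep(voxel_size_mm, length.out = 3))
  smooth3d(x, sig)
}

#' Motion quality-control rule
#'
#' @param max_translation_mm,max_rotation_deg Exclusion thresholds applied to
#'   the per-axis mean absolute motion parameters (defaults 2 mm / 2 deg).
#' @return An object of class `qc_rule`.
#' @export
qc_rule <- function(max_translation_mm = 2, max_rotation_deg = 2) {
  if (max_translation_mm <= 0 || max_rotation_deg <= 0)
    stopf("QC thresholds must be positive")
  structure(list(max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg), class = "qc_rule")
}

#' Motion-based subject exclusion
#'
#' A subject is excluded when the mean over time of the absolute value of any
#' translation axis exceeds `max_translation_mm`, or of any rotation axis
#' exceeds `max_rotation_deg`.
#'
#' @param motion_params t x 6 matrix: translations (mm) in columns 1-3,
#'   rotations (degrees) in columns 4-6.
#' @param rule A [qc_rule].
#' @return List with `keep` (logical) and `reasons` (character vector naming
#'   offending axes, empty when kept).
#' @export
qc_motion_exclude <- function(motion_params, rule = qc_rule()) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L)
    stopf("motion table must have 6 columns, got %d", ncol(motion_params))
  means <- colMeans(abs(motion_params))
  axes <- c("x", "y", "z")
  reasons <- c(
    paste0(axes, "-translation")[means[1:3] > rule$max_translation_mm],
    paste0(axes, "-rotation")[means[4:6] > rule$max_rotation_deg])
  list(keep = length(reasons) == 0L, reasons = reasons,
       mean_abs = means)
}

#' Read SPM-style motion parameter file
#'
#' Six whitespace-delimited columns, one row per timepoint. In the SPM
#' `rp_*.txt` dialect columns 4-6 are rotations in radians and are converted
#' to degrees; set `rotations = "degrees"` for degree-native files.
#'
#' @param path Motion parameter text file.
#' @param rotations Unit of the rotation columns in the file.
#' @return t x 6 numeric matrix (translations mm, rotations degrees).
#' @export
read_motion_params <- function(path, rotations = c("radians", "degrees")) {
  rotations <- match.arg(rotations)
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stopf("motion file %s must have 6 columns", path)
  if (rotations == "radians") m[, 4:6] <- m[, 4:6] * 180 / pi
  unname(m)
}

# mean signal within an eroded high-probability tissue mask; thin
# compartments that erosion would empty fall back to the uneroded mask
tissue_signal <- function(series, prob_map, threshold = 0.9) {
  hard <- prob_map > threshold
  mask <- erode_mask(hard)
  if (!any(mask)) mask <- hard
  if (!any(mask)) stopf("tissue mask empty")
  M <- as_tv_matrix(series)
  rowMeans(M[, as.vector(mask), drop = FALSE])
}

# one-voxel 6-neighbour binary erosion
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    # out-of-range neighbours count as background
    pad <- seq_len(n) + by < 1L | seq_len(n) + by > n
    idx[[ax]] <- src
    res <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
    idx2 <- rep(list(quote(expr = )), 3)
    idx2[[ax]] <- which(pad)
    if (any(pad)) res <- do.call(`[<-`, c(list(res), idx2, list(value = FALSE)))
    res
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, ax, by)
  out
}

#' Standard preprocessing stream
#'
#' Runs discard, spatial smoothing, linear detrend, band-pass and nuisance
#' regression in the conventional order (smoothing before temporal
#' filtering; set `smooth_first = FALSE` to smooth after filtering). WM and
#' CSF nuisance signals are the mean signal within the one-voxel-eroded
#' high-probability (> 0.9) tissue masks of each branch's own series.
#'
#' Returns both the fully processed series used for entropy mapping and an
#' un-band-passed branch (detrended + nuisance-corrected only) that is the
#' conventional input for ALFF, whose band selection happens in the spectral
#' sum itself.
#'
#' @param series Raw [bold_series].
#' @param motion t0 x 6 motion matrix (translations mm, rotations degrees)
#'   covering the undiscarded series; the first `discard_k` rows are dropped
#'   with the volumes.
#' @param wm_prob,csf_prob 3D tissue probability maps; when `NULL` the WM/CSF
#'   regressors are omitted and only motion is removed.
#' @param discard_k,fwhm_mm,band Preprocessing parameters (defaults 10,
#'   6 mm, 0.01-0.08 Hz).
#' @param smooth_first Apply spatial smoothing before the temporal steps
#'   (default) or after them.
#' @param mask Optional 3D brain mask: temporal steps then run only on
#'   in-mask voxels (the steps are voxel-independent, so in-mask results are
#'   unchanged) and the background is set to exactly 0.
#' @param alff Also produce the un-band-passed ALFF branch (default `TRUE`).
#' @return List with elements `ben_input` and (when `alff`) `alff_input`,
#'   both [bold_series].
#' @export
preprocess_bold <- function(series, motion, wm_prob = NULL, csf_prob = NULL,
                            discard_k = 10L, fwhm_mm = 6,
                            band = c(0.01, 0.08), smooth_first = TRUE,
                            mask = NULL, alff = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_timepoints(series))
    stopf("motion rows (%d) must match raw series length (%d)",
          nrow(motion), n_timepoints(series))
  s <- discard_initial_volumes(series, discard_k)
  if (discard_k > 0) motion <- motion[-seq_len(discard_k), , drop = FALSE]
  if (smooth_first) s <- smooth_gaussian(s, fwhm_mm)
  d <- dim(s$data)
  t <- d[4]

  # all temporal steps are voxel-independent, so they run on a single
  # time-by-voxel matrix; with a mask only in-mask columns are processed and
  # the background is set to exactly 0
  if (!is.null(mask)) {
    mask <- check_mask(mask, d[1:3])
    cols <- which(as.vector(mask))
  } else cols <- seq_len(prod(d[1:3]))
  M <- t(matrix(s$data, prod(d[1:3]), t)[cols, , drop = FALSE])

  # linear detrend
  Xd <- cbind(1, seq_len(t))
  M <- M - Xd %*% qr.coef(qr(Xd), M)

  col_signal <- function(Mat, prob_map) {
    hard <- prob_map > 0.9
    em <- erode_mask(hard)
    if (!any(em)) em <- hard
    sel <- match(which(as.vector(em)), cols)
    sel <- sel[!is.na(sel)]
    if (!length(sel)) stopf("tissue mask empty within processed voxels")
    rowMeans(Mat[, sel, drop = FALSE])
  }
  resid_on <- function(Mat) {
    X <- cbind(intercept = 1, motion)
    if (!is.null(wm_prob)) X <- cbind(X, wm = col_signal(Mat, wm_prob))
    if (!is.null(csf_prob)) X <- cbind(X, csf = col_signal(Mat, csf_prob))
    q <- qr(X)
    if (q$rank < ncol(X)) stopf("nuisance design is rank deficient")
    Mat - X %*% qr.coef(q, Mat)
  }
  rebuild <- function(Mat, steps) {
    flat <- matrix(0, prod(d[1:3]), t)
    flat[cols, ] <- t(Mat)
    out <- s
    out$data <- array(flat, d)
    out$provenance <- c(out$provenance, "detrend", steps)
    if (!smooth_first) out <- smooth_gaussian(out, fwhm_mm)
    out
  }

  out <- list()
  if (alff) out$alff_input <- rebuild(resid_on(M), "nuisance")
  # ideal band-pass on the detrended matrix
  freq <- seq.int(0, t - 1) / (t * s$tr_s)
  freq <- pmin(freq, 1 / s$tr_s - freq)
  keep <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  F <- mvfft(M)
  F[!keep, ] <- 0
  Mbp <- Re(mvfft(F, inverse = TRUE)) / t
  out$ben_input <- rebuild(resid_on(Mbp),
                           c(sprintf("bandpass:%g-%g", band[1], band[2]),
                             "nuisance"))
  out[c("ben_input", if (alff) "alff_input")]
}
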