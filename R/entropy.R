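# Voxel-wise sample entropy (brain entropy, BEN) and its map-level
# post-processing.
#
# SampEn(m, r, N, x) = -ln(A / B), where B counts ordered template pairs
# (i, j), i != j, whose m-point templates are within Chebyshev distance r,
# and A the same for (m+1)-point templates; template starts are restricted
# to 1..N-m so that every m-template has an extension, and r is a fraction
# of the series' sample standard deviation. Lower values mean more regular
# (more temporally coherent) dynamics.

#' Sample entropy parameters
#'
#' @param m Template (window) length, default 3.
#' @param r_frac Match tolerance as a fraction of the series' sample standard
#'   deviation, default 0.6.
#' @param normalization `"standard"` uses the matched-pair count ratio
#'   directly (the Richman-Moorman convention). `"literal"` applies the
#'   asymmetric normalizers `(N-m)(N-m+1)` to the m-point count and
#'   `(N-m)(N-m-1)` to the (m+1)-point count before the log; this form is
#'   internally inconsistent (it yields negative entropy even when every
#'   template pair matches at both lengths) and is provided only for
#'   comparability with toolboxes that print it.
#' @param distance Distance metric between templates; only Chebyshev
#'   (maximum absolute coordinate difference) is supported.
#' @return An object of class `sampen_params`.
#' @export
sampen_params <- function(m = 3L, r_frac = 0.6,
                          normalization = c("standard", "literal"),
                          distance = "chebyshev") {
  m <- as.integer(m)
  if (m < 1) stopf("m must be >= 1")
  if (r_frac <= 0) stopf("r_frac must be positive")
  normalization <- match.arg(normalization)
  distance <- match.arg(distance, "chebyshev")
  structure(list(m = m, r_frac = r_frac, normalization = normalization,
                 distance = distance), class = "sampen_params")
}

sampen_from_counts <- function(B, A, n, m, normalization) {
  if (is.na(B) || is.na(A) || B == 0 || A == 0) return(NA_real_)
  if (normalization == "literal") {
    Bm <- B / ((n - m) * (n - m + 1))
    Am <- A / ((n - m) * (n - m - 1))
    return(-log(Am / Bm))
  }
  -log(A / B)
}

#' Sample entropy of a single time series
#'
#' @param x Numeric time series of length N >= m + 2.
#' @param params A [sampen_params].
#' @return SampEn value; `NA` (flagged undefined) when the series is
#'   constant or when no template pair matches at either length, never an
#'   unflagged infinity.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(100))
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  x <- as.numeric(x)
  n <- length(x)
  if (n < params$m + 2) stopf("series too short: need N >= m + 2")
  if (any(!is.finite(x))) stopf("non-finite values in series")
  s <- sd(x)
  if (s == 0) return(NA_real_)
  cnt <- .sampen_counts(x, params$m, params$r_frac * s)
  sampen_from_counts(cnt[["B"]], cnt[["A"]], n, params$m, params$normalization)
}

#' 3D brain-entropy map container
#'
#' @param values 3D array of entropy values (0 outside the mask).
#' @param mask 3D logical brain mask.
#' @param params The [sampen_params] used.
#' @param standardized Whether map-level standardization has been applied.
#' @param undefined 3D logical array flagging in-mask voxels where SampEn was
#'   undefined.
#' @param affine Voxel-to-world transform.
#' @param voxel_size_mm Voxel size in mm.
#' @return An object of class `ben_map`.
#' @export
ben_map_object <- function(values, mask, params, standardized = FALSE,
                           undefined = NULL, affine = NULL,
                           voxel_size_mm = 3) {
  if (is.null(undefined)) undefined <- array(FALSE, dim(values))
  structure(list(values = values, mask = mask, params = params,
                 standardized = standardized, undefined = undefined,
                 affine = affine %||% default_affine(dim(values), voxel_size_mm),
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3)),
            class = "ben_map")
}

#' @export
print.ben_map <- function(x, ...) {
  cat(sprintf("<ben_map> %s, %d mask voxels (%d undefined), m=%d r=%.2g, %s\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              sum(x$undefined), x$params$m, x$params$r_frac,
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' Voxel-wise brain entropy (BEN) map
#'
#' Applies [sample_entropy()] independently to every in-mask voxel of a
#' preprocessed BOLD series. Out-of-mask voxels are 0; in-mask voxels with
#' undefined entropy (constant series or no template matches) are flagged in
#' the returned object rather than silently zeroed.
#'
#' @param series Preprocessed [bold_series].
#' @param mask 3D brain mask aligned with the series.
#' @param params A [sampen_params].
#' @return A `ben_map` (see [ben_map_object()]).
#' @export
ben_map <- function(series, mask, params = sampen_params()) {
  stopifnot(inherits(series, "bold_series"), inherits(params, "sampen_params"))
  d <- dim(series$data)
  mask <- check_mask(mask, d[1:3])
  M <- as_tv_matrix(series)[, as.vector(mask), drop = FALSE]
  cnt <- .sampen_counts_matrix(M, params$m, params$r_frac)
  n <- d[4]
  vals <- mapply(sampen_from_counts, cnt[1, ], cnt[2, ],
                 MoreArgs = list(n = n, m = params$m,
                                 normalization = params$normalization))
  out <- array(0, d[1:3])
  undef <- array(FALSE, d[1:3])
  out[mask] <- ifelse(is.na(vals), 0, vals)
  undef[mask] <- is.na(vals)
  ben_map_object(out, mask, params, standardized = FALSE, undefined = undef,
                 affine = series$affine, voxel_size_mm = series$voxel_size_mm)
}

#' Smooth and standardize a BEN (or ALFF) map
#'
#' Mask-normalized Gaussian smoothing of the in-mask values (undefined voxels
#' carry no weight), followed by map-level standardization. `mode = "zscore"`
#' subtracts the in-mask mean and divides by the in-mask standard deviation.
#' `mode = "artanh"` applies Fisher's r-to-z transform `atanh`, which is only
#' defined when every in-mask value lies strictly inside (-1, 1) -- raw
#' sample-entropy values typically exceed 1, in which case an explicit error
#' is raised; z-scoring is therefore the default.
#'
#' @param map A `ben_map` (or `alff_map`) that has not been standardized.
#' @param fwhm_mm Smoothing FWHM in mm (0 = no smoothing).
#' @param mode Standardization mode, `"zscore"` (default) or `"artanh"`.
#' @return The smoothed, standardized map object.
#' @export
smooth_and_standardize_ben <- function(map, fwhm_mm = 6,
                                       mode = c("zscore", "artanh")) {
  mode <- match.arg(mode)
  if (isTRUE(map$standardized)) stopf("map is already standardized")
  mask <- map$mask & !map$undefined
  vals <- map$values
  if (fwhm_mm > 0) {
    sig <- fwhm_to_sigma_vox(fwhm_mm, map$voxel_size_mm)
    w <- array(0, dim(vals)); w[mask] <- 1
    num <- smooth3d(vals * w, sig)
    den <- smooth3d(w, sig)
    vals[mask] <- num[mask] / den[mask]
    vals[!mask] <- 0
  }
  inm <- vals[mask]
  if (mode == "artanh") {
    if (any(abs(inm) >= 1))
      stopf("artanh standardization requires all in-mask values in (-1, 1); max |value| = %.3g",
            max(abs(inm)))
    vals[mask] <- atanh(inm)
  } else {
    s <- sd(inm)
    if (s == 0) stopf("cannot z-score a constant map")
    vals[mask] <- (inm - mean(inm)) / s
  }
  map$values <- vals
  map$mask <- mask
  map$standardized <- TRUE
  map
}

#' Amplitude of low-frequency fluctuations (ALFF) map
#'
#' Per voxel, the square root of the sum of squared DFT magnitudes over the
#' positive-frequency bins within `band` (unnormalized forward transform
#' convention, so a unit-amplitude sinusoid on an in-band bin gives
#' ALFF = N/2). The conventional input is the detrended, nuisance-corrected
#' but *not* band-passed series: band selection happens in this spectral sum.
#'
#' @param series Preprocessed (un-band-passed) [bold_series].
#' @param mask 3D brain mask.
#' @param band Frequency band in Hz, default `c(0.01, 0.08)`.
#' @return An object of class `alff_map` (fields as [ben_map_object()], plus
#'   `band`).
#' @export
alff_map <- function(series, mask, band = c(0.01, 0.08)) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$data)
  mask <- check_mask(mask, d[1:3])
  t <- d[4]
  nyq <- 1 / (2 * series$tr_s)
  if (band[1] < 0 || band[1] >= band[2] || band[2] > nyq + 1e-12)
    stopf("invalid band [%g, %g] Hz (Nyquist %g Hz)", band[1], band[2], nyq)
  kpos <- seq_len(floor(t / 2))  # positive-frequency bins
  freq <- kpos / (t * series$tr_s)
  inband <- freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12
  if (!any(inband)) stopf("no DFT bins inside band [%g, %g] Hz", band[1], band[2])
  M <- as_tv_matrix(series)[, as.vector(mask), drop = FALSE]
  F <- mvfft(M)
  pw <- Mod(F[kpos[inband] + 1L, , drop = FALSE])^2
  vals <- sqrt(colSums(pw))
  out <- array(0, d[1:3])
  out[mask] <- vals
  m <- ben_map_object(out, mask, sampen_params(), standardized = FALSE,
                      affine = series$affine,
                      voxel_size_mm = series$voxel_size_mm)
  m$band <- band
  class(m) <- c("alff_map", "ben_map")
  m
}

#' Write a BEN/ALFF map with its QC sidecar
#'
#' Writes the 3D values as NIfTI-1 and a JSON sidecar recording parameters,
#' standardization state and the undefined-voxel count.
#'
#' @param map A `ben_map` or `alff_map`.
#' @param path Output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  write_nifti_map(map$values, path, voxel_size_mm = map$voxel_size_mm,
                  affine = map$affine)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(
    type = class(map)[1],
    standardized = map$standardized,
    n_mask = sum(map$mask),
    n_undefined = sum(map$undefined),
    params = unclass(map$params))
  if (!is.null(map$band)) meta$band_hz <- map$band
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
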