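# internal helpers: smoothing kernels, affines, small validators

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Gaussian kernel standard deviation in voxels
#'
#' Converts a smoothing kernel's full width at half maximum (FWHM, mm) to the
#' Gaussian standard deviation in voxel units for a given voxel size, using
#' sigma = FWHM / (2 * sqrt(2 * log(2))).
#'
#' @param fwhm_mm Kernel FWHM in millimetres.
#' @param voxel_size_mm Voxel edge length in millimetres (scalar or length 3).
#' @return Numeric vector of sigma values in voxel units.
#' @export
#' @examples
#' fwhm_to_sigma_vox(6, 3)  # 0.8493...
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  if (any(fwhm_mm < 0)) stopf("fwhm_mm must be non-negative")
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

# unit-sum 1D Gaussian kernel, truncated at radius ceiling(4*sigma)
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  radius <- max(1L, as.integer(ceiling(4 * sigma)))
  off <- seq.int(-radius, radius)
  k <- exp(-off^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 3D Gaussian smoothing of a 3D array (or each volume of a 4D
# array), circular boundary so total mass is preserved exactly; sigma per
# axis in voxels
smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  if (all(sigma_vox <= 0)) return(arr)
  kernels <- lapply(1:3, function(ax) gaussian_kernel(sigma_vox[ax]))
  array(.smooth3d_cpp(as.numeric(arr), as.integer(d[1:3]), kernels), d)
}

# default RAS affine: voxel (0-based ijk) to world mm, origin at grid centre
default_affine <- function(dim3, voxel_size_mm) {
  vs <- rep(voxel_size_mm, length.out = 3)
  aff <- diag(c(vs, 1))
  aff[1:3, 4] <- -vs * (dim3 - 1) / 2
  aff
}

# world-mm coordinates of 0-based voxel indices (matrix n x 3)
voxel_to_world <- function(ijk0, affine) {
  ijk0 <- matrix(ijk0, ncol = 3)
  t(affine %*% rbind(t(ijk0), 1))[, 1:3, drop = FALSE]
}

check_mask <- function(mask, dim3) {
  if (!is.logical(mask)) mask <- mask != 0
  if (!identical(dim(mask), as.integer(dim3)))
    stopf("mask dimensions (%s) do not match data (%s)",
          paste(dim(mask), collapse = "x"), paste(dim3, collapse = "x"))
  mask
}

# derive a fresh sub-seed stream below 2^31 from a base seed
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr with a local RNG state seeded by `seed` (NULL = use current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
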