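#' 4D BOLD time series container
#'
#' Wraps a 4D array of BOLD data together with its voxel geometry, repetition
#' time and voxel-to-world affine. All temporal operations in the package
#' consume and return this class and append a step label to its provenance.
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 2 and finite values.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param tr_s Repetition time in seconds.
#' @param affine 4x4 voxel(0-based)-to-world transform; default is an RAS
#'   affine centred on the grid.
#' @param provenance Character vector of processing steps already applied.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_size_mm, tr_s, affine = NULL,
                        provenance = character()) {
  if (length(dim(data)) != 4L) stopf("data must be a 4D array")
  if (dim(data)[4L] < 2L) stopf("need at least 2 timepoints")
  if (!all(is.finite(data))) stopf("BOLD data contains non-finite values")
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  if (any(voxel_size_mm <= 0)) stopf("voxel_size_mm must be positive")
  if (is.null(affine)) affine <- default_affine(dim(data)[1:3], voxel_size_mm)
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, tr_s = as.numeric(tr_s),
         affine = affine, provenance = as.character(provenance)),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels x %d timepoints, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size_mm), collapse = "x"), x$tr_s))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_timepoints <- function(series) dim(series$data)[4L]

add_provenance <- function(series, step) {
  series$provenance <- c(series$provenance, step)
  series
}

#' Read a 4D BOLD NIfTI file
#'
#' Loads a NIfTI-1/2 image, requiring four dimensions, and populates the
#' voxel geometry, affine and repetition time (taken from the header's fourth
#' pixdim unless overridden).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param tr_s Optional repetition time override in seconds. If the header
#'   carries no usable TR and no override is given, a warning is issued and
#'   1 s is assumed.
#' @return A [bold_series].
#' @export
load_bold <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot read NIfTI file %s: %s",
                                            path, conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stopf("expected a 4D image, got %dD: %s", length(dim(a)), path)
  hdr <- RNifti::niftiHeader(img)
  pd <- hdr$pixdim
  header_tr <- if (length(pd) >= 5 && is.finite(pd[5]) && pd[5] > 0) pd[5] else NA
  if (is.null(tr_s)) {
    if (is.na(header_tr)) {
      warning(sprintf("no TR in header of %s; assuming 1 s", path))
      tr_s <- 1
    } else tr_s <- header_tr
  }
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  bold_series(array(as.numeric(a), dim(a)), voxel_size_mm = abs(pd[2:4]),
              tr_s = tr_s, affine = aff, provenance = sprintf("load:%s", basename(path)))
}

#' Write a BOLD series or 3D map as NIfTI-1
#'
#' @param x A [bold_series], or a 3D/4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm,tr_s,affine Geometry used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_size_mm = 3, tr_s = 1,
                            affine = NULL) {
  if (inherits(x, "bold_series")) {
    arr <- x$data; voxel_size_mm <- x$voxel_size_mm
    tr_s <- x$tr_s; affine <- x$affine
  } else arr <- x
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  if (is.null(affine)) affine <- default_affine(dim(arr)[1:3], voxel_size_mm)
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 4L) c(voxel_size_mm, tr_s) else voxel_size_mm
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
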