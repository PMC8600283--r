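#' Convert a Gaussian FWHM to its standard deviation
#'
#' Smoothing kernels in PET pipelines are specified by their full-width at
#' half-maximum. The corresponding standard deviation of the Gaussian is
#' `fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm Full-width at half-maximum in mm (non-negative scalar).
#' @return The standard deviation in mm.
#' @examples
#' fwhm_to_sigma(6)
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || is.na(fwhm) || fwhm < 0)
    stop("'fwhm' must be a single non-negative number")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Physical voxel dimensions of a volume
#'
#' Returns the edge lengths (mm) of a voxel along each axis. For images read
#' with [read_volume()] (RNifti images) the NIfTI pixdim is used; otherwise a
#' `voxel_mm` attribute is honoured, falling back to 1 mm isotropic.
#'
#' @param x A 3D array or `niftiImage`.
#' @return Numeric vector of length 3 (mm).
#' @export
voxel_size <- function(x) {
  if (inherits(x, "niftiImage")) {
    pd <- RNifti::pixdim(x)
    return(as.numeric(pd[seq_len(3L)]))
  }
  vm <- attr(x, "voxel_mm")
  if (!is.null(vm)) return(rep_len(as.numeric(vm), 3L))
  c(1, 1, 1)
}

#' Read / write a single 3D NIfTI volume
#'
#' Thin wrappers around RNifti. `read_volume` drops a trailing singleton
#' fourth dimension; `read_mask` additionally binarizes (`values != 0`).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_volume`: a `niftiImage` (3D array); `read_mask`: a logical
#'   3D array with the source voxel dimensions in the `voxel_mm` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) dim(img) <- d[seq_len(3L)]
  if (length(dim(img)) != 3L)
    stop("expected a single 3D volume in ", path)
  img
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  m <- array(as.vector(img) != 0, dim = dim(img))
  attr(m, "voxel_mm") <- voxel_size(img)
  m
}

#' @rdname read_volume
#' @param x A 3D array of values to write.
#' @param voxel_mm Voxel edge lengths in mm used for the NIfTI header.
#' @export
write_volume <- function(x, path, voxel_mm = voxel_size(x)) {
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize a scan to a reference region
#'
#' Divides every voxel by the mean intensity over the reference region (the
#' pons for FDG), so the output is a dimensionless uptake ratio whose
#' reference-region mean is exactly 1. The operation is invariant to global
#' rescaling of the input.
#'
#' @param scan 3D numeric array of uptake values.
#' @param ref Logical 3D array on the same grid marking the reference region.
#' @return The normalized array (attributes preserved).
#' @export
normalize_to_reference <- function(scan, ref) {
  if (!identical(dim(scan), dim(ref)))
    stop("scan and reference mask are on different grids")
  if (!any(ref)) stop("reference mask is empty")
  m <- mean(scan[ref])
  tol <- 1e-8 * abs(mean(scan))
  if (!is.finite(m) || abs(m) <= tol)
    stop("degenerate reference region: mean intensity is (near) zero")
  out <- scan / m
  attributes(out) <- attributes(scan)
  out
}

# Fold out-of-range indices back into 1..n by whole-sample mirror reflection
# about the edge voxels (i -> 2 - i below, i -> 2n - i above).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep_len(1L, length(idx)))
  while (any(bad <- idx < 1L | idx > n)) {
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
  }
  idx
}

# 1D convolution of a 3D array along one axis, mirror boundaries.
convolve_axis <- function(x, kernel, axis) {
  h <- (length(kernel) - 1L) %/% 2L
  if (h == 0L) return(x * kernel)
  n <- dim(x)[axis]
  out <- array(0, dim(x))
  for (t in -h:h) {
    idx <- reflect_index(seq_len(n) + t, n)
    shifted <- switch(axis,
                      x[idx, , , drop = FALSE],
                      x[, idx, , drop = FALSE],
                      x[, , idx, drop = FALSE])
    out <- out + kernel[t + h + 1L] * shifted
  }
  out
}

#' Smooth a volume with a Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `fwhm_to_sigma(fwhm) / voxel_mm`. Boundaries are handled by mirror
#' reflection, so a constant image is a fixed point and, away from the
#' boundary, total intensity is conserved. `fwhm = 0` is the identity.
#'
#' @param scan 3D numeric array.
#' @param fwhm Kernel full-width at half-maximum in mm.
#' @param voxel_mm Voxel edge lengths in mm (default: taken from the image).
#' @return The smoothed array (attributes preserved).
#' @export
gaussian_smooth <- function(scan, fwhm, voxel_mm = voxel_size(scan)) {
  if (!is.array(scan) || length(dim(scan)) != 3L)
    stop("'scan' must be a 3D array")
  sigma_mm <- fwhm_to_sigma(fwhm)   # validates fwhm
  if (fwhm == 0) return(scan)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  out <- array(as.numeric(scan), dim = dim(scan))
  for (axis in 1:3) {
    sig <- sigma_mm / voxel_mm[axis]
    h <- max(1L, as.integer(ceiling(4 * sig)))
    k <- stats::dnorm(-h:h, sd = sig)
    out <- convolve_axis(out, k / sum(k), axis)
  }
  attributes(out) <- attributes(scan)
  out
}

# Order-stable fingerprint of a mask and the voxel ordering derived from it;
# used to refuse projecting scans extracted under a different mask.
mask_fingerprint <- function(mask) {
  idx <- which(mask)
  sprintf("%s|n=%d|s1=%.0f|s2=%.0f",
          paste(dim(mask), collapse = "x"), length(idx),
          sum(idx %% 97651) %% 2147483647,
          sum((idx %% 65521)^2) %% 2147483647)
}

#' Extract within-mask voxel values from one scan
#'
#' Values are taken in the fixed lexicographic (column-major) order of grid
#' indices, the same ordering [stack_cohort()] records, so a row of the cohort
#' matrix round-trips with this function.
#'
#' @param scan 3D numeric array.
#' @param mask Logical 3D array (the analysis/brain mask).
#' @return Numeric vector of length `sum(mask)` with the mask fingerprint
#'   attached as attribute `mask_fingerprint`.
#' @export
masked_values <- function(scan, mask) {
  if (!identical(dim(scan), dim(mask)))
    stop("scan and mask are on different grids")
  v <- as.numeric(scan[which(mask)])
  attr(v, "mask_fingerprint") <- mask_fingerprint(mask)
  v
}

#' Preprocess a cohort of scans into the analysis matrix
#'
#' The standard pipeline applied to each scan: intensity normalization to the
#' reference region, Gaussian smoothing at the given FWHM, then extraction of
#' within-brain-mask voxels into a subjects x voxels matrix (masking happens
#' after smoothing).
#'
#' @param scans List of co-registered 3D arrays.
#' @param brain_mask Logical 3D array; analysis mask.
#' @param ref_mask Logical 3D array; reference (e.g. pons) region.
#' @param fwhm Smoothing kernel FWHM in mm (default 6).
#' @param ids Subject identifiers.
#' @param voxel_mm Voxel sizes in mm (default: from the first scan).
#' @return A cohort matrix as returned by [stack_cohort()].
#' @export
preprocess_scans <- function(scans, brain_mask, ref_mask, fwhm = 6,
                             ids = names(scans),
                             voxel_mm = voxel_size(scans[[1L]])) {
  proc <- lapply(scans, function(s)
    gaussian_smooth(normalize_to_reference(s, ref_mask), fwhm,
                    voxel_mm = voxel_mm))
  stack_cohort(proc, brain_mask, ids = ids)
}

#' Assemble the subjects-by-voxels cohort matrix
#'
#' Stacks within-mask voxel values of co-registered scans, one row per
#' participant, in input order. The voxel ordering (linear grid indices) and a
#' mask fingerprint are recorded as attributes so eigenbrains can later be
#' placed back into the volume and new scans can be checked for compatibility.
#'
#' @param scans List of 3D arrays on a common grid.
#' @param mask Logical 3D array; the analysis (brain) mask.
#' @param ids Character vector of unique subject identifiers.
#' @return A numeric matrix (subjects x voxels) with `ids` as rownames and
#'   attributes `voxel_order`, `grid_dim`, `mask_fingerprint`.
#' @export
stack_cohort <- function(scans, mask, ids = names(scans)) {
  if (!is.list(scans) || length(scans) < 2L)
    stop("need at least 2 scans to assemble a cohort matrix")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(scans))
  ids <- as.character(ids)
  if (length(ids) != length(scans)) stop("'ids' must match the number of scans")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (i in seq_along(scans))
    if (!identical(dim(scans[[i]]), dim(mask)))
      stop(sprintf("scan %d (%s) is on a different grid than the mask", i, ids[i]))
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  mat <- t(vapply(scans, function(s) as.numeric(s[idx]), numeric(length(idx))))
  rownames(mat) <- ids
  attr(mat, "voxel_order") <- idx
  attr(mat, "grid_dim") <- dim(mask)
  attr(mat, "mask_fingerprint") <- mask_fingerprint(mask)
  mat
}
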