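#' Gaussian kernel width conversions and resolution arithmetic
#'
#' Gaussian kernels are parameterised by their full width at half maximum
#' (FWHM). `fwhm_to_sigma` converts an FWHM in mm to a standard deviation in
#' voxels, per axis: sigma = FWHM / (2 sqrt(2 ln 2)) / voxel_size.
#' `effective_resolution` combines an intrinsic point-spread FWHM with an
#' applied smoothing kernel in quadrature, per axis: sqrt(intrinsic^2 +
#' kernel^2) — the resolution of the smoothed image.
#'
#' @param fwhm_mm kernel FWHM in mm (scalar or length 3).
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @return `fwhm_to_sigma`: numeric length 3, sigma in voxel units.
#' @examples
#' fwhm_to_sigma(2 * sqrt(2 * log(2)) , 1)  # 1 voxel
#' effective_resolution(c(6.6, 6.6, 5.1), 8)  # 10.4 10.4 9.5 mm
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  stopifnot(length(fwhm_mm) == 3L, all(fwhm_mm >= 0))
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}

#' @rdname fwhm_to_sigma
#' @param intrinsic_fwhm_mm intrinsic scanner point-spread FWHM, mm
#'   (scalar or length 3).
#' @param kernel_fwhm_mm applied smoothing kernel FWHM, mm (scalar or
#'   length 3).
#' @return `effective_resolution`: numeric length 3, mm.
#' @export
effective_resolution <- function(intrinsic_fwhm_mm, kernel_fwhm_mm) {
  if (length(intrinsic_fwhm_mm) == 1L) intrinsic_fwhm_mm <- rep(intrinsic_fwhm_mm, 3L)
  if (length(kernel_fwhm_mm) == 1L) kernel_fwhm_mm <- rep(kernel_fwhm_mm, 3L)
  stopifnot(length(intrinsic_fwhm_mm) == 3L, length(kernel_fwhm_mm) == 3L,
            all(intrinsic_fwhm_mm >= 0), all(kernel_fwhm_mm >= 0))
  sqrt(intrinsic_fwhm_mm^2 + kernel_fwhm_mm^2)
}

# Dense 1D convolution matrix for a normalised Gaussian of sd `sigma`
# (voxels), truncated at 4 sigma and renormalised row-wise so that a
# constant signal is preserved exactly, including at the boundaries. The
# matrix is symmetric under simultaneous reversal of rows and columns, so
# smoothing commutes with mirror flips.
gaussian_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma))
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    o <- offs[j]
    rows <- seq_len(n)
    cols <- rows + o
    ok <- cols >= 1L & cols <= n
    M[cbind(rows[ok], cols[ok])] <- M[cbind(rows[ok], cols[ok])] + k[j]
  }
  M / rowSums(M)
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with an axis-separable Gaussian of the given FWHM
#' (in mm, per axis). Kernels are truncated at 4 sigma and renormalised at
#' the array boundaries, so constant images are preserved exactly and the
#' operation commutes with a flip along any axis. FWHM 0 on an axis is the
#' identity.
#'
#' @param x 3D numeric array, or a [static_image()].
#' @param fwhm_mm FWHM in mm, scalar or per-axis length 3.
#' @param voxel_size_mm voxel size in mm (taken from the image if `x` is a
#'   [static_image()]).
#' @return Same type as `x`, smoothed.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size_mm = NULL) {
  if (inherits(x, "static_image")) {
    x$voxels <- gaussian_smooth(x$voxels, fwhm_mm, x$voxel_size_mm)
    return(x)
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (is.null(voxel_size_mm)) stop("voxel_size_mm required for bare arrays")
  sig <- fwhm_to_sigma(fwhm_mm, voxel_size_mm)
  if (all(sig <= 0)) return(x)
  d <- dim(x)
  # axis 1: (n1, n2*n3) matrix product
  if (sig[1] > 0) {
    M <- gaussian_conv_matrix(d[1], sig[1])
    x <- array(M %*% matrix(x, d[1]), d)
  }
  if (sig[2] > 0) {
    M <- gaussian_conv_matrix(d[2], sig[2])
    x <- aperm(array(M %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  if (sig[3] > 0) {
    M <- gaussian_conv_matrix(d[3], sig[3])
    x <- aperm(array(M %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
                     c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  x
}
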