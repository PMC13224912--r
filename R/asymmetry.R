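#' Mirror an image across the midsagittal plane
#'
#' Reverses the left-right (first) axis. In the symmetric template grid
#' (even first dimension: midplane between the two central voxel columns;
#' odd: midplane on the central column) this is an exact involution.
#'
#' @param img a [static_image()] or 3D array.
#' @return Same type, flipped.
#' @export
mirror_flip <- function(img) {
  if (inherits(img, "static_image")) {
    img$voxels <- mirror_array(img$voxels)
    return(img)
  }
  stopifnot(is.array(img), length(dim(img)) == 3L)
  mirror_array(img)
}

#' Voxelwise hemispheric asymmetry map (mirrored subtraction)
#'
#' The lesion-mapping workflow: smooth the image with a Gaussian kernel,
#' flip the smoothed image across the midline, and compute the voxelwise
#' percent difference against the mirrored (contralateral) value:
#' delta% = 100 (I - I_mirror) / I_mirror. The map is masked to the
#' cortical labels of the stated (ipsilateral) hemisphere; voxels whose
#' mirrored value is at or below a guard epsilon (1% of the robust image
#' maximum) are excluded and counted.
#'
#' @param img a [static_image()] in the symmetric grid.
#' @param atlas a [label_volume()] on the same grid.
#' @param side `"left"` or `"right"`: the hemisphere under scrutiny.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 = no smoothing.
#' @param tissue atlas tissue classes forming the analysis mask (default
#'   the cortical compartments).
#' @param denominator `"contralateral"` (the mirrored value, default) or
#'   `"symmetric"` (the mean of both sides, which makes side-swapping an
#'   exact sign flip).
#' @return An `asymmetry_map`: list with `delta_pct` (3D, NA outside the
#'   mask), `mask` (logical 3D), `smoothing_fwhm_mm`, `side`,
#'   `voxel_size_mm`, `n_excluded`.
#' @export
percent_difference_map <- function(img, atlas, side, fwhm_mm = 8,
                                   tissue = c("cortex", "temporal_lobe"),
                                   denominator = c("contralateral",
                                                   "symmetric")) {
  stopifnot(inherits(img, "static_image"), inherits(atlas, "label_volume"))
  side <- match.arg(side, c("left", "right"))
  denominator <- match.arg(denominator)
  sm <- if (any(fwhm_mm > 0))
    gaussian_smooth(img$voxels, fwhm_mm, img$voxel_size_mm) else img$voxels
  mir <- mirror_array(sm)
  eps <- 0.01 * stats::quantile(sm, 0.99, names = FALSE)
  den <- if (denominator == "contralateral") mir else (sm + mir) / 2
  mask <- hemisphere_mask(atlas, side, tissue)
  bad <- mask & den <= eps
  mask <- mask & den > eps
  delta <- array(NA_real_, dim(sm))
  delta[mask] <- 100 * (sm[mask] - mir[mask]) / den[mask]
  structure(list(delta_pct = delta, mask = mask,
                 smoothing_fwhm_mm = fwhm_mm, side = side,
                 voxel_size_mm = img$voxel_size_mm,
                 denominator = denominator, n_excluded = sum(bad)),
            class = "asymmetry_map")
}

#' @export
print.asymmetry_map <- function(x, ...) {
  cat(sprintf(
    "<asymmetry_map> side %s, fwhm %s mm, %d voxels in mask (%d excluded)\n",
    x$side, paste(format(x$smoothing_fwhm_mm), collapse = "x"),
    sum(x$mask), x$n_excluded))
  invisible(x)
}

#' Suprathreshold lesion mask with most-affected retention
#'
#' Selects hypo-signal voxels (delta% <= -threshold_pct), then retains the
#' `keep_fraction` of suprathreshold voxels with the largest asymmetry
#' magnitude (rank by |delta%| descending, ties broken by voxel index) —
#' restricting lesion metrics to the most affected 90% of voxels by
#' default, which suppresses edge noise and partial-volume effects at the
#' lesion boundary.
#'
#' @param map an [percent_difference_map()] result.
#' @param threshold_pct asymmetry threshold in percent (default 8).
#' @param keep_fraction fraction of suprathreshold voxels retained
#'   (default 0.90).
#' @return logical 3D array.
#' @export
lesion_mask <- function(map, threshold_pct = 8, keep_fraction = 0.90) {
  stopifnot(inherits(map, "asymmetry_map"), threshold_pct >= 0,
            keep_fraction > 0, keep_fraction <= 1)
  supra <- which(!is.na(map$delta_pct) & map$delta_pct <= -threshold_pct)
  out <- array(FALSE, dim(map$delta_pct))
  if (length(supra) == 0L) return(out)
  n_keep <- floor(keep_fraction * length(supra) + 0.5)
  if (n_keep >= 1L) {
    ord <- supra[order(-abs(map$delta_pct[supra]), supra)]
    out[ord[seq_len(n_keep)]] <- TRUE
  }
  out
}

#' Lesion severity and volume
#'
#' Severity is the mean delta% over the retained mask; volume is the voxel
#' count times the voxel volume in mL. An empty mask yields `NA` severity
#' and zero volume.
#'
#' @param map an [percent_difference_map()] result.
#' @param mask logical array from [lesion_mask()].
#' @param voxel_size_mm voxel size (defaults to the map's).
#' @return list with `severity_pct`, `volume_mL`, `n_voxels`.
#' @export
lesion_metrics <- function(map, mask, voxel_size_mm = NULL) {
  stopifnot(inherits(map, "asymmetry_map"))
  if (is.null(voxel_size_mm)) voxel_size_mm <- map$voxel_size_mm
  n <- sum(mask)
  vox_mL <- prod(voxel_size_mm) / 1000
  list(severity_pct = if (n == 0L) NA_real_ else
         mean(map$delta_pct[mask], na.rm = TRUE),
       volume_mL = n * vox_mL, n_voxels = n)
}

#' Smoothing-kernel sweep: lesion signal vs background noise
#'
#' Recomputes the asymmetry map, lesion metrics and background noise for a
#' range of Gaussian kernels. Background noise is the SD of the delta% map
#' over the contralateral cortical mask (the only lesion-free cortical
#' compartment); lesion signal is |severity|.
#'
#' @param img a [static_image()].
#' @param atlas a [label_volume()].
#' @param side ipsilateral (lesion) hemisphere.
#' @param kernels_mm kernel FWHMs to evaluate (default 0..20 mm).
#' @param threshold_pct,keep_fraction passed to [lesion_mask()].
#' @param tissue analysis tissue classes.
#' @return Data frame per kernel: `fwhm_mm`, `lesion_signal_pct`,
#'   `background_noise_pct`, `lesion_volume_mL`, `n_voxels`.
#' @export
kernel_sweep <- function(img, atlas, side, kernels_mm = seq(0, 20, by = 2),
                         threshold_pct = 8, keep_fraction = 0.90,
                         tissue = c("cortex", "temporal_lobe")) {
  other <- if (side == "left") "right" else "left"
  rows <- lapply(kernels_mm, function(k) {
    m_ips <- percent_difference_map(img, atlas, side, k, tissue = tissue)
    m_con <- percent_difference_map(img, atlas, other, k, tissue = tissue)
    lm_ <- lesion_mask(m_ips, threshold_pct, keep_fraction)
    met <- lesion_metrics(m_ips, lm_)
    data.frame(fwhm_mm = k,
               lesion_signal_pct = abs(met$severity_pct),
               background_noise_pct = stats::sd(m_con$delta_pct[m_con$mask]),
               lesion_volume_mL = met$volume_mL, n_voxels = met$n_voxels)
  })
  do.call(rbind, rows)
}

#' Write an asymmetry map as NIfTI
#'
#' Voxels outside the analysis mask are written as 0.
#'
#' @param map an [percent_difference_map()] result.
#' @param path output path.
#' @export
write_asymmetry_nifti <- function(map, path) {
  arr <- map$delta_pct
  arr[is.na(arr)] <- 0
  write_pet_nifti(static_image(arr, map$voxel_size_mm, units = "delta%"),
                  path)
}
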