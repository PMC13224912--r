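#' Unilateral lesion specification
#'
#' A spherical lesion centered on the centroid of a named region in one
#' hemisphere. `severity_frac` is the fractional reduction of late-phase
#' (specific binding / metabolic) signal; `perfusion_frac` the fractional
#' reduction of tracer delivery (K1). In the dynamic generator a perfusion
#' deficit scales K1 and k2 together (binding potential preserved), while a
#' binding deficit scales VT down via k2 inflation with delivery unchanged;
#' a metabolic (FDG) lesion is a plain multiplicative reduction. Lesions may
#' be composed (e.g. a broad perfusion deficit containing a tighter binding
#' core, emulating a metabolic penumbra larger than the synaptic lesion).
#'
#' @param center_region region `name` or `tissue` in the atlas (its
#'   side-matched centroid is the lesion center).
#' @param side `"left"` or `"right"`.
#' @param radius_mm lesion radius, mm.
#' @param severity_frac fractional reduction of binding/uptake, in \[0, 1).
#' @param perfusion_frac fractional reduction of K1, in \[0, 1).
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(center_region, side, radius_mm,
                        severity_frac, perfusion_frac = 0) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(radius_mm > 0, severity_frac >= 0, severity_frac < 1,
            perfusion_frac >= 0, perfusion_frac < 1)
  structure(list(center_region = center_region, side = side,
                 radius_mm = radius_mm, severity_frac = severity_frac,
                 perfusion_frac = perfusion_frac),
            class = "lesion_spec")
}

#' Voxels belonging to a lesion
#'
#' Sphere of `radius_mm` about the centroid of the side-matched center
#' region, clipped to the stated hemisphere (so lesion voxels never cross
#' the midline) and to labelled tissue.
#'
#' @param atlas a [label_volume()].
#' @param lesion a [lesion_spec()].
#' @return logical 3D array.
#' @export
lesion_voxels <- function(atlas, lesion) {
  stopifnot(inherits(atlas, "label_volume"), inherits(lesion, "lesion_spec"))
  reg <- atlas$regions
  cand <- reg$side == lesion$side &
    (reg$name %in% lesion$center_region | reg$tissue %in% lesion$center_region)
  if (!any(cand))
    stop(sprintf("no region matching '%s' on side %s",
                 paste(lesion$center_region, collapse = ","), lesion$side))
  sel <- array(atlas$labels %in% reg$label[cand], dim(atlas$labels))
  gs <- dim(atlas$labels)
  co <- grid_coords(gs, atlas$voxel_size_mm)
  idx <- which(sel, arr.ind = TRUE)
  ctr <- c(mean(co[[1]][idx[, 1]]), mean(co[[2]][idx[, 2]]),
           mean(co[[3]][idx[, 3]]))
  X <- array(co[[1]], gs)
  Y <- array(rep(co[[2]], each = gs[1]), gs)
  Z <- array(rep(co[[3]], each = gs[1] * gs[2]), gs)
  m <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= lesion$radius_mm^2
  hemi <- if (lesion$side == "right") X > 0 else X < 0
  m & hemi & atlas$labels > 0L
}

# paint one frame's regional values into the grid
paint_labels <- function(labels, value_by_label) {
  maxl <- max(labels)
  lut <- numeric(maxl + 1L)
  lut[as.integer(names(value_by_label)) + 1L] <- value_by_label
  array(lut[labels + 1L], dim(labels))
}

# frame-duration-scaled Gaussian noise: SD = noise_scale *
# sqrt(max(value, eps) / duration_s); a Gaussian surrogate for
# reconstructed-PET Poisson noise (variance proportional to activity,
# inverse to acquisition time)
add_frame_noise <- function(vol, duration_s, noise_scale, eps = 0.01) {
  if (noise_scale <= 0) return(vol)
  sd <- noise_scale * sqrt(pmax(vol, eps) / duration_s)
  vol + array(stats::rnorm(length(vol), 0, 1), dim(vol)) * sd
}

#' Render a dynamic image from regional time-activity curves
#'
#' Per frame: paints each label with its TAC value, convolves with a
#' Gaussian point-spread function of the stated intrinsic FWHM, and adds
#' zero-mean Gaussian noise with SD = `noise_scale *
#' sqrt(max(value, eps) / frame_duration_s)`. Reproducible for a fixed
#' seed.
#'
#' @param atlas a [label_volume()].
#' @param tacs named list (names = label numbers) of [simulate_tac()]
#'   results or numeric per-frame vectors; every label present in the atlas
#'   must have one, all on `sched`.
#' @param sched the [frame_schedule()].
#' @param psf_fwhm_mm intrinsic resolution FWHM, mm (default the scanner
#'   intrinsic 6.6 x 6.6 x 5.1 mm); 0 disables blurring.
#' @param noise_scale noise amplitude (0 disables noise); units
#'   kBq/mL * sqrt(s / (kBq/mL)).
#' @param seed integer RNG seed.
#' @param injected_dose_MBq,body_weight_kg metadata for the result.
#' @return A [dynamic_image()].
#' @export
render_dynamic_image <- function(atlas, tacs, sched,
                                 psf_fwhm_mm = c(6.6, 6.6, 5.1),
                                 noise_scale = 0, seed = 1L,
                                 injected_dose_MBq = NA_real_,
                                 body_weight_kg = NA_real_) {
  stopifnot(inherits(atlas, "label_volume"), inherits(sched, "frame_schedule"))
  present <- setdiff(unique(as.vector(atlas$labels)), 0L)
  missing <- setdiff(as.character(present), names(tacs))
  if (length(missing))
    stop(sprintf("no TAC supplied for label(s) %s",
                 paste(missing, collapse = ", ")))
  nf <- nrow(sched)
  vals <- vapply(tacs, function(tc) {
    v <- if (inherits(tc, "tac") || is.data.frame(tc)) tc$value else tc
    if (length(v) != nf) stop("TAC length does not match schedule")
    as.numeric(v)
  }, numeric(nf))
  set.seed(seed)
  gs <- dim(atlas$labels)
  out <- array(0, c(gs, nf))
  for (f in seq_len(nf)) {
    v <- vals[f, ]
    names(v) <- colnames(vals)
    vol <- paint_labels(atlas$labels, v)
    if (any(psf_fwhm_mm > 0))
      vol <- gaussian_smooth(vol, psf_fwhm_mm, atlas$voxel_size_mm)
    out[, , , f] <- add_frame_noise(vol, sched$duration_s[f], noise_scale)
  }
  dynamic_image(out, sched, atlas$voxel_size_mm, injected_dose_MBq,
                body_weight_kg)
}

#' Render a static FDG-like image
#'
#' Paints per-label uptake values, applies an optional multiplicative
#' lesion (uptake scaled by `1 - severity_frac` inside the lesion sphere),
#' blurs with the PSF and adds acquisition-duration-scaled noise.
#'
#' @param atlas a [label_volume()].
#' @param uptake named numeric (names = label numbers) of uptake values;
#'   every label present must have one.
#' @param lesion a [lesion_spec()] or `NULL`.
#' @param psf_fwhm_mm,noise_scale,seed as in [render_dynamic_image()].
#' @param acq_duration_s effective acquisition duration used for the noise
#'   model (default 1200 s, a 30-50 min static acquisition).
#' @param injected_dose_MBq,body_weight_kg metadata for the result.
#' @return A [static_image()].
#' @export
render_static_fdg <- function(atlas, uptake, lesion = NULL,
                              psf_fwhm_mm = c(6.6, 6.6, 5.1),
                              noise_scale = 0, seed = 1L,
                              acq_duration_s = 1200,
                              injected_dose_MBq = NA_real_,
                              body_weight_kg = NA_real_) {
  stopifnot(inherits(atlas, "label_volume"))
  present <- setdiff(unique(as.vector(atlas$labels)), 0L)
  missing <- setdiff(as.character(present), names(uptake))
  if (length(missing))
    stop(sprintf("no uptake supplied for label(s) %s",
                 paste(missing, collapse = ", ")))
  set.seed(seed)
  vol <- paint_labels(atlas$labels, uptake)
  if (!is.null(lesion)) {
    m <- lesion_voxels(atlas, lesion)
    vol[m] <- vol[m] * (1 - lesion$severity_frac)
  }
  if (any(psf_fwhm_mm > 0))
    vol <- gaussian_smooth(vol, psf_fwhm_mm, atlas$voxel_size_mm)
  vol <- add_frame_noise(vol, acq_duration_s, noise_scale)
  static_image(vol, atlas$voxel_size_mm, injected_dose_MBq, body_weight_kg)
}
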