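#' Image containers
#'
#' Two light-weight containers are used throughout: `dynamic_image`
#' (a 4D activity-concentration array, kBq/mL, plus its [frame_schedule()]
#' and dose/weight metadata) and `static_image` (a 3D volume). The first
#' array axis is the left-right axis of the symmetric template grid.
#'
#' @param voxels 4D numeric array (x, y, z, frame), activity in kBq/mL.
#' @param schedule a [frame_schedule()]; its length must match `dim(voxels)[4]`.
#' @param voxel_size_mm numeric length-3 voxel size in mm.
#' @param injected_dose_MBq injected activity in MBq (must be positive).
#' @param body_weight_kg body weight in kg (must be positive).
#' @return An object of class `dynamic_image` or `static_image`.
#' @export
dynamic_image <- function(voxels, schedule, voxel_size_mm,
                          injected_dose_MBq = NA_real_,
                          body_weight_kg = NA_real_) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L,
            inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4L] != nrow(schedule))
    stop(sprintf("frame axis length (%d) does not match schedule length (%d)",
                 dim(voxels)[4L], nrow(schedule)))
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  if (!is.na(injected_dose_MBq) && injected_dose_MBq <= 0)
    stop("injected_dose_MBq must be positive")
  if (!is.na(body_weight_kg) && body_weight_kg <= 0)
    stop("body_weight_kg must be positive")
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_size_mm = voxel_size_mm,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg),
            class = "dynamic_image")
}

#' @rdname dynamic_image
#' @param units unit label carried as metadata ("kBq/mL" or "SUV" or
#'   "SUVR:<ref>").
#' @export
static_image <- function(voxels, voxel_size_mm,
                         injected_dose_MBq = NA_real_,
                         body_weight_kg = NA_real_,
                         units = "kBq/mL") {
  stopifnot(is.array(voxels) || is.numeric(voxels))
  if (length(dim(voxels)) != 3L) stop("static_image expects a 3D array")
  if (any(!is.finite(voxels))) stop("static_image values must be finite")
  voxel_size_mm <- check_voxel_size(voxel_size_mm)
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg, units = units),
            class = "static_image")
}

check_voxel_size <- function(voxel_size_mm) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive values")
  as.numeric(voxel_size_mm)
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels x %d frames, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size_mm), collapse = "x")))
  if (!is.na(x$injected_dose_MBq))
    cat(sprintf("  dose %.1f MBq, weight %.1f kg\n",
                x$injected_dose_MBq, x$body_weight_kg))
  invisible(x)
}

#' @export
print.static_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<static_image> %dx%dx%d voxels, voxel %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_mm), collapse = "x"), x$units))
  invisible(x)
}

#' Convert activity concentration to standardized uptake value (SUV)
#'
#' SUV = C\[kBq/mL\] / (injected dose\[kBq\] / body weight\[g\]), assuming a
#' tissue density of 1 g/mL. Works on `dynamic_image`, `static_image`, or a
#' bare numeric array.
#'
#' @param image image container or numeric array of activity in kBq/mL.
#' @param dose_MBq injected dose in MBq; defaults to the image metadata.
#' @param weight_kg body weight in kg; defaults to the image metadata.
#' @return The same container with voxel values in SUV (g/mL convention).
#' @examples
#' suv(2.5, dose_MBq = 185, weight_kg = 74)  # 1.0
#' @export
suv <- function(image, dose_MBq = NULL, weight_kg = NULL) {
  if (inherits(image, c("dynamic_image", "static_image"))) {
    if (is.null(dose_MBq)) dose_MBq <- image$injected_dose_MBq
    if (is.null(weight_kg)) weight_kg <- image$body_weight_kg
  }
  if (is.null(dose_MBq) || is.null(weight_kg) ||
      is.na(dose_MBq) || is.na(weight_kg))
    stop("dose_MBq and weight_kg are required (argument or image metadata)")
  if (dose_MBq <= 0 || weight_kg <= 0)
    stop("dose_MBq and weight_kg must be positive")
  # dose in kBq per gram of body weight
  scale <- (dose_MBq * 1000) / (weight_kg * 1000)
  if (inherits(image, c("dynamic_image", "static_image"))) {
    image$voxels <- image$voxels / scale
    if (inherits(image, "static_image")) image$units <- "SUV"
    image
  } else {
    image / scale
  }
}

#' Duration-weighted average of a dynamic image over a time window
#'
#' Averages the frames fully contained in `[t0_s, t1_s]`, weighting each by
#' its duration. The window must contain at least one full frame.
#'
#' @param dyn a [dynamic_image()].
#' @param t0_s,t1_s window bounds in seconds.
#' @return A [static_image()] carrying the dose/weight metadata.
#' @export
window_average <- function(dyn, t0_s, t1_s) {
  stopifnot(inherits(dyn, "dynamic_image"))
  idx <- frames_in_window(dyn$schedule, t0_s, t1_s)
  if (length(idx) == 0L)
    stop(sprintf("no frame fully contained in window [%g, %g] s", t0_s, t1_s))
  w <- dyn$schedule$duration_s[idx]
  w <- w / sum(w)
  d <- dim(dyn$voxels)
  out <- array(0, d[1:3])
  for (i in seq_along(idx))
    out <- out + w[i] * dyn$voxels[, , , idx[i]]
  static_image(out, dyn$voxel_size_mm, dyn$injected_dose_MBq,
               dyn$body_weight_kg, units = "kBq/mL")
}

#' Reference-region normalisation (SUVR)
#'
#' Divides every voxel by the mean value over the reference-region labels.
#' Standard references for this protocol: cerebellum (early phase),
#' centrum semiovale (late phase), with pons and whole-brain global mean
#' as alternates.
#'
#' @param img a [static_image()].
#' @param atlas a [label_volume()] on the same grid.
#' @param ref reference name (matched against `atlas$regions$tissue`:
#'   `"cerebellum"`, `"centrum_semiovale"`, `"pons"`, `"global"`) or an
#'   integer vector of labels.
#' @return A [static_image()] in SUVR units; the mean over the reference
#'   region of the output is exactly 1.
#' @export
suvr <- function(img, atlas, ref = "cerebellum") {
  stopifnot(inherits(img, "static_image"), inherits(atlas, "label_volume"))
  labels <- resolve_reference_labels(atlas, ref)
  sel <- atlas$labels %in% labels
  if (!any(sel)) stop("reference region is empty in this atlas")
  m <- mean(img$voxels[sel])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("reference-region mean must be positive (got %g)", m))
  img$voxels <- img$voxels / m
  img$units <- paste0("SUVR:", if (is.character(ref)) ref else "labels")
  img
}

#' @rdname suvr
#' @export
resolve_reference_labels <- function(atlas, ref) {
  stopifnot(inherits(atlas, "label_volume"))
  if (is.numeric(ref)) {
    labels <- as.integer(ref)
    if (!all(labels %in% atlas$regions$label))
      stop("reference labels absent from atlas")
    return(labels)
  }
  ref <- match.arg(ref, c("cerebellum", "centrum_semiovale", "pons",
                          "global", "whole_brain_global_mean", "cso"))
  if (ref %in% c("global", "whole_brain_global_mean"))
    return(atlas$regions$label)
  if (ref == "cso") ref <- "centrum_semiovale"
  labels <- atlas$regions$label[atlas$regions$tissue == ref]
  if (length(labels) == 0L)
    stop(sprintf("no region with tissue '%s' in atlas", ref))
  labels
}
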