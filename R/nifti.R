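#' Read and write PET images as NIfTI-1
#'
#' Thin wrappers around RNifti that round-trip the containers used by this
#' package. Voxel values, voxel size and (for dynamic images) the frame
#' count are preserved exactly; the frame schedule itself is not stored in
#' the NIfTI header and must be supplied on read.
#'
#' @param image a [dynamic_image()], [static_image()] or [label_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_pet_nifti` returns `path` invisibly.
#' @export
write_pet_nifti <- function(image, path) {
  if (inherits(image, "dynamic_image")) {
    arr <- image$voxels
    pixdim <- c(image$voxel_size_mm, total_duration(image$schedule) /
                  nrow(image$schedule))
  } else if (inherits(image, "static_image")) {
    arr <- image$voxels
    pixdim <- image$voxel_size_mm
  } else if (inherits(image, "label_volume")) {
    arr <- image$labels
    storage.mode(arr) <- "integer"
    pixdim <- image$voxel_size_mm
  } else stop("unsupported image type")
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- pixdim
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# plain numeric array from a niftiImage (drops header attributes)
strip_nifti <- function(nii) {
  arr <- as.array(nii)
  array(as.vector(arr), dim(arr))
}

#' @rdname write_pet_nifti
#' @param schedule a [frame_schedule()] matching the 4th dimension of the
#'   file (required for dynamic reads).
#' @param injected_dose_MBq,body_weight_kg optional dose metadata to attach.
#' @export
read_dynamic_nifti <- function(path, schedule,
                               injected_dose_MBq = NA_real_,
                               body_weight_kg = NA_real_) {
  nii <- RNifti::readNifti(path)
  arr <- strip_nifti(nii)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D dynamic volume, got %dD", length(dim(arr))))
  dynamic_image(arr, schedule, RNifti::pixdim(nii)[1:3],
                injected_dose_MBq, body_weight_kg)
}

#' @rdname write_pet_nifti
#' @export
read_static_nifti <- function(path, injected_dose_MBq = NA_real_,
                              body_weight_kg = NA_real_) {
  nii <- RNifti::readNifti(path)
  arr <- strip_nifti(nii)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D static volume, got %dD", length(dim(arr))))
  static_image(arr, RNifti::pixdim(nii)[1:3], injected_dose_MBq,
               body_weight_kg)
}

#' @rdname write_pet_nifti
#' @param regions region table to attach to the label volume on read
#'   (see [label_volume()]).
#' @export
read_label_nifti <- function(path, regions) {
  nii <- RNifti::readNifti(path)
  arr <- strip_nifti(nii)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D label volume, got %dD", length(dim(arr))))
  storage.mode(arr) <- "integer"
  label_volume(arr, RNifti::pixdim(nii)[1:3], regions)
}
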