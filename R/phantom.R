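#' Label volumes (digital atlas)
#'
#' A `label_volume` couples a 3D integer array of region labels
#' (background = 0) with its voxel size and a region table
#' (`label`, `name`, `side`, `tissue`). The first array axis is the
#' left-right axis; for an even first dimension the midsagittal plane lies
#' between the two central voxel columns, so a plain reversal of axis 1 is
#' the mirror operation.
#'
#' @param labels 3D integer array of region labels.
#' @param voxel_size_mm voxel size, mm (scalar or length 3).
#' @param regions data frame with columns `label` (unique positive
#'   integers), `name`, `side` (`"left"`, `"right"` or `"midline"`) and
#'   `tissue` (grouping used for kinetics and reference-region lookup,
#'   e.g. `"cortex"`, `"cerebellum"`, `"centrum_semiovale"`).
#' @return A `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_mm, regions) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  req <- c("label", "name", "side", "tissue")
  if (!all(req %in% names(regions)))
    stop("regions must have columns label, name, side, tissue")
  if (anyDuplicated(regions$label) || any(regions$label <= 0))
    stop("region labels must be unique positive integers")
  if (!all(regions$side %in% c("left", "right", "midline")))
    stop("side must be left, right or midline")
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% regions$label))
    stop("label array contains labels absent from the region table")
  structure(list(labels = labels,
                 voxel_size_mm = check_voxel_size(voxel_size_mm),
                 regions = regions[order(regions$label), , drop = FALSE]),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %dx%dx%d voxels, %d regions, voxel %s mm\n",
              d[1], d[2], d[3], nrow(x$regions),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Phantom specification
#'
#' Describes a left-right symmetric digital brain phantom: the grid, and a
#' set of geometric regions. Right-hemisphere and midline primitives are
#' declared; left-hemisphere counterparts are generated by mirroring, which
#' makes the label volume exactly flip-symmetric by construction.
#'
#' Two primitive kinds are supported: `sphere` (center_mm, radius_mm) and
#' `shell_sector` (a spherical shell `r0..r1` about `center_mm`, cut to
#' `zmin_mm` and split into `n_sectors` angular sectors in the (y, z)
#' plane per hemisphere — used to emulate a multi-region cortical
#' parcellation).
#'
#' @param grid_shape integer length 3; first axis is left-right.
#' @param voxel_size_mm voxel size, mm.
#' @param regions list of region definitions (see [default_phantom_spec()]).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, regions) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = check_voxel_size(voxel_size_mm),
                 regions = regions),
            class = "phantom_spec")
}

#' Default symmetric brain phantom
#'
#' A desk-scale symmetric template emulating the anatomy needed by the
#' analysis: a cortical shell split into `n_cortex_sectors` angular sectors
#' per hemisphere (emulating a multi-region cortical atlas; the default 10
#' gives 20 cortical labels), paired temporal lobe, basal ganglia,
#' thalamus, cerebellum and centrum semiovale, a midline pons, and a
#' midline venous blood pool for image-derived input functions. All
#' coordinates are in mm relative to the grid center.
#'
#' @param grid_shape voxels per axis; default 96 x 96 x 80.
#' @param voxel_size_mm default 2 mm isotropic.
#' @param n_cortex_sectors cortical sectors per hemisphere (>= 1).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(grid_shape = c(96, 96, 80),
                                 voxel_size_mm = 2,
                                 n_cortex_sectors = 10) {
  sphere_pair <- function(name, tissue, center, r)
    list(kind = "sphere", name = name, tissue = tissue, side = "pair",
         center_mm = center, radius_mm = r)
  regions <- list(
    list(kind = "shell_sector", name = "cortex", tissue = "cortex",
         side = "pair", center_mm = c(0, 0, 0), r0_mm = 55, r1_mm = 75,
         zmin_mm = -20, n_sectors = n_cortex_sectors),
    sphere_pair("temporal_lobe", "temporal_lobe", c(48, -10, -42), 18),
    sphere_pair("basal_ganglia", "basal_ganglia", c(16, 8, -2), 11),
    sphere_pair("thalamus", "thalamus", c(9, -12, 2), 8),
    sphere_pair("cerebellum", "cerebellum", c(22, -45, -50), 16),
    sphere_pair("centrum_semiovale", "centrum_semiovale", c(20, 10, 28), 13),
    list(kind = "sphere", name = "pons", tissue = "pons", side = "midline",
         center_mm = c(0, -35, -40), radius_mm = 9),
    list(kind = "sphere", name = "blood_pool", tissue = "blood",
         side = "midline", center_mm = c(0, 20, 42), radius_mm = 5)
  )
  phantom_spec(grid_shape, voxel_size_mm, regions)
}

# voxel-center coordinates in mm relative to the grid center; axis 1 is
# signed left-right distance from the midsagittal plane (right = positive)
grid_coords <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(a)
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * voxel_size_mm[a])
}

#' Build the symmetric label volume from a phantom specification
#'
#' Paints each region into the grid; paired regions are painted on the
#' right hemisphere and mirrored exactly to the left (left label =
#' right label + 1). Overlapping definitions are an error naming both
#' labels. The result is exactly flip-symmetric: reversing axis 1 and
#' swapping left/right labels reproduces the volume.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()] whose region table carries `tissue` and
#'   `side` for every label.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vs <- spec$voxel_size_mm
  co <- grid_coords(gs, vs)
  X <- array(co[[1]], gs)
  Y <- array(rep(co[[2]], each = gs[1]), gs)
  Z <- array(rep(co[[3]], each = gs[1] * gs[2]), gs)
  lab <- array(0L, gs)
  rows <- list()
  next_label <- 1L

  paint <- function(mask, label, name) {
    clash <- mask & lab > 0L
    if (any(clash)) {
      other <- unique(lab[clash])[1L]
      stop(sprintf("region '%s' (label %d) overlaps label %d", name,
                   label, other))
    }
    lab[mask] <<- label
  }
  add_row <- function(label, name, side, tissue)
    rows[[length(rows) + 1L]] <<- data.frame(label = label, name = name,
                                             side = side, tissue = tissue)

  for (rg in spec$regions) {
    if (rg$kind == "sphere") {
      c0 <- rg$center_mm
      if (identical(rg$side, "midline")) {
        if (abs(c0[1]) > 1e-9) stop("midline region must have center x = 0")
        m <- (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= rg$radius_mm^2
        paint(m, next_label, rg$name)
        add_row(next_label, rg$name, "midline", rg$tissue)
        next_label <- next_label + 1L
      } else {
        cr <- abs(c0[1])
        if (cr < rg$radius_mm)
          stop(sprintf("paired region '%s' crosses the midline", rg$name))
        mR <- (X - cr)^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= rg$radius_mm^2
        paint(mR, next_label, paste0(rg$name, "_right"))
        add_row(next_label, paste0(rg$name, "_right"), "right", rg$tissue)
        mL <- mirror_array(mR)
        paint(mL, next_label + 1L, paste0(rg$name, "_left"))
        add_row(next_label + 1L, paste0(rg$name, "_left"), "left", rg$tissue)
        next_label <- next_label + 2L
      }
    } else if (rg$kind == "shell_sector") {
      r2 <- (X - rg$center_mm[1])^2 + (Y - rg$center_mm[2])^2 +
        (Z - rg$center_mm[3])^2
      shellR <- r2 >= rg$r0_mm^2 & r2 <= rg$r1_mm^2 &
        Z >= rg$zmin_mm & X > 0
      ang <- atan2(Z - rg$center_mm[3], Y - rg$center_mm[2])
      breaks <- seq(-pi, pi, length.out = rg$n_sectors + 1L)
      sector <- pmin(findInterval(ang, breaks, rightmost.closed = TRUE),
                     rg$n_sectors)
      for (s in seq_len(rg$n_sectors)) {
        mR <- shellR & sector == s
        nmR <- sprintf("%s_%02d_right", rg$name, s)
        nmL <- sprintf("%s_%02d_left", rg$name, s)
        paint(mR, next_label, nmR)
        add_row(next_label, nmR, "right", rg$tissue)
        mL <- mirror_array(mR)
        paint(mL, next_label + 1L, nmL)
        add_row(next_label + 1L, nmL, "left", rg$tissue)
        next_label <- next_label + 2L
      }
    } else stop(sprintf("unknown region kind '%s'", rg$kind))
  }
  label_volume(lab, vs, do.call(rbind, rows))
}

# reverse an array along the left-right (first) axis
mirror_array <- function(x) {
  d <- dim(x)
  x[d[1]:1, , , drop = FALSE]
}

#' Swap left/right labels after a mirror flip
#'
#' Returns the label volume that results from mirroring: axis 1 reversed
#' and each left label replaced by its right partner and vice versa.
#' For an exactly symmetric phantom this reproduces the input.
#'
#' @param atlas a [label_volume()].
#' @return A [label_volume()].
#' @export
mirror_labels <- function(atlas) {
  stopifnot(inherits(atlas, "label_volume"))
  flipped <- mirror_array(atlas$labels)
  reg <- atlas$regions
  map <- seq_len(max(reg$label))
  base <- sub("_(left|right)$", "", reg$name)
  for (i in seq_len(nrow(reg))) {
    if (reg$side[i] == "midline") next
    partner_side <- if (reg$side[i] == "left") "right" else "left"
    j <- which(base == base[i] & reg$side == partner_side)
    if (length(j) != 1L)
      stop(sprintf("no unique mirror partner for region '%s'", reg$name[i]))
    map[reg$label[i]] <- reg$label[j]
  }
  out <- flipped
  nz <- flipped > 0L
  out[nz] <- map[flipped[nz]]
  label_volume(out, atlas$voxel_size_mm, reg)
}

#' Hemisphere masks from a label volume
#'
#' @param atlas a [label_volume()].
#' @param side `"left"` or `"right"`.
#' @param tissue optional tissue filter (e.g. `"cortex"`).
#' @return logical 3D array.
#' @export
hemisphere_mask <- function(atlas, side, tissue = NULL) {
  side <- match.arg(side, c("left", "right"))
  reg <- atlas$regions
  keep <- reg$side == side
  if (!is.null(tissue)) keep <- keep & reg$tissue %in% tissue
  array(atlas$labels %in% reg$label[keep], dim(atlas$labels))
}
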