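#' Extract a regional time-activity curve from a dynamic image
#'
#' Per-frame mean over the mask voxels.
#'
#' @param dyn a [dynamic_image()].
#' @param mask logical 3D array (or integer indices) selecting voxels.
#' @param region,subject optional identifiers attached to the result.
#' @return A `tac` data frame (`midpoint_s`, `value`).
#' @export
extract_tac <- function(dyn, mask, region = NA_character_,
                        subject = NA_character_) {
  stopifnot(inherits(dyn, "dynamic_image"))
  if (is.logical(mask)) {
    nv3 <- prod(dim(dyn$voxels)[1:3])
    if (length(mask) != nv3)
      stop("logical mask does not match the image grid")
    mask <- which(mask)
  }
  if (length(mask) == 0L) stop("mask is empty")
  nf <- nrow(dyn$schedule)
  nv <- prod(dim(dyn$voxels)[1:3])
  vals <- vapply(seq_len(nf),
                 function(f) mean(dyn$voxels[(f - 1L) * nv + mask]),
                 numeric(1))
  new_tac(dyn$schedule, vals, region = region, subject = subject)
}

#' Regional TACs for every atlas region
#'
#' @param dyn a [dynamic_image()].
#' @param atlas a [label_volume()] on the same grid.
#' @return Tidy data frame: `subject`, `region`, `label`, `frame`,
#'   `frame_start_s`, `frame_duration_s`, `midpoint_s`, `value`.
#' @param subject optional subject id.
#' @export
extract_regional_tacs <- function(dyn, atlas, subject = NA_character_) {
  stopifnot(inherits(atlas, "label_volume"))
  sched <- dyn$schedule
  out <- lapply(seq_len(nrow(atlas$regions)), function(r) {
    lb <- atlas$regions$label[r]
    tc <- extract_tac(dyn, atlas$labels == lb)
    data.frame(subject = subject, region = atlas$regions$name[r],
               label = lb, frame = seq_len(nrow(sched)),
               frame_start_s = sched$start_s,
               frame_duration_s = sched$duration_s,
               midpoint_s = sched$midpoint_s, value = tc$value)
  })
  do.call(rbind, out)
}

#' Locate the peak of a time-activity curve
#'
#' Returns the frame midpoint (minutes) and value of the curve maximum;
#' ties resolve to the earliest frame. Peaks are located on the raw,
#' unsmoothed curve.
#'
#' @param tac a `tac` (or any data frame with `midpoint_s`, `value`).
#' @return list with `t_peak_min` and `peak_value`.
#' @export
tac_peak <- function(tac) {
  stopifnot(all(c("midpoint_s", "value") %in% names(tac)))
  i <- which.max(tac$value)  # which.max returns the first maximum
  list(t_peak_min = tac$midpoint_s[i] / 60, peak_value = tac$value[i])
}

#' Duration-weighted window mean of a TAC
#'
#' @param tac a `tac` carrying its schedule attribute, or a data frame with
#'   `frame_start_s`/`frame_duration_s` columns.
#' @param t0_s,t1_s window bounds, seconds.
#' @return scalar mean.
#' @export
tac_window_mean <- function(tac, t0_s, t1_s) {
  sched <- attr(tac, "schedule")
  if (is.null(sched)) {
    stopifnot(all(c("frame_start_s", "frame_duration_s") %in% names(tac)))
    tac <- tac[order(tac$frame_start_s), ]
    sched <- frame_schedule(tac$frame_start_s, tac$frame_duration_s)
  }
  idx <- frames_in_window(sched, t0_s, t1_s)
  if (length(idx) == 0L) stop("no frame fully contained in window")
  stats::weighted.mean(tac$value[idx], sched$duration_s[idx])
}

#' Collapse a tidy TAC table from labels to tissue classes
#'
#' Averages the per-label curves of each tissue class (e.g. the cortical
#' sectors into one "cortex" curve) per subject and frame, so group
#' comparisons can run on the anatomical compartments.
#'
#' @param tacs tidy TAC table (see [cohort_tac_table()]).
#' @param atlas the [label_volume()] the table was extracted from.
#' @return The same tidy layout with `region` = tissue class.
#' @export
collapse_tissue <- function(tacs, atlas) {
  reg <- atlas$regions
  tacs$region <- reg$tissue[match(tacs$label, reg$label)]
  agg <- stats::aggregate(value ~ subject + region + frame + frame_start_s +
                            frame_duration_s + midpoint_s,
                          data = tacs, FUN = mean)
  agg$label <- NA_integer_
  agg[order(agg$subject, agg$region, agg$frame), ]
}

#' Blocked-vs-unblocked group comparison per region and window
#'
#' For each region and each analysis window, compares the window-mean
#' signal between unblocked and blocked subjects with a two-sided unpaired
#' t test (Welch by default; groups of 21 vs 8 with unequal variances),
#' then adjusts p values across regions within each window with the
#' Holm-Sidak step-down ([holm_sidak()]).
#'
#' @param tacs tidy TAC table as produced by [cohort_tac_table()] /
#'   [extract_regional_tacs()]: columns `subject`, `region`,
#'   `frame_start_s`, `frame_duration_s`, `value`.
#' @param blocked named logical vector: `blocked[subject]`.
#' @param windows named list of `c(t0_s, t1_s)` windows (defaults: early
#'   0-10 min, late 30-60 min).
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return Data frame with one row per region x window: means, percent
#'   change (100 * (blocked - unblocked) / unblocked), raw and adjusted p.
#' @export
compare_groups <- function(tacs, blocked,
                           windows = list(early = c(0, 600),
                                          late = c(1800, 3600)),
                           var_equal = FALSE) {
  stopifnot(is.logical(blocked), !is.null(names(blocked)))
  subs <- unique(tacs$subject)
  if (!all(subs %in% names(blocked)))
    stop("blocked status missing for some subjects")
  if (sum(blocked[subs]) < 2 || sum(!blocked[subs]) < 2)
    stop("each group needs at least 2 subjects")
  regions <- unique(tacs$region)
  out <- list()
  for (w in names(windows)) {
    t0 <- windows[[w]][1]; t1 <- windows[[w]][2]
    rows <- lapply(regions, function(rg) {
      d <- tacs[tacs$region == rg, ]
      means <- vapply(split(d, d$subject), tac_window_mean, numeric(1),
                      t0_s = t0, t1_s = t1)
      grp <- blocked[names(means)]
      tt <- stats::t.test(means[grp], means[!grp], var.equal = var_equal)
      m_u <- mean(means[!grp]); m_b <- mean(means[grp])
      data.frame(region = rg, window = w, mean_unblocked = m_u,
                 mean_blocked = m_b,
                 percent_change = 100 * (m_b - m_u) / m_u,
                 raw_p = tt$p.value)
    })
    tab <- do.call(rbind, rows)
    tab$adjusted_p <- holm_sidak(tab$raw_p)$adjusted
    out[[w]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tidy TAC table for a whole cohort
#'
#' Uses the regional curves carried by a `"tac"`-rendered cohort, or
#' extracts them from the rendered volumes for an `"images"` cohort.
#' Values are in SUV units.
#'
#' @param cohort a [generate_cohort()] result.
#' @return Tidy data frame (`subject`, `region`, `label`, `frame`,
#'   `frame_start_s`, `frame_duration_s`, `midpoint_s`, `value`).
#' @export
cohort_tac_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  sched <- cohort$schedule
  reg <- cohort$atlas$regions
  out <- lapply(cohort$subjects, function(s) {
    if (!is.null(s$dynamic)) {
      tab <- extract_regional_tacs(suv(s$dynamic), cohort$atlas,
                                   subject = s$id)
      return(tab)
    }
    tacs <- if (!is.null(s$tacs_noisy)) s$tacs_noisy else s$tacs
    do.call(rbind, lapply(seq_len(nrow(reg)), function(r) {
      data.frame(subject = s$id, region = reg$name[r], label = reg$label[r],
                 frame = seq_len(nrow(sched)),
                 frame_start_s = sched$start_s,
                 frame_duration_s = sched$duration_s,
                 midpoint_s = sched$midpoint_s,
                 value = tacs[[as.character(reg$label[r])]]$value)
    }))
  })
  do.call(rbind, out)
}
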