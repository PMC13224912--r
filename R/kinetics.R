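#' Image-derived input function
#'
#' Extracts the blood-pool time-activity curve from a dynamic image and
#' linearly interpolates the frame-midpoint samples to a fine uniform grid
#' (anchored at Cp(0) = 0), yielding an [input_function()] usable by the
#' Logan estimator. A simplified image-derived input: no partial-volume or
#' spill-over correction is applied, so it is faithful only to the extent
#' the blood pool is resolved.
#'
#' @param dyn a [dynamic_image()].
#' @param blood_mask logical 3D array (or indices) of blood-pool voxels.
#' @param dt_s output sampling interval (default 1 s).
#' @return An [input_function()].
#' @export
idif_extract <- function(dyn, blood_mask, dt_s = 1) {
  if (is.array(blood_mask) && !any(blood_mask)) stop("blood mask is empty")
  if (!is.array(blood_mask) && length(blood_mask) == 0L)
    stop("blood mask is empty")
  tac <- extract_tac(dyn, blood_mask)
  t_end <- dyn$schedule$end_s[nrow(dyn$schedule)]
  grid <- seq(0, t_end, by = dt_s)
  cp <- stats::approx(c(0, tac$midpoint_s), c(0, tac$value), xout = grid,
                      rule = 2)$y
  as_input_function(grid, pmax(cp, 0))
}

# running trapezoidal integral of y(t) from 0, prepending a (0,0) anchor
trapz_running <- function(t, y) {
  tt <- c(0, t); yy <- c(0, y)
  c(0, cumsum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2))[-1]
}

#' Logan graphical estimate of the total volume of distribution
#'
#' Regresses int_0^t CT / CT(t) on int_0^t Cp / CT(t) over the frames with
#' midpoint >= t_star; the slope estimates VT (= K1/k2 for the one-tissue
#' model). Running integrals use trapezoids on the frame midpoints (tissue)
#' and on the fine input grid (plasma).
#'
#' @param tac a `tac` (midpoint_s, value), in the same concentration units
#'   as the input function.
#' @param input_fn an [input_function()].
#' @param t_star_min start of the linear fit range, minutes (default 15,
#'   well past the synthetic cortical peak).
#' @return list with `VT`, `intercept`, `r2`, `n_fit`.
#' @export
logan_vt <- function(tac, input_fn, t_star_min = 15) {
  stopifnot(inherits(input_fn, "input_function"),
            all(c("midpoint_s", "value") %in% names(tac)))
  t_min <- tac$midpoint_s / 60
  fit <- which(t_min >= t_star_min)
  if (length(fit) < 3L)
    stop("need at least 3 frames with midpoint >= t_star")
  if (any(tac$value[fit] <= 0))
    stop("non-positive tissue activity in the fit range")
  int_ct <- trapz_running(t_min, tac$value)
  cp_t_min <- input_fn$time_s / 60
  int_cp_all <- trapz_running(cp_t_min, input_fn$cp)
  int_cp <- stats::approx(cp_t_min, int_cp_all, xout = t_min, rule = 2)$y
  x <- int_cp[fit] / tac$value[fit]
  y <- int_ct[fit] / tac$value[fit]
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  fitted <- cf[1] + cf[2] * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(VT = unname(cf[2]), intercept = unname(cf[1]), r2 = r2,
       n_fit = length(fit))
}

#' Reference-tissue Logan estimate of the distribution volume ratio
#'
#' Reference Logan: regresses int CT / CT on
#' (int Cref + Cref / k2_ref) / CT over frames with midpoint >= t_star;
#' the slope estimates DVR = VT_target / VT_reference.
#'
#' @param tac_target,tac_reference `tac`s on the same schedule.
#' @param t_star_min fit start, minutes.
#' @param k2_ref reference-region efflux rate (1/min) for the correction
#'   term (from generator truth in tests, from configuration in runs).
#' @return list with `DVR`, `intercept`, `r2`, `n_fit`.
#' @export
logan_dvr <- function(tac_target, tac_reference, t_star_min = 15,
                      k2_ref = NULL) {
  stopifnot(all(c("midpoint_s", "value") %in% names(tac_target)),
            all(c("midpoint_s", "value") %in% names(tac_reference)),
            length(tac_target$value) == length(tac_reference$value))
  t_min <- tac_target$midpoint_s / 60
  fit <- which(t_min >= t_star_min)
  if (length(fit) < 3L)
    stop("need at least 3 frames with midpoint >= t_star")
  if (any(tac_target$value[fit] <= 0))
    stop("non-positive target activity in the fit range")
  int_ct <- trapz_running(t_min, tac_target$value)
  int_cr <- trapz_running(t_min, tac_reference$value)
  corr <- if (is.null(k2_ref)) 0 else tac_reference$value / k2_ref
  x <- (int_cr[fit] + corr[fit]) / tac_target$value[fit]
  y <- int_ct[fit] / tac_target$value[fit]
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  fitted <- cf[1] + cf[2] * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(DVR = unname(cf[2]), intercept = unname(cf[1]), r2 = r2,
       n_fit = length(fit))
}

#' Kinetic outcomes for every region of a subject
#'
#' Computes Logan VT (from the supplied or image-derived input function),
#' the VT ratio to the reference region, and the reference-Logan DVR for
#' every regional TAC.
#'
#' @param tacs named list of `tac`s (names = region identifiers).
#' @param input_fn an [input_function()] (arterial or image-derived).
#' @param reference name of the reference region in `tacs`.
#' @param t_star_min fit start, minutes.
#' @param k2_ref reference efflux rate for the DVR correction term.
#' @return Data frame: `region`, `VT`, `VTr`, `DVR`, `t_star_min`,
#'   `fit_r2`.
#' @export
kinetic_outcomes <- function(tacs, input_fn, reference, t_star_min = 15,
                             k2_ref = NULL) {
  stopifnot(reference %in% names(tacs))
  ref_fit <- logan_vt(tacs[[reference]], input_fn, t_star_min)
  rows <- lapply(names(tacs), function(nm) {
    v <- logan_vt(tacs[[nm]], input_fn, t_star_min)
    d <- logan_dvr(tacs[[nm]], tacs[[reference]], t_star_min, k2_ref)
    data.frame(region = nm, VT = v$VT, VTr = v$VT / ref_fit$VT,
               DVR = d$DVR, t_star_min = t_star_min, fit_r2 = v$r2)
  })
  do.call(rbind, rows)
}

#' Agreement between static SUVR and kinetic outcome measures
#'
#' For each region, correlates the late-window SUVR (regional window mean
#' over the reference-region window mean) with the Logan VT ratio and the
#' reference-Logan DVR across the subjects of a cohort — the validation
#' that static late-phase measures track dynamic modelling.
#'
#' @param cohort a [generate_cohort()] result (TAC-level rendering is
#'   sufficient).
#' @param window late analysis window `c(t0_s, t1_s)` (default 30-60 min).
#' @param reference_tissue reference tissue class (default
#'   `"centrum_semiovale"`).
#' @param t_star_min Logan fit start.
#' @return Data frame per region: `region`, `r_vtr`, `p_vtr`, `r_dvr`,
#'   `p_dvr`, `n`.
#' @export
static_vs_kinetic_agreement <- function(cohort, window = c(1800, 3600),
                                        reference_tissue = "centrum_semiovale",
                                        t_star_min = 15) {
  stopifnot(inherits(cohort, "cohort"))
  reg <- cohort$atlas$regions
  ref_labels <- as.character(reg$label[reg$tissue == reference_tissue])
  if (length(ref_labels) == 0L) stop("reference tissue absent from atlas")
  per_subject <- lapply(cohort$subjects, function(s) {
    tacs <- if (!is.null(s$tacs_noisy)) s$tacs_noisy else s$tacs
    ref_tac <- tacs[[ref_labels[1]]]
    if (length(ref_labels) > 1L) {
      for (lb in ref_labels[-1]) ref_tac$value <- ref_tac$value +
          tacs[[lb]]$value
      ref_tac$value <- ref_tac$value / length(ref_labels)
    }
    k2_ref <- s$params[[ref_labels[1]]]$k2_eff
    ref_vt <- logan_vt(ref_tac, s$cp, t_star_min)$VT
    ref_win <- tac_window_mean(ref_tac, window[1], window[2])
    rows <- lapply(as.character(reg$label[reg$tissue != "blood"]),
                   function(lb) {
      tc <- tacs[[lb]]
      data.frame(subject = s$id, region = lb,
                 suvr = tac_window_mean(tc, window[1], window[2]) / ref_win,
                 vtr = logan_vt(tc, s$cp, t_star_min)$VT / ref_vt,
                 dvr = logan_dvr(tc, ref_tac, t_star_min, k2_ref)$DVR)
    })
    do.call(rbind, rows)
  })
  tab <- do.call(rbind, per_subject)
  rows <- lapply(split(tab, tab$region), function(d) {
    a <- pearson_r_p(d$suvr, d$vtr)
    b <- pearson_r_p(d$suvr, d$dvr)
    data.frame(region = d$region[1], r_vtr = a$r, p_vtr = a$p,
               r_dvr = b$r, p_dvr = b$p, n = a$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
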