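#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation; the p value comes from the exact null
#' distribution via t = r sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of
#' freedom, two-sided. Zero variance in either vector is an error (distinct
#' from r = 0).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r`, `p`, `n`.
#' @seealso [pearson_p()] for the p value at a given (r, n).
#' @export
pearson_r_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(r = r, p = pearson_p(r, n), n = n)
}

#' @rdname pearson_r_p
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @return `pearson_p`: the two-sided p value.
#' @examples
#' pearson_p(0.70, 21)  # ~ 0.0004
#' pearson_p(0.14, 21)  # ~ 0.55
#' @export
pearson_p <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Framewise correlation between a dynamic tracer and a static tracer
#'
#' For one region, correlates the per-subject dynamic value of every frame
#' with the per-subject static (FDG-like) value, yielding a correlation
#' curve over the acquisition. Subjects missing either modality are
#' excluded (count reported in the result).
#'
#' @param dynamic_values data frame `subject`, `frame`, `midpoint_s`,
#'   `value` for one region (e.g. one region of [cohort_tac_table()]).
#' @param static_values named numeric: static value per subject.
#' @param scaling label recorded on the curve (e.g. `"SUV"` or
#'   `"SUVR:cerebellum"`).
#' @return A `correlation_curve` data frame: `frame`, `midpoint_s`, `r`,
#'   `p`, `n`, `scaling`; attribute `n_excluded`.
#' @export
framewise_correlation <- function(dynamic_values, static_values,
                                  scaling = "SUV") {
  stopifnot(all(c("subject", "frame", "midpoint_s", "value") %in%
                  names(dynamic_values)))
  subs <- unique(dynamic_values$subject)
  have_static <- subs %in% names(static_values) &
    is.finite(static_values[subs])
  excluded <- sum(!have_static)
  keep <- subs[have_static]
  if (length(keep) < 3L)
    stop("fewer than 3 subjects with both modalities")
  d <- dynamic_values[dynamic_values$subject %in% keep, ]
  frames <- sort(unique(d$frame))
  rows <- lapply(frames, function(f) {
    df <- d[d$frame == f, ]
    x <- df$value[match(keep, df$subject)]
    y <- as.numeric(static_values[keep])
    ct <- pearson_r_p(x, y)
    data.frame(frame = f, midpoint_s = df$midpoint_s[1],
               r = ct$r, p = ct$p, n = ct$n)
  })
  out <- do.call(rbind, rows)
  out$scaling <- scaling
  attr(out, "n_excluded") <- excluded
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Within-subject correlation across atlas regions
#'
#' Correlates the regional means of a windowed dynamic image with the
#' regional means of a static image across the regions of the unaffected
#' (contralateral) hemisphere — the within-subject agreement between a
#' dynamic-tracer phase and the static reference tracer.
#'
#' @param dyn_regional named numeric: windowed dynamic value per region.
#' @param static_regional named numeric: static value per region (same
#'   names).
#' @param regions character vector of region names to use (the unaffected
#'   hemisphere); at least 3.
#' @return list with `r`, `p`, `n`.
#' @export
intrasubject_region_correlation <- function(dyn_regional, static_regional,
                                            regions) {
  if (length(regions) < 3L) stop("need at least 3 regions")
  if (!all(regions %in% names(dyn_regional)) ||
      !all(regions %in% names(static_regional)))
    stop("regional values missing for some regions")
  pearson_r_p(as.numeric(dyn_regional[regions]),
              as.numeric(static_regional[regions]))
}

#' Select analysis time windows from a correlation curve
#'
#' Maximal runs of at least `min_run` consecutive frames with p < alpha,
#' reported as time intervals (start of the first frame to end of the last
#' frame in the run).
#'
#' @param curve a [framewise_correlation()] result.
#' @param sched the [frame_schedule()] the curve was computed on.
#' @param alpha significance threshold (default 0.05, uncorrected along
#'   frames).
#' @param min_run minimum run length in frames (default 3, suppressing
#'   single-frame noise).
#' @return Data frame with `t_start_s`, `t_end_s`, `first_frame`,
#'   `last_frame` (zero rows if no run qualifies).
#' @export
select_windows <- function(curve, sched, alpha = 0.05, min_run = 3L) {
  stopifnot(inherits(sched, "frame_schedule"),
            all(curve$frame %in% seq_len(nrow(sched))))
  sig <- curve$p < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_run)
  out <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                    first_frame = integer(0), last_frame = integer(0))
  for (k in keep) {
    f0 <- curve$frame[starts[k]]
    f1 <- curve$frame[ends[k]]
    out <- rbind(out, data.frame(t_start_s = sched$start_s[f0],
                                 t_end_s = sched$end_s[f1],
                                 first_frame = f0, last_frame = f1))
  }
  out
}
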