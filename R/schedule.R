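#' Frame schedules for dynamic PET acquisitions
#'
#' A frame schedule is the ordered list of (start, duration) pairs, in
#' seconds, describing a dynamic acquisition. Frames must be contiguous
#' (each frame starts where the previous one ends) with strictly positive
#' durations. Frame midpoints are the standard time coordinate for
#' time-activity curves on variable-duration frames.
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param duration_s numeric vector of frame durations (seconds).
#' @return A `frame_schedule`: a data frame with columns `start_s`,
#'   `duration_s`, `end_s` and `midpoint_s`.
#' @examples
#' sched <- frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' frame_midpoints(sched)
#' @export
frame_schedule <- function(start_s, duration_s) {
  if (length(start_s) != length(duration_s) || length(start_s) == 0L)
    stop("start_s and duration_s must be non-empty vectors of equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite")
  if (any(duration_s <= 0))
    stop("frame durations must be positive")
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  end_s <- start_s + duration_s
  if (length(start_s) > 1L &&
      any(abs(start_s[-1L] - end_s[-length(end_s)]) > 1e-9))
    stop("frames must be contiguous: each start must equal the previous end")
  out <- data.frame(
    start_s = as.numeric(start_s),
    duration_s = as.numeric(duration_s),
    end_s = as.numeric(end_s),
    midpoint_s = as.numeric(start_s + duration_s / 2)
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Parse a compact frame-specification string
#'
#' Expands a specification such as `"12x5,6x10,3x20,7x60,4x300,3x600"`
#' (count x duration-in-seconds, comma separated; `×`, whitespace and
#' `*` are tolerated) into a contiguous [frame_schedule()] starting at 0.
#' The default corresponds to a 60-min acquisition in 35 frames.
#'
#' @param spec character scalar, e.g. `"12x5,6x10"`.
#' @return A [frame_schedule()].
#' @examples
#' sched <- parse_frame_spec("12x5,6x10,3x20,7x60,4x300,3x600")
#' nrow(sched)              # 35
#' total_duration(sched)    # 3600 s
#' @export
parse_frame_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("spec must be a single non-empty string")
  clean <- gsub("[[:space:]]", "", spec)
  clean <- gsub("×|\\*", "x", clean)
  tokens <- strsplit(clean, ",", fixed = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("no frame tokens in spec")
  durations <- numeric(0)
  for (tok in tokens) {
    parts <- strsplit(tok, "x", fixed = TRUE)[[1L]]
    ok <- length(parts) == 2L && all(grepl("^[0-9]+$", parts))
    if (!ok) stop(sprintf("malformed frame token '%s' (expected COUNTxSECONDS)", tok))
    n <- as.integer(parts[1L]); d <- as.integer(parts[2L])
    if (n <= 0L || d <= 0L)
      stop(sprintf("malformed frame token '%s': count and duration must be positive", tok))
    durations <- c(durations, rep(d, n))
  }
  starts <- cumsum(c(0, durations[-length(durations)]))
  frame_schedule(starts, durations)
}

#' @rdname frame_schedule
#' @param sched a `frame_schedule`.
#' @export
frame_midpoints <- function(sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  sched$midpoint_s
}

#' @rdname frame_schedule
#' @export
total_duration <- function(sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  sched$end_s[nrow(sched)] - sched$start_s[1L]
}

#' @rdname frame_schedule
#' @export
n_frames <- function(sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  nrow(sched)
}

#' Indices of frames fully contained in a time window
#'
#' A frame belongs to the window `[t0, t1]` iff `start >= t0` and
#' `end <= t1` (full containment; the standard early/late analysis windows
#' align with frame boundaries, so no partial-frame weighting is needed).
#'
#' @param sched a [frame_schedule()].
#' @param t0_s,t1_s window bounds in seconds.
#' @return integer vector of frame indices (possibly empty).
#' @export
frames_in_window <- function(sched, t0_s, t1_s) {
  stopifnot(inherits(sched, "frame_schedule"), t1_s > t0_s)
  which(sched$start_s >= t0_s - 1e-9 & sched$end_s <= t1_s + 1e-9)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f s total (%.1f min)\n",
              nrow(x), total_duration(x), total_duration(x) / 60))
  NextMethod()
}
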