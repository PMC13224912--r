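#' Parametric arterial plasma input function
#'
#' A smooth bolus-plus-tail model of the plasma activity concentration
#' Cp(t): a gamma-variate bolus peak followed by a biexponential washout
#' tail that switches on over the bolus timescale, so Cp(0) = 0, there is a
#' single early peak, and the tail decays monotonically. Units are
#' arbitrary concentration (the cohort generator works in SUV-equivalent
#' units and converts to kBq/mL via dose/weight).
#'
#' @param duration_s total sampled duration in seconds.
#' @param dt_s sampling interval in seconds (must be <= 1 s; the tissue
#'   model integrates on this grid).
#' @param peak_time_min time of the bolus peak, minutes.
#' @param peak_value bolus peak amplitude.
#' @param bolus_sharpness gamma-variate shape parameter alpha; larger is a
#'   narrower bolus.
#' @param tail_fractions amplitudes of the two tail exponentials relative
#'   to `peak_value`.
#' @param tail_halflives_min half-lives of the two tail exponentials,
#'   minutes.
#' @return An `input_function`: list with `time_s`, `cp`, `dt_s`.
#' @examples
#' cp <- input_function(3600)
#' cp$time_s[which.max(cp$cp)] / 60  # bolus peak near 0.75 min
#' @export
input_function <- function(duration_s, dt_s = 0.5,
                           peak_time_min = 0.75, peak_value = 30,
                           bolus_sharpness = 3,
                           tail_fractions = c(0.04, 0.015),
                           tail_halflives_min = c(5, 45)) {
  stopifnot(duration_s > 0, dt_s > 0, dt_s <= 1,
            peak_time_min > 0, peak_value >= 0, bolus_sharpness > 0,
            length(tail_fractions) == 2L, all(tail_fractions >= 0),
            length(tail_halflives_min) == 2L, all(tail_halflives_min > 0))
  t_s <- seq(0, duration_s, by = dt_s)
  tm <- t_s / 60
  tp <- peak_time_min
  a <- bolus_sharpness
  # gamma variate normalised to peak 1 at tp
  bolus <- (tm / tp)^a * exp(a * (1 - tm / tp))
  lam <- log(2) / tail_halflives_min
  ramp <- 1 - exp(-3 * tm / tp)  # tail switches on over the bolus rise
  tail <- ramp * (tail_fractions[1] * exp(-lam[1] * tm) +
                  tail_fractions[2] * exp(-lam[2] * tm))
  cp <- peak_value * (bolus + tail)
  structure(list(time_s = t_s, cp = cp, dt_s = dt_s),
            class = "input_function")
}

#' @rdname input_function
#' @param time_s,cp explicit samples for a measured or image-derived input
#'   function; must start at t = 0 on a uniform grid.
#' @export
as_input_function <- function(time_s, cp) {
  stopifnot(length(time_s) == length(cp), length(time_s) >= 2L)
  if (any(cp < -1e-9)) stop("input function must be non-negative")
  dt <- diff(time_s)
  if (abs(time_s[1]) > 1e-9 || any(abs(dt - dt[1]) > 1e-6))
    stop("input function must be sampled uniformly from t = 0")
  structure(list(time_s = as.numeric(time_s), cp = pmax(cp, 0),
                 dt_s = dt[1]), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  i <- which.max(x$cp)
  cat(sprintf("<input_function> %d samples, dt %.2f s, peak %.2f at %.2f min\n",
              length(x$cp), x$dt_s, x$cp[i], x$time_s[i] / 60))
  invisible(x)
}
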