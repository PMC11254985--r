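#' Time profile container
#'
#' A minimal carrier for one subject's simulated time course: a strictly
#' increasing time grid starting at 0 (minutes) paired with values (plasma or
#' effect-site concentration in ng/mL, or UPDRS change from baseline in
#' points).
#'
#' @param time_min Numeric vector of times in minutes; strictly increasing,
#'   first element 0.
#' @param value Numeric vector of the same length; must be finite.
#' @param unit Free-text unit label carried along for printing/export.
#' @return A `data.frame` of class `time_profile` with columns `time_min` and
#'   `value` and a `unit` attribute.
#' @export
time_profile <- function(time_min, value, unit = "") {
  if (length(time_min) < 2L || time_min[1] != 0 || any(diff(time_min) <= 0))
    stop("`time_min` must be strictly increasing and start at 0", call. = FALSE)
  if (length(value) != length(time_min) || !all(is.finite(value)))
    stop("`value` must be finite and match `time_min` in length", call. = FALSE)
  structure(data.frame(time_min = time_min, value = value),
            unit = unit, class = c("time_profile", "data.frame"))
}

#' Default simulation time grid
#'
#' Uniform grid over the post-dose evaluation window, in minutes. The default
#' (0 to 90 min in 0.25-min steps, 361 points) keeps grid-based peak-time and
#' threshold-crossing errors well below half a minute.
#'
#' @param t_end End of the window (min).
#' @param dt Step (min).
#' @return Numeric vector of times (min).
#' @export
time_grid <- function(t_end = 90, dt = 0.25) {
  stopifnot(t_end > 0, dt > 0, dt < t_end)
  seq(0, t_end, by = dt)
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("time_profile: %d points, %g-%g min%s\n", nrow(x), x$time_min[1],
              x$time_min[nrow(x)],
              if (nzchar(attr(x, "unit"))) paste0(" [", attr(x, "unit"), "]") else ""))
  cat(sprintf("  range of values: %g to %g\n", min(x$value), max(x$value)))
  invisible(x)
}

# trapezoidal integral over the full profile (internal)
trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
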