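# Per-subject endpoint extraction: non-compartmental exposure metrics and the
# five threshold-based clinical response parameters.

#' Exposure metrics (AUC0-90, Cmax, Tmax)
#'
#' Computes non-compartmental exposure summaries from a plasma profile over
#' the 0-90 min evaluation window: `auc_0_90` by the composite trapezoidal
#' rule (ng*min/mL), `cmax` as the maximum sampled concentration (ng/mL), and
#' `tmax` as the earliest time attaining it (min). `tmax` is refined below
#' grid resolution by fitting a parabola through the peak sample and its
#' neighbours; the reported `cmax` stays the sampled maximum.
#'
#' @param cp A [time_profile()] of plasma concentration covering `[0, t_end]`.
#' @param t_end End of the integration window (min), default 90; the profile
#'   must reach it.
#' @return A one-row `data.frame` with `auc_0_90`, `cmax`, `tmax`.
#' @examples
#' exposure_metrics(sc_plasma_profile(sc_pk_params(), 1))
#' @export
exposure_metrics <- function(cp, t_end = 90) {
  stopifnot(inherits(cp, "time_profile"))
  ew <- clip_window(cp$time_min, cp$value, t_end)
  data.frame(auc_0_90 = trapz(ew$t, ew$v),
             cmax = max(ew$v),
             tmax = refined_argmax(ew$t, ew$v))
}

#' Clinical response metrics from a UPDRS change profile
#'
#' Extracts the five response-qualifying parameters over the 0-90 min window
#' from a change-from-baseline profile, against a clinically-relevant-change
#' threshold `mcic` (positive magnitude; a subject responds when the change
#' reaches `-mcic`):
#' \describe{
#'   \item{time_to_response}{first time the profile crosses `-mcic`, by
#'     linear interpolation between grid points (min); `NA` for
#'     non-responders.}
#'   \item{response_duration}{total time spent at or below `-mcic`,
#'     interpolating at every crossing (min); 0 for non-responders.}
#'   \item{auec_0_90}{area under the (sign-flipped) effect curve, i.e. the
#'     trapezoidal integral of `-change` over 0-90 min (UPDRS points * min).}
#'   \item{max_change}{most negative change from baseline (points).}
#'   \item{time_to_max_change}{earliest time attaining it (min), refined by
#'     parabolic interpolation like `tmax`.}
#'   \item{responder_flag}{whether `-mcic` was reached at all.}
#' }
#'
#' @param d_updrs A [time_profile()] (or `data.frame` with `time_min`,
#'   `value`) of UPDRS change from baseline, values <= 0.
#' @param mcic Positive threshold magnitude (UPDRS points).
#' @param t_end End of the evaluation window (min), default 90.
#' @return A one-row `data.frame` with the six fields above.
#' @export
response_metrics <- function(d_updrs, mcic, t_end = 90) {
  if (!is.numeric(mcic) || length(mcic) != 1L || !is.finite(mcic) || mcic <= 0)
    stop("`mcic` must be a single positive number", call. = FALSE)
  ew <- clip_window(d_updrs$time_min, d_updrs$value, t_end)
  response_metrics_vec(ew$t, ew$v, mcic)
}

# vectorless core shared with the trial simulator (t, v already windowed)
response_metrics_vec <- function(t, v, mcic) {
  thr <- -mcic
  max_change <- min(v)
  responder <- max_change <= thr
  ttr <- NA_real_
  dur <- 0
  if (responder) {
    below <- v <= thr
    first <- which(below)[1]
    ttr <- if (first == 1L) t[1] else
      t[first - 1] + (thr - v[first - 1]) / (v[first] - v[first - 1]) *
        (t[first] - t[first - 1])
    # accumulate time below the threshold segment by segment, splitting
    # segments that cross it
    v1 <- v[-length(v)]; v2 <- v[-1]
    dt <- diff(t)
    b1 <- below[-length(below)]; b2 <- below[-1]
    frac <- as.numeric(b1 & b2)
    cross <- b1 != b2
    # sub-length below the line: distance from the below-threshold endpoint
    # to the interpolated crossing
    frac[cross] <- abs((thr - ifelse(b1, v1, v2))[cross] / (v2 - v1)[cross])
    dur <- sum(frac * dt)
  }
  data.frame(time_to_response = ttr,
             response_duration = dur,
             auec_0_90 = trapz(t, -v),
             max_change = max_change,
             time_to_max_change = refined_argmax(t, -v),
             responder_flag = responder)
}

#' All endpoints for one simulated subject
#'
#' Convenience wrapper combining [exposure_metrics()] on the plasma profile
#' and [response_metrics()] on the UPDRS change profile of a
#' [subject_profiles()] table.
#'
#' @param prof A `data.frame` from [subject_profiles()] (columns `time_min`,
#'   `cp`, `d_updrs`).
#' @param mcic Positive response threshold (UPDRS points).
#' @param t_end End of the evaluation window (min).
#' @return A one-row `data.frame` with all nine endpoint fields.
#' @export
subject_endpoints <- function(prof, mcic = 3.25, t_end = 90) {
  ew <- clip_window(prof$time_min, prof$cp, t_end)
  exp_m <- data.frame(auc_0_90 = trapz(ew$t, ew$v), cmax = max(ew$v),
                      tmax = refined_argmax(ew$t, ew$v))
  dw <- clip_window(prof$time_min, prof$d_updrs, t_end)
  cbind(exp_m, response_metrics_vec(dw$t, dw$v, mcic))
}

# -- internals ----------------------------------------------------------------

# restrict a sampled profile to [0, t_end], interpolating the endpoint
clip_window <- function(t, v, t_end) {
  if (t[length(t)] < t_end)
    stop("profile must cover the full window [0, ", t_end, "] min",
         call. = FALSE)
  keep <- t <= t_end
  tt <- t[keep]; vv <- v[keep]
  if (tt[length(tt)] < t_end) {
    vend <- stats::approx(t, v, xout = t_end)$y
    tt <- c(tt, t_end); vv <- c(vv, vend)
  }
  list(t = tt, v = vv)
}

# earliest argmax, refined below grid resolution by the vertex of a parabola
# through the peak and its two neighbours (skipped on plateaus and at the
# window edges, where the sampled time is returned unchanged)
refined_argmax <- function(t, v) {
  i <- which.max(v)
  if (i == 1L || i == length(v)) return(t[i])
  a <- v[i - 1]; b <- v[i]; c <- v[i + 1]
  denom <- a - 2 * b + c
  if (denom >= 0 || a >= b || c >= b) return(t[i])   # plateau or tie
  delta <- 0.5 * (a - c) / denom
  t[i] + max(-0.5, min(0.5, delta)) * (t[i + 1] - t[i])
}
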