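#' Feed schedules
#'
#' Fed-batch feeds are described by a profile (constant rate, linearly
#' rising ramp, or discrete pulses), an active time window, and the
#' composition of the feed solution.  Flow rates are given in ml/min, the
#' working unit of laboratory pumps; internally they are converted to l/h.
#'
#' The linear ramp follows F(t) = F_end / t_end * (t - t_start) for
#' t >= t_start and 0 before.  Note that under this convention the rate
#' actually reached at t_end is F_end * (t_end - t_start) / t_end; the
#' alternative convention that reaches exactly F_end at t_end is available
#' via \code{ramp_convention = "reach_Fend_at_tend"}.
#'
#' @param id feed identifier, e.g. "glc".
#' @param kind "constant", "linear_ramp" or "pulses".
#' @param F constant flow, ml/min (kind = "constant").
#' @param F_end ramp endpoint flow, ml/min (kind = "linear_ramp").
#' @param t_start,t_end active window, h.
#' @param composition named numeric vector, g/l of each model component in
#'   the feed solution (state names of the process model).
#' @param pulses data.frame with columns \code{time} (h) and \code{volume}
#'   (l) for kind = "pulses".
#' @param ramp_convention "as_printed" (default) or "reach_Fend_at_tend".
#' @return object of class \code{mdoe_feed}.
#' @export
feed_schedule <- function(id, kind = c("constant", "linear_ramp", "pulses"),
                          F = NULL, F_end = NULL, t_start = 0, t_end = Inf,
                          composition = numeric(0), pulses = NULL,
                          ramp_convention = c("as_printed", "reach_Fend_at_tend")) {
  kind <- match.arg(kind)
  ramp_convention <- match.arg(ramp_convention)
  if (t_start >= t_end) stop("feed_schedule: t_start must be < t_end")
  if (any(composition < 0)) stop("feed_schedule: negative feed concentration")
  if (kind == "constant" && (is.null(F) || F < 0))
    stop("feed_schedule: constant feed needs F >= 0 (ml/min)")
  if (kind == "linear_ramp" && (is.null(F_end) || F_end < 0))
    stop("feed_schedule: ramp feed needs F_end >= 0 (ml/min)")
  if (kind == "pulses") {
    if (is.null(pulses) || !all(c("time", "volume") %in% names(pulses)))
      stop("feed_schedule: pulses need a data.frame(time, volume)")
    if (any(pulses$volume < 0)) stop("feed_schedule: negative pulse volume")
  }
  structure(list(id = id, kind = kind, F = F, F_end = F_end,
                 t_start = t_start, t_end = t_end,
                 composition = composition, pulses = pulses,
                 ramp_convention = ramp_convention),
            class = "mdoe_feed")
}

#' Instantaneous feed rate
#'
#' @param schedule an \code{mdoe_feed}.
#' @param t time(s), h (>= 0).
#' @return flow in ml/min (vectorized over t).  Pulse feeds return 0: their
#'   volume additions are handled as solver events, not as continuous flow.
#' @examples
#' f <- feed_schedule("glc", "linear_ramp", F_end = 0.42, t_start = 1, t_end = 48)
#' feed_rate(f, 25)  # 0.42/48 * 24 = 0.21 ml/min
#' @export
feed_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "mdoe_feed"))
  if (any(t < 0)) stop("feed_rate: t must be >= 0")
  out <- switch(schedule$kind,
    constant = ifelse(t >= schedule$t_start & t <= schedule$t_end,
                      schedule$F, 0),
    linear_ramp = {
      slope <- if (schedule$ramp_convention == "as_printed")
        schedule$F_end / schedule$t_end
      else
        schedule$F_end / (schedule$t_end - schedule$t_start)
      ifelse(t >= schedule$t_start & t <= schedule$t_end,
             slope * (t - schedule$t_start), 0)
    },
    pulses = rep(0, length(t)))
  if (any(out < 0)) stop("feed_rate: computed negative flow")
  out
}

#' Cumulative fed volume over an interval
#'
#' Exact (analytic) integral of the feed profile, used for the volume
#' balance check of simulated trajectories.
#'
#' @param schedule an \code{mdoe_feed}.
#' @param t0,t1 interval bounds, h.
#' @return volume in liters (pulse volumes inside the interval included).
#' @export
feed_volume <- function(schedule, t0, t1) {
  stopifnot(inherits(schedule, "mdoe_feed"), t1 >= t0)
  a <- max(t0, schedule$t_start)
  b <- min(t1, schedule$t_end)
  vol_ml_min_h <- 0
  if (b > a) {
    vol_ml_min_h <- switch(schedule$kind,
      constant = schedule$F * (b - a),
      linear_ramp = {
        slope <- if (schedule$ramp_convention == "as_printed")
          schedule$F_end / schedule$t_end
        else
          schedule$F_end / (schedule$t_end - schedule$t_start)
        slope / 2 * ((b - schedule$t_start)^2 - (a - schedule$t_start)^2)
      },
      pulses = 0)
  }
  v <- vol_ml_min_h * ML_MIN_TO_L_H
  if (schedule$kind == "pulses") {
    sel <- schedule$pulses$time >= t0 & schedule$pulses$time <= t1
    v <- v + sum(schedule$pulses$volume[sel])
  }
  v
}
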