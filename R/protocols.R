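#' Exercise protocols
#'
#' An exercise protocol is a piecewise work-rate function `W(t)` (watts,
#' time in minutes), zero outside `[t_start, t_end]`, together with the
#' sorted list of its discontinuity times (`events`) which the simulation
#' engine uses as integration restart points so no bout edge is stepped
#' over.
#'
#' @name protocols
NULL

new_protocol <- function(work_rate, t_start, t_end, events, label,
                         extra = list()) {
  structure(c(list(work_rate = work_rate, t_start = t_start, t_end = t_end,
                   events = sort(unique(events)), label = label), extra),
            class = "ms_protocol")
}

#' @export
print.ms_protocol <- function(x, ...) {
  cat(sprintf("Exercise protocol '%s': t = [%g, %g] min, %d events\n",
              x$label, x$t_start, x$t_end, length(x$events)))
  invisible(x)
}

#' Evaluate the work rate of a protocol
#' @param protocol a `ms_protocol`.
#' @param t time (min), vectorised.
#' @return power in watts.
#' @export
protocol_power <- function(protocol, t) protocol$work_rate(t)

#' Incremental ramp protocol to exhaustion
#'
#' Power grows linearly from zero at `slope` W/min until all muscle fibers
#' are recruited (`W = W_max` of the recruitment model), which defines
#' exhaustion and terminates the exercise.  With the default slope of
#' 10 W/min and `W_max = 250` W, type II fibers (recruited above 24% of
#' `W_max`) come in at minute 6 and exhaustion occurs at minute 25 at
#' 250 W.
#'
#' @param slope ramp slope (W/min), > 0.
#' @param t_start exercise onset (min).
#' @param recruitment a [recruitment_model()]; its `W_max` sets the
#'   exhaustion power.
#' @return a `ms_protocol` with extra fields `t_exhaustion` and
#'   `W_peak` (power at the exhaustion event).
#' @export
ramp_protocol <- function(slope = 10, t_start = 0,
                          recruitment = recruitment_model()) {
  stopifnot(slope > 0)
  W_max <- recruitment$W_max
  t_exh <- t_start + W_max / slope
  wr <- function(t) ifelse(t >= t_start & t <= t_exh,
                           slope * (t - t_start), 0)
  new_protocol(wr, t_start, t_exh, c(t_start, t_exh),
               sprintf("ramp %g W/min", slope),
               extra = list(t_exhaustion = t_exh, W_peak = W_max,
                            slope = slope))
}

#' Interval (intermittent) protocol
#'
#' Square wave alternating `W_peak` during work and zero during recovery.
#' Bout durations are given in seconds (interval patterns are
#' conventionally quoted as work:recovery seconds, e.g. 16:32) and
#' converted to minutes internally.
#'
#' @param work_s,rest_s work and recovery durations (s), > 0.
#' @param n_bouts number of work bouts.
#' @param W_peak bout power (W).
#' @param t_start onset (min).
#' @return a `ms_protocol`; `events` contains every bout edge.
#' @export
interval_protocol <- function(work_s, rest_s, n_bouts, W_peak = 250,
                              t_start = 0) {
  stopifnot(work_s > 0, rest_s > 0, n_bouts >= 1)
  wm <- work_s / 60; rm_ <- rest_s / 60
  starts <- t_start + (seq_len(n_bouts) - 1L) * (wm + rm_)
  stops <- starts + wm
  t_end <- stops[n_bouts]
  wr <- function(t) {
    on <- rep(FALSE, length(t))
    for (i in seq_len(n_bouts)) on <- on | (t >= starts[i] & t < stops[i])
    ifelse(on, W_peak, 0)
  }
  new_protocol(wr, t_start, t_end, c(starts, stops),
               sprintf("interval %g:%g s x%d @ %g W",
                       work_s, rest_s, n_bouts, W_peak),
               extra = list(bout_starts = starts, bout_stops = stops,
                            W_peak = W_peak))
}

#' Continuous constant-intensity protocol
#'
#' @param fraction_vo2max exercise intensity as a fraction of the power at
#'   maximal oxygen uptake, in (0, 1].
#' @param duration_min exercise duration (min).
#' @param W_max power at VO2max (W).
#' @param t_start onset (min).
#' @return a `ms_protocol`.
#' @export
continuous_protocol <- function(fraction_vo2max, duration_min,
                                W_max = 250, t_start = 0) {
  stopifnot(fraction_vo2max > 0, fraction_vo2max <= 1, duration_min > 0)
  W <- fraction_vo2max * W_max
  t_end <- t_start + duration_min
  wr <- function(t) ifelse(t >= t_start & t < t_end, W, 0)
  new_protocol(wr, t_start, t_end, c(t_start, t_end),
               sprintf("continuous %.0f%% VO2max, %g min",
                       100 * fraction_vo2max, duration_min),
               extra = list(W_constant = W))
}

#' Fiber-type recruitment model
#'
#' Type I fibers are recruited from exercise onset; type II fibers only
#' above a threshold fraction `theta` of `W_max` (default 24%).  Above the
#' threshold the split is piecewise linear, with both fiber types reaching
#' their power caps simultaneously at `W_max` (default caps 125 W + 125 W
#' at `W_max` = 250 W).
#'
#' @param W_max power at full recruitment (W).
#' @param theta type-II onset as a fraction of `W_max`.
#' @param cap_I,cap_II per-fiber-type peak powers; must sum to `W_max`.
#' @return a `ms_recruitment` object.
#' @export
recruitment_model <- function(W_max = 250, theta = 0.24,
                              cap_I = W_max / 2, cap_II = W_max / 2) {
  stopifnot(W_max > 0, theta > 0, theta < 1)
  if (abs(cap_I + cap_II - W_max) > 1e-9)
    stop("fiber power caps must sum to W_max")
  if (cap_I < theta * W_max)
    stop("cap_I must be at least the type-II onset power")
  structure(list(W_max = W_max, theta = theta, cap_I = cap_I,
                 cap_II = cap_II), class = "ms_recruitment")
}

#' Split total power into fiber-type contributions
#'
#' Below the type-II onset power all work is done by type I fibers; above
#' it, type I power rises linearly to its cap and type II fibers take the
#' growing remainder, so that `W_I + W_II = W` exactly and both reach
#' their caps together at `W_max`.  Requests above `W_max` signal
#' exhaustion: the split saturates and the `"exhausted"` attribute is set.
#'
#' @param W total power (W), vectorised.
#' @param model a [recruitment_model()].
#' @return matrix with columns `W_I`, `W_II`; attribute `exhausted` is
#'   `TRUE` where `W > W_max`.
#' @export
recruit <- function(W, model = recruitment_model()) {
  stopifnot(all(W >= 0))
  W0 <- model$theta * model$W_max
  span <- model$W_max - W0
  Wc <- pmin(W, model$W_max)
  frac <- pmax(Wc - W0, 0) / span
  W_I <- pmin(Wc, W0) + frac * (model$cap_I - W0)
  W_II <- frac * model$cap_II
  out <- cbind(W_I = W_I, W_II = W_II)
  attr(out, "exhausted") <- W > model$W_max
  out
}

#' Fatigue as a decline of type-II power
#'
#' A coarse representation of fatigue: within each work bout the type-II
#' power declines linearly from its nominal value at `decline` (fraction
#' of nominal per minute); type I power is unchanged and total power is
#' the sum, hence non-increasing within a bout.
#'
#' @param enabled logical.
#' @param decline per-bout decline rate of type-II power (fraction/min,
#'   >= 0).
#' @return a `ms_fatigue` object.
#' @export
fatigue_model <- function(enabled = TRUE, decline = 0.05) {
  stopifnot(decline >= 0)
  structure(list(enabled = isTRUE(enabled), decline = decline),
            class = "ms_fatigue")
}

#' Per-fiber power time courses of a protocol
#'
#' Applies the recruitment split (and optionally fatigue) to a protocol,
#' returning the type-I and type-II power as functions of time.  With
#' fatigue enabled, the type-II decline restarts at each work-bout onset.
#'
#' @param protocol a `ms_protocol`.
#' @param recruitment a [recruitment_model()].
#' @param fatigue `NULL` or a [fatigue_model()].
#' @return list with vectorised functions `W_I(t)`, `W_II(t)`, `W(t)`
#'   (total after fatigue) and the protocol `events`.
#' @export
apply_fatigue <- function(protocol, recruitment = recruitment_model(),
                          fatigue = NULL) {
  bout_start <- function(t) {
    ## last protocol event at or before t where the nominal power is > 0
    ev <- protocol$events
    vapply(t, function(ti) {
      prior <- ev[ev <= ti]
      if (!length(prior)) return(protocol$t_start)
      max(prior)
    }, numeric(1))
  }
  W_II_fun <- function(t) {
    sp <- recruit(protocol$work_rate(t), recruitment)
    w2 <- sp[, "W_II"]
    if (!is.null(fatigue) && fatigue$enabled && fatigue$decline > 0) {
      el <- pmax(t - bout_start(t), 0)
      w2 <- w2 * pmax(1 - fatigue$decline * el, 0)
    }
    w2
  }
  W_I_fun <- function(t) recruit(protocol$work_rate(t), recruitment)[, "W_I"]
  list(W_I = W_I_fun, W_II = W_II_fun,
       W = function(t) W_I_fun(t) + W_II_fun(t),
       events = protocol$events)
}

#' Build an exercise protocol from a tabular work-rate file
#'
#' Wraps [load_protocol_table()] into a `ms_protocol` usable by the
#' simulation engine; the tabulated time points become protocol events.
#'
#' @param path delimited file with `time` (min) and `power` (W) columns.
#' @param mode interpolation mode, see [load_protocol_table()].
#' @return a `ms_protocol`.
#' @export
protocol_from_table <- function(path, mode = c("constant", "spline")) {
  f <- load_protocol_table(path, mode = match.arg(mode))
  dom <- attr(f, "domain")
  wr <- function(t) ifelse(t >= dom[1] & t <= dom[2], pmax(f(t), 0), 0)
  ## only genuine discontinuities become solver restart points
  tt <- attr(f, "events")
  pw <- f(tt)
  ev <- c(dom, tt[c(FALSE, abs(diff(pw)) > 0)])
  new_protocol(wr, dom[1], dom[2], ev,
               sprintf("table %s", basename(path)))
}
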