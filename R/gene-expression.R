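#' Transcription rate with constitutive and activated components
#'
#' Every modelled gene transcribes at a constitutive rate `k0` regardless
#' of the considered transcription factors; activated transcription adds
#' `Vmax * Hill(drive_excess)`, where the drive excess is the
#' transcription-factor activity above its resting baseline (so the rate
#' equals `k0` exactly at rest and the fold change stays 1).  Early
#' response genes (NR4A2, NR4A3) and the intermediate factor X are driven
#' by active CREB1 combined multiplicatively with its coactivator CRTC;
#' the delayed gene PPARGC1A is driven by the accumulated protein of
#' factor X.
#'
#' @param drive transcription-factor drive (e.g.
#'   `(CREB1_p/ref) * (CRTC/ref)` or `protein_X`).
#' @param drive0 resting value of the drive.
#' @param k0 constitutive transcription rate (1/min in
#'   baseline-normalised mRNA units).
#' @param Vmax maximal activated transcription rate.
#' @param K Hill constant on the drive excess; `n` Hill coefficient.
#' @return transcription rate (mRNA units/min).
#' @export
transcription_rate <- function(drive, drive0, k0, Vmax, K, n = 1) {
  k0 + Vmax * hill(drive - drive0, K, n)
}

#' Fold change of an observable relative to its pre-exercise baseline
#'
#' @param time time grid (min).
#' @param x trajectory values.
#' @param baseline_end end of the resting baseline segment (min); the
#'   baseline is the mean over `time <= baseline_end` (default: the first
#'   sample).
#' @return vector `x / baseline`.
#' @export
fold_change <- function(time, x, baseline_end = NULL) {
  if (is.null(baseline_end)) {
    base <- x[[1L]]
  } else {
    sel <- time <= baseline_end
    if (!any(sel)) stop("no baseline segment before ", baseline_end, " min")
    base <- mean(x[sel])
  }
  if (!is.finite(base) || base <= 0) stop("invalid baseline value")
  x / base
}

#' Time of the post-exercise expression peak
#'
#' @param time time grid (min).
#' @param x trajectory (e.g. mRNA fold change).
#' @param t_end exercise termination time (min).
#' @param horizon_h minimal post-exercise horizon (h) the trajectory must
#'   cover.
#' @return peak time in hours after exercise end (ties broken to the
#'   earliest).
#' @export
peak_timing <- function(time, x, t_end, horizon_h = 6) {
  post <- time >= t_end
  if (!any(post) || (max(time) - t_end) / 60 < horizon_h - 1e-9)
    stop("trajectory must span at least ", horizon_h, " h after exercise")
  tp <- time[post]; xp <- x[post]
  (tp[which.max(xp)] - t_end) / 60
}

#' Volume-weighted mixed-muscle observable
#'
#' Whole-muscle readouts (as measured in a mixed biopsy) are the
#' fiber-volume-weighted mean of the type I and type II trajectories.
#'
#' @param x_I,x_II per-fiber-type trajectories on a common grid.
#' @param V_I,V_II fiber-type volumes (kg w.w.).
#' @return mixed-muscle trajectory.
#' @export
mixed_muscle <- function(x_I, x_II, V_I = 2, V_II = 2) {
  if (length(x_I) != length(x_II))
    stop("fiber trajectories must share one time grid")
  (V_I * x_I + V_II * x_II) / (V_I + V_II)
}
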