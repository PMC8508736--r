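#' Myoplasmic calcium drive
#'
#' The contraction-averaged myoplasmic Ca2+ concentration rises linearly
#' with the fiber's relative exercise intensity (fraction of its maximal
#' recruitment): `Ca_target = Ca_rest + slope * intensity`.  In
#' simulations the calcium state relaxes towards this target with time
#' constant `tau_Ca`, so the returned value is the steady-state level.
#'
#' @param intensity_fraction fiber work rate over its power cap, in
#'   `[0, 1]`.
#' @param Ca_rest resting myoplasmic calcium (uM).
#' @param slope calcium increase at full recruitment (uM).
#' @return steady-state calcium concentration (uM).
#' @export
calcium_drive <- function(intensity_fraction, Ca_rest = 0.1, slope = 1.5) {
  stopifnot(all(intensity_fraction >= 0), all(intensity_fraction <= 1 + 1e-9))
  Ca_rest + slope * intensity_fraction
}

#' Steady-state phospho-fraction of a kinase under constant drive
#'
#' For phosphorylation dynamics
#' `dP/dt = k_on * (T - P) - k_off * P` the fixed point is
#' `P/T = k_on / (k_on + k_off)`.  Used as the closed-form oracle for
#' CaMKII, CRTC, CREB1 and AMPK steady states in tests and calibration.
#'
#' @param k_on total phosphorylation (or activation) rate constant
#'   (1/min).
#' @param k_off total dephosphorylation rate constant (1/min).
#' @return steady-state fraction in `[0, 1]`.
#' @export
phospho_steady_state <- function(k_on, k_off) k_on / (k_on + k_off)

#' Per-heterotrimer AMPK phosphorylation balance
#'
#' AMPK Thr172 is phosphorylated by LKB1 and by Ca2+/calmodulin-activated
#' CaMKK2, and dephosphorylated at a rate that AMP binding suppresses
#' (protection) and ATP binding restores.  The three muscle heterotrimers
#' (alpha2-beta2-gamma3, alpha2-beta2-gamma1, alpha1-beta2-gamma1) share
#' this law and differ only in parameters; the gamma3 complex combines
#' strong AMP protection with a large CaMKK2 coupling, which is why it is
#' the exercise-responsive species.
#'
#' @param P phosphorylated amount; `total` heterotrimer amount.
#' @param camkk2 CaMKK2 activity (0-1); `lkb1` LKB1 activity (constant 1
#'   by default).
#' @param AMP,ATP free AMP and total ATP (mmol/kg w.w.).
#' @param p parameter list with `k_ph` (basal phosphorylation rate by
#'   LKB1, 1/min), `c_camkk` (CaMKK2 coupling), `k_dp` (maximal
#'   dephosphorylation rate, 1/min), `K_amp` (AMP protection constant,
#'   mmol/kg), `ATP0` (reference ATP).
#' @return `dP/dt` (amount/min).
#' @export
ampk_phospho_rate <- function(P, total, camkk2, lkb1, AMP, ATP, p) {
  k_on <- p$k_ph * (lkb1 + p$c_camkk * camkk2)
  k_off <- p$k_dp * (ATP / p$ATP0) / (1 + AMP / p$K_amp)
  k_on * (total - P) - k_off * P
}

#' AMPK heterotrimer activity
#'
#' `activity = total * baseline + c_act * P * allosteric`, with the
#' allosteric factor a Hill function (coefficient 1) of the AMP/ATP
#' ratio normalised to rest.  The whole-cell AMPK activity is the sum of
#' the three heterotrimer activities.
#'
#' @inheritParams ampk_phospho_rate
#' @param p parameter list with `baseline`, `c_act`, `K_allo`,
#'   `ratio0` (resting AMP/ATP).
#' @return activity (arbitrary units).
#' @export
ampk_activity <- function(P, total, AMP, ATP, p) {
  rel <- (AMP / ATP) / p$ratio0
  total * p$baseline + p$c_act * P * (1 + hill(rel, p$K_allo, 1))
}
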