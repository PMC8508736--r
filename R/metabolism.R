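#' Free ADP and AMP from creatine-kinase / adenylate-kinase equilibria
#'
#' Most cellular ADP is protein-bound; the thermodynamically active (free)
#' concentrations that feed back on energy metabolism and activate AMPK
#' are computed from the near-equilibrium creatine-kinase and
#' adenylate-kinase reactions:
#' `ADP_free = ATP * Cr / (PCr * H * Keq_CK)` and
#' `AMP_free = Keq_AK * ADP_free^2 / ATP`.
#'
#' @param ATP,PCr,Cr concentrations (mmol/kg w.w.).
#' @param H proton concentration in mol/L (e.g. `10^-7.05`).
#' @param Keq_CK creatine-kinase equilibrium constant (1/M).
#' @param Keq_AK adenylate-kinase equilibrium constant (dimensionless).
#' @return named list with `ADP` and `AMP` (mmol/kg w.w.).
#' @export
free_adp_amp <- function(ATP, PCr, Cr, H, Keq_CK = 1.66e9, Keq_AK = 1.05) {
  if (any(PCr <= 0)) stop("PCr must be positive")
  if (any(H <= 0)) stop("H must be positive")
  ADP <- ATP * Cr / (PCr * H * Keq_CK)
  AMP <- Keq_AK * ADP^2 / pmax(ATP, .Machine$double.eps)
  list(ADP = ADP, AMP = AMP)
}

#' Muscle pH from proton concentration (and inverse)
#'
#' Concentrations are carried in mmol/kg w.w. (taken equivalent to
#' mmol/L): `pH = -log10(H * 1e-3)`.
#'
#' @param H proton concentration (mmol/kg w.w.), > 0.
#' @param pH pH value.
#' @return `ph_from_proton`: pH; `proton_from_ph`: mmol/kg w.w.
#' @export
ph_from_proton <- function(H) {
  if (any(H <= 0)) stop("proton concentration must be positive")
  -log10(H * 1e-3)
}

#' @rdname ph_from_proton
#' @export
proton_from_ph <- function(pH) 10^(-pH) * 1e3

#' Normalised Michaelis-Menten modulation
#'
#' `mm_norm(C, C0, Km)` is `C/(Km+C)` scaled to equal 1 at the reference
#' (resting) concentration `C0`.  Rate laws of the reduced metabolic core
#' are written as `J_rest * activation * prod(mm_norm(...))`, which makes
#' the shipped resting state an exact steady state by construction.
#'
#' @param C concentration.
#' @param C0 reference concentration (> 0).
#' @param Km half-saturation constant (> 0).
#' @return dimensionless factor, 1 at `C = C0`.
#' @export
mm_norm <- function(C, C0, Km) {
  (C / (Km + C)) / (C0 / (Km + C0))
}

#' ATPase (contractile ATP hydrolysis) rate
#'
#' Basal ATP hydrolysis scaled by the exercise activation factor; the
#' activation coefficient is fiber-type specific (type II larger,
#' reflecting the higher ATP cost of fast-twitch contraction).
#'
#' @param ATP cytosolic ATP (mmol/kg w.w.).
#' @param act activation factor (from [activation()] or its ODE form),
#'   driven by the fiber's own work rate.
#' @param basal resting hydrolysis flux (mmol/min/kg w.w.).
#' @param ATP0,Km_ATP reference concentration and half-saturation for the
#'   substrate dependence.
#' @return flux (mmol/min/kg w.w.).
#' @export
atpase_rate <- function(ATP, act, basal, ATP0 = 6.2, Km_ATP = 0.5) {
  basal * act * mm_norm(ATP, ATP0, Km_ATP)
}

#' Glycogen synthase rate
#'
#' Exercise increases glycogen-synthase activity even while net glycogen
#' falls; the flux depends on glycogen content only (saturating decrease
#' with glycogen, i.e. relief of product inhibition as stores empty),
#' multiplied by the exercise activation factor, and is identical between
#' fiber types at equal glycogen and work rate.
#'
#' @param glycogen glycogen content (mmol glucosyl/kg w.w.), >= 0.
#' @param act activation factor.
#' @param basal resting synthase flux (mmol/min/kg w.w.).
#' @param gly0 reference (resting) glycogen content.
#' @param K_gly inhibition constant (mmol/kg w.w.).
#' @return flux (mmol/min/kg w.w.).
#' @export
glycogen_synthase_rate <- function(glycogen, act, basal, gly0 = 85,
                                   K_gly = 150) {
  stopifnot(all(glycogen >= 0))
  basal * act * (K_gly / (K_gly + glycogen)) / (K_gly / (K_gly + gly0))
}

#' Hill function
#'
#' `x^n / (K^n + x^n)`, the saturating activation used for
#' calcium-calmodulin binding, allosteric AMP activation and
#' transcription-factor drives.
#'
#' @param x input (>= 0).
#' @param K half-saturation constant.
#' @param n Hill coefficient.
#' @return value in `[0, 1)`.
#' @export
hill <- function(x, K, n = 1) {
  xp <- pmax(x, 0)^n
  xp / (K^n + xp)
}
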