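#' Exercise activation function
#'
#' The multiplicative stress factor applied to physiological variables and
#' metabolic/transport fluxes during exercise,
#' `1 + alpha * W * (1 - exp((t_start - t) / tau))`: unity at rest and at
#' exercise onset, rising monotonically with time constant `tau` towards
#' the asymptote `1 + alpha * W`.
#'
#' This closed form describes the response to a constant work rate applied
#' from `t_start`.  Inside simulations the same response is realised as a
#' first-order state `da/dt = ((1 + alpha * W(t)) - a) / tau`, which
#' coincides with the closed form for constant `W` and extends it
#' continuously to stepwise-changing protocols (each power step relaxes
#' towards its new asymptote with the same `tau`).
#'
#' @param t time (min), vectorised.
#' @param W work rate (W).
#' @param alpha activation coefficient (1/W), >= 0.
#' @param tau time constant (min), > 0.
#' @param t_start exercise onset (min).
#' @return dimensionless factor >= 1.
#' @export
activation <- function(t, W, alpha, tau, t_start = 0) {
  stopifnot(tau > 0, alpha >= 0)
  ifelse(t <= t_start | W == 0, 1,
         1 + alpha * W * (1 - exp((t_start - t) / tau)))
}

#' Activation parameter set
#'
#' @param alpha activation coefficient (1/W).
#' @param tau time constant (min).
#' @param t_start exercise onset (min).
#' @return a list used by [activation()]-based operations.
#' @export
activation_params <- function(alpha, tau, t_start = 0) {
  stopifnot(tau > 0, alpha >= 0)
  list(alpha = alpha, tau = tau, t_start = t_start)
}

#' Muscle blood flow and muscle volume during exercise
#'
#' Both change as linear functions of the work rate with first-order
#' dynamics: `Q = Q0 * activation(t, W; alpha, tau)` and
#' `V_mus = V_mus0 * activation(t, W; alpha, tau)`, with resting blood
#' flow `Q0 = 0.9` L/min (both legs), resting muscle volume
#' `V_mus0 = 5` kg wet weight, and time constants
#' `tau_Q = tau_V = 0.4` min.
#'
#' @param t time (min).
#' @param W work rate (W).
#' @param Q0 resting muscle blood flow (L/min).
#' @param V_mus0 resting muscle volume (kg w.w.).
#' @param alpha activation coefficient (1/W).
#' @param tau time constant (min).
#' @param t_start exercise onset (min).
#' @return `blood_flow`: Q in L/min; `muscle_volume`: V_mus in kg w.w.
#' @export
blood_flow <- function(t, W, Q0 = 0.9, alpha = 0.0165, tau = 0.4,
                       t_start = 0) {
  Q0 * activation(t, W, alpha, tau, t_start)
}

#' @rdname blood_flow
#' @export
muscle_volume <- function(t, W, V_mus0 = 5, alpha = 0.002, tau = 0.4,
                          t_start = 0) {
  V_mus0 * activation(t, W, alpha, tau, t_start)
}

#' Passive (diffusive) inter-compartment flux
#'
#' `lambda * (C_a - C_b) * act`: linear diffusion scaled by the
#' permeability-surface area coefficient and the exercise activation
#' factor.  Antisymmetric in the two concentrations and zero at
#' equilibrium.  Used for CO2, O2, alanine and glycerol between blood and
#' cytosol and for CO2 and O2 between cytosol and mitochondria.
#'
#' @param C_a,C_b concentrations on the two sides (mmol/kg w.w.).
#' @param lambda permeability-surface area coefficient
#'   (1/min, per kg w.w.).
#' @param act activation factor (dimensionless, >= 1 during exercise).
#' @return flux (mmol/min/kg w.w.), positive from side a to side b.
#' @export
passive_flux <- function(C_a, C_b, lambda, act = 1) {
  lambda * (C_a - C_b) * act
}

#' Facilitated (carrier-mediated) inter-compartment flux
#'
#' `Rmax * (C_a/(KM + C_a) - C_b/(KM + C_b)) * act`: saturating
#' carrier-mediated transport, bounded by `±Rmax * act`, zero at equal
#' concentrations.  Used for glucose, pyruvate, lactate, free fatty acids
#' and protons between blood and cytosol, and for protons, pyruvate,
#' fatty acyl-CoA, CoA and inorganic phosphate between cytosol and
#' mitochondria.
#'
#' @param C_a,C_b concentrations on the two sides (mmol/kg w.w.).
#' @param Rmax maximal flux (mmol/min/kg w.w.).
#' @param KM half-saturation constant (mmol/kg w.w.).
#' @param act activation factor.
#' @return flux (mmol/min/kg w.w.), positive from side a to side b.
#' @export
facilitated_flux <- function(C_a, C_b, Rmax, KM, act = 1) {
  Rmax * (C_a / (KM + C_a) - C_b / (KM + C_b)) * act
}

#' Capillary-blood mass balance
#'
#' `dC_bl/dt = (Q * (C_art - C_bl) - T_R * V_R - T_W * V_W) / V_bl`:
#' arterial wash-in minus the volume-weighted uptake of the two fiber
#' types, over the effective blood + interstitial volume.
#'
#' @param C_bl,C_art capillary and arterial concentrations (mmol/kg w.w.).
#' @param Q blood flow (L/min; 1 L is taken equivalent to 1 kg w.w.).
#' @param T_R,T_W blood-to-cytosol transport flux into type I and type II
#'   fibers (mmol/min/kg w.w. of fiber).
#' @param V_R,V_W fiber volumes (kg w.w.).
#' @param V_bl blood + interstitial volume (kg w.w.).
#' @return dC_bl/dt (mmol/kg w.w./min).
#' @export
blood_rhs <- function(C_bl, C_art, Q, T_R, T_W, V_R = 2, V_W = 2,
                      V_bl = 1) {
  (Q * (C_art - C_bl) - T_R * V_R - T_W * V_W) / V_bl
}

#' Compartment volumes of the two fiber types
#'
#' Cytosol and mitochondria partition each fiber volume: 88% / 12% in
#' type I (high mitochondrial content) and 92% / 8% in type II; by default
#' each fiber type occupies half of the 4 kg w.w. tissue volume
#' (`V_tis = 0.8 * V_mus`, `V_mus = 5` kg w.w.).
#'
#' @param V_R,V_W fiber-type volumes (kg w.w.).
#' @param mito_R,mito_W mitochondrial volume fractions.
#' @return named list with `V_R`, `V_W`, `V_cyt_R`, `V_mit_R`, `V_cyt_W`,
#'   `V_mit_W`.
#' @export
fiber_volumes <- function(V_R = 2, V_W = 2, mito_R = 0.12, mito_W = 0.08) {
  stopifnot(V_R > 0, V_W > 0, mito_R > 0, mito_R < 1, mito_W > 0,
            mito_W < 1)
  list(V_R = V_R, V_W = V_W,
       V_cyt_R = (1 - mito_R) * V_R, V_mit_R = mito_R * V_R,
       V_cyt_W = (1 - mito_W) * V_W, V_mit_W = mito_W * V_W)
}
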