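#' Default model configuration
#'
#' One nested list holds every tunable quantity of the simulator:
#' physiology (volumes, resting blood flow, activation of flow/volume),
#' recruitment and fatigue settings, resting concentrations per
#' compartment, metabolic rate-law parameters (resting fluxes, activation
#' coefficients per fiber type, half-saturation constants, equilibrium
#' speeds), transport half-saturations and activation, signalling rate
#' constants (calcium, CaMKII, calcineurin/CRTC, the three AMPK
#' heterotrimers, CREB1), gene-expression kinetics and solver settings.
#'
#' Units: time min, power W, volumes kg wet weight (1 kg w.w. taken
#' equivalent to 1 L for blood-flow coupling), concentrations mmol/kg
#' w.w. (calcium in uM, mRNA in baseline-normalised units), fluxes
#' mmol/min/kg w.w.
#'
#' Resting concentrations are typical human vastus lateralis literature
#' values and are calibration inputs of this package; all resting fluxes
#' are balanced exactly at these concentrations by
#' [derive_parameters()], so the rest state is a steady state by
#' construction.
#'
#' @param overrides optional named list merged recursively over the
#'   defaults (e.g. `list(signaling = list(tau_Ca = 1))`).
#' @return a `ms_config` list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    physiology = list(
      Q0 = 0.9,            # resting muscle blood flow, both legs (L/min)
      V_mus0 = 5,          # resting muscle volume (kg w.w.)
      blood_frac = 0.2,    # V_bl = 0.2 * V_mus
      alpha_Q = 0.02, alpha_V = 0.0004, tau_QV = 0.4,
      V_R = 2, V_W = 2,    # fiber-type volumes (kg w.w.)
      mito_R = 0.12, mito_W = 0.08),

    recruitment = list(W_max = 250, theta = 0.24, cap_I = 125, cap_II = 125),
    fatigue = list(enabled = FALSE, decline = 0.05),

    rest = list(
      blood = c(O2 = 6.0, CO2 = 1.2, Glc = 4.2, Lac = 1.0, Pyr = 0.08,
                Ala = 0.45, Glr = 0.06, FFA = 0.7, H = 3.981072e-05),
      cyt = list(
        I = c(ATP = 6.2, PCr = 20, Cr = 13, Pi = 2.9, Gly = 80,
              Glc = 0.5, Pyr = 0.1, Lac = 1.1, Ala = 0.6, Glr = 0.08,
              FFA = 0.3, FAC = 0.01, CoA = 0.02, O2 = 4.0, CO2 = 1.5,
              H = 8.912509e-05),
        II = c(ATP = 6.2, PCr = 23, Cr = 11, Pi = 2.9, Gly = 90,
               Glc = 0.5, Pyr = 0.1, Lac = 1.1, Ala = 0.6, Glr = 0.08,
               FFA = 0.3, FAC = 0.01, CoA = 0.02, O2 = 4.0, CO2 = 1.5,
               H = 8.912509e-05)),
      mit = c(Pyr = 0.06, O2 = 3.9, CO2 = 1.6, NADH = 0.3, FAC = 0.005,
              CoA = 0.025, Pi = 2.9, H = 8.912509e-05)),

    metabolism = list(
      ## resting flux routing (mmol/min per kg w.w. of fiber)
      atpase0 = c(I = 0.30, II = 0.25),
      fat_share = c(I = 0.60, II = 0.40),  # share of resting NADH from fat
      lac_rel0 = 0.012, ala_rel0 = 0.001, pyr_rel0 = 0.0005,
      gp0 = 0.002,           # resting glycogen turnover (= synthase flux)
      lipolysis0 = 0.0002,   # glycerol release (3 FFA freed per glycerol)
      P_per_NADH = 2.5, nadh_per_pyr = 5, co2_per_pyr = 3,
      nadh_per_fac = 46, co2_per_fac = 16,
      atp_cost_gs = 2, atp_cost_fac = 2,
      h_per_atpase = 0.3, h_per_lac = 1,
      n_ADP_ox = 3,      # steepness of ADP respiratory control
      NAD_tot = 3.0, buffer_beta = 22,   # mmol/kg w.w. per pH unit
      Keq_CK = 1.66e9, Keq_AK = 1.05,
      ## equilibrium-enzyme speeds (per kg fiber)
      k_CK = 5, k_AK = 10, k_LDH = 20, k_ALT = 2,
      ## substrate half-saturations (mmol/kg w.w.)
      Km = list(ATP_atpase = 0.5, Gly_gp = 20, Glc_gly = 0.3,
                Pi_gly = 1.5, ADP_gly = 0.30, K_gly_gs = 150,
                Pyr_pdh = 0.08, NAD_pdh = 1.0, FAC_box = 0.004,
                NADH_ox = 0.15, O2_ox = 0.50, ADP_ox = 0.80, Pi_ox = 2.0,
                FFA_fac = 0.2, CoA_fac = 0.01),
      ## activation coefficients (1/W of fiber power) and time constants
      alpha = list(
        atpase = c(I = 0.30, II = 0.36),
        glycolysis = c(I = 0.50, II = 1.20),
        gp = c(I = 1.6, II = 3.2),
        gs = c(I = 0.02, II = 0.02),      # equal in both fiber types
        pdh = c(I = 0.50, II = 0.45),
        fat = c(I = 0.24, II = 0.30),
        ox = c(I = 0.035, II = 0.032),
        lipolysis = c(I = 0.02, II = 0.02)),
      tau = list(atpase = 0.18, glycolysis = 0.25, gp = 0.25, gs = 1,
                 pdh = 0.25, fat = 1, ox = 0.3, lipolysis = 2)),

    transport = list(
      ## blood <-> cytosol: passive CO2, O2, Ala, Glr; facilitated rest
      KM_bl = c(Glc = 1.5, Pyr = 0.15, Lac = 2.0, FFA = 0.3, H = 1e-4),
      alpha_bl = c(O2 = 0.15, CO2 = 0.30, Glc = 0.06, Lac = 0.06,
                   Pyr = 0.05, Ala = 0.02, Glr = 0.02, FFA = 0.40,
                   H = 0.15),
      ## cytosol <-> mitochondria: passive CO2, O2; facilitated rest
      KM_mt = c(Pyr = 0.1, FAC = 0.01, CoA = 0.02, Pi = 2.0, H = 1e-4),
      alpha_mt = c(O2 = 0.05, CO2 = 0.15, Pyr = 0.45, FAC = 0.25,
                   CoA = 0.25, Pi = 0.05, H = 0.05),
      Rmax_Pi_mt = 0.5, Rmax_H_mt = 0.2,   # zero resting net flux
      Rmax_H_bl = 0.6,   # acid extrusion capacity (mmol/min/kg fiber)
      ## blood carries acid on buffers: each unit of free-H arterial-venous
      ## difference transports sigma_H_blood units of titratable acid
      sigma_H_blood = 2.5e5, beta_blood = 25,
      tau = 0.4),

    signaling = list(
      Ca_rest = 0.1, Ca_slope = 1.5, tau_Ca = 0.5,   # uM, min
      K_CaM = 1.0, n_CaM = 4,
      camkii = list(k_basal = 0.01, k_cam = 0.6, k_dp = 0.3),
      calcineurin = list(K = 0.3),
      camkk2 = list(K = 0.5),
      crtc = list(k_basal = 0.005, k_cn = 0.5, k_rp = 0.13),
      lkb1 = 1,
      ampk = list(
        ## totals: heterotrimer shares of the muscle AMPK pool
        total = c(a2b2g1 = 0.65, a2b2g3 = 0.20, a1b2g1 = 0.15),
        a2b2g3 = list(k_ph = 0.02, c_camkk = 64, k_dp = 1.9,
                      K_amp = 2e-3, ATP0 = 6.2, baseline = 0.2,
                      c_act = 1, K_allo = 3, ratio0 = 2.0e-5),
        a2b2g1 = list(k_ph = 0.01, c_camkk = 0.15, k_dp = 0.28,
                      K_amp = 0.1, ATP0 = 6.2, baseline = 1.0,
                      c_act = 1, K_allo = 3, ratio0 = 2.0e-5),
        a1b2g1 = list(k_ph = 0.01, c_camkk = 0.15, k_dp = 0.33,
                      K_amp = 0.1, ATP0 = 6.2, baseline = 1.0,
                      c_act = 1, K_allo = 3, ratio0 = 2.0e-5)),
      creb = list(k_basal = 0.01, k_camkii = 0.5, k_ampk = 0.05,
                  k_dp = 0.25)),

    genes = list(
      ## drive = (CREB1_p/ref) * (CRTC_active/ref); excess over rest
      K_drive = 30, n_drive = 1,
      NR4A3 = list(k_deg = 0.05, fold_max = 14),
      NR4A2 = list(k_deg = 0.023, fold_max = 9),
      X = list(k_deg = 0.025, fold_max = 6, k_trans = 0.1,
               k_deg_prot = 0.008),
      PPARGC1A = list(k_deg = 0.006, fold_max = 8, K_X = 8),
      direct_creb_regulation = FALSE,
      x_factor_enabled = TRUE),

    solver = list(rtol = 1e-8, atol = 1e-10, dt_out = 0.1))

  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = c("ms_config", "list"))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    o <- over[[nm]]
    ## YAML represents named numeric vectors as maps; coerce to the
    ## shape the defaults use
    if (is.list(o) && is.numeric(base[[nm]]) && length(o) &&
        all(vapply(o, is.numeric, logical(1))))
      o <- unlist(o)
    if (is.list(o) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], o)
    else if (is.numeric(o) && is.numeric(base[[nm]]) &&
             !is.null(names(base[[nm]])) && !is.null(names(o))) {
      v <- base[[nm]]; v[names(o)] <- o
      base[[nm]] <- v
    } else base[[nm]] <- o
  }
  base
}

#' Read or write a configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `ms_config` list.
#' @return `read_config`: a `ms_config` (defaults overridden by the file
#'   contents); `write_config`: the path, invisibly.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ## named numeric vectors become YAML maps (atomic vectors would lose
  ## their names as plain sequences)
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(config)), path)
  invisible(path)
}

#' Derive the rest-balanced kinetic parameters
#'
#' Solves the resting flux routing for each fiber type so that every
#' metabolite is at steady state at the configured resting
#' concentrations: the resting NADH turnover follows from the ATP
#' balance (hydrolysis + synthase and fatty-acid-activation costs =
#' glycolytic + oxidative production), pyruvate production matches
#' oxidation plus lactate/alanine/pyruvate release, and every transport
#' coefficient (`lambda`, `Rmax`) and arterial concentration is chosen to
#' carry exactly the required resting flux down the configured
#' concentration gradient.  Free resting ADP/AMP come from the
#' creatine-kinase/adenylate-kinase equilibria, which also fix the
#' apparent equilibrium constants of the explicit CK/AK/LDH/ALT
#' reactions.
#'
#' @param config a `ms_config`.
#' @return nested list with per-fiber resting fluxes, transport
#'   coefficients, arterial concentrations and apparent equilibrium
#'   constants.
#' @export
derive_parameters <- function(config = default_config()) {
  met <- config$metabolism
  tr <- config$transport
  phy <- config$physiology
  fibers <- c("I", "II")

  per_fiber <- lapply(fibers, function(ft) {
    cyt <- config$rest$cyt[[ft]]
    mit <- config$rest$mit
    a0 <- met$atpase0[[ft]]
    fs <- met$fat_share[[ft]]
    S <- met$lac_rel0 + met$ala_rel0 + met$pyr_rel0
    ## resting NADH turnover from the ATP balance
    J_N <- (a0 + met$atp_cost_gs * met$gp0 - 1.5 * S) /
      (1.5 * (1 - fs) / met$nadh_per_pyr + met$P_per_NADH -
         met$atp_cost_fac * fs / met$nadh_per_fac)
    J_pdh <- (1 - fs) * J_N / met$nadh_per_pyr
    J_box <- fs * J_N / met$nadh_per_fac
    G <- (J_pdh + S) / 2                      # glycolytic hexose flux
    J_fac <- J_box
    ffa_uptake <- J_fac - 3 * met$lipolysis0
    if (ffa_uptake < 0)
      stop("lipolysis exceeds fatty-acid activation at rest (fiber ", ft, ")")
    o2 <- J_N / 2
    co2 <- met$co2_per_pyr * J_pdh + met$co2_per_fac * J_box
    ## proton stoichiometry of oxidative phosphorylation closes the
    ## resting proton balance (ATPase + lactate - efflux)
    c_H_ox <- met$h_per_atpase * a0 / J_N

    ## free nucleotides and apparent equilibrium constants
    eq <- free_adp_amp(cyt[["ATP"]], cyt[["PCr"]], cyt[["Cr"]],
                       cyt[["H"]] * 1e-3, met$Keq_CK, met$Keq_AK)
    Keq_CK_app <- cyt[["ATP"]] * cyt[["Cr"]] / (cyt[["PCr"]] * eq$ADP)
    Keq_AK_app <- cyt[["ATP"]] * eq$AMP / eq$ADP^2
    Keq_LDH_app <- cyt[["Lac"]] / (cyt[["Pyr"]] - met$lac_rel0 / met$k_LDH)
    Keq_ALT_app <- cyt[["Ala"]] / (cyt[["Pyr"]] - met$ala_rel0 / met$k_ALT)

    ## blood <-> cytosol transport: positive flux = uptake by the fiber
    bl <- config$rest$blood
    F_bl <- c(O2 = o2, CO2 = -co2, Glc = G, Lac = -met$lac_rel0,
              Pyr = -met$pyr_rel0, Ala = -met$ala_rel0,
              Glr = -met$lipolysis0, FFA = ffa_uptake, H = -met$lac_rel0)
    lambda_bl <- c(O2 = NA, CO2 = NA, Ala = NA, Glr = NA)
    for (sp in names(lambda_bl))
      lambda_bl[[sp]] <- F_bl[[sp]] / (bl[[sp]] - cyt[[sp]])
    Rmax_bl <- c(Glc = NA, Pyr = NA, Lac = NA, FFA = NA)
    for (sp in names(Rmax_bl)) {
      km <- tr$KM_bl[[sp]]
      Rmax_bl[[sp]] <- F_bl[[sp]] /
        (bl[[sp]] / (km + bl[[sp]]) - cyt[[sp]] / (km + cyt[[sp]]))
    }
    if (any(c(lambda_bl, Rmax_bl) <= 0))
      stop("resting blood-cytosol gradients inconsistent with fluxes (fiber ",
           ft, ")")

    ## cytosol <-> mitochondria: positive flux = into mitochondria
    F_mt <- c(O2 = o2, CO2 = -co2, Pyr = J_pdh, FAC = J_box, CoA = -J_box)
    lambda_mt <- c(O2 = F_mt[["O2"]] / (cyt[["O2"]] - mit[["O2"]]),
                   CO2 = F_mt[["CO2"]] / (cyt[["CO2"]] - mit[["CO2"]]))
    Rmax_mt <- c(Pyr = NA, FAC = NA, CoA = NA)
    for (sp in names(Rmax_mt)) {
      km <- tr$KM_mt[[sp]]
      Rmax_mt[[sp]] <- F_mt[[sp]] /
        (cyt[[sp]] / (km + cyt[[sp]]) - mit[[sp]] / (km + mit[[sp]]))
    }
    Rmax_mt <- c(Rmax_mt, Pi = tr$Rmax_Pi_mt, H = tr$Rmax_H_mt)
    if (any(c(lambda_mt, Rmax_mt) <= 0))
      stop("resting cytosol-mitochondria gradients inconsistent (fiber ",
           ft, ")")

    list(J_N = J_N, J_pdh = J_pdh, J_box = J_box, G = G, J_fac = J_fac,
         ffa_uptake = ffa_uptake, o2 = o2, co2 = co2, c_H_ox = c_H_ox,
         ADP0 = eq$ADP, AMP0 = eq$AMP,
         Keq_CK_app = Keq_CK_app, Keq_AK_app = Keq_AK_app,
         Keq_LDH_app = Keq_LDH_app, Keq_ALT_app = Keq_ALT_app,
         F_bl = F_bl, lambda_bl = lambda_bl, Rmax_bl = Rmax_bl,
         F_mt = F_mt, lambda_mt = lambda_mt, Rmax_mt = Rmax_mt)
  })
  names(per_fiber) <- fibers

  ## arterial concentrations balance the resting blood compartment
  bl <- config$rest$blood
  C_art <- bl
  for (sp in names(bl)) {
    tot <- per_fiber$I$F_bl[[sp]] * phy$V_R + per_fiber$II$F_bl[[sp]] * phy$V_W
    carry <- if (sp == "H") tr$sigma_H_blood else 1
    C_art[[sp]] <- bl[[sp]] + tot / (phy$Q0 * carry)
  }
  if (any(C_art < 0)) stop("negative arterial concentration in rest balance")

  list(fiber = per_fiber, C_art = C_art)
}
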