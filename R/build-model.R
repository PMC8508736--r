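## Assembly of the integrated modular muscle model.
##
## Module graph (one blood module, per fiber type t in {R = type I,
## W = type II}: transport, cytosol, mitochondria, intra-fiber transport,
## signalling, gene expression, plus one protocol module):
##
##   aprot --(W buses)--> blood, cyt*, mit*, sig*, zbl*, zmt*
##   blood <==(9 species buses)==> zblR/zblW <--> cytR/cytW
##   cyt* <--> zmt* <--> mit*;  mit* draws cytosolic ADP/Pi/H for
##   oxidative ATP synthesis;  sig* reads ATP/PCr/Cr/H;  zgn* reads
##   CREB1_p/CRTC_a from sig*.
##
## Fiber modules of the two types are built by one constructor and differ
## only in parameter values.

BLOOD_SPECIES <- c("O2", "CO2", "Glc", "Lac", "Pyr", "Ala", "Glr", "FFA", "H")
MITO_TRANSPORT <- c("O2", "CO2", "Pyr", "FAC", "CoA", "Pi", "H")

pvars <- function(x) {
  lapply(names(x), function(nm) ms_variable(nm, x[[nm]], kind = "parameter"))
}

## first-order activation state: da/dt = ((1 + alpha * W) - a) / tau
act_rule <- function(state, alpha_par, tau_par, W_var = "W_f") {
  ms_rate_rule(state, bquote(
    ((1 + .(as.name(alpha_par)) * .(as.name(W_var))) - .(as.name(state))) /
      .(as.name(tau_par))))
}

## ---- protocol module -------------------------------------------------

protocol_module <- function(power) {
  module_def(
    "aprot",
    variables = pvars(c(W_tot = 0, W_I = 0, W_II = 0)),
    assignments = list(
      ms_assignment("W_tot", quote(fW_tot(t))),
      ms_assignment("W_I", quote(fW_I(t))),
      ms_assignment("W_II", quote(fW_II(t)))),
    ports = list(ms_port("W_tot", direction = "output"),
                 ms_port("W_I", direction = "output"),
                 ms_port("W_II", direction = "output")),
    functions = list(fW_tot = power$W, fW_I = power$W_I, fW_II = power$W_II))
}

## ---- capillary blood module ------------------------------------------

blood_module <- function(config, derived) {
  phy <- config$physiology
  bl <- config$rest$blood
  sp_vars <- lapply(BLOOD_SPECIES, function(sp)
    ms_variable(sp, bl[[sp]], compartment = "blood",
                buffered = if (sp == "H") "beta_H_bl" else NA_character_))
  pars <- pvars(c(
    Q0 = phy$Q0, Vmus0 = phy$V_mus0, blood_frac = phy$blood_frac,
    alpha_Q = phy$alpha_Q, alpha_V = phy$alpha_V, tau_QV = phy$tau_QV,
    sigma_H = config$transport$sigma_H_blood,
    beta_H_bl = config$transport$beta_blood,
    W_tot = 0,
    ## assignment targets (initialised to resting values)
    Q = phy$Q0, V_mus = phy$V_mus0, V_bl = phy$blood_frac * phy$V_mus0,
    stats::setNames(as.numeric(derived$C_art[BLOOD_SPECIES]),
                    paste0("Cart_", BLOOD_SPECIES))))
  acts <- list(ms_variable("act_Q", 1), ms_variable("act_V", 1))

  washes <- lapply(BLOOD_SPECIES, function(sp) {
    carry <- if (sp == "H") quote(Q * sigma_H) else quote(Q)
    ms_reaction(paste0("wash_", sp),
                products = stats::setNames(1, sp),
                rate = bquote(.(carry) *
                                (.(as.name(paste0("Cart_", sp))) -
                                   .(as.name(sp)))))
  })

  module_def(
    "blood",
    variables = c(sp_vars, acts, pars),
    reactions = washes,
    assignments = list(
      ms_assignment("Q", quote(Q0 * act_Q)),
      ms_assignment("V_mus", quote(Vmus0 * act_V)),
      ms_assignment("V_bl", quote(blood_frac * V_mus))),
    rate_rules = list(act_rule("act_Q", "alpha_Q", "tau_QV", "W_tot"),
                      act_rule("act_V", "alpha_V", "tau_QV", "W_tot")),
    ports = c(lapply(BLOOD_SPECIES, function(sp)
      ms_port(sp, direction = "contact")),
      list(ms_port("W_tot", direction = "input"))),
    compartments = c(blood = "V_bl"))
}

## extra variables the assignments above target
blood_module_vars <- function(m) m   # (assignment targets must be declared)

## ---- blood <-> cytosol transport module ------------------------------

bl_transport_module <- function(name, ft, config, derived, comp_cyt) {
  tr <- config$transport
  der <- derived$fiber[[ft]]
  bl <- config$rest$blood
  cyt <- config$rest$cyt[[ft]]
  V_f <- if (ft == "I") config$physiology$V_R else config$physiology$V_W

  vars <- list(); reactions <- list(); rules <- list(); ports <- list()
  pars <- c(V_f = V_f, W_f = 0, tau_tr = tr$tau)

  for (sp in BLOOD_SPECIES) {
    b <- paste0(sp, "_b"); cc <- paste0(sp, "_c")
    vars <- c(vars, list(
      ms_variable(b, bl[[sp]], compartment = "blood"),
      ms_variable(cc, cyt[[sp]], compartment = comp_cyt),
      ms_variable(paste0("act_", sp), 1)))
    pars[paste0("alpha_", sp)] <- tr$alpha_bl[[sp]]
    rules <- c(rules, list(act_rule(paste0("act_", sp),
                                    paste0("alpha_", sp), "tau_tr")))
    passive <- sp %in% c("O2", "CO2", "Ala", "Glr")
    reactants <- stats::setNames(1, b); products <- stats::setNames(1, cc)
    if (passive) {
      pars[paste0("lam_", sp)] <- der$lambda_bl[[sp]]
      rate <- bquote(V_f * passive_flux(.(as.name(b)), .(as.name(cc)),
                                        .(as.name(paste0("lam_", sp))),
                                        .(as.name(paste0("act_", sp)))))
    } else if (sp == "H") {
      ## lumped acid extruders (NHE/NBC): no net flux at the resting
      ## transmembrane pH gradient, export when the cytosol acidifies
      pars["Rmax_H"] <- tr$Rmax_H_bl * V_f / V_f  # per kg fiber
      pars["KM_H"] <- tr$KM_bl[["H"]]
      pars["frH_c0"] <- cyt[["H"]] / (tr$KM_bl[["H"]] + cyt[["H"]])
      pars["frH_b0"] <- bl[["H"]] / (tr$KM_bl[["H"]] + bl[["H"]])
      reactants <- stats::setNames(1, cc); products <- stats::setNames(1, b)
      rate <- bquote(V_f * Rmax_H *
                       ((.(as.name(cc)) / (KM_H + .(as.name(cc)))) / frH_c0 -
                          (.(as.name(b)) / (KM_H + .(as.name(b)))) / frH_b0) *
                       .(as.name(paste0("act_", sp))))
    } else {
      pars[paste0("Rmax_", sp)] <- der$Rmax_bl[[sp]]
      pars[paste0("KM_", sp)] <- tr$KM_bl[[sp]]
      rate <- bquote(V_f * facilitated_flux(.(as.name(b)), .(as.name(cc)),
                                            .(as.name(paste0("Rmax_", sp))),
                                            .(as.name(paste0("KM_", sp))),
                                            .(as.name(paste0("act_", sp)))))
    }
    if (sp == "Lac") {
      ## monocarboxylate transport carries one proton per lactate
      reactants <- c(reactants, stats::setNames(1, "H_b"))
      products <- c(products, stats::setNames(1, "H_c"))
    }
    reactions <- c(reactions, list(ms_reaction(
      paste0("T_", sp), reactants = reactants,
      products = products, rate = rate)))
    ports <- c(ports, list(ms_port(b, direction = "contact"),
                           ms_port(cc, direction = "contact")))
  }
  ports <- c(ports, list(ms_port("W_f", direction = "input")))
  module_def(name, variables = c(vars, pvars(pars)),
             reactions = reactions, rate_rules = rules, ports = ports)
}

## ---- cytosol module --------------------------------------------------

cytosol_module <- function(name, ft, config, derived, comp_cyt) {
  met <- config$metabolism
  der <- derived$fiber[[ft]]
  cyt <- config$rest$cyt[[ft]]
  phy <- config$physiology
  V_f <- if (ft == "I") phy$V_R else phy$V_W
  V_cyt <- V_f * (1 - if (ft == "I") phy$mito_R else phy$mito_W)
  Km <- met$Km

  sp0 <- c(cyt, ADP = unname(der$ADP0), AMP = unname(der$AMP0))
  sp_vars <- lapply(names(sp0), function(sp)
    ms_variable(sp, sp0[[sp]], compartment = comp_cyt,
                buffered = if (sp == "H") "beta_H" else NA_character_))

  pars <- c(
    V_f = V_f, V_cyt = V_cyt, W_f = 0, beta_H = met$buffer_beta,
    ## total (mmol/min) resting fluxes
    J_atpase = met$atpase0[[ft]] * V_f, J_gp = met$gp0 * V_f,
    J_gs = met$gp0 * V_f, J_gly = der$G * V_f,
    J_lip = met$lipolysis0 * V_f, J_facact = der$J_fac * V_f,
    k_CK = met$k_CK * V_f, k_AK = met$k_AK * V_f,
    k_LDH = met$k_LDH * V_f, k_ALT = met$k_ALT * V_f,
    Keq_CK = der$Keq_CK_app, Keq_AK = der$Keq_AK_app,
    Keq_LDH = der$Keq_LDH_app, Keq_ALT = der$Keq_ALT_app,
    h_atpase = met$h_per_atpase, h_lac = met$h_per_lac,
    ## references and half-saturations
    ATP0 = cyt[["ATP"]], H0 = cyt[["H"]], Gly0 = cyt[["Gly"]],
    Glc0 = cyt[["Glc"]], Pi0 = cyt[["Pi"]], ADP0 = der$ADP0,
    FFA0 = cyt[["FFA"]], CoA0 = cyt[["CoA"]],
    Km_ATP = Km$ATP_atpase, Km_Gly = Km$Gly_gp, Km_Glc = Km$Glc_gly,
    Km_Pi = Km$Pi_gly, Km_ADPg = Km$ADP_gly, K_gs = Km$K_gly_gs,
    Km_FFA = Km$FFA_fac, Km_CoA = Km$CoA_fac,
    ## activation
    a_atpase = met$alpha$atpase[[ft]], a_glyco = met$alpha$glycolysis[[ft]],
    a_gp = met$alpha$gp[[ft]],
    a_gs = met$alpha$gs[[ft]], a_fat = met$alpha$fat[[ft]],
    a_lip = met$alpha$lipolysis[[ft]],
    tau_atpase = met$tau$atpase, tau_glyco = met$tau$glycolysis,
    tau_gp = met$tau$gp,
    tau_gs = met$tau$gs, tau_fat = met$tau$fat, tau_lip = met$tau$lipolysis)

  acts <- c("act_atpase", "act_glyco", "act_gp", "act_gs", "act_fat",
            "act_lip")
  act_vars <- lapply(acts, function(a) ms_variable(a, 1))
  rules <- list(
    act_rule("act_atpase", "a_atpase", "tau_atpase"),
    act_rule("act_glyco", "a_glyco", "tau_glyco"),
    act_rule("act_gp", "a_gp", "tau_gp"),
    act_rule("act_gs", "a_gs", "tau_gs"),
    act_rule("act_fat", "a_fat", "tau_fat"),
    act_rule("act_lip", "a_lip", "tau_lip"))

  reactions <- list(
    ms_reaction("ATPase", reactants = c(ATP = 1),
                products = c(ADP = 1, Pi = 1,
                             H = met$h_per_atpase),
                rate = quote(J_atpase * act_atpase *
                               mm_norm(ATP, ATP0, Km_ATP))),
    ms_reaction("CK", reactants = c(PCr = 1, ADP = 1, H = 1),
                products = c(ATP = 1, Cr = 1),
                rate = quote(k_CK * (PCr * ADP * (H / H0) -
                                       ATP * Cr / Keq_CK))),
    ms_reaction("AK", reactants = c(ADP = 2),
                products = c(ATP = 1, AMP = 1),
                rate = quote(k_AK * (ADP^2 - ATP * AMP / Keq_AK))),
    ms_reaction("GP", reactants = c(Gly = 1), products = c(Glc = 1),
                rate = quote(J_gp * act_gp *
                               mm_norm(Gly, Gly0, Km_Gly))),
    ms_reaction("GS", reactants = c(Glc = 1, ATP = met$atp_cost_gs),
                products = c(Gly = 1, ADP = met$atp_cost_gs,
                             Pi = met$atp_cost_gs),
                rate = quote(J_gs * act_gs * ((K_gs / (K_gs + Gly)) /
                                                (K_gs / (K_gs + Gly0))))),
    ms_reaction("GLY", reactants = c(Glc = 1, ADP = 3, Pi = 3),
                products = c(Pyr = 2, ATP = 3),
                rate = quote(J_gly * act_glyco *
                               mm_norm(Glc, Glc0, Km_Glc) *
                               mm_norm(Pi, Pi0, Km_Pi) *
                               mm_norm(ADP, ADP0, Km_ADPg))),
    ms_reaction("LDH", reactants = c(Pyr = 1),
                products = c(Lac = 1, H = met$h_per_lac),
                rate = quote(k_LDH * (Pyr - Lac / Keq_LDH))),
    ms_reaction("ALT", reactants = c(Pyr = 1), products = c(Ala = 1),
                rate = quote(k_ALT * (Pyr - Ala / Keq_ALT))),
    ms_reaction("LIP", products = c(Glr = 1, FFA = 3),
                rate = quote(J_lip * act_lip)),
    ms_reaction("FACact",
                reactants = c(FFA = 1, CoA = 1, ATP = met$atp_cost_fac),
                products = c(FAC = 1, ADP = met$atp_cost_fac,
                             Pi = met$atp_cost_fac),
                rate = quote(J_facact * act_fat *
                               mm_norm(FFA, FFA0, Km_FFA) *
                               mm_norm(CoA, CoA0, Km_CoA))))

  contact <- c(BLOOD_SPECIES, "Pi", "FAC", "CoA", "ATP", "ADP", "AMP",
               "PCr", "Cr")
  module_def(name, variables = c(sp_vars, act_vars, pvars(pars)),
             reactions = reactions, rate_rules = rules,
             ports = c(lapply(unique(contact), function(sp)
               ms_port(sp, direction = "contact")),
               list(ms_port("W_f", direction = "input"))),
             compartments = stats::setNames("V_cyt", comp_cyt))
}

## ---- mitochondria module ---------------------------------------------

mito_module <- function(name, ft, config, derived, comp_cyt, comp_mit) {
  met <- config$metabolism
  der <- derived$fiber[[ft]]
  mit <- config$rest$mit
  cyt <- config$rest$cyt[[ft]]
  phy <- config$physiology
  V_f <- if (ft == "I") phy$V_R else phy$V_W
  V_mit <- V_f * (if (ft == "I") phy$mito_R else phy$mito_W)
  Km <- met$Km

  sp_vars <- lapply(names(mit), function(sp)
    ms_variable(sp, mit[[sp]], compartment = comp_mit,
                buffered = if (sp == "H") "beta_Hm" else NA_character_))
  ## cytosolic species drawn on by oxidative phosphorylation
  placeholders <- list(
    ms_variable("cATP", cyt[["ATP"]], compartment = comp_cyt),
    ms_variable("cADP", der$ADP0, compartment = comp_cyt),
    ms_variable("cPi", cyt[["Pi"]], compartment = comp_cyt,
                buffered = NA_character_),
    ms_variable("cH", cyt[["H"]], compartment = comp_cyt))

  pars <- c(
    V_mit = V_mit, W_f = 0, beta_Hm = met$buffer_beta,
    NAD_tot = met$NAD_tot,
    J_pdh = der$J_pdh * V_f, J_box = der$J_box * V_f,
    J_ox = der$J_N * V_f, cH_ox = der$c_H_ox,
    Pyr0 = mit[["Pyr"]], NADH0 = mit[["NADH"]], FAC0 = mit[["FAC"]],
    O20 = mit[["O2"]], ADP0 = der$ADP0,
    Km_Pyr = Km$Pyr_pdh, Km_NAD = Km$NAD_pdh, Km_FAC = Km$FAC_box,
    Km_NADH = Km$NADH_ox, Km_O2 = Km$O2_ox, Km_ADPox = Km$ADP_ox,
    Pi0m = cyt[["Pi"]], Km_Piox = Km$Pi_ox, n_ADP = met$n_ADP_ox,
    a_pdh = met$alpha$pdh[[ft]], a_fat = met$alpha$fat[[ft]],
    a_ox = met$alpha$ox[[ft]],
    tau_pdh = met$tau$pdh, tau_fat = met$tau$fat, tau_ox = met$tau$ox)

  act_vars <- list(ms_variable("act_pdh", 1), ms_variable("act_fat", 1),
                   ms_variable("act_ox", 1))
  rules <- list(act_rule("act_pdh", "a_pdh", "tau_pdh"),
                act_rule("act_fat", "a_fat", "tau_fat"),
                act_rule("act_ox", "a_ox", "tau_ox"))

  reactions <- list(
    ## pyruvate dehydrogenase + lumped TCA turn
    ms_reaction("PDH", reactants = c(Pyr = 1),
                products = c(CO2 = met$co2_per_pyr,
                             NADH = met$nadh_per_pyr),
                rate = quote(J_pdh * act_pdh * mm_norm(Pyr, Pyr0, Km_Pyr) *
                               mm_norm(NAD_tot - NADH, NAD_tot - NADH0,
                                       Km_NAD) *
                               mm_norm(cADP, ADP0, Km_ADPox))),
    ## beta-oxidation + TCA of fatty acyl-CoA
    ms_reaction("BOX", reactants = c(FAC = 1),
                products = c(CoA = 1, CO2 = met$co2_per_fac,
                             NADH = met$nadh_per_fac),
                rate = quote(J_box * act_fat * mm_norm(FAC, FAC0, Km_FAC) *
                               mm_norm(NAD_tot - NADH, NAD_tot - NADH0,
                                       Km_NAD) *
                               mm_norm(cADP, ADP0, Km_ADPox))),
    ## oxidative phosphorylation (proton balance closes on the cytosol)
    ms_reaction("OXPHOS",
                reactants = c(NADH = 1, O2 = 0.5,
                              cADP = met$P_per_NADH,
                              cPi = met$P_per_NADH, cH = der$c_H_ox),
                products = c(cATP = met$P_per_NADH),
                rate = quote(J_ox * act_ox * mm_norm(NADH, NADH0, Km_NADH) *
                               mm_norm(O2, O20, Km_O2) *
                               mm_norm(cADP, ADP0, Km_ADPox)^n_ADP *
                               mm_norm(cPi, Pi0m, Km_Piox))))

  module_def(name, variables = c(sp_vars, placeholders, act_vars,
                                 pvars(pars)),
             reactions = reactions, rate_rules = rules,
             ports = c(lapply(names(mit), function(sp)
               ms_port(sp, direction = "contact")),
               lapply(c("cATP", "cADP", "cPi", "cH"), function(sp)
                 ms_port(sp, direction = "contact")),
               list(ms_port("W_f", direction = "input"))),
             compartments = stats::setNames("V_mit", comp_mit))
}

## ---- cytosol <-> mitochondria transport module -----------------------

mt_transport_module <- function(name, ft, config, derived, comp_cyt,
                                comp_mit) {
  tr <- config$transport
  der <- derived$fiber[[ft]]
  cyt <- config$rest$cyt[[ft]]
  mit <- config$rest$mit
  V_f <- if (ft == "I") config$physiology$V_R else config$physiology$V_W

  vars <- list(); reactions <- list(); rules <- list(); ports <- list()
  pars <- c(V_f = V_f, W_f = 0, tau_tr = tr$tau)

  for (sp in MITO_TRANSPORT) {
    cc <- paste0("c", sp); mm <- paste0("m", sp)
    vars <- c(vars, list(
      ms_variable(cc, cyt[[sp]], compartment = comp_cyt),
      ms_variable(mm, mit[[sp]], compartment = comp_mit),
      ms_variable(paste0("act_", sp), 1)))
    pars[paste0("alpha_", sp)] <- tr$alpha_mt[[sp]]
    rules <- c(rules, list(act_rule(paste0("act_", sp),
                                    paste0("alpha_", sp), "tau_tr")))
    if (sp %in% c("O2", "CO2")) {
      pars[paste0("lam_", sp)] <- der$lambda_mt[[sp]]
      rate <- bquote(V_f * passive_flux(.(as.name(cc)), .(as.name(mm)),
                                        .(as.name(paste0("lam_", sp))),
                                        .(as.name(paste0("act_", sp)))))
    } else {
      pars[paste0("Rmax_", sp)] <- der$Rmax_mt[[sp]]
      pars[paste0("KM_", sp)] <- tr$KM_mt[[sp]]
      rate <- bquote(V_f * facilitated_flux(.(as.name(cc)), .(as.name(mm)),
                                            .(as.name(paste0("Rmax_", sp))),
                                            .(as.name(paste0("KM_", sp))),
                                            .(as.name(paste0("act_", sp)))))
    }
    reactions <- c(reactions, list(ms_reaction(
      paste0("T_", sp), reactants = stats::setNames(1, cc),
      products = stats::setNames(1, mm), rate = rate)))
    ports <- c(ports, list(ms_port(cc, direction = "contact"),
                           ms_port(mm, direction = "contact")))
  }
  ports <- c(ports, list(ms_port("W_f", direction = "input")))
  module_def(name, variables = c(vars, pvars(pars)),
             reactions = reactions, rate_rules = rules, ports = ports)
}

## ---- signalling module -----------------------------------------------

#' Resting steady state of the signalling cascade
#'
#' Computed in closed form by propagating the resting calcium level
#' through calmodulin, the kinase/phosphatase balances
#' ([phospho_steady_state()]) and the AMPK activity sum; used both as
#' initial conditions and as the baseline references of the
#' gene-expression drive.
#'
#' @param config a `ms_config`.
#' @param ft fiber type (`"I"` or `"II"`).
#' @param derived output of [derive_parameters()].
#' @return named list of resting signalling values.
#' @export
rest_signaling <- function(config, ft, derived = derive_parameters(config)) {
  sg <- config$signaling
  der <- derived$fiber[[ft]]
  cyt <- config$rest$cyt[[ft]]
  CaCaM0 <- hill(sg$Ca_rest, sg$K_CaM, sg$n_CaM)
  camkii0 <- phospho_steady_state(
    sg$camkii$k_basal + sg$camkii$k_cam * CaCaM0, sg$camkii$k_dp)
  cn0 <- CaCaM0 / (sg$calcineurin$K + CaCaM0)
  kk0 <- CaCaM0 / (sg$camkk2$K + CaCaM0)
  crtc0 <- phospho_steady_state(
    sg$crtc$k_basal + sg$crtc$k_cn * cn0, sg$crtc$k_rp)
  amp_ratio0 <- der$AMP0 / cyt[["ATP"]]
  P0 <- list(); act0 <- 0
  for (h in names(sg$ampk$total)) {
    p <- sg$ampk[[h]]
    k_on <- p$k_ph * (sg$lkb1 + p$c_camkk * kk0)
    k_off <- p$k_dp * (cyt[["ATP"]] / p$ATP0) / (1 + der$AMP0 / p$K_amp)
    P0[[h]] <- sg$ampk$total[[h]] * phospho_steady_state(k_on, k_off)
    p$ratio0 <- amp_ratio0
    act0 <- act0 + ampk_activity(P0[[h]], sg$ampk$total[[h]], der$AMP0,
                                 cyt[["ATP"]], p)
  }
  creb0 <- phospho_steady_state(
    sg$creb$k_basal + sg$creb$k_camkii * camkii0 + sg$creb$k_ampk * act0,
    sg$creb$k_dp)
  list(CaCaM0 = CaCaM0, camkii0 = camkii0, cn0 = cn0, kk0 = kk0,
       crtc0 = crtc0, P0 = P0, ampk_act0 = act0, creb0 = creb0,
       amp_ratio0 = amp_ratio0)
}

signaling_module <- function(name, ft, config, derived, comp_cyt, cap_f) {
  sg <- config$signaling
  der <- derived$fiber[[ft]]
  cyt <- config$rest$cyt[[ft]]
  r0 <- rest_signaling(config, ft, derived)

  placeholders <- list(
    ms_variable("ATP", cyt[["ATP"]], compartment = comp_cyt),
    ms_variable("PCr", cyt[["PCr"]], compartment = comp_cyt),
    ms_variable("Cr", cyt[["Cr"]], compartment = comp_cyt),
    ms_variable("H", cyt[["H"]], compartment = comp_cyt))

  states <- list(
    ms_variable("Ca", sg$Ca_rest),
    ms_variable("CaMKII_p", r0$camkii0),
    ms_variable("CRTC_a", r0$crtc0),
    ms_variable("CREB1_p", r0$creb0),
    ms_variable("P_g3", r0$P0$a2b2g3),
    ms_variable("P_g1a2", r0$P0$a2b2g1),
    ms_variable("P_g1a1", r0$P0$a1b2g1))

  pars <- c(
    W_f = 0, cap_f = cap_f,
    Ca_rest = sg$Ca_rest, Ca_slope = sg$Ca_slope, tau_Ca = sg$tau_Ca,
    K_CaM = sg$K_CaM, n_CaM = sg$n_CaM,
    ck_b = sg$camkii$k_basal, ck_cam = sg$camkii$k_cam,
    ck_dp = sg$camkii$k_dp,
    K_cn = sg$calcineurin$K, K_kk = sg$camkk2$K,
    crtc_b = sg$crtc$k_basal, crtc_cn = sg$crtc$k_cn,
    crtc_rp = sg$crtc$k_rp, lkb1 = sg$lkb1,
    Keq_CK_f = config$metabolism$Keq_CK,
    Keq_AK_f = config$metabolism$Keq_AK,
    ratio0 = r0$amp_ratio0,
    creb_b = sg$creb$k_basal, creb_ck = sg$creb$k_camkii,
    creb_ak = sg$creb$k_ampk, creb_dp = sg$creb$k_dp)
  hn <- c(a2b2g3 = "g3", a2b2g1 = "g1a2", a1b2g1 = "g1a1")
  for (h in names(hn)) {
    p <- sg$ampk[[h]]; s <- hn[[h]]
    pars[paste0(c("T_", "kph_", "ckk_", "kdp_", "Kamp_", "base_",
                  "cact_", "Kallo_"), s)] <-
      c(sg$ampk$total[[h]], p$k_ph, p$c_camkk, p$k_dp, p$K_amp,
        p$baseline, p$c_act, p$K_allo)
  }
  pars["ATP0s"] <- sg$ampk$a2b2g3$ATP0

  ampk_act_expr <- quote(
    T_g3 * base_g3 + cact_g3 * P_g3 * (1 + hill(rel_amp, Kallo_g3, 1)) +
    T_g1a2 * base_g1a2 +
      cact_g1a2 * P_g1a2 * (1 + hill(rel_amp, Kallo_g1a2, 1)) +
    T_g1a1 * base_g1a1 +
      cact_g1a1 * P_g1a1 * (1 + hill(rel_amp, Kallo_g1a1, 1)))

  assignments <- list(
    ms_assignment("CaCaM", quote(hill(Ca, K_CaM, n_CaM))),
    ms_assignment("CN_act", quote(CaCaM / (K_cn + CaCaM))),
    ms_assignment("KK_act", quote(CaCaM / (K_kk + CaCaM))),
    ## free nucleotides from the CK/AK near-equilibria (H in mol/L)
    ms_assignment("ADP_f",
                  quote(ATP * Cr / (PCr * (H * 1e-3) * Keq_CK_f))),
    ms_assignment("AMP_f", quote(Keq_AK_f * ADP_f^2 / ATP)),
    ms_assignment("rel_amp", quote((AMP_f / ATP) / ratio0)),
    ms_assignment("AMPK_act", ampk_act_expr))

  ampk_rule <- function(state, s) ms_rate_rule(state, bquote(
    .(as.name(paste0("kph_", s))) *
      (lkb1 + .(as.name(paste0("ckk_", s))) * KK_act) *
      (.(as.name(paste0("T_", s))) - .(as.name(state))) -
      .(as.name(paste0("kdp_", s))) * (ATP / ATP0s) /
      (1 + AMP_f / .(as.name(paste0("Kamp_", s)))) * .(as.name(state))))

  rate_rules <- list(
    ms_rate_rule("Ca", quote(
      ((Ca_rest + Ca_slope * (W_f / cap_f)) - Ca) / tau_Ca)),
    ms_rate_rule("CaMKII_p", quote(
      (ck_b + ck_cam * CaCaM) * (1 - CaMKII_p) - ck_dp * CaMKII_p)),
    ms_rate_rule("CRTC_a", quote(
      (crtc_b + crtc_cn * CN_act) * (1 - CRTC_a) - crtc_rp * CRTC_a)),
    ampk_rule("P_g3", "g3"),
    ampk_rule("P_g1a2", "g1a2"),
    ampk_rule("P_g1a1", "g1a1"),
    ms_rate_rule("CREB1_p", quote(
      (creb_b + creb_ck * CaMKII_p + creb_ak * AMPK_act) *
        (1 - CREB1_p) - creb_dp * CREB1_p)))

  asg_targets <- pvars(c(CaCaM = r0$CaCaM0, CN_act = r0$cn0,
                         KK_act = r0$kk0, ADP_f = der$ADP0,
                         AMP_f = der$AMP0, rel_amp = 1,
                         AMPK_act = r0$ampk_act0))

  module_def(name,
             variables = c(placeholders, states, asg_targets, pvars(pars)),
             assignments = assignments, rate_rules = rate_rules,
             ports = c(lapply(c("ATP", "PCr", "Cr", "H"), function(sp)
               ms_port(sp, direction = "contact")),
               list(ms_port("CREB1_p", direction = "contact"),
                    ms_port("CRTC_a", direction = "contact"),
                    ms_port("W_f", direction = "input"))))
}

## ---- gene-expression module ------------------------------------------

gene_module <- function(name, ft, config, derived) {
  gn <- config$genes
  r0 <- rest_signaling(config, ft, derived)

  placeholders <- list(ms_variable("CREB1_p", r0$creb0),
                       ms_variable("CRTC_a", r0$crtc0))
  x_trans <- if (isTRUE(gn$x_factor_enabled)) gn$X$k_trans else 0
  pX0 <- if (x_trans > 0) x_trans / gn$X$k_deg_prot else 0

  pars <- c(
    CREB0 = r0$creb0, CRTC0 = r0$crtc0,
    K_drive = gn$K_drive, n_drive = gn$n_drive,
    kd_N3 = gn$NR4A3$k_deg, Vm_N3 = gn$NR4A3$k_deg * (gn$NR4A3$fold_max - 1),
    kd_N2 = gn$NR4A2$k_deg, Vm_N2 = gn$NR4A2$k_deg * (gn$NR4A2$fold_max - 1),
    kd_X = gn$X$k_deg, Vm_X = gn$X$k_deg * (gn$X$fold_max - 1),
    k_trans = x_trans, kd_pX = gn$X$k_deg_prot, pX0 = pX0,
    kd_P = gn$PPARGC1A$k_deg,
    Vm_P = gn$PPARGC1A$k_deg * (gn$PPARGC1A$fold_max - 1),
    K_X = gn$PPARGC1A$K_X)

  states <- list(
    ms_variable("mNR4A3", 1), ms_variable("mNR4A2", 1),
    ms_variable("mX", 1), ms_variable("pX", pX0),
    ms_variable("mPPARGC1A", 1))

  p_drive <- if (isTRUE(gn$direct_creb_regulation))
    quote(Vm_P * hillD) else quote(Vm_P * hill(pX - pX0, K_X, 1))

  module_def(name,
             variables = c(placeholders, states,
                           pvars(c(drive = 1, hillD = 0)), pvars(pars)),
             assignments = list(
               ms_assignment("drive",
                             quote((CREB1_p / CREB0) * (CRTC_a / CRTC0))),
               ms_assignment("hillD",
                             quote(hill(drive - 1, K_drive, n_drive)))),
             rate_rules = list(
               ms_rate_rule("mNR4A3", quote(
                 kd_N3 + Vm_N3 * hillD - kd_N3 * mNR4A3)),
               ms_rate_rule("mNR4A2", quote(
                 kd_N2 + Vm_N2 * hillD - kd_N2 * mNR4A2)),
               ms_rate_rule("mX", quote(kd_X + Vm_X * hillD - kd_X * mX)),
               ms_rate_rule("pX", quote(k_trans * mX - kd_pX * pX)),
               ms_rate_rule("mPPARGC1A", bquote(
                 kd_P + .(p_drive) - kd_P * mPPARGC1A))),
             ports = list(ms_port("CREB1_p", direction = "contact"),
                          ms_port("CRTC_a", direction = "contact")))
}

## ---- assembly --------------------------------------------------------

#' Build the integrated modular muscle model
#'
#' Constructs the full module graph: a protocol module broadcasting total
#' and per-fiber work rates over buses, the capillary-blood module, and
#' for each fiber type a transport, cytosol, mitochondria, intra-fiber
#' transport, signalling and gene-expression module.  The two fiber
#' branches are structurally identical and differ only in parameter
#' values.
#'
#' @param config a [default_config()] list.
#' @param protocol a `ms_protocol` (or `NULL` for rest).
#' @return a validated [modular_model()].
#' @export
build_model <- function(config = default_config(), protocol = NULL) {
  derived <- derive_parameters(config)
  rec <- with(config$recruitment,
              recruitment_model(W_max, theta, cap_I, cap_II))
  fat <- if (isTRUE(config$fatigue$enabled))
    fatigue_model(TRUE, config$fatigue$decline) else NULL
  power <- if (is.null(protocol)) {
    zero <- function(t) rep(0, length(t))
    list(W_I = zero, W_II = zero, W = zero, events = numeric())
  } else apply_fatigue(protocol, rec, fat)

  fiber_branch <- function(ft) {
    sfx <- if (ft == "I") "R" else "W"
    comp_cyt <- paste0("cyt_", sfx); comp_mit <- paste0("mit_", sfx)
    cap_f <- if (ft == "I") rec$cap_I else rec$cap_II
    list(
      zbl = bl_transport_module(paste0("zbl", sfx), ft, config, derived,
                                comp_cyt),
      cyt = cytosol_module(paste0("cyt", sfx), ft, config, derived,
                           comp_cyt),
      mit = mito_module(paste0("mit", sfx), ft, config, derived,
                        comp_cyt, comp_mit),
      zmt = mt_transport_module(paste0("zmt", sfx), ft, config, derived,
                                comp_cyt, comp_mit),
      sig = signaling_module(paste0("sig", sfx), ft, config, derived,
                             comp_cyt, cap_f),
      zgn = gene_module(paste0("zgn", sfx), ft, config, derived))
  }
  brR <- fiber_branch("I"); brW <- fiber_branch("II")

  modules <- c(list(protocol_module(power), blood_module(config, derived)),
               unname(brR), unname(brW))

  conns <- list(); buses <- list()
  cc <- function(a, b) ms_connection(a, b, directed = FALSE)

  ## blood species run over named buses
  for (sp in BLOOD_SPECIES)
    buses[[length(buses) + 1L]] <- ms_bus(paste0("bus_", sp), list(
      c("blood", sp), c("zblR", paste0(sp, "_b")),
      c("zblW", paste0(sp, "_b"))))

  ## work-rate broadcast buses (one output port, many inputs)
  buses[[length(buses) + 1L]] <- ms_bus("bus_W_tot", list(
    c("aprot", "W_tot"), c("blood", "W_tot")))
  for (d in list(c("I", "R"), c("II", "W"))) {
    sfx <- d[[2]]
    buses[[length(buses) + 1L]] <- ms_bus(paste0("bus_W_", d[[1]]), c(
      list(c("aprot", paste0("W_", d[[1]]))),
      lapply(paste0(c("zbl", "cyt", "mit", "zmt", "sig"), sfx),
             function(m) c(m, "W_f"))))
  }

  for (sfx in c("R", "W")) {
    zbl <- paste0("zbl", sfx); cyt <- paste0("cyt", sfx)
    mit <- paste0("mit", sfx); zmt <- paste0("zmt", sfx)
    sig <- paste0("sig", sfx); zgn <- paste0("zgn", sfx)
    for (sp in BLOOD_SPECIES)
      conns[[length(conns) + 1L]] <- cc(c(zbl, paste0(sp, "_c")),
                                        c(cyt, sp))
    for (sp in MITO_TRANSPORT) {
      conns[[length(conns) + 1L]] <- cc(c(zmt, paste0("c", sp)), c(cyt, sp))
      conns[[length(conns) + 1L]] <- cc(c(zmt, paste0("m", sp)), c(mit, sp))
    }
    for (pr in list(c("cATP", "ATP"), c("cADP", "ADP"), c("cPi", "Pi"),
                    c("cH", "H")))
      conns[[length(conns) + 1L]] <- cc(c(mit, pr[[1]]), c(cyt, pr[[2]]))
    for (sp in c("ATP", "PCr", "Cr", "H"))
      conns[[length(conns) + 1L]] <- cc(c(sig, sp), c(cyt, sp))
    conns[[length(conns) + 1L]] <- cc(c(zgn, "CREB1_p"), c(sig, "CREB1_p"))
    conns[[length(conns) + 1L]] <- cc(c(zgn, "CRTC_a"), c(sig, "CRTC_a"))
  }

  modular_model(modules, conns, buses)
}
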