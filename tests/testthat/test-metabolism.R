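test_that("free ADP/AMP follow the CK/AK near-equilibrium formulas", {
  ## direct formula evaluation as the oracle
  ATP <- 6; PCr <- 24; Cr <- 12; H <- 10^-7.1
  eq <- free_adp_amp(ATP, PCr, Cr, H)
  expect_equal(eq$ADP, ATP * Cr / (PCr * H * 1.66e9))
  expect_equal(eq$AMP, 1.05 * eq$ADP^2 / ATP)

  ## no creatine, no free ADP/AMP
  z <- free_adp_amp(6, 24, 0, 1e-7)
  expect_equal(z$ADP, 0)
  expect_equal(z$AMP, 0)

  ## decreasing PCr at fixed others strictly increases free ADP
  pcr <- seq(25, 5, by = -5)
  adp <- free_adp_amp(6, pcr, 12, 1e-7)$ADP
  expect_true(all(diff(adp) > 0))

  expect_error(free_adp_amp(6, 0, 12, 1e-7), "PCr")
  expect_error(free_adp_amp(6, 24, 12, 0), "H")
})

test_that("pH conversions are exact and log-linear", {
  expect_equal(ph_from_proton(1e-4), 7.0)   # 1e-7 mol/L in mmol/kg
  pH <- runif(20, 6, 7.5)
  expect_equal(ph_from_proton(proton_from_ph(pH)), pH)
  H <- 10^runif(20, -4.5, -3.5)
  expect_equal(ph_from_proton(2 * H), ph_from_proton(H) - log10(2))
  expect_error(ph_from_proton(-1), "positive")
})

test_that("normalised Michaelis-Menten modulation is anchored at rest", {
  expect_equal(mm_norm(2.9, 2.9, 1.5), 1)
  expect_true(mm_norm(5, 2.9, 1.5) > 1)
  expect_true(mm_norm(1, 2.9, 1.5) < 1)
})

test_that("ATPase rate scales with activation and fiber type ordering holds", {
  expect_equal(atpase_rate(6.2, act = 1, basal = 0.3), 0.3)  # rest
  ## activation factor 2 (alpha * W = 1 at steady exercise) doubles the rate
  expect_equal(atpase_rate(6.2, act = 2, basal = 0.3), 0.6)
  ## configured activation coefficients: type II >= type I
  cfg <- default_config()
  expect_true(all(cfg$metabolism$alpha$atpase[["II"]] >=
                    cfg$metabolism$alpha$atpase[["I"]]))
})

test_that("glycogen synthase is fiber-type symmetric and glycogen-inhibited", {
  ## identical rates for both fiber types at equal glycogen and work rate
  cfg <- default_config()
  expect_equal(cfg$metabolism$alpha$gs[["I"]], cfg$metabolism$alpha$gs[["II"]])
  r1 <- glycogen_synthase_rate(70, act = 1.5, basal = 0.002)
  expect_equal(r1, glycogen_synthase_rate(70, act = 1.5, basal = 0.002))
  expect_equal(glycogen_synthase_rate(70, act = 2, basal = 0), 0)
  gly <- seq(20, 140, by = 20)
  rr <- glycogen_synthase_rate(gly, act = 1, basal = 0.002)
  expect_true(all(diff(rr) < 0))
  expect_error(glycogen_synthase_rate(-5, 1, 0.002))
})

test_that("moieties are conserved under CK/AK/ATPase-only dynamics", {
  ## closed toy cytosol: adenine pool (ATP+ADP+AMP) and creatine pool
  ## (PCr+Cr) are invariant
  vars <- list(
    ms_variable("ATP", 6.2), ms_variable("ADP", 0.03),
    ms_variable("AMP", 1e-4), ms_variable("PCr", 20),
    ms_variable("Cr", 13), ms_variable("Pi", 2.9),
    ms_variable("H", 8.9e-5),
    ms_variable("kCK", 5, kind = "parameter"),
    ms_variable("kAK", 10, kind = "parameter"),
    ms_variable("kAtp", 0.4, kind = "parameter"),
    ms_variable("KeqCK", 6.2 * 13 / (20 * 0.03), kind = "parameter"),
    ms_variable("KeqAK", 6.2 * 1e-4 / 0.03^2, kind = "parameter"),
    ms_variable("H0", 8.9e-5, kind = "parameter"))
  m <- module_def(
    "ck", variables = vars,
    reactions = list(
      ms_reaction("CK", reactants = c(PCr = 1, ADP = 1, H = 1),
                  products = c(ATP = 1, Cr = 1),
                  rate = quote(kCK * (PCr * ADP * (H / H0) -
                                        ATP * Cr / KeqCK))),
      ms_reaction("AK", reactants = c(ADP = 2),
                  products = c(ATP = 1, AMP = 1),
                  rate = quote(kAK * (ADP^2 - ATP * AMP / KeqAK))),
      ms_reaction("ATPase", reactants = c(ATP = 1),
                  products = c(ADP = 1, Pi = 1),
                  rate = quote(kAtp * ATP / (0.5 + ATP)))))
  flat <- flatten_single(m)
  sim <- simulate_flat(flat, seq(0, 10, by = 0.5))
  adenine <- sim[, "ATP"] + sim[, "ADP"] + sim[, "AMP"]
  creatine <- sim[, "PCr"] + sim[, "Cr"]
  expect_equal(adenine, rep(adenine[1], length(adenine)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(creatine, rep(creatine[1], length(creatine)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## ATPase is running (PCr buffers ATP): PCr falls, Cr rises
  expect_lt(sim[nrow(sim), "PCr"], sim[1, "PCr"])
})

test_that("single-reaction stoichiometry maps to volume-scaled derivatives", {
  ## toy config with only an ATPase flux r: dATP/dt = -r/V,
  ## dADP/dt = +r/V, dPi/dt = +r/V
  m <- module_def(
    "toy",
    variables = list(
      ms_variable("ATP", 6, compartment = "cyt"),
      ms_variable("ADP", 0.1, compartment = "cyt"),
      ms_variable("Pi", 3, compartment = "cyt"),
      ms_variable("V", 1.76, kind = "parameter"),
      ms_variable("r", 0.42, kind = "parameter")),
    reactions = list(ms_reaction(
      "ATPase", reactants = c(ATP = 1), products = c(ADP = 1, Pi = 1),
      rate = quote(r))),
    compartments = c(cyt = "V"))
  rhs <- musclesim:::flat_rhs(flatten_single(m))
  d <- rhs$func(0, rhs$y0, NULL)[[1]]
  names(d) <- rhs$states
  expect_equal(d[["ATP"]], -0.42 / 1.76)
  expect_equal(d[["ADP"]], 0.42 / 1.76)
  expect_equal(d[["Pi"]], 0.42 / 1.76)
})

test_that("mitochondrial balances follow transport and stoichiometry", {
  ## pyruvate import only: dPyr_mit/dt = T / V_mit
  m <- module_def(
    "mt",
    variables = list(
      ms_variable("Pyr_c", 0.2, compartment = "cyt"),
      ms_variable("Pyr_m", 0.05, compartment = "mit"),
      ms_variable("Vc", 1.76, kind = "parameter"),
      ms_variable("Vm", 0.24, kind = "parameter"),
      ms_variable("Rmax", 0.1, kind = "parameter"),
      ms_variable("KM", 0.1, kind = "parameter")),
    reactions = list(ms_reaction(
      "T", reactants = c(Pyr_c = 1), products = c(Pyr_m = 1),
      rate = quote(facilitated_flux(Pyr_c, Pyr_m, Rmax, KM)))),
    compartments = c(cyt = "Vc", mit = "Vm"))
  rhs <- musclesim:::flat_rhs(flatten_single(m))
  d <- rhs$func(0, rhs$y0, NULL)[[1]]
  names(d) <- rhs$states
  Tflux <- facilitated_flux(0.2, 0.05, 0.1, 0.1)
  expect_equal(d[["Pyr_m"]], Tflux / 0.24)
  expect_equal(d[["Pyr_c"]], -Tflux / 1.76)
})
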