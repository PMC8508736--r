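test_that("activation function matches its closed form and limits", {
  expect_equal(activation(10, W = 0, alpha = 0.004, tau = 0.4), 1.0)
  expect_equal(activation(2, W = 150, alpha = 0.01, tau = 0.4,
                          t_start = 2), 1.0)
  ## asymptote 1 + alpha * W
  expect_equal(activation(1e3, W = 250, alpha = 0.004, tau = 0.4), 2.0,
               tolerance = 1e-12)
  ## monotone rise
  a <- activation(seq(0, 5, 0.1), W = 100, alpha = 0.01, tau = 0.5)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 1))
})

test_that("blood flow and muscle volume follow the activation law", {
  expect_equal(blood_flow(0, W = 0), 0.9)
  expect_equal(blood_flow(5, W = 180, t_start = 5), 0.9)
  expect_equal(muscle_volume(0, W = 0), 5)
  ## one time constant: Q - Q0 = (1 - e^-1) * (Qinf - Q0)
  Q0 <- 0.9; alpha <- 0.02; W <- 200
  Qinf <- Q0 * (1 + alpha * W)
  expect_equal(blood_flow(0.4, W, alpha = alpha, tau = 0.4),
               Q0 + (1 - exp(-1)) * (Qinf - Q0), tolerance = 1e-12)
})

test_that("the first-order activation state reproduces the closed form", {
  m <- module_def(
    "act",
    variables = list(ms_variable("a", 1),
                     ms_variable("alpha", 0.01, kind = "parameter"),
                     ms_variable("tau", 0.7, kind = "parameter"),
                     ms_variable("W", 120, kind = "parameter")),
    rate_rules = list(ms_rate_rule("a", quote(((1 + alpha * W) - a) / tau))))
  tt <- seq(0, 5, by = 0.1)
  sim <- simulate_flat(flatten_single(m), tt)
  expect_equal(sim[, "a"], activation(tt, 120, 0.01, 0.7),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("passive flux is linear, antisymmetric and zero at equilibrium", {
  expect_equal(passive_flux(1.3, 1.3, lambda = 2, act = 5), 0)
  expect_equal(passive_flux(2, 1, lambda = 1, act = 1), 1.0)
  for (cs in list(c(2, 1), c(0.1, 3), c(5, 5)))
    expect_equal(passive_flux(cs[1], cs[2], 0.7, 2),
                 -passive_flux(cs[2], cs[1], 0.7, 2))
  expect_equal(passive_flux(2, 1, lambda = 1, act = 3), 3)
})

test_that("facilitated flux saturates and is bounded by Rmax", {
  expect_equal(facilitated_flux(0.8, 0.8, Rmax = 2, KM = 1), 0)
  ## half-saturation: C_a = KM, C_b = 0
  expect_equal(facilitated_flux(1.5, 0, Rmax = 2, KM = 1.5), 1.0)
  ## saturation limit
  expect_equal(facilitated_flux(1e6, 0, Rmax = 2, KM = 1.5), 2,
               tolerance = 1e-5)
  C <- runif(50, 0, 10)
  fx <- facilitated_flux(C, rev(C), Rmax = 3, KM = 0.5, act = 2)
  expect_true(all(abs(fx) <= 6 + 1e-12))
})

test_that("blood mass balance: equilibrium, direct evaluation, conservation", {
  expect_equal(blood_rhs(C_bl = 2, C_art = 2, Q = 3, T_R = 0, T_W = 0), 0)
  expect_equal(blood_rhs(C_bl = 1, C_art = 2, Q = 0.9, T_R = 0, T_W = 0,
                         V_bl = 1), 0.9)

  ## closed two-compartment toy (Q = 0, passive exchange only):
  ## V_bl * C_bl + V_cyt * C_cyt is conserved
  blood <- module_def(
    "bl",
    variables = list(ms_variable("S", 2, compartment = "blood"),
                     ms_variable("V_bl", 1, kind = "parameter")),
    ports = list(ms_port("S", direction = "contact")),
    compartments = c(blood = "V_bl"))
  tissue <- module_def(
    "tis",
    variables = list(ms_variable("S_b", 2, compartment = "blood"),
                     ms_variable("S_c", 0.5, compartment = "cyt"),
                     ms_variable("V_cyt", 1.76, kind = "parameter"),
                     ms_variable("lam", 0.8, kind = "parameter")),
    reactions = list(ms_reaction(
      "T", reactants = c(S_b = 1), products = c(S_c = 1),
      rate = quote(passive_flux(S_b, S_c, lam)))),
    ports = list(ms_port("S_b", direction = "contact")),
    compartments = c(cyt = "V_cyt"))
  mm <- modular_model(list(blood, tissue), list(
    ms_connection(c("bl", "S"), c("tis", "S_b"), directed = FALSE)))
  flat <- mm_flatten(mm)
  sim <- simulate_flat(flat, seq(0, 20, by = 1))
  total <- 1 * sim[, flat_name(flat, "bl.S")] +
    1.76 * sim[, flat_name(flat, "tis.S_c")]
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## and the two sides approach the same concentration
  n <- nrow(sim)
  expect_equal(sim[n, flat_name(flat, "bl.S")],
               sim[n, flat_name(flat, "tis.S_c")], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("fiber volume partitions are consistent", {
  v <- fiber_volumes()
  expect_equal(v$V_cyt_R + v$V_mit_R, v$V_R)
  expect_equal(v$V_cyt_W + v$V_mit_W, v$V_W)
  expect_equal(v$V_cyt_R, 0.88 * 2)
  expect_equal(v$V_cyt_W, 0.92 * 2)
  expect_equal(v$V_R + v$V_W, 0.8 * 5)   # V_tis = 0.8 * V_mus
})
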