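test_that("well-formed and trivial models validate cleanly", {
  expect_equal(nrow(mm_validate(three_module_model())), 0L)
  expect_equal(nrow(mm_validate(three_module_model(use_bus = TRUE))), 0L)

  single <- modular_model(list(module_def(
    "solo", variables = list(ms_variable("S", 1)),
    reactions = list(ms_reaction("decay", c(S = 1), rate = quote(0.1 * S))))))
  expect_equal(nrow(mm_validate(single)), 0L)
})

test_that("direction typing and driver violations are reported, not raised", {
  mk <- function(dir) module_def(
    paste0("m", dir), variables = list(ms_variable("v", 1)),
    ports = list(ms_port("v", direction = dir)))
  oo <- modular_model(list(mk("output"), module_def(
    "m2", variables = list(ms_variable("v", 1)),
    ports = list(ms_port("v", direction = "output")))),
    list(ms_connection(c("moutput", "v"), c("m2", "v"), directed = TRUE)))
  d <- mm_validate(oo)
  expect_equal(sum(d$type == "direction typing"), 1L)

  ## two outputs driving one input
  m_in <- module_def("sink", variables = list(ms_variable("v", 0)),
                     ports = list(ms_port("v", direction = "input")))
  m_o1 <- module_def("srcA", variables = list(ms_variable("v", 1)),
                     ports = list(ms_port("v", direction = "output")))
  m_o2 <- module_def("srcB", variables = list(ms_variable("v", 2)),
                     ports = list(ms_port("v", direction = "output")))
  md <- modular_model(list(m_in, m_o1, m_o2), list(
    ms_connection(c("srcA", "v"), c("sink", "v")),
    ms_connection(c("srcB", "v"), c("sink", "v"))))
  expect_true("multiply-driven input" %in% mm_validate(md)$type)

  ## dangling endpoint
  dg <- modular_model(list(m_o1), list(
    ms_connection(c("srcA", "v"), c("nowhere", "v"))))
  expect_true("dangling port" %in% mm_validate(dg)$type)
})

test_that("flattening the worked three-module example merges shared species", {
  flat <- mm_flatten(three_module_model())
  expect_equal(length(flat$reactions), 3L)
  expect_equal(ode_count(flat), 8L)

  ## shared A is one flat variable, consumed by both the M1 and M3 reactions
  a <- flat_name(flat, "M1.A")
  expect_identical(a, flat_name(flat, "M3.A"))
  consuming <- vapply(flat$reactions, function(r) a %in% names(r$reactants),
                      logical(1))
  expect_equal(sum(consuming), 2L)

  ## flat species set matches the expected eight
  sp <- dynamic_states(flat)
  expect_setequal(sub("^[^.]+\\.", "", sp),
                  c("A", "B", "A:B", "C", "C{p}", "X", "Z", "A_1"))

  ## provenance map is total over all module variables
  expect_setequal(unlist(flat$provenance),
                  c(paste0("M1.", c("A", "B", "A:B", "k1")),
                    paste0("M2.", c("A:B", "C", "C{p}", "k2")),
                    paste0("M3.", c("A", "A_1", "X", "Z", "C{p}", "k3"))))
})

test_that("bus-rewritten and direct-connection variants flatten identically", {
  fa <- mm_flatten(three_module_model(use_bus = FALSE))
  fb <- mm_flatten(three_module_model(use_bus = TRUE))
  expect_identical(fa$variables, fb$variables)
  expect_identical(lapply(fa$reactions, function(r) deparse(r$rate)),
                   lapply(fb$reactions, function(r) deparse(r$rate)))
  expect_identical(fa$provenance, fb$provenance)
})

test_that("flattening a single port-free module is the identity", {
  m <- module_def(
    "solo",
    variables = list(ms_variable("S", 2), ms_variable("P", 0),
                     ms_variable("k", 0.7, kind = "parameter")),
    reactions = list(ms_reaction("conv", c(S = 1), c(P = 1),
                                 rate = quote(k * S))))
  flat <- flatten_single(m)
  expect_setequal(names(flat$variables), c("S", "P", "k"))
  expect_equal(ode_count(flat), 2L)
  expect_equal(deparse(flat$reactions[[1]]$rate), "k * S")

  ## empty model: no reactions, no dynamic states
  empty <- flatten_single(module_def("void", variables = list(
    ms_variable("c0", 1, kind = "parameter"))))
  expect_equal(ode_count(empty), 0L)
})

test_that("flatten raises on validation failure, unit and value conflicts", {
  m_in <- module_def("sink", variables = list(ms_variable("v", 0)),
                     ports = list(ms_port("v", direction = "input")))
  bad <- modular_model(list(m_in), list(
    ms_connection(c("sink", "v"), c("sink", "v"))))
  expect_error(mm_flatten(bad), "does not validate")

  mku <- function(name, unit, value = 1) module_def(
    name, variables = list(ms_variable("v", value, unit = unit)),
    ports = list(ms_port("v", direction = "contact")))
  uc <- modular_model(list(mku("a", "mM"), mku("b", "uM")), list(
    ms_connection(c("a", "v"), c("b", "v"), directed = FALSE)))
  expect_error(mm_flatten(uc), "unit conflict")

  vc <- modular_model(list(mku("a", "mM", 1), mku("b", "mM", 2)), list(
    ms_connection(c("a", "v"), c("b", "v"), directed = FALSE)))
  expect_error(mm_flatten(vc), "initial-value conflict")
})

test_that("merging modules through a contact reduces the state count by one", {
  mk <- function(name) module_def(
    name,
    variables = list(ms_variable("S", 1),
                     ms_variable("k", 0.2, kind = "parameter")),
    reactions = list(ms_reaction("r", c(S = 1), rate = quote(k * S))),
    ports = list(ms_port("S", direction = "contact")))
  disjoint <- mm_flatten(modular_model(list(mk("u"), mk("w"))))
  merged <- mm_flatten(modular_model(
    list(mk("u"), mk("w")),
    list(ms_connection(c("u", "S"), c("w", "S"), directed = FALSE))))
  expect_equal(ode_count(disjoint), 2L)
  expect_equal(ode_count(merged), 1L)
})

test_that("flattened trajectories match the hand-written flat oracle", {
  flat <- mm_flatten(three_module_model())
  oracle <- three_module_manual_flat()
  times <- seq(0, 20, by = 0.5)
  sim <- simulate_flat(flat, times)
  ref <- simulate_flat(oracle, times)
  pairs <- c("M1.A" = "A", "M1.B" = "B", "M1.A:B" = "AB", "M2.C" = "C",
             "M2.C{p}" = "Cp", "M3.X" = "X", "M3.Z" = "Z", "M3.A_1" = "A_1")
  for (q in names(pairs)) {
    expect_equal(sim[, flat_name(flat, q)], ref[, pairs[[q]]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("contact derivatives are the sum of per-module rate contributions", {
  ## two modules each degrade the shared species S with first-order rates;
  ## closed form: S(t) = S0 * exp(-(k1+k2) t)
  mk <- function(name, k) module_def(
    name,
    variables = list(ms_variable("S", 3),
                     ms_variable("k", k, kind = "parameter")),
    reactions = list(ms_reaction("deg", c(S = 1), rate = quote(k * S))),
    ports = list(ms_port("S", direction = "contact")))
  mm <- modular_model(list(mk("m1", 0.11), mk("m2", 0.07)), list(
    ms_connection(c("m1", "S"), c("m2", "S"), directed = FALSE)))
  flat <- mm_flatten(mm)
  times <- seq(0, 10, by = 1)
  sim <- simulate_flat(flat, times)
  expect_equal(sim[, flat_name(flat, "m1.S")], 3 * exp(-0.18 * times),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("discrete events fire at their trigger time in a flat simulation", {
  m <- module_def(
    "ev",
    variables = list(ms_variable("S", 1),
                     ms_variable("k", 0.1, kind = "parameter")),
    reactions = list(ms_reaction("deg", c(S = 1), rate = quote(k * S))),
    events = list(ms_event("halve", quote(t >= 5), list(S = quote(S / 2)))))
  flat <- flatten_single(m)
  sim <- simulate_flat(flat, seq(0, 10, by = 0.25))
  s5m <- sim[sim[, "time"] == 4.75, "S"]
  s5p <- sim[sim[, "time"] == 5.25, "S"]
  expect_lt(s5p, s5m / 2)               # halved, then keeps decaying
  expect_equal(sim[sim[, "time"] == 10, "S"],
               1 * exp(-0.5) / 2 * exp(-0.5), tolerance = 1e-6,
               ignore_attr = TRUE)
})
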