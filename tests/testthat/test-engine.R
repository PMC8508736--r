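# Integration-level behaviour of the assembled muscle model.  The
# simulations used by several tests are computed once here.

cfg <- default_config()
rest_run <- simulate_muscle(cfg, protocol = NULL, t_end = 30, dt_out = 1)
ex70 <- simulate_muscle(cfg, continuous_protocol(0.7, 30),
                        recovery_min = 60, dt_out = 0.5)
ex50 <- simulate_muscle(cfg, continuous_protocol(0.5, 30),
                        recovery_min = 0, dt_out = 0.5)

at <- function(run, t) which.min(abs(run$obs$time - t))

test_that("the default model graph validates and flattens consistently", {
  model <- build_model(cfg)
  expect_equal(nrow(mm_validate(model)), 0L)
  flat <- mm_flatten(model)
  ## every blood-exchanged species is exactly one flat variable with
  ## aliases in the blood module and both transport modules
  for (sp in c("O2", "CO2", "Glc", "Lac", "Pyr", "Ala", "Glr", "FFA", "H")) {
    hits <- vapply(flat$provenance, function(al)
      paste0("blood.", sp) %in% al, logical(1))
    expect_equal(sum(hits), 1L)
    aliases <- flat$provenance[[names(which(hits))]]
    expect_true(all(paste0(c("zblR.", "zblW."), sp, "_b") %in% aliases))
  }
})

test_that("the two fiber branches are structurally identical", {
  model <- build_model(cfg)
  for (pair in list(c("cytR", "cytW"), c("mitR", "mitW"),
                    c("sigR", "sigW"), c("zblR", "zblW"),
                    c("zmtR", "zmtW"), c("zgnR", "zgnW"))) {
    a <- model$modules[[pair[1]]]; b <- model$modules[[pair[2]]]
    expect_identical(names(a$variables), names(b$variables))
    expect_identical(vapply(a$reactions, `[[`, character(1), "id"),
                     vapply(b$reactions, `[[`, character(1), "id"))
    ## same rate laws, differing only in parameter values
    expect_identical(lapply(a$reactions, function(r) deparse(r$rate)),
                     lapply(b$reactions, function(r) deparse(r$rate)))
  }
})

test_that("the resting muscle is at steady state", {
  flat <- rest_run$flat
  rhs <- musclesim:::flat_rhs(flat)
  d0 <- rhs$func(0, rhs$y0, NULL)[[1]]
  expect_lt(max(abs(d0)), 1e-6)
  ## and stays flat over 30 simulated minutes
  drift <- apply(rest_run$states[, -1], 2, function(x)
    max(abs(x - x[1])) / max(abs(x[1]), 1e-12))
  expect_lt(max(drift), 1e-5)
})

test_that("simulation is deterministic", {
  a <- simulate_muscle(cfg, continuous_protocol(0.7, 3), recovery_min = 1,
                       dt_out = 0.5)
  b <- simulate_muscle(cfg, continuous_protocol(0.7, 3), recovery_min = 1,
                       dt_out = 0.5)
  expect_identical(a$states, b$states)
  expect_identical(a$obs, b$obs)
})

test_that("moderate exercise reproduces the expected metabolic pattern", {
  o <- ex70$obs
  i0 <- 1; iend <- at(ex70, 30)
  for (ft in c("I", "II")) {
    expect_lt(o[[paste0("PCr_", ft)]][iend], o[[paste0("PCr_", ft)]][i0])
    expect_gt(o[[paste0("Lac_", ft)]][iend], o[[paste0("Lac_", ft)]][i0])
    expect_lt(o[[paste0("pH_", ft)]][iend], o[[paste0("pH_", ft)]][i0])
    ## ATP approximately constant (creatine-kinase buffering)
    expect_lt(abs(o[[paste0("ATP_", ft)]][iend] -
                    o[[paste0("ATP_", ft)]][i0]) /
                o[[paste0("ATP_", ft)]][i0], 0.05)
  }
  ## muscle pH stays in the physiological window
  expect_true(all(o$pH_I > 6.0 & o$pH_I < 7.4))
  expect_true(all(o$pH_II > 6.0 & o$pH_II < 7.4))
})

test_that("no state becomes negative on the exercise fixture", {
  expect_true(all(ex70$states[, -1] > -1e-8))
})

test_that("all phosphorylation fractions stay within [0, 100]%", {
  o <- ex70$obs
  for (v in grep("pfrac|afrac", names(o), value = TRUE))
    expect_true(all(o[[v]] >= 0 & o[[v]] <= 100), label = v)
})

test_that("blood flow rises during exercise and returns to rest", {
  o <- ex70$obs
  seg <- o$time < 30
  expect_true(all(diff(o$Q[seg]) >= -1e-6))
  expect_gt(o$Q[at(ex70, 30)], 0.9 * 3)
  expect_equal(o$Q[nrow(o)], 0.9, tolerance = 1e-3)
  expect_equal(o$Q[1], 0.9)
})

test_that("signalling readouts increase with exercise intensity", {
  iend <- at(ex70, 30)
  for (v in c("CaMKII_pfrac_I", "AMPK_g3_pfrac_mixed", "CREB1_pfrac_I",
              "Ca_I")) {
    rest_v <- rest_run$obs[[v]][nrow(rest_run$obs)]
    v50 <- ex50$obs[[v]][at(ex50, 30)]
    v70 <- ex70$obs[[v]][iend]
    expect_true(rest_v < v50 && v50 < v70, label = v)
  }
})

test_that("signalling returns to within 1% of baseline an hour after exercise", {
  o <- ex70$obs
  iend <- nrow(o)   # 60 min post-exercise
  for (v in c("Ca_I", "Ca_II", "CaMKII_pfrac_I", "CaMKII_pfrac_II",
              "CRTC_afrac_I", "CREB1_pfrac_I", "AMPK_g3_pfrac_I",
              "AMPK_g3_pfrac_II", "AMPK_a2_pfrac_I")) {
    rel <- abs(o[[v]][iend] - o[[v]][1]) / abs(o[[v]][1])
    expect_lt(rel, 0.01, label = v)
  }
})

test_that("interval exercise imprints one PCr trough per bout", {
  ip <- interval_protocol(16, 32, n_bouts = 4, W_peak = 250)
  ir <- simulate_muscle(cfg, ip, recovery_min = 1, dt_out = 0.02)
  for (v in c("PCr_I", "PCr_II")) {
    pc <- ir$obs[[v]]
    minima <- sum(diff(sign(diff(pc))) > 0)
    expect_equal(minima, 4L, label = v)
  }
})

test_that("trajectories are converged with respect to solver tolerances", {
  p <- continuous_protocol(0.7, 8)
  base <- simulate_muscle(cfg, p, recovery_min = 2, dt_out = 0.5)
  tight <- simulate_muscle(
    default_config(list(solver = list(rtol = 5e-9, atol = 5e-11))),
    p, recovery_min = 2, dt_out = 0.5)
  scale <- apply(abs(base$states[, -1]), 2, max)
  dev <- apply(abs(base$states[, -1] - tight$states[, -1]), 2, max)
  expect_lt(max(dev / pmax(scale, 1e-12)), 1e-3)
})

test_that("removing factor X abolishes the delayed PPARGC1A response", {
  p <- continuous_protocol(0.7, 30)
  with_x <- simulate_muscle(cfg, p, recovery_min = 240, dt_out = 2)
  no_x <- simulate_muscle(
    default_config(list(genes = list(x_factor_enabled = FALSE))),
    p, recovery_min = 240, dt_out = 2)
  expect_gt(max(with_x$obs$PPARGC1A_fold_mixed), 1.3)
  expect_lt(max(no_x$obs$PPARGC1A_fold_mixed), 1.05)
  ## early genes unaffected by the knockout
  expect_equal(max(no_x$obs$NR4A3_fold_mixed),
               max(with_x$obs$NR4A3_fold_mixed), tolerance = 1e-6)
})

test_that("the direct-CREB model variant responds without factor X", {
  p <- continuous_protocol(0.7, 30)
  direct <- simulate_muscle(
    default_config(list(genes = list(direct_creb_regulation = TRUE,
                                     x_factor_enabled = FALSE))),
    p, recovery_min = 240, dt_out = 2)
  o <- direct$obs
  expect_gt(max(o$PPARGC1A_fold_mixed), 1.3)
  ## the direct variant peaks early (no protein-accumulation delay)
  pk <- peak_timing(o$time, o$PPARGC1A_fold_mixed, 30, horizon_h = 4)
  expect_lt(pk, 2)
})

test_that("results export to CSV and configurations round-trip as YAML", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(rest_run, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(rest_run$obs))
  expect_true(all(c("time", "PCr_I", "NR4A3_fold_mixed") %in% names(back)))

  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, ypath)
  back_cfg <- read_config(ypath)
  expect_equal(back_cfg$metabolism$alpha$atpase, cfg$metabolism$alpha$atpase)
  expect_equal(back_cfg$signaling$ampk$a2b2g3, cfg$signaling$ampk$a2b2g3)
  expect_equal(back_cfg$rest$cyt$I, cfg$rest$cyt$I)
})

test_that("the shipped defaults.yaml matches the frozen configuration", {
  path <- system.file("extdata", "defaults.yaml", package = "musclesim")
  expect_true(nzchar(path))
  expect_equal(read_config(path), default_config())
})
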