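#' Simulate the integrated muscle model
#'
#' Builds the modular model for a protocol, flattens it, integrates the
#' stiff hybrid ODE system with restarts at every protocol discontinuity,
#' and computes derived observables (muscle pH, phosphorylation
#' fractions, AMPK activities, mRNA fold changes, mixed-muscle
#' averages).  Deterministic: repeated runs with one configuration give
#' identical results.
#'
#' @param config a [default_config()] list.
#' @param protocol a `ms_protocol` or `NULL` (rest).
#' @param t_end end of the simulated span (min); defaults to the protocol
#'   end plus `recovery_min` (or 60 min at rest).
#' @param recovery_min post-exercise recovery to append (min).
#' @param dt_out output grid step (min).
#' @return a `ms_sim_result`: list with `time`, `states` (matrix of all
#'   state trajectories, flat names), `obs` (data.frame of derived
#'   observables), `flat`, `config`, `protocol`.
#' @export
simulate_muscle <- function(config = default_config(), protocol = NULL,
                            t_end = NULL, recovery_min = 30,
                            dt_out = config$solver$dt_out) {
  if (is.null(t_end))
    t_end <- if (is.null(protocol)) 60 else protocol$t_end + recovery_min
  model <- build_model(config, protocol)
  flat <- mm_flatten(model)
  times <- seq(0, t_end, by = dt_out)
  breaks <- if (is.null(protocol)) numeric() else protocol$events
  states <- simulate_flat(flat, times, breaks = breaks,
                          rtol = config$solver$rtol,
                          atol = config$solver$atol)
  if (anyNA(states) || any(!is.finite(states)))
    stop("simulation produced non-finite values")
  res <- structure(
    list(time = states[, "time"], states = states, flat = flat,
         config = config, protocol = protocol),
    class = "ms_sim_result")
  res$obs <- compute_observables(res)
  res
}

#' Extract one state trajectory by qualified name
#'
#' @param result a `ms_sim_result`.
#' @param qualified `"module.variable"` name (any alias of the flat
#'   variable).
#' @return numeric trajectory on the output grid.
#' @export
sim_state <- function(result, qualified) {
  result$states[, flat_name(result$flat, qualified)]
}

compute_observables <- function(res) {
  cfg <- res$config
  g <- function(q) sim_state(res, q)
  tt <- res$time
  V_R <- cfg$physiology$V_R; V_W <- cfg$physiology$V_W
  mx <- function(a, b) mixed_muscle(a, b, V_R, V_W)
  tot <- cfg$signaling$ampk$total

  ## work-rate inputs are algebraic; recompute from the protocol
  rec <- with(cfg$recruitment, recruitment_model(W_max, theta, cap_I, cap_II))
  fat <- if (isTRUE(cfg$fatigue$enabled))
    fatigue_model(TRUE, cfg$fatigue$decline) else NULL
  power <- if (is.null(res$protocol)) {
    zero <- function(t) rep(0, length(t))
    list(W_I = zero, W_II = zero, W = zero)
  } else apply_fatigue(res$protocol, rec, fat)
  W_I <- power$W_I(tt); W_II <- power$W_II(tt)
  obs <- data.frame(
    time = tt,
    W = W_I + W_II, W_I = W_I, W_II = W_II,
    Q = cfg$physiology$Q0 * g("blood.act_Q"),
    V_mus = cfg$physiology$V_mus0 * g("blood.act_V"))
  derived <- derive_parameters(cfg)

  for (d in list(c("I", "R"), c("II", "W"))) {
    ft <- d[[1]]; s <- d[[2]]
    cyt <- function(v) g(paste0("cyt", s, ".", v))
    sig <- function(v) g(paste0("sig", s, ".", v))
    obs[[paste0("PCr_", ft)]] <- cyt("PCr")
    obs[[paste0("ATP_", ft)]] <- cyt("ATP")
    obs[[paste0("Lac_", ft)]] <- cyt("Lac")
    obs[[paste0("Gly_", ft)]] <- cyt("Gly")
    obs[[paste0("pH_", ft)]] <- ph_from_proton(cyt("H"))
    eq <- free_adp_amp(cyt("ATP"), cyt("PCr"), cyt("Cr"), cyt("H") * 1e-3,
                       cfg$metabolism$Keq_CK, cfg$metabolism$Keq_AK)
    obs[[paste0("ADP_free_", ft)]] <- eq$ADP
    obs[[paste0("AMP_free_", ft)]] <- eq$AMP
    obs[[paste0("Ca_", ft)]] <- sig("Ca")
    obs[[paste0("CaMKII_pfrac_", ft)]] <- 100 * sig("CaMKII_p")
    obs[[paste0("CRTC_afrac_", ft)]] <- 100 * sig("CRTC_a")
    obs[[paste0("CREB1_pfrac_", ft)]] <- 100 * sig("CREB1_p")
    ## AMPK phospho-fractions (%), per heterotrimer and alpha2-containing
    obs[[paste0("AMPK_g3_pfrac_", ft)]] <-
      100 * sig("P_g3") / tot[["a2b2g3"]]
    obs[[paste0("AMPK_a2_pfrac_", ft)]] <-
      100 * (sig("P_g3") + sig("P_g1a2")) /
      (tot[["a2b2g3"]] + tot[["a2b2g1"]])
    r0 <- rest_signaling(cfg, ft, derived)
    hn <- c(a2b2g3 = "P_g3", a2b2g1 = "P_g1a2", a1b2g1 = "P_g1a1")
    act <- 0
    for (h in names(hn)) {
      p <- cfg$signaling$ampk[[h]]
      p$ratio0 <- r0$amp_ratio0
      act <- act + ampk_activity(sig(hn[[h]]), tot[[h]], eq$AMP,
                                 cyt("ATP"), p)
    }
    obs[[paste0("AMPK_act_", ft)]] <- act
    for (gene in c("NR4A3", "NR4A2", "X", "PPARGC1A")) {
      v <- g(paste0("zgn", s, ".m", gene))
      obs[[paste0(gene, "_fold_", ft)]] <- fold_change(tt, v)
    }
  }

  ## mixed-muscle (volume-weighted) readouts
  for (v in c("PCr", "Lac", "pH"))
    obs[[paste0(v, "_mixed")]] <- mx(obs[[paste0(v, "_I")]],
                                     obs[[paste0(v, "_II")]])
  for (gene in c("NR4A3", "NR4A2", "X", "PPARGC1A"))
    obs[[paste0(gene, "_fold_mixed")]] <- mx(obs[[paste0(gene, "_fold_I")]],
                                             obs[[paste0(gene, "_fold_II")]])
  for (v in c("AMPK_g3_pfrac", "AMPK_a2_pfrac", "CaMKII_pfrac",
              "CREB1_pfrac"))
    obs[[paste0(v, "_mixed")]] <- mx(obs[[paste0(v, "_I")]],
                                     obs[[paste0(v, "_II")]])
  obs
}

#' @export
print.ms_sim_result <- function(x, ...) {
  lbl <- if (is.null(x$protocol)) "rest" else x$protocol$label
  cat(sprintf("Muscle simulation (%s): %d time points over %g min, %d states\n",
              lbl, length(x$time), max(x$time), ncol(x$states) - 1L))
  invisible(x)
}

#' Write simulation observables to CSV
#'
#' @param result a `ms_sim_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results_csv <- function(result, path) {
  utils::write.csv(result$obs, path, row.names = FALSE)
  invisible(path)
}
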