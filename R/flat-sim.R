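#' Build the ODE right-hand side of a flat model
#'
#' Generates (by code generation, for speed) a `function(t, y, parms)`
#' suitable for [deSolve::ode()]: it unpacks the dynamic state, evaluates
#' all algebraic assignments in dependency order, evaluates every reaction
#' flux, and accumulates stoichiometry-weighted, volume-normalised
#' derivatives plus any rate rules.  Non-dynamic variables (parameters,
#' boundary species) are bound as constants in the enclosing environment.
#'
#' @param flat a `ms_flat_model`.
#' @return list with `func` (the deSolve derivative function), `y0` (named
#'   initial state) and `states` (state names in order).
#' @keywords internal
flat_rhs <- function(flat) {
  states <- dynamic_states(flat)
  n <- length(states)
  bt <- function(x) paste0("`", x, "`")

  ## evaluation environment: parameters, constants, module functions;
  ## parented on the package namespace so rate laws can use the exported
  ## kinetic helpers (hill, mm_norm, facilitated_flux, ...)
  env <- new.env(parent = parent.env(environment()))
  for (v in flat$variables)
    if (!v$name %in% states) assign(v$name, v$value, envir = env)
  for (fn in names(flat$functions)) assign(fn, flat$functions[[fn]], envir = env)

  vol_expr <- function(species) {
    comp <- flat$variables[[species]]$compartment
    if (is.na(comp)) return("1")
    vol <- flat$compartments[[comp]]
    if (is.null(vol)) stop("no volume variable declared for compartment '",
                           comp, "' (species '", species, "')")
    bt(vol)
  }

  lines <- character()
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%s <- y[[%dL]]", bt(states[[i]]), i))

  ## assignments in dependency order
  asg <- topo_sort_assignments(flat$assignments)
  for (a in asg)
    lines <- c(lines, sprintf("%s <- %s", bt(a$variable),
                              paste(deparse(a$expr), collapse = " ")))

  ## reaction fluxes
  terms <- stats::setNames(vector("list", n), states)   # derivative terms
  for (k in seq_along(flat$reactions)) {
    r <- flat$reactions[[k]]
    fx <- sprintf(".flux%d", k)
    lines <- c(lines, sprintf("%s <- %s", fx,
                              paste(deparse(r$rate), collapse = " ")))
    st <- c(-r$reactants, r$products)
    ## same species on both sides: net stoichiometry
    st <- tapply(st, names(st), sum)
    for (sp in names(st)) {
      if (st[[sp]] == 0) next
      terms[[sp]] <- c(terms[[sp]],
                       sprintf("%s * %s / %s", format(st[[sp]]), fx, vol_expr(sp)))
    }
  }
  for (rr in flat$rate_rules)
    terms[[rr$variable]] <- c(terms[[rr$variable]],
                              paste(deparse(rr$expr), collapse = " "))

  lines <- c(lines, sprintf(".d <- numeric(%dL)", n))
  for (i in seq_len(n)) {
    sp <- states[[i]]
    tm <- terms[[sp]]
    rhs <- if (length(tm)) paste(tm, collapse = " + ") else "0"
    buf <- flat$variables[[sp]]$buffered
    if (!is.na(buf))
      rhs <- sprintf("2.302585092994046 * %s * (%s) / %s", bt(sp), rhs, bt(buf))
    lines <- c(lines, sprintf(".d[[%dL]] <- %s", i, rhs))
  }
  lines <- c(lines, "list(.d)")

  src <- paste0("function(t, y, parms) {\n",
                paste(lines, collapse = "\n"), "\n}")
  func <- eval(parse(text = src)[[1L]], envir = env)

  y0 <- vapply(states, function(s) flat$variables[[s]]$value, numeric(1))
  list(func = func, y0 = y0, states = states, env = env)
}

## order assignments so that each target is computed before it is used
topo_sort_assignments <- function(assignments) {
  if (!length(assignments)) return(list())
  tgts <- vapply(assignments, `[[`, character(1), "variable")
  deps <- lapply(assignments, function(a) intersect(expr_symbols(a$expr), tgts))
  names(deps) <- tgts
  done <- character(); out <- list()
  pending <- tgts
  while (length(pending)) {
    ready <- pending[vapply(pending, function(tg)
      all(deps[[tg]] %in% done), logical(1))]
    if (!length(ready))
      stop("cyclic assignment dependency among: ",
           paste(pending, collapse = ", "))
    for (tg in ready) out[[length(out) + 1L]] <- assignments[[match(tg, tgts)]]
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  out
}

#' Numerically integrate a flat model
#'
#' Integrates the flattened hybrid ODE system with a stiff BDF solver
#' ([deSolve::vode()] with internally generated full Jacobian).  Discrete
#' events of the flat model and externally supplied break times (e.g.
#' exercise-protocol discontinuities) partition the integration into
#' segments so that no discontinuity is stepped over; events firing at the
#' same instant execute in their stored (module-name) order.
#'
#' Supported event triggers are `t >= c` / `t > c` with constant `c`
#' (time events) and arbitrary numeric expressions fired at their first
#' upward zero-crossing (root events).
#'
#' @param flat a `ms_flat_model`.
#' @param times output time grid.
#' @param breaks additional times at which integration restarts.
#' @param rtol,atol relative/absolute solver tolerance.
#' @param maxsteps maximum internal steps per output interval.
#' @return matrix (deSolve style): column `time` then one column per
#'   dynamic state.
#' @export
simulate_flat <- function(flat, times, breaks = numeric(),
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000L) {
  rhs <- flat_rhs(flat)
  if (length(rhs$states) == 0L)
    return(cbind(time = times))

  ## classify events
  tev <- list(); rev_ <- list()
  for (ev in flat$events) {
    tr <- ev$trigger
    if (is.call(tr) && as.character(tr[[1L]]) %in% c(">=", ">") &&
        identical(tr[[2L]], as.name("t")) && is.numeric(tr[[3L]]))
      tev[[length(tev) + 1L]] <- list(at = tr[[3L]], ev = ev)
    else rev_[[length(rev_) + 1L]] <- ev
  }

  apply_event <- function(ev, t, y) {
    e <- new.env(parent = rhs$env)
    for (i in seq_along(rhs$states)) assign(rhs$states[[i]], y[[i]], envir = e)
    assign("t", t, envir = e)
    for (a in topo_sort_assignments(flat$assignments))
      assign(a$variable, eval(a$expr, envir = e), envir = e)
    for (v in names(ev$assignments)) {
      val <- eval(ev$assignments[[v]], envir = e)
      i <- match(v, rhs$states)
      if (is.na(i)) stop("event assigns non-dynamic variable: ", v)
      y[[i]] <- val
    }
    y
  }

  stops <- sort(unique(c(breaks,
                         vapply(tev, function(x) x$at, numeric(1)))))
  stops <- stops[stops > min(times) & stops < max(times)]
  edges <- unique(c(min(times), stops, max(times)))
  ## merge numerically coincident segment edges
  edges <- edges[c(TRUE, diff(edges) > 1e-7)]
  if (edges[length(edges)] < max(times)) edges[length(edges)] <- max(times)

  rootfun <- if (length(rev_)) {
    function(t, y, parms) {
      e <- new.env(parent = rhs$env)
      for (i in seq_along(rhs$states)) assign(rhs$states[[i]], y[[i]], envir = e)
      assign("t", t, envir = e)
      for (a in topo_sort_assignments(flat$assignments))
        assign(a$variable, eval(a$expr, envir = e), envir = e)
      vapply(rev_, function(ev) as.numeric(eval(ev$trigger, envir = e)),
             numeric(1))
    }
  } else NULL

  y <- rhs$y0
  out <- NULL
  for (s in seq_len(length(edges) - 1L)) {
    t0 <- edges[[s]]; t1 <- edges[[s + 1L]]
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    ## fire pending time events at segment start
    for (x in tev) if (isTRUE(all.equal(x$at, t0))) y <- apply_event(x$ev, t0, y)
    sol <- if (is.null(rootfun)) {
      ## stiff BDF (VODE, mf = 22: internally generated full Jacobian)
      deSolve::ode(y = y, times = seg_times, func = rhs$func,
                   parms = NULL, method = "vode", mf = 22,
                   rtol = rtol, atol = atol, maxsteps = maxsteps)
    } else {
      ## root-triggered events need lsodar (stiff/BDF when it matters)
      deSolve::ode(y = y, times = seg_times, func = rhs$func,
                   parms = NULL, method = "lsodar",
                   rtol = rtol, atol = atol, maxsteps = maxsteps,
                   rootfun = rootfun,
                   events = list(func = function(t, y, parms) {
                     for (ev in rev_) y <- apply_event(ev, t, y)
                     y
                   }, root = TRUE))
    }
    y <- as.numeric(sol[nrow(sol), -1L])
    out <- if (is.null(out)) sol else rbind(out, sol[-1L, , drop = FALSE])
  }
  colnames(out) <- c("time", rhs$states)
  ## drop helper rows added at segment edges that are not on the grid
  out[out[, "time"] %in% times, , drop = FALSE]
}
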