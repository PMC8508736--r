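#' Flatten a modular model into a single hybrid ODE model
#'
#' Resolves the connection/bus graph by union-find over qualified variable
#' names (`module.variable`): each equivalence class of connected variables
#' becomes exactly one flat variable, named after the lexicographically
#' first qualified name in the class.  All reactions, assignments, rate
#' rules and events of all modules are carried over with their symbols
#' rewritten to flat names, so a contact variable automatically accumulates
#' the rate contributions of every module that modifies it.  The provenance
#' map records every original qualified name for each flat variable.
#'
#' Merging raises an error on conflicting non-empty units, on conflicting
#' initial values (only variables behind `input` ports yield their value to
#' the driver), and on conflicting compartment attributions.
#'
#' @param model a validated [modular_model()].
#' @return an object of class `ms_flat_model` with elements `variables`
#'   (named list of [ms_variable()]), `reactions`, `assignments`,
#'   `rate_rules`, `events`, `functions`, `compartments` and `provenance`.
#' @export
mm_flatten <- function(model) {
  stopifnot(inherits(model, "ms_modular_model"))
  diags <- mm_validate(model)
  if (nrow(diags))
    stop("model does not validate:\n  ",
         paste(diags$message, collapse = "\n  "))

  qname <- function(module, var) paste(module, var, sep = ".")

  ## ---- union-find over qualified names -------------------------------
  parent <- new.env(parent = emptyenv())
  uf_find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (identical(p, x)) return(x)
    r <- uf_find(p)
    assign(x, r, envir = parent)
    r
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (!identical(ra, rb)) assign(ra, rb, envir = parent)
  }

  all_q <- character()
  is_input_var <- character()       # qualified names behind input ports
  for (m in model$modules) {
    for (v in m$variables) all_q <- c(all_q, qname(m$name, v$name))
    for (p in m$ports)
      if (p$direction == "input")
        is_input_var <- c(is_input_var, qname(m$name, p$variable))
  }

  port_var <- function(ep) {
    p <- port_lookup(model, ep[1L], ep[2L])
    qname(ep[1L], p$variable)
  }
  for (cn in model$connections) uf_union(port_var(cn$from), port_var(cn$to))
  for (b in model$buses) {
    qs <- vapply(b$ports, port_var, character(1))
    if (length(qs) > 1L) for (i in seq_along(qs)[-1L]) uf_union(qs[1L], qs[i])
  }

  roots <- vapply(all_q, uf_find, character(1))
  classes <- split(all_q, roots)

  ## ---- one flat variable per class -----------------------------------
  variables <- list()
  provenance <- list()
  flat_of <- character()          # qualified name -> flat name
  for (cls in classes) {
    cls <- sort(cls)
    flat <- cls[[1L]]
    members <- lapply(cls, function(q) {
      ## module names contain no "."; variable names may
      mod <- sub("\\..*$", "", q)
      var <- sub("^[^.]+\\.", "", q)
      model$modules[[mod]]$variables[[var]]
    })
    units <- unique(Filter(nzchar, vapply(members, `[[`, character(1), "unit")))
    if (length(units) > 1L)
      stop("unit conflict for merged variable '", flat, "': ",
           paste(units, collapse = " vs "))
    comps <- unique(stats::na.omit(vapply(members, `[[`, character(1), "compartment")))
    if (length(comps) > 1L)
      stop("compartment conflict for merged variable '", flat, "': ",
           paste(comps, collapse = " vs "))
    owns_value <- !(cls %in% is_input_var)
    vals <- unique(vapply(members[owns_value], `[[`, numeric(1), "value"))
    if (length(vals) > 1L)
      stop("initial-value conflict for merged variable '", flat, "': ",
           paste(vals, collapse = " vs "))
    if (!length(vals)) vals <- members[[1L]]$value
    kinds <- vapply(members, `[[`, character(1), "kind")
    ## qualify buffer-parameter references for later remapping
    buf <- character()
    for (i in seq_along(members))
      if (!is.na(members[[i]]$buffered))
        buf <- c(buf, qname(sub("\\..*$", "", cls[[i]]),
                            members[[i]]$buffered))
    buf <- unique(buf)
    v <- ms_variable(flat, value = vals[[1L]],
                     kind = if (any(kinds == "species")) "species" else "parameter",
                     unit = if (length(units)) units else "",
                     compartment = if (length(comps)) comps else NA_character_,
                     buffered = if (length(buf)) buf[[1L]] else NA_character_)
    variables[[flat]] <- v
    provenance[[flat]] <- cls
    flat_of[cls] <- flat
  }

  ## buffer parameters now resolve to flat names
  for (fv in names(variables))
    if (!is.na(variables[[fv]]$buffered))
      variables[[fv]]$buffered <- flat_of[[variables[[fv]]$buffered]]

  ## ---- carry over elements with renamed symbols ----------------------
  reactions <- list(); assignments <- list(); rate_rules <- list()
  events <- list(); functions <- list(); compartments <- character()

  for (m in model$modules) {
    map <- as.list(flat_of[qname(m$name, names(m$variables))])
    names(map) <- names(m$variables)
    ren <- function(e) expr_rename(e, map)
    ren_names <- function(x) { names(x) <- unlist(map[names(x)]); x }

    for (r in m$reactions)
      reactions[[length(reactions) + 1L]] <- ms_reaction(
        id = paste(m$name, r$id, sep = "."),
        reactants = ren_names(r$reactants),
        products = ren_names(r$products),
        modifiers = unlist(map[r$modifiers], use.names = FALSE) %||% character(),
        rate = ren(r$rate))

    for (a in m$assignments) {
      tgt <- map[[a$variable]]
      if (!is.null(assignments[[tgt]]))
        stop("conflicting assignments for flat variable '", tgt, "'")
      assignments[[tgt]] <- ms_assignment(tgt, ren(a$expr))
    }

    for (rr in m$rate_rules) {
      tgt <- map[[rr$variable]]
      if (is.null(rate_rules[[tgt]]))
        rate_rules[[tgt]] <- ms_rate_rule(tgt, ren(rr$expr))
      else   # contact variables accumulate rate contributions
        rate_rules[[tgt]] <- ms_rate_rule(
          tgt, call("+", rate_rules[[tgt]]$expr, ren(rr$expr)))
    }

    for (ev in m$events) {
      asg <- lapply(ev$assignments, ren)
      names(asg) <- unlist(map[names(ev$assignments)])
      events[[length(events) + 1L]] <-
        ms_event(paste(m$name, ev$id, sep = "."), ren(ev$trigger), asg)
    }

    for (fn in names(m$functions)) {
      if (!is.null(functions[[fn]]) &&
          !identical(functions[[fn]], m$functions[[fn]]))
        stop("conflicting definitions of function '", fn, "'")
      functions[[fn]] <- m$functions[[fn]]
    }

    for (cn in names(m$compartments)) {
      vol <- flat_of[[qname(m$name, m$compartments[[cn]])]]
      if (cn %in% names(compartments) && compartments[[cn]] != vol)
        stop("conflicting volume variables for compartment '", cn, "'")
      compartments[cn] <- vol
    }
  }

  ## events from different modules firing together run in module-name order
  if (length(events))
    events <- events[order(vapply(events, `[[`, character(1), "id"))]

  structure(list(variables = variables, reactions = reactions,
                 assignments = assignments, rate_rules = rate_rules,
                 events = events, functions = functions,
                 compartments = compartments, provenance = provenance),
            class = "ms_flat_model")
}

#' Number of dynamic state variables of a flat model
#'
#' A variable is dynamic when it is a species consumed or produced by at
#' least one reaction, or the target of a rate rule.
#'
#' @param flat a `ms_flat_model`.
#' @return integer count (the number of ODEs of the flat system).
#' @export
ode_count <- function(flat) {
  length(dynamic_states(flat))
}

dynamic_states <- function(flat) {
  stopifnot(inherits(flat, "ms_flat_model"))
  dyn <- character()
  for (r in flat$reactions)
    dyn <- c(dyn, names(r$reactants), names(r$products))
  dyn <- c(dyn, names(flat$rate_rules))
  dyn <- unique(dyn)
  ## keep declared order
  names(flat$variables)[names(flat$variables) %in% dyn]
}

#' Resolve a qualified variable name to its flat name
#'
#' @param flat a `ms_flat_model`.
#' @param qualified `"module.variable"` name as written in any source module.
#' @return the flat variable name.
#' @export
flat_name <- function(flat, qualified) {
  for (fn in names(flat$provenance))
    if (qualified %in% flat$provenance[[fn]]) return(fn)
  if (qualified %in% names(flat$variables)) return(qualified)
  stop("unknown qualified variable: ", qualified)
}

#' @export
print.ms_flat_model <- function(x, ...) {
  cat("Flat model:", length(x$variables), "variables (",
      ode_count(x), "dynamic ),", length(x$reactions), "reactions,",
      length(x$assignments), "assignments,", length(x$events), "events\n")
  invisible(x)
}

#' Wrap a single module as an already-flat model
#'
#' Flattening a one-module model with no ports preserves all names except
#' for module qualification; this helper flattens and then strips the
#' redundant qualifier, so the result is the module itself (identity).
#'
#' @param module a [module_def()].
#' @return `ms_flat_model`.
#' @export
flatten_single <- function(module) {
  flat <- mm_flatten(modular_model(list(module)))
  prefix <- paste0(module$name, ".")
  map <- as.list(sub(prefix, "", names(flat$variables), fixed = TRUE))
  names(map) <- names(flat$variables)
  rename_flat(flat, map)
}

## rename flat variables according to map old -> new (internal)
rename_flat <- function(flat, map) {
  ren <- function(e) expr_rename(e, map)
  nm <- function(x) { if (length(x)) names(x) <- unlist(map[names(x)]); x }
  variables <- lapply(flat$variables, function(v) {
    v$name <- map[[v$name]]
    if (!is.na(v$buffered)) v$buffered <- map[[v$buffered]] %||% v$buffered
    v
  })
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  reactions <- lapply(flat$reactions, function(r) {
    r$reactants <- nm(r$reactants); r$products <- nm(r$products)
    r$modifiers <- unlist(map[r$modifiers], use.names = FALSE) %||% character()
    r$rate <- ren(r$rate); r
  })
  assignments <- lapply(flat$assignments, function(a)
    ms_assignment(map[[a$variable]], ren(a$expr)))
  names(assignments) <- vapply(assignments, `[[`, character(1), "variable")
  rate_rules <- lapply(flat$rate_rules, function(r)
    ms_rate_rule(map[[r$variable]], ren(r$expr)))
  names(rate_rules) <- vapply(rate_rules, `[[`, character(1), "variable")
  events <- lapply(flat$events, function(ev) {
    asg <- lapply(ev$assignments, ren)
    names(asg) <- unlist(map[names(ev$assignments)])
    ms_event(ev$id, ren(ev$trigger), asg)
  })
  compartments <- flat$compartments
  if (length(compartments))
    compartments[] <- unlist(map[compartments])
  provenance <- flat$provenance
  names(provenance) <- unlist(map[names(provenance)])
  structure(list(variables = variables, reactions = reactions,
                 assignments = assignments, rate_rules = rate_rules,
                 events = events, functions = flat$functions,
                 compartments = compartments, provenance = provenance),
            class = "ms_flat_model")
}
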