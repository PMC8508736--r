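#' @title Port-based modular models
#'
#' @description
#' A modular model is a set of independently defined kinetic modules (state
#' variables, reactions, assignments, rate rules, discrete events) whose
#' interfaces are *ports*: named references to module variables with one of
#' three directions.  `input` ports receive a value computed elsewhere,
#' `output` ports expose a value computed inside the module, and `contact`
#' ports expose a shared variable that several modules may modify
#' simultaneously (their rate contributions add).  Directed connections link
#' an output to an input; undirected connections link contact to contact.
#' A *bus* is a named junction: every port attached to clones of one bus
#' resolves to the same variable, which only declutters the wiring and never
#' changes semantics.
#'
#' Models built from these pieces are checked with [mm_validate()] and
#' collapsed into a single flat hybrid ODE system with [mm_flatten()].
#'
#' @name model-graph
NULL

#' Declare a module variable
#'
#' @param name variable name (any string; species names such as `"A:B"` or
#'   `"C{p}"` are allowed).
#' @param value initial value (species) or constant value (parameter).
#' @param kind `"species"` (may change dynamically) or `"parameter"`.
#' @param unit opaque unit string; merged variables with differing non-empty
#'   units are a flattening error.
#' @param compartment optional compartment name; species derivatives are
#'   divided by the compartment volume (see [module_def()] `compartments`).
#' @param buffered optional name of a buffer-capacity parameter `beta`; the
#'   raw per-volume derivative `d` of a buffered species `H` is transformed
#'   to `log(10) * H * d / beta`, which keeps `-log10(H)` dynamics on a
#'   physical buffering scale (used for protons).
#' @return a `ms_variable` object.
#' @export
ms_variable <- function(name, value = 0, kind = c("species", "parameter"),
                        unit = "", compartment = NA_character_,
                        buffered = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(value), length(value) == 1L)
  structure(list(name = name, value = as.numeric(value), kind = kind,
                 unit = unit, compartment = compartment, buffered = buffered),
            class = "ms_variable")
}

#' Declare a module port
#'
#' @param name port name.
#' @param variable name of the module variable the port exposes.
#' @param direction one of `"input"`, `"output"`, `"contact"`.
#' @return a `ms_port` object.
#' @export
ms_port <- function(name, variable = name,
                    direction = c("input", "output", "contact")) {
  direction <- match.arg(direction)
  structure(list(name = name, variable = variable, direction = direction),
            class = "ms_port")
}

#' Declare a reaction
#'
#' Rate expressions are unevaluated R expressions over module variable
#' names, `t`, and functions declared in the module (or base R maths); the
#' rate is the total reaction flux in amount per time (for compartmental
#' species the species derivative is the stoichiometry-weighted flux divided
#' by the compartment volume).
#'
#' @param id reaction identifier, unique within the module.
#' @param reactants,products named numeric vectors of stoichiometries.
#' @param modifiers character vector of variables appearing in the rate law
#'   without being consumed or produced.
#' @param rate an unevaluated expression (`quote(...)` or [bquote()]).
#' @return a `ms_reaction` object.
#' @export
ms_reaction <- function(id, reactants = numeric(), products = numeric(),
                        modifiers = character(), rate) {
  stopifnot(is.numeric(reactants), is.numeric(products))
  if (length(reactants)) stopifnot(!is.null(names(reactants)))
  if (length(products)) stopifnot(!is.null(names(products)))
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, rate = rate),
            class = "ms_reaction")
}

#' Declare an algebraic assignment, a rate rule, or a discrete event
#'
#' Assignments are evaluated (in dependency order) before any rate law;
#' rate rules contribute `d(variable)/dt = expr` directly; events fire when
#' the trigger becomes true and apply their assignments instantaneously.
#'
#' @param variable target variable name.
#' @param expr unevaluated expression.
#' @return the corresponding object.
#' @export
ms_assignment <- function(variable, expr) {
  structure(list(variable = variable, expr = expr), class = "ms_assignment")
}

#' @rdname ms_assignment
#' @export
ms_rate_rule <- function(variable, expr) {
  structure(list(variable = variable, expr = expr), class = "ms_rate_rule")
}

#' @rdname ms_assignment
#' @param id event identifier.
#' @param trigger unevaluated boolean expression (e.g. `quote(t >= 5)`).
#' @param assignments named list of unevaluated expressions, one per target
#'   variable.
#' @export
ms_event <- function(id, trigger, assignments) {
  stopifnot(is.list(assignments), !is.null(names(assignments)))
  structure(list(id = id, trigger = trigger, assignments = assignments),
            class = "ms_event")
}

#' Define a module
#'
#' @param name module name (used to qualify variables as `module.variable`).
#' @param variables list of [ms_variable()].
#' @param reactions list of [ms_reaction()].
#' @param assignments list of [ms_assignment()].
#' @param rate_rules list of [ms_rate_rule()].
#' @param events list of [ms_event()].
#' @param ports list of [ms_port()].
#' @param functions named list of R functions available to this module's
#'   expressions (closures survive flattening; they make a flat model
#'   non-exportable to SBML).
#' @param compartments named character vector mapping compartment name to
#'   the module variable holding its volume.
#' @return a `ms_module` object.
#' @export
module_def <- function(name, variables = list(), reactions = list(),
                       assignments = list(), rate_rules = list(),
                       events = list(), ports = list(), functions = list(),
                       compartments = character()) {
  if (grepl(".", name, fixed = TRUE))
    stop("module names must not contain '.': ", name)
  vn <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vn))
    stop("module '", name, "': duplicated variable names: ",
         paste(unique(vn[duplicated(vn)]), collapse = ", "))
  for (p in ports)
    if (!p$variable %in% vn)
      stop("module '", name, "': port '", p$name,
           "' references unknown variable '", p$variable, "'")
  known <- c(vn, "t", names(functions))
  for (r in reactions) {
    bad <- setdiff(expr_symbols(r$rate), known)
    if (length(bad))
      stop("module '", name, "': rate of reaction '", r$id,
           "' references unknown symbols: ", paste(bad, collapse = ", "))
    sb <- setdiff(c(names(r$reactants), names(r$products), r$modifiers), vn)
    if (length(sb))
      stop("module '", name, "': reaction '", r$id,
           "' references unknown species: ", paste(sb, collapse = ", "))
  }
  names(variables) <- vn
  structure(list(name = name, variables = variables, reactions = reactions,
                 assignments = assignments, rate_rules = rate_rules,
                 events = events, ports = ports, functions = functions,
                 compartments = compartments),
            class = "ms_module")
}

#' Connect two module ports
#'
#' @param from,to length-2 character vectors `c(module, port)`.  For a
#'   directed connection `from` must be an output and `to` an input port;
#'   undirected connections join two contact ports.
#' @param directed logical.
#' @return a `ms_connection` object.
#' @export
ms_connection <- function(from, to, directed = TRUE) {
  stopifnot(length(from) == 2L, length(to) == 2L)
  structure(list(from = from, to = to, directed = isTRUE(directed)),
            class = "ms_connection")
}

#' Attach ports to a named bus
#'
#' @param name bus name.
#' @param ports list of length-2 character vectors `c(module, port)`.
#' @return a `ms_bus` object.
#' @export
ms_bus <- function(name, ports) {
  structure(list(name = name, ports = ports), class = "ms_bus")
}

#' Assemble a modular model
#'
#' @param modules list of [module_def()] objects.
#' @param connections list of [ms_connection()] objects.
#' @param buses list of [ms_bus()] objects.
#' @return a `ms_modular_model` object.
#' @export
modular_model <- function(modules, connections = list(), buses = list()) {
  stopifnot(length(modules) >= 1L)
  mn <- vapply(modules, function(m) m$name, character(1))
  if (anyDuplicated(mn)) stop("duplicated module names")
  names(modules) <- mn
  structure(list(modules = modules, connections = connections, buses = buses),
            class = "ms_modular_model")
}

#' @export
print.ms_modular_model <- function(x, ...) {
  cat("Modular model:", length(x$modules), "modules,",
      length(x$connections), "connections,", length(x$buses), "buses\n")
  for (m in x$modules)
    cat("  -", m$name, ":", length(m$variables), "variables,",
        length(m$reactions), "reactions,", length(m$ports), "ports\n")
  invisible(x)
}

## All symbols used in an expression, excluding call heads (function names).
expr_symbols <- function(e) {
  syms <- character()
  walk <- function(x) {
    if (is.name(x)) {
      syms[[length(syms) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      for (a in as.list(x)[-1L]) if (!missing(a)) walk(a)
    }
  }
  walk(e)
  unique(syms)
}

## Function names called anywhere in an expression.
expr_fun_names <- function(e) {
  fns <- character()
  walk <- function(x) {
    if (is.call(x)) {
      if (is.name(x[[1L]])) fns[[length(fns) + 1L]] <<- as.character(x[[1L]])
      for (a in as.list(x)[-1L]) if (!missing(a)) walk(a)
    }
  }
  walk(e)
  unique(fns)
}

## Rename symbols in an expression according to a named map old -> new.
expr_rename <- function(e, map) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (!is.null(map[[nm]])) return(as.name(map[[nm]]))
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- expr_rename(e[[i]], map)
    return(e)
  }
  e
}

port_lookup <- function(model, module, port) {
  m <- model$modules[[module]]
  if (is.null(m)) return(NULL)
  for (p in m$ports) if (p$name == port) return(p)
  NULL
}

#' Validate a modular model
#'
#' Checks, without raising, that every connection endpoint exists, that
#' directed connections link an output to an input and undirected
#' connections link contact to contact, and that every connected input port
#' has exactly one driver (counting outputs sharing a bus).
#'
#' @param model a [modular_model()].
#' @return a data.frame of diagnostics with columns `type` and `message`;
#'   empty when the model is well formed.
#' @export
mm_validate <- function(model) {
  stopifnot(inherits(model, "ms_modular_model"))
  diags <- list()
  note <- function(type, message)
    diags[[length(diags) + 1L]] <<- data.frame(type = type, message = message)

  drivers <- list()   # input "module.port" -> number of driving outputs
  add_driver <- function(module, port)
    drivers[[paste(module, port, sep = ".")]] <<-
      (drivers[[paste(module, port, sep = ".")]] %||% 0L) + 1L

  for (cn in model$connections) {
    pa <- port_lookup(model, cn$from[1L], cn$from[2L])
    pb <- port_lookup(model, cn$to[1L], cn$to[2L])
    if (is.null(pa)) note("dangling port",
        sprintf("connection endpoint %s.%s does not exist", cn$from[1L], cn$from[2L]))
    if (is.null(pb)) note("dangling port",
        sprintf("connection endpoint %s.%s does not exist", cn$to[1L], cn$to[2L]))
    if (is.null(pa) || is.null(pb)) next
    if (cn$directed) {
      if (pa$direction != "output" || pb$direction != "input")
        note("direction typing",
             sprintf("directed connection %s.%s (%s) -> %s.%s (%s) must link output to input",
                     cn$from[1L], cn$from[2L], pa$direction,
                     cn$to[1L], cn$to[2L], pb$direction))
      else add_driver(cn$to[1L], cn$to[2L])
    } else {
      if (pa$direction != "contact" || pb$direction != "contact")
        note("direction typing",
             sprintf("undirected connection %s.%s (%s) -- %s.%s (%s) must link contact to contact",
                     cn$from[1L], cn$from[2L], pa$direction,
                     cn$to[1L], cn$to[2L], pb$direction))
    }
  }

  for (b in model$buses) {
    dirs <- character()
    ins <- list(); outs <- 0L
    for (ep in b$ports) {
      p <- port_lookup(model, ep[1L], ep[2L])
      if (is.null(p)) {
        note("dangling port",
             sprintf("bus '%s' endpoint %s.%s does not exist", b$name, ep[1L], ep[2L]))
        next
      }
      dirs <- c(dirs, p$direction)
      if (p$direction == "input") ins[[length(ins) + 1L]] <- ep
      if (p$direction == "output") outs <- outs + 1L
    }
    if (any(dirs == "contact") && any(dirs != "contact"))
      note("direction typing",
           sprintf("bus '%s' mixes contact with directed ports", b$name))
    if (outs > 1L)
      note("direction typing",
           sprintf("bus '%s' has %d output ports attached", b$name, outs))
    for (ep in ins)
      if (outs > 0L) drivers[[paste(ep[1L], ep[2L], sep = ".")]] <-
          (drivers[[paste(ep[1L], ep[2L], sep = ".")]] %||% 0L) + outs
  }

  ## every input port that participates in the wiring needs exactly one driver
  wired <- unique(c(
    unlist(lapply(model$connections,
                  function(cn) c(paste(cn$from, collapse = "."),
                                 paste(cn$to, collapse = ".")))),
    unlist(lapply(model$buses,
                  function(b) vapply(b$ports, paste, character(1), collapse = ".")))))
  for (m in model$modules) for (p in m$ports) {
    key <- paste(m$name, p$name, sep = ".")
    if (p$direction != "input" || !key %in% wired) next
    n <- drivers[[key]] %||% 0L
    if (n == 0L) note("dangling port",
                      sprintf("input port %s has no driver", key))
    if (n > 1L) note("multiply-driven input",
                     sprintf("input port %s has %d drivers", key, n))
  }

  if (length(diags)) do.call(rbind, diags)
  else data.frame(type = character(), message = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
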