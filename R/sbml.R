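## SBML Level 3 Version 2 export/import for flat models.
##
## The exporter covers the constructs flat models are made of: species,
## parameters, (static) compartments, reactions with MathML kinetic laws,
## assignment rules, rate rules and discrete events.  Constructs with no
## SBML counterpart (closure-valued module functions, buffered species,
## dynamically sized compartments) raise before anything is written.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
TIME_URL <- "http://www.sbml.org/sbml/symbols/time"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

## map arbitrary variable names to unique SBML SIds
make_sids <- function(names) {
  sids <- gsub("[^A-Za-z0-9_]", "_", names)
  sids <- ifelse(grepl("^[A-Za-z_]", sids), sids, paste0("x_", sids))
  while (anyDuplicated(sids)) {
    d <- duplicated(sids)
    sids[d] <- paste0(sids[d], "_")
  }
  stats::setNames(sids, names)
}

## ---- R expression -> MathML ------------------------------------------

expr_to_mathml <- function(e, sid) {
  rec <- function(x) {
    if (is.numeric(x)) return(sprintf("<cn> %s </cn>", format(x, digits = 17)))
    if (is.name(x)) {
      nm <- as.character(x)
      if (nm == "t")
        return(sprintf('<csymbol encoding="text" definitionURL="%s"> t </csymbol>',
                       TIME_URL))
      if (is.null(sid[[nm]])) stop("MathML export: unknown symbol '", nm, "'")
      return(sprintf("<ci> %s </ci>", sid[[nm]]))
    }
    if (is.call(x)) {
      op <- as.character(x[[1L]])
      args <- as.list(x)[-1L]
      if (op == "(") return(rec(args[[1L]]))
      if (op == "-" && length(args) == 1L)
        return(sprintf("<apply><minus/>%s</apply>", rec(args[[1L]])))
      tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "^" = "power", "exp" = "exp",
                    "sqrt" = "root", "log10" = NA, "log" = "ln",
                    ">=" = "geq", ">" = "gt", "<=" = "leq", "<" = "lt",
                    "==" = "eq", "min" = "min", "max" = "max",
                    "abs" = "abs", NULL)
      if (op == "log10")
        return(sprintf("<apply><log/><logbase><cn> 10 </cn></logbase>%s</apply>",
                       rec(args[[1L]])))
      if (is.null(tag))
        stop("MathML export: unsupported function '", op, "'")
      return(sprintf("<apply><%s/>%s</apply>", tag,
                     paste(vapply(args, rec, character(1)), collapse = "")))
    }
    stop("MathML export: unsupported expression component")
  }
  sprintf('<math xmlns="%s">%s</math>', MATHML_NS, rec(e))
}

## ---- MathML -> R expression ------------------------------------------

mathml_to_expr <- function(node, name_of) {
  rec <- function(nd) {
    tag <- xml2::xml_name(nd)
    kids <- xml2::xml_children(nd)
    switch(tag,
      cn = as.numeric(xml2::xml_text(nd)),
      ci = {
        id <- trimws(xml2::xml_text(nd))
        as.name(name_of[[id]] %||% id)
      },
      csymbol = as.name("t"),
      apply = {
        op <- xml2::xml_name(kids[[1L]])
        if (op == "log") {
          lb <- rec(xml2::xml_child(kids[[2L]]))
          arg <- rec(kids[[3L]])
          if (identical(lb, 10)) return(call("log10", arg))
          return(call("log", arg, lb))
        }
        args <- lapply(kids[-1L], rec)
        fn <- switch(op, plus = "+", minus = "-", times = "*",
                     divide = "/", power = "^", exp = "exp", ln = "log",
                     root = "sqrt", geq = ">=", gt = ">", leq = "<=",
                     lt = "<", eq = "==", min = "min", max = "max",
                     abs = "abs",
                     stop("MathML import: unsupported operator '", op, "'"))
        if (fn %in% c("+", "*") && length(args) > 2L)
          Reduce(function(a, b) call(fn, a, b), args)
        else do.call(call, c(list(fn), args), quote = TRUE)
      },
      stop("MathML import: unsupported element <", tag, ">"))
  }
  rec(node)
}

## ---- export ----------------------------------------------------------

#' Export a flat model to SBML Level 3 Version 2
#'
#' Every variable becomes a species (dynamic, in its compartment) or a
#' parameter; reactions carry MathML kinetic laws giving the total reaction
#' extent rate; assignments, rate rules and events are preserved.  The
#' produced document must pass [sbml_check()] or the export fails.
#'
#' @param flat a `ms_flat_model`.
#' @param path output file path.
#' @param model_id SBML model id.
#' @return invisibly, the path.
#' @export
export_sbml <- function(flat, path, model_id = "flat_model") {
  stopifnot(inherits(flat, "ms_flat_model"))
  if (length(flat$functions))
    stop("cannot export models with closure-valued module functions to SBML")
  for (v in flat$variables)
    if (!is.na(v$buffered))
      stop("cannot export buffered species '", v$name, "' to SBML")
  dyn <- dynamic_states(flat)
  comps <- flat$compartments
  for (cn in names(comps)) {
    vol <- comps[[cn]]
    if (vol %in% dyn || !is.null(flat$assignments[[vol]]))
      stop("cannot export dynamically sized compartment '", cn, "' to SBML")
  }

  sid <- as.list(make_sids(names(flat$variables)))
  csid <- as.list(make_sids(paste0("comp_", c(names(comps), "default"))))
  names(csid) <- c(names(comps), ".default")

  species <- character(); params <- character()
  need_default <- FALSE
  for (v in flat$variables) {
    if (v$kind == "species" && v$name %in% dyn) {
      comp <- if (is.na(v$compartment)) { need_default <- TRUE; ".default" }
              else v$compartment
      species <- c(species, sprintf(
        '<species id="%s" name="%s" compartment="%s" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
        sid[[v$name]], xml_escape(v$name), csid[[comp]],
        format(v$value, digits = 17)))
    } else if (!v$name %in% unname(unlist(comps))) {
      const <- is.null(flat$assignments[[v$name]]) &&
        !v$name %in% names(flat$rate_rules) && !v$name %in% dyn
      params <- c(params, sprintf(
        '<parameter id="%s" name="%s" value="%s" constant="%s"/>',
        sid[[v$name]], xml_escape(v$name), format(v$value, digits = 17),
        if (const) "true" else "false"))
    }
  }

  comp_lines <- character()
  for (cn in names(comps)) {
    vol_var <- comps[[cn]]
    comp_lines <- c(comp_lines, sprintf(
      '<compartment id="%s" name="%s" size="%s" spatialDimensions="3" constant="true"/>',
      csid[[cn]], xml_escape(cn),
      format(flat$variables[[vol_var]]$value, digits = 17)))
  }
  if (need_default || !length(comp_lines))
    comp_lines <- c(comp_lines, sprintf(
      '<compartment id="%s" size="1" spatialDimensions="3" constant="true"/>',
      csid[[".default"]]))

  rxn_lines <- character()
  for (r in flat$reactions) {
    refs <- function(st, tag) paste(vapply(names(st), function(s) sprintf(
      '<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
      sid[[s]], format(st[[s]], digits = 17)), character(1)), collapse = "")
    mods <- paste(vapply(r$modifiers, function(s) sprintf(
      '<modifierSpeciesReference species="%s"/>', sid[[s]]), character(1)),
      collapse = "")
    rid <- make_sids(r$id)[[1L]]
    rxn_lines <- c(rxn_lines, paste0(
      sprintf('<reaction id="%s" name="%s" reversible="true">', rid,
              xml_escape(r$id)),
      if (length(r$reactants)) paste0("<listOfReactants>", refs(r$reactants),
                                      "</listOfReactants>") else "",
      if (length(r$products)) paste0("<listOfProducts>", refs(r$products),
                                     "</listOfProducts>") else "",
      if (length(r$modifiers)) paste0("<listOfModifiers>", mods,
                                      "</listOfModifiers>") else "",
      "<kineticLaw>", expr_to_mathml(r$rate, sid), "</kineticLaw>",
      "</reaction>"))
  }

  rule_lines <- character()
  for (a in flat$assignments)
    rule_lines <- c(rule_lines, sprintf(
      '<assignmentRule variable="%s">%s</assignmentRule>',
      sid[[a$variable]], expr_to_mathml(a$expr, sid)))
  for (rr in flat$rate_rules)
    rule_lines <- c(rule_lines, sprintf(
      '<rateRule variable="%s">%s</rateRule>',
      sid[[rr$variable]], expr_to_mathml(rr$expr, sid)))

  ev_lines <- character()
  for (ev in flat$events) {
    asg <- paste(vapply(names(ev$assignments), function(v) sprintf(
      '<eventAssignment variable="%s">%s</eventAssignment>',
      sid[[v]], expr_to_mathml(ev$assignments[[v]], sid)), character(1)),
      collapse = "")
    ev_lines <- c(ev_lines, paste0(
      sprintf('<event id="%s" useValuesFromTriggerTime="true">',
              make_sids(ev$id)[[1L]]),
      '<trigger initialValue="true" persistent="true">',
      expr_to_mathml(ev$trigger, sid), "</trigger>",
      "<listOfEventAssignments>", asg, "</listOfEventAssignments>",
      "</event>"))
  }

  wrap <- function(tag, lines)
    if (length(lines)) paste0("<", tag, ">", paste(lines, collapse = ""),
                              "</", tag, ">") else ""
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="2">', SBML_NS),
    sprintf('<model id="%s">', model_id),
    wrap("listOfCompartments", comp_lines),
    wrap("listOfSpecies", species),
    wrap("listOfParameters", params),
    wrap("listOfRules", rule_lines),
    wrap("listOfReactions", rxn_lines),
    wrap("listOfEvents", ev_lines),
    "</model></sbml>")

  doc <- xml2::read_xml(txt)   # fails if not well-formed XML
  issues <- sbml_check(doc)
  if (length(issues))
    stop("exported SBML fails the consistency check:\n  ",
         paste(issues, collapse = "\n  "))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Structural consistency check of an SBML document
#'
#' Verifies that the document declares SBML L3V2, that every `<ci>` symbol
#' in kinetic laws, rules and events references a declared species,
#' parameter or compartment, that every species references an existing
#' compartment, that ids are unique, and that rules/event assignments
#' target declared non-constant entities.
#'
#' @param doc an `xml2` document or a file path.
#' @return character vector of problems; `character(0)` when consistent.
#' @export
sbml_check <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  doc <- xml2::xml_root(doc)
  issues <- character()
  if (!identical(xml2::xml_attr(doc, "level"), "3") ||
      !identical(xml2::xml_attr(doc, "version"), "2"))
    issues <- c(issues, "document is not SBML Level 3 Version 2")
  d <- xml2::read_xml(as.character(doc))
  xml2::xml_ns_strip(d)

  ids <- xml2::xml_attr(
    xml2::xml_find_all(d, "//species | //parameter | //compartment"), "id")
  if (anyDuplicated(ids))
    issues <- c(issues, paste("duplicated ids:",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  comp_ids <- xml2::xml_attr(xml2::xml_find_all(d, "//compartment"), "id")
  for (sp in xml2::xml_find_all(d, "//species")) {
    cp <- xml2::xml_attr(sp, "compartment")
    if (is.na(cp) || !cp %in% comp_ids)
      issues <- c(issues, paste0("species '", xml2::xml_attr(sp, "id"),
                                 "' references missing compartment"))
  }
  for (ci in xml2::xml_find_all(d, "//ci")) {
    ref <- trimws(xml2::xml_text(ci))
    if (!ref %in% ids)
      issues <- c(issues, paste0("<ci> references undeclared id '", ref, "'"))
  }
  for (sr in xml2::xml_find_all(d, "//speciesReference | //modifierSpeciesReference")) {
    ref <- xml2::xml_attr(sr, "species")
    if (!ref %in% ids)
      issues <- c(issues, paste0("speciesReference to undeclared id '", ref, "'"))
  }
  for (rl in xml2::xml_find_all(d, "//assignmentRule | //rateRule | //eventAssignment")) {
    ref <- xml2::xml_attr(rl, "variable")
    if (!ref %in% ids)
      issues <- c(issues, paste0("rule targets undeclared id '", ref, "'"))
  }
  unique(issues)
}

#' Import an SBML file written by [export_sbml()]
#'
#' Reconstructs a `ms_flat_model` from the subset of SBML emitted by this
#' package (species, parameters, static compartments, reactions with
#' kinetic laws, rules, events).  Original variable names are recovered
#' from the SBML `name` attributes when present.
#'
#' @param path SBML file path.
#' @return a `ms_flat_model`.
#' @export
import_sbml <- function(path) {
  d <- xml2::read_xml(path)
  xml2::xml_ns_strip(d)

  name_of <- list()
  for (nd in xml2::xml_find_all(d, "//species | //parameter | //compartment")) {
    id <- xml2::xml_attr(nd, "id")
    nm <- xml2::xml_attr(nd, "name")
    name_of[[id]] <- if (!is.na(nm)) nm else id
  }

  variables <- list()
  compartments <- character()
  for (nd in xml2::xml_find_all(d, "//compartment")) {
    id <- xml2::xml_attr(nd, "id")
    cname <- name_of[[id]]
    vol_var <- paste0("size_", cname)
    variables[[vol_var]] <- ms_variable(
      vol_var, as.numeric(xml2::xml_attr(nd, "size")), kind = "parameter")
    compartments[cname] <- vol_var
  }
  for (nd in xml2::xml_find_all(d, "//species")) {
    id <- xml2::xml_attr(nd, "id")
    nm <- name_of[[id]]
    comp <- name_of[[xml2::xml_attr(nd, "compartment")]]
    variables[[nm]] <- ms_variable(
      nm, as.numeric(xml2::xml_attr(nd, "initialConcentration")),
      kind = "species", compartment = comp)
  }
  for (nd in xml2::xml_find_all(d, "//parameter")) {
    nm <- name_of[[xml2::xml_attr(nd, "id")]]
    variables[[nm]] <- ms_variable(
      nm, as.numeric(xml2::xml_attr(nd, "value")), kind = "parameter")
  }

  reactions <- list()
  for (nd in xml2::xml_find_all(d, "//reaction")) {
    get_refs <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, vapply(xml2::xml_attr(refs, "species"),
                                 function(i) name_of[[i]], character(1)))
    }
    mods <- vapply(xml2::xml_attr(
      xml2::xml_find_all(nd, ".//modifierSpeciesReference"), "species"),
      function(i) name_of[[i]], character(1))
    math <- xml2::xml_find_first(nd, ".//kineticLaw/math/*")
    rid <- xml2::xml_attr(nd, "name")
    if (is.na(rid)) rid <- xml2::xml_attr(nd, "id")
    reactions[[length(reactions) + 1L]] <- ms_reaction(
      rid, reactants = get_refs(".//listOfReactants/speciesReference"),
      products = get_refs(".//listOfProducts/speciesReference"),
      modifiers = unname(mods),
      rate = mathml_to_expr(math, name_of))
  }

  assignments <- list(); rate_rules <- list()
  for (nd in xml2::xml_find_all(d, "//assignmentRule")) {
    tgt <- name_of[[xml2::xml_attr(nd, "variable")]]
    assignments[[tgt]] <- ms_assignment(
      tgt, mathml_to_expr(xml2::xml_find_first(nd, "./math/*"), name_of))
  }
  for (nd in xml2::xml_find_all(d, "//rateRule")) {
    tgt <- name_of[[xml2::xml_attr(nd, "variable")]]
    rate_rules[[tgt]] <- ms_rate_rule(
      tgt, mathml_to_expr(xml2::xml_find_first(nd, "./math/*"), name_of))
  }

  events <- list()
  for (nd in xml2::xml_find_all(d, "//event")) {
    trig <- mathml_to_expr(
      xml2::xml_find_first(nd, ".//trigger/math/*"), name_of)
    asg <- list()
    for (ea in xml2::xml_find_all(nd, ".//eventAssignment")) {
      tgt <- name_of[[xml2::xml_attr(ea, "variable")]]
      asg[[tgt]] <- mathml_to_expr(xml2::xml_find_first(ea, "./math/*"),
                                   name_of)
    }
    events[[length(events) + 1L]] <-
      ms_event(xml2::xml_attr(nd, "id"), trig, asg)
  }

  provenance <- lapply(names(variables), function(x) x)
  names(provenance) <- names(variables)
  structure(list(variables = variables, reactions = reactions,
                 assignments = assignments, rate_rules = rate_rules,
                 events = events, functions = list(),
                 compartments = compartments, provenance = provenance),
            class = "ms_flat_model")
}
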