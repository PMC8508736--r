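#' Parse Transpath-style species notation
#'
#' The text dialect denotes a complex of entities `A` and `B` as `"A:B"`,
#' an entity with (ordered) state labels as `"A{p}"`, and a multimer as
#' `"(A)3"`.  These compose, e.g. `"(A{p})3:B{r}{p}:C"`.  State labels in
#' braces are opaque ordered tokens.  Multimers of complexes (`"(A:B)2"`)
#' are accepted as a natural closure of the grammar.
#'
#' @param text a single species string.
#' @return a `ms_species` object: a list with `kind` (`"entity"`,
#'   `"multimer"` or `"complex"`) and, depending on kind, `name` +
#'   `states`, `component` + `multiplicity`, or `components`.
#' @seealso [emit_species()] for the inverse.
#' @export
parse_species <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty species string")
  chars <- strsplit(text, "")[[1L]]
  pos <- 1L
  n <- length(chars)

  fail <- function(msg) stop(sprintf("species notation error at position %d: %s (in \"%s\")",
                                     pos, msg, text), call. = FALSE)
  peek <- function() if (pos <= n) chars[[pos]] else ""
  advance <- function() pos <<- pos + 1L

  parse_entity <- function() {
    start <- pos
    while (pos <= n && !chars[[pos]] %in% c(":", "{", "}", "(", ")")) advance()
    name <- paste(chars[seq(start, length.out = pos - start)], collapse = "")
    if (!nzchar(name)) fail("empty component")
    states <- character()
    while (peek() == "{") {
      advance()
      s0 <- pos
      while (pos <= n && chars[[pos]] != "}") {
        if (chars[[pos]] %in% c("{", "(", ")")) fail("unbalanced braces")
        advance()
      }
      if (pos > n) fail("unbalanced braces")
      states <- c(states, paste(chars[seq(s0, length.out = pos - s0)],
                                collapse = ""))
      advance()
    }
    structure(list(kind = "entity", name = name, states = states),
              class = "ms_species")
  }

  parse_component <- function() {
    if (peek() == "(") {
      advance()
      inner <- parse_complex(closing = TRUE)
      if (peek() != ")") fail("unbalanced parentheses")
      advance()
      d0 <- pos
      while (pos <= n && grepl("[0-9]", chars[[pos]])) advance()
      if (pos == d0) fail("multimer requires a multiplicity")
      mult <- as.integer(paste(chars[seq(d0, length.out = pos - d0)],
                               collapse = ""))
      if (mult < 2L) fail("multiplicity must be >= 2")
      structure(list(kind = "multimer", component = inner,
                     multiplicity = mult), class = "ms_species")
    } else parse_entity()
  }

  parse_complex <- function(closing = FALSE) {
    comps <- list(parse_component())
    while (peek() == ":") {
      advance()
      comps[[length(comps) + 1L]] <- parse_component()
    }
    if (length(comps) == 1L) return(comps[[1L]])
    structure(list(kind = "complex", components = comps),
              class = "ms_species")
  }

  out <- parse_complex()
  if (pos <= n) fail(sprintf("unexpected character '%s'", peek()))
  out
}

#' Emit Transpath-style species notation
#'
#' Inverse of [parse_species()]: `parse_species(emit_species(s))` is
#' identical to `s` for every valid structure.
#'
#' @param s a `ms_species` object.
#' @return a single string.
#' @export
emit_species <- function(s) {
  stopifnot(inherits(s, "ms_species"))
  switch(s$kind,
    entity = paste0(s$name,
                    paste0(vapply(s$states, function(x) paste0("{", x, "}"),
                                  character(1)), collapse = "")),
    multimer = paste0("(", emit_species(s$component), ")", s$multiplicity),
    complex = paste(vapply(s$components, emit_species, character(1)),
                    collapse = ":"),
    stop("unknown species kind: ", s$kind))
}

#' @export
print.ms_species <- function(x, ...) {
  cat("<species>", emit_species(x), "\n")
  invisible(x)
}

#' Parse "@" annotation lines
#'
#' The annotation dialect extends a host model text format with lines of
#' the form `@entity_id.property = value` (for example
#' `@AMPK_2_2_3.sbgnType = complex`).  Lines not starting with `@` are
#' passed through untouched for downstream handling by the host-language
#' parser and returned in the `"passthrough"` attribute.
#'
#' @param text a multi-line string or character vector of lines.
#' @return a data.frame with columns `entity_id`, `property`, `value` and
#'   `line` (1-based source line number); attribute `"passthrough"` holds
#'   the non-annotation lines.
#' @export
parse_annotations <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else as.character(text)
  recs <- list()
  passthrough <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!startsWith(trimws(ln), "@")) {
      passthrough <- c(passthrough, ln)
      next
    }
    body <- sub("^\\s*@", "", ln)
    m <- regmatches(body, regexec(
      "^([^=]+?)\\.([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*)$", body))[[1L]]
    if (length(m) != 4L)
      stop(sprintf("malformed annotation on line %d: \"%s\" (expected @entity_id.property = value)",
                   i, ln), call. = FALSE)
    value <- trimws(m[[4L]])
    value <- sub('^"(.*)"$', "\\1", value)
    recs[[length(recs) + 1L]] <-
      data.frame(entity_id = trimws(m[[2L]]), property = m[[3L]],
                 value = value, line = i)
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(entity_id = character(), property = character(),
                         value = character(), line = integer())
  attr(out, "passthrough") <- passthrough
  out
}

#' Load a tabular exercise-protocol file
#'
#' Reads a delimited file with a time column (minutes) and a power column
#' (watts) and returns an interpolating work-rate function.  The default
#' `"constant"` mode yields a left-continuous piecewise-constant step
#' function (each tabulated power holds until the next time point), which
#' matches stepped exercise bouts; `"spline"` fits a natural cubic spline.
#' Evaluation outside `[min(time), max(time)]` clamps to the boundary
#' values.
#'
#' @param path CSV (or TSV) file path; the separator is sniffed from the
#'   header line.
#' @param mode `"constant"` or `"spline"`.
#' @param time_col,power_col column names.
#' @return a function `f(t)` (vectorised) with attributes `domain`
#'   (length-2 numeric) and `events` (the tabulated time points, i.e. the
#'   potential discontinuities).
#' @export
load_protocol_table <- function(path, mode = c("constant", "spline"),
                                time_col = "time", power_col = "power") {
  mode <- match.arg(mode)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c(time_col, power_col) %in% names(df)))
    stop("protocol table must have columns '", time_col, "' and '",
         power_col, "'; found: ", paste(names(df), collapse = ", "))
  tt <- as.numeric(df[[time_col]])
  pp <- as.numeric(df[[power_col]])
  if (anyNA(tt) || anyNA(pp)) stop("non-numeric values in protocol table")
  if (is.unsorted(tt, strictly = TRUE))
    stop("time column must be strictly increasing")
  f <- if (length(tt) == 1L) {
    function(t) rep(pp, length(t))
  } else if (mode == "constant") {
    g <- stats::approxfun(tt, pp, method = "constant", f = 0, rule = 2)
    function(t) g(t)
  } else {
    g <- stats::splinefun(tt, pp, method = "natural")
    function(t) g(pmin(pmax(t, min(tt)), max(tt)))
  }
  attr(f, "domain") <- range(tt)
  attr(f, "events") <- tt
  f
}
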