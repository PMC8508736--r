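random_species <- function(depth = 3L) {
  entity <- function() {
    nm <- paste(sample(c(LETTERS, letters, 0:9, "_"), sample(1:6, 1),
                       replace = TRUE), collapse = "")
    states <- if (runif(1) < 0.4)
      replicate(sample(1:3, 1), paste(sample(letters, sample(1:2, 1),
                                             replace = TRUE), collapse = ""))
    else character()
    structure(list(kind = "entity", name = nm, states = as.character(states)),
              class = "ms_species")
  }
  component <- function(d) {
    if (d > 0L && runif(1) < 0.25)
      structure(list(kind = "multimer", component = node(d - 1L),
                     multiplicity = sample(2:5, 1)), class = "ms_species")
    else entity()
  }
  node <- function(d) {
    if (d > 0L && runif(1) < 0.35) {
      k <- sample(2:4, 1)
      structure(list(kind = "complex",
                     components = replicate(k, component(d - 1L),
                                            simplify = FALSE)),
                class = "ms_species")
    } else component(d)
  }
  node(depth)
}

test_that("species notation parses the documented forms", {
  ab <- parse_species("A:B")
  expect_equal(ab$kind, "complex")
  expect_equal(vapply(ab$components, `[[`, character(1), "name"), c("A", "B"))

  ap <- parse_species("A{p}")
  expect_equal(ap$kind, "entity")
  expect_equal(ap$name, "A")
  expect_equal(ap$states, "p")

  a3 <- parse_species("(A)3")
  expect_equal(a3$kind, "multimer")
  expect_equal(a3$multiplicity, 3L)
  expect_equal(a3$component$name, "A")

  adv <- parse_species("(A{p})3:B{r}{p}:C")
  expect_equal(adv$kind, "complex")
  expect_length(adv$components, 3L)
  expect_equal(adv$components[[1]]$kind, "multimer")
  expect_equal(adv$components[[1]]$component$states, "p")
  expect_equal(adv$components[[2]]$states, c("r", "p"))
  expect_equal(adv$components[[3]]$name, "C")

  ## nested complex multimer (grammar closure)
  nested <- parse_species("(A:B)2")
  expect_equal(nested$component$kind, "complex")
})

test_that("species notation rejects malformed input with a position", {
  expect_error(parse_species(""), "empty")
  expect_error(parse_species("A{p"), "position")
  expect_error(parse_species("(A)1"), "multiplicity")
  expect_error(parse_species("(A"), "position")
  expect_error(parse_species("A::B"), "empty component")
  expect_error(parse_species("A)3"), "position")
})

test_that("parse/emit round-trips on 1000 random structures", {
  set.seed(421)
  for (i in 1:1000) {
    s <- random_species()
    txt <- emit_species(s)
    expect_identical(parse_species(txt), s, label = txt)
  }
})

test_that("annotation lines parse and compose with species notation", {
  rec <- parse_annotations("@AMPK_2_2_3.sbgnType = complex")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$entity_id, "AMPK_2_2_3")
  expect_equal(rec$property, "sbgnType")
  expect_equal(rec$value, "complex")

  expect_equal(nrow(parse_annotations("")), 0L)

  mixed <- parse_annotations(c("S1 -> S2; k*S1",
                               '@x.sbgnViewTitle = "A{p}:B"',
                               "x = 3"))
  expect_equal(nrow(mixed), 1L)
  expect_equal(attr(mixed, "passthrough"), c("S1 -> S2; k*S1", "x = 3"))
  v <- parse_species(mixed$value[1])
  expect_equal(v$kind, "complex")
  expect_length(v$components, 2L)

  expect_error(parse_annotations("@broken"), "line 1")
  expect_error(parse_annotations(c("ok", "@a.b c")), "line 2")
})

test_that("protocol tables interpolate as steps or splines with clamping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,power", "0,0", "10,100"), path)
  f <- load_protocol_table(path)
  expect_equal(f(5), 0)
  expect_equal(f(10), 100)
  expect_equal(f(-1), 0)     # clamped to boundary
  expect_equal(f(99), 100)
  expect_equal(attr(f, "events"), c(0, 10))

  single <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,power", "0,50"), single)
  g <- load_protocol_table(single)
  expect_equal(g(c(-5, 0, 7)), c(50, 50, 50))

  lin <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tpower", "0\t0", "5\t50", "10\t100"), lin)
  h <- load_protocol_table(lin, mode = "spline")
  expect_equal(h(2.5), 25, tolerance = 1e-9)
  expect_equal(h(7.5), 75, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,power", "5,0", "1,10"), bad)
  expect_error(load_protocol_table(bad), "increasing")
  writeLines(c("minutes,watts", "0,0"), bad)
  expect_error(load_protocol_table(bad), "columns")
})
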