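# Shared toy-model fixtures, built in code.

# Three interacting modules:
#   M1: A + B -> A:B            (A shared/contact, A:B exposed as output)
#   M2: C -> C{p}, catalysed by A:B (input)
#   M3: A + X -> A_1 + Z, catalysed by C{p} (input); A is a contact shared
#       with M1, so its concentration is co-modified by both modules.
three_module_model <- function(use_bus = FALSE) {
  M1 <- module_def(
    "M1",
    variables = list(
      ms_variable("A", 1.0), ms_variable("B", 0.8),
      ms_variable("A:B", 0.0),
      ms_variable("k1", 0.5, kind = "parameter")),
    reactions = list(ms_reaction(
      "R1", reactants = c("A" = 1, "B" = 1), products = c("A:B" = 1),
      rate = quote(k1 * A * B))),
    ports = list(ms_port("A", direction = "contact"),
                 ms_port("A:B", direction = "output")))

  M2 <- module_def(
    "M2",
    variables = list(
      ms_variable("A:B", 0.0), ms_variable("C", 1.2),
      ms_variable("C{p}", 0.0),
      ms_variable("k2", 0.4, kind = "parameter")),
    reactions = list(ms_reaction(
      "R1", reactants = c("C" = 1), products = c("C{p}" = 1),
      modifiers = "A:B",
      rate = bquote(k2 * .(as.name("A:B")) * C))),
    ports = list(ms_port("A:B", direction = "input"),
                 ms_port("C{p}", direction = "output")))

  M3 <- module_def(
    "M3",
    variables = list(
      ms_variable("A", 1.0), ms_variable("A_1", 0.0),
      ms_variable("X", 2.0), ms_variable("Z", 0.0),
      ms_variable("C{p}", 0.0),
      ms_variable("k3", 0.3, kind = "parameter")),
    reactions = list(ms_reaction(
      "R1", reactants = c("A" = 1, "X" = 1),
      products = c("A_1" = 1, "Z" = 1),
      modifiers = "C{p}",
      rate = bquote(k3 * .(as.name("C{p}")) * A * X))),
    ports = list(ms_port("C{p}", direction = "input"),
                 ms_port("A", direction = "contact")))

  mods <- list(M1, M2, M3)
  conns <- list(
    ms_connection(c("M1", "A:B"), c("M2", "A:B"), directed = TRUE),
    ms_connection(c("M2", "C{p}"), c("M3", "C{p}"), directed = TRUE))
  if (use_bus) {
    modular_model(mods, conns,
                  buses = list(ms_bus("A", list(c("M1", "A"), c("M3", "A")))))
  } else {
    modular_model(mods, c(conns, list(
      ms_connection(c("M1", "A"), c("M3", "A"), directed = FALSE))))
  }
}

# Hand-written flat version of the same system: the independent oracle.
three_module_manual_flat <- function() {
  flatten_single(module_def(
    "flatref",
    variables = list(
      ms_variable("A", 1.0), ms_variable("B", 0.8), ms_variable("AB", 0.0),
      ms_variable("C", 1.2), ms_variable("Cp", 0.0), ms_variable("X", 2.0),
      ms_variable("Z", 0.0), ms_variable("A_1", 0.0),
      ms_variable("k1", 0.5, kind = "parameter"),
      ms_variable("k2", 0.4, kind = "parameter"),
      ms_variable("k3", 0.3, kind = "parameter")),
    reactions = list(
      ms_reaction("R1", c(A = 1, B = 1), c(AB = 1), rate = quote(k1 * A * B)),
      ms_reaction("R2", c(C = 1), c(Cp = 1), modifiers = "AB",
                  rate = quote(k2 * AB * C)),
      ms_reaction("R3", c(A = 1, X = 1), c(A_1 = 1, Z = 1), modifiers = "Cp",
                  rate = quote(k3 * Cp * A * X)))))
}
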