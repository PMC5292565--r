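# Shared fixtures: tiny hand-built models plus a per-session cache of the
# packaged model (network generation is expensive, so it runs once).

toy_types <- function() {
  molecule_type_set(list(
    molecule_type("L", "r"),
    molecule_type("R", "l")))
}

# reversible binding L + R <-> LR with seeds
toy_binding_model <- function(kon = 0.1, koff = 1, L0 = 100, R0 = 50) {
  types <- toy_types()
  seeds <- list(
    structure(species(types, "L"), amount = L0),
    structure(species(types, "R"), amount = R0))
  rules <- parse_rule("bind: L(r) + R(l) <-> L(r!1).R(l!1) kon, koff", types)
  list(types = types, seeds = seeds, rules = rules,
       params = tibble::tibble(name = c("kon", "koff"),
                               value = c(kon, koff)),
       observables = list(
         list(name = "bound", type = "molecules",
              patterns = list(pattern("L(r!+)", types)))))
}

# dimerization A + A <-> AA
toy_dimer_model <- function() {
  types <- molecule_type_set(list(molecule_type("A", "d")))
  seeds <- list(structure(species(types, "A"), amount = 10))
  rules <- parse_rule("dim: A(d) + A(d) <-> A(d!1).A(d!1) kf, kr", types)
  list(types = types, seeds = seeds, rules = rules,
       params = tibble::tibble(name = c("kf", "kr"), value = c(1, 1)),
       observables = list())
}

.vegfsig_test_cache <- new.env(parent = emptyenv())

test_model <- function() {
  got <- .vegfsig_test_cache$model
  if (is.null(got)) {
    got <- vegf_model()
    .vegfsig_test_cache$model <- got
  }
  got
}

cache_get <- function(key, expr) {
  got <- .vegfsig_test_cache[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .vegfsig_test_cache[[key]] <- got
  }
  got
}
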