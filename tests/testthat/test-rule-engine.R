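# Site-graph engine: canonical labels, embedding counts, and network
# closure on small hand-checkable models.

# brute-force isomorphism oracle, independent of the canonical labeller:
# try every molecule bijection and every permutation of same-named site
# copies, then compare states and bond partnerships directly
iso_oracle <- function(g1, g2, types) {
  if (!identical(g1$comp, g2$comp)) return(FALSE)
  if (!identical(sort(g1$mol), sort(g2$mol))) return(FALSE)
  n <- length(g1$mol)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  bond_set <- function(g, mol_map, site_maps) {
    # endpoints translated through the maps, normalized as sorted strings
    eps <- list()
    for (mi in seq_along(g$mol)) {
      bv <- g$bond[[mi]]
      for (si in which(bv > 0L)) {
        key <- as.character(bv[si])
        eps[[key]] <- c(eps[[key]],
                        list(c(mol_map[mi], site_maps[[mi]][si])))
      }
    }
    unname(sort(vapply(eps, function(pr) {
      a <- paste(pr[[1]], collapse = ".")
      b <- paste(pr[[2]], collapse = ".")
      paste(sort(c(a, b)), collapse = "-")
    }, character(1))))
  }
  site_maps_options <- function(g) {
    # per molecule: permutations over same-named site groups
    lapply(seq_along(g$mol), function(mi) {
      tp <- types[[g$mol[mi]]]
      vegfsig:::site_perm_options_compute(tp)
    })
  }
  id_maps <- lapply(seq_along(g1$mol), function(mi) {
    seq_along(types[[g1$mol[mi]]]$sites)
  })
  ref_bonds <- bond_set(g1, seq_len(n), id_maps)
  opts2 <- site_maps_options(g2)
  for (p in perms(seq_len(n))) {
    # p maps g2 molecule i to g1 slot p[i]
    if (!identical(g2$mol, g1$mol[p])) next
    combos <- expand_combo(lapply(seq_len(n), function(i) seq_along(opts2[[i]])))
    ok_state <- TRUE
    for (combo in combos) {
      ok <- TRUE
      site_maps <- vector("list", n)
      for (i in seq_len(n)) {
        perm <- opts2[[i]][[combo[i]]]
        # g2 molecule i site s corresponds to g1 molecule p[i] site perm[s]
        st2 <- g2$state[[i]]
        st1 <- g1$state[[p[i]]]
        if (!identical(st2[order(perm)], st2[order(perm)])) ok <- FALSE
        # state comparison: site s of g2 maps to slot perm[s]... compare
        for (s in seq_along(st2)) {
          v1 <- st1[perm[s]]
          v2 <- st2[s]
          if (!identical(is.na(v1), is.na(v2)) ||
              (!is.na(v1) && v1 != v2)) { ok <- FALSE; break }
        }
        if (!ok) break
        m <- integer(length(perm))
        m[seq_along(perm)] <- perm
        site_maps[[i]] <- m
      }
      if (!ok) next
      if (identical(bond_set(g2, p, site_maps), ref_bonds)) return(TRUE)
      ok_state
    }
  }
  FALSE
}

expand_combo <- function(choices) {
  out <- list(integer(0))
  for (ch in choices) {
    new <- list()
    for (o in out) for (c1 in ch) new[[length(new) + 1]] <- c(o, c1)
    out <- new
  }
  out
}

test_that("canonical labels are invariant to molecule insertion order", {
  types <- molecule_type_set(list(
    molecule_type("V", c("a", "a")),
    molecule_type("R", c("l", "y"), states = list(y = c("U", "P")))))
  d1 <- species(types, c("V", "R", "R"),
                bonds = list(c(1, "a", 2, "l"), c(1, "a", 3, "l")),
                states = list(NULL, list(y = "P"), list(y = "U")))
  d2 <- species(types, c("R", "V", "R"),
                bonds = list(c(2, "a", 1, "l"), c(2, "a", 3, "l")),
                states = list(list(y = "U"), NULL, list(y = "P")))
  expect_identical(canonical_label(d1, types), canonical_label(d2, types))
})

test_that("site states distinguish otherwise identical species", {
  types <- molecule_type_set(list(
    molecule_type("R", "y", states = list(y = c("U", "P")))))
  u <- species(types, "R", states = list(list(y = "U")))
  p <- species(types, "R", states = list(list(y = "P")))
  expect_false(canonical_label(u, types) == canonical_label(p, types))
})

test_that("random reorderings keep labels equal iff graphs are isomorphic", {
  types <- molecule_type_set(list(
    molecule_type("V", c("a", "a", "n")),
    molecule_type("R", c("l", "c", "y"), states = list(y = c("U", "P"))),
    molecule_type("N", "v")))
  set.seed(42)
  build_random <- function() {
    # a bridged dimer with random states and optional N decoration
    st <- sample(c("U", "P"), 2, replace = TRUE)
    with_n <- sample(c(TRUE, FALSE), 1)
    mols <- c("V", "R", "R", if (with_n) "N")
    bonds <- list(c(1, "a", 2, "l"), c(1, "a", 3, "l"))
    if (with_n) bonds <- c(bonds, list(c(1, "n", 4, "v")))
    species(types, mols, bonds = bonds,
            states = list(NULL, list(y = st[1]), list(y = st[2])))
  }
  for (rep in 1:25) {
    g1 <- build_random()
    g2 <- build_random()
    same_label <- canonical_label(g1, types) == canonical_label(g2, types)
    expect_identical(same_label, iso_oracle(g1, g2, types))
  }
})

test_that("malformed graphs with dangling half-bonds are rejected", {
  types <- toy_types()
  g <- species(types, c("L", "R"), bonds = list(c(1, "r", 2, "l")))
  g$bond[[2]][1] <- 0L # break one endpoint
  expect_error(canonical_label(g, types), "half-bond")
})

test_that("embedding counts match hand counts and exhaustive enumeration", {
  types <- molecule_type_set(list(
    molecule_type("V", c("a", "a")),
    molecule_type("R", c("l", "y"), states = list(y = c("U", "P")))))
  mono <- species(types, "R")
  expect_equal(count_embeddings(pattern("R(l)", types), mono, types), 1)
  # free V has two equivalent arms: two embeddings of a single-arm pattern
  freeV <- species(types, "V")
  expect_equal(count_embeddings(pattern("V(a)", types), freeV, types), 2)
  dimer <- species(types, c("V", "R", "R"),
                   bonds = list(c(1, "a", 2, "l"), c(1, "a", 3, "l")),
                   states = list(NULL, list(y = "P"), list(y = "P")))
  expect_equal(count_embeddings(pattern("R(y~P)", types), dimer, types), 2)
  expect_equal(count_embeddings(pattern("V(a!1).R(l!1)", types), dimer, types), 2)
  expect_equal(count_embeddings(pattern("R(y~U)", types), dimer, types), 0)
  # exhaustive oracle on random small complexes: count injective maps of a
  # one-molecule pattern by direct enumeration over molecules/site copies
  set.seed(7)
  for (rep in 1:20) {
    st <- sample(c("U", "P"), 2, replace = TRUE)
    g <- species(types, c("V", "R", "R"),
                 bonds = list(c(1, "a", 2, "l"), c(1, "a", 3, "l")),
                 states = list(NULL, list(y = st[1]), list(y = st[2])))
    target <- sample(c("U", "P"), 1)
    expected <- sum(vapply(seq_along(g$mol), function(i) {
      g$mol[i] == "R" && identical(g$state[[i]][2], target)
    }, logical(1)))
    expect_equal(
      count_embeddings(pattern(paste0("R(y~", target, ")"), types), g, types),
      expected)
  }
})

test_that("toy reversible binding closes to three species", {
  net <- generate_network(toy_binding_model())
  cts <- network_counts(net)
  expect_equal(unname(cts["species"]), 3)
  expect_equal(unname(cts["reactions"]), 2) # two directed
  expect_equal(unname(network_counts(net, directed = FALSE)["reactions"]), 1)
  expect_true(net$converged)
})

test_that("a lone monomer with no rules yields one species, no reactions", {
  types <- molecule_type_set(list(molecule_type("X", "s")))
  mdl <- list(types = types,
              seeds = list(structure(species(types, "X"), amount = 5)),
              rules = list(),
              params = tibble::tibble(name = character(), value = numeric()),
              observables = list())
  net <- generate_network(mdl)
  expect_equal(unname(network_counts(net)), c(1, 0))
})

test_that("homodimerization carries the 1/2 statistical factor", {
  net <- generate_network(toy_dimer_model())
  fw <- Filter(function(r) r$rule == "dim", net$reactions)[[1]]
  expect_equal(fw$mult, 0.5)
  rv <- Filter(function(r) r$rule == "dim_rev", net$reactions)[[1]]
  expect_equal(rv$mult, 1)
})

test_that("generation is deterministic and order-independent", {
  mdl <- toy_binding_model()
  net1 <- generate_network(mdl)
  net2 <- generate_network(mdl)
  expect_identical(net1$species$label, net2$species$label)
  expect_identical(tidy(net1), tidy(net2))
  # shuffle seeds and rules: same species/reaction sets
  mdl2 <- mdl
  mdl2$seeds <- rev(mdl$seeds)
  mdl2$rules <- rev(mdl$rules)
  net3 <- generate_network(mdl2)
  expect_setequal(net1$species$label, net3$species$label)
  key <- function(net) {
    sort(vapply(net$reactions, function(r) {
      paste(paste(sort(net$species$label[r$reactants]), collapse = "+"),
            paste(sort(net$species$label[r$products]), collapse = "+"),
            r$rate, r$mult)
    }, character(1)))
  }
  expect_identical(key(net1), key(net3))
})

test_that("non-degradation reactions balance molecule counts", {
  net <- cache_get("full_net", test_model()$net)
  M <- vegfsig:::species_composition(net)
  for (r in net$reactions) {
    if (r$tag == "degradation") next
    lhs <- rowSums(M[, r$reactants, drop = FALSE])
    rhs <- rowSums(M[, r$products, drop = FALSE])
    if (!isTRUE(all.equal(lhs, rhs))) {
      fail(paste("unbalanced reaction from rule", r$rule))
    }
  }
  succeed()
})

test_that("species count grows monotonically to a fixed point", {
  mdl <- toy_binding_model()
  # iteration cap of 1 yields a flagged partial network
  expect_warning(net_part <- generate_network(mdl, max_iter = 1),
                 "cap")
  expect_false(net_part$converged)
  net_full <- generate_network(mdl)
  expect_true(net_full$converged)
  expect_gte(nrow(net_full$species), nrow(net_part$species))
})

test_that("unresolvable rate references are rejected", {
  mdl <- toy_binding_model()
  mdl$params <- mdl$params[1, ]
  expect_error(generate_network(mdl), "unresolvable")
})
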