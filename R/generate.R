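# Network generation: breadth-first closure of the species set under the
# rule set, with BNGL-style statistical factors. Reversible rules are stored
# as directed reaction pairs; `network_counts(net, directed = FALSE)` merges
# them for reporting under the one-per-reversible convention.

#' Generate the reaction network implied by seeds and rules
#'
#' Iterates rule application starting from the seed species until no rule
#' produces a new species (fixed point) or a cap is hit. Reaction
#' multiplicities are embedding counts corrected by pattern symmetry
#' factors: a rule with an automorphic reactant pattern tuple (identical
#' patterns drawing on the same species) contributes `k * m * x^2` with `m`
#' halved, matching mass-action conventions for indistinguishable pairs.
#'
#' @param model A model list with `types`, `seeds` (list of `species_graph`
#'   with `amount` attributes), `rules`, `params`, `observables` — see
#'   [read_model()] / [vegf_model()].
#' @param max_iter Iteration cap.
#' @param max_species Species-count cap.
#' @param quiet Suppress progress messages.
#' @return A `reaction_network`: species table, reaction list, observable
#'   weight matrix, convergence flag.
#' @export
generate_network <- function(model, max_iter = 50L, max_species = 20000L,
                             quiet = TRUE) {
  types <- model$types
  rules <- model$rules
  if (max_iter < 1L || max_species < 1L) stop("caps must be positive")
  # resolve every rate reference up front
  for (r in rules) {
    if (!rate_resolvable(r$rate, model$params)) {
      stop("unresolvable rate reference '", r$rate, "' in rule ", r$name)
    }
  }

  labels <- character(0)
  graphs <- list()
  label_idx <- new.env(parent = emptyenv())
  add_species <- function(g) {
    lab <- canonical_label(g, types)
    got <- label_idx[[lab]]
    if (!is.null(got)) return(got)
    idx <- length(labels) + 1L
    labels[idx] <<- lab
    graphs[[idx]] <<- g
    label_idx[[lab]] <- idx
    idx
  }
  for (s in model$seeds) add_species(s)
  n_seed <- length(labels)

  # per-rule precomputed symmetry factors
  rule_auto <- lapply(rules, function(r) {
    vapply(r$reactants, pattern_automorphisms, numeric(1), types = types)
  })
  rule_identical_pair <- vapply(rules, function(r) {
    length(r$reactants) == 2L &&
      identical(pattern_key(r$reactants[[1]]), pattern_key(r$reactants[[2]]))
  }, logical(1))

  # per-rule-slot embedding store and match index lists, filled incrementally
  # as species are discovered
  emb_store <- lapply(rules, function(r) lapply(r$reactants, function(p) list()))
  match_idx <- lapply(rules, function(r) lapply(r$reactants, function(p) integer(0)))
  scan_species <- function(si) {
    g <- graphs[[si]]
    for (ri in seq_along(rules)) {
      for (slot in seq_along(rules[[ri]]$reactants)) {
        e <- match_embeddings(rules[[ri]]$reactants[[slot]], g, types)
        if (length(e)) {
          for (ex in rules[[ri]]$excludes) {
            if (ex$reactant == slot &&
                count_embeddings(ex$pattern, g, types) > 0L) {
              e <- list()
              break
            }
          }
        }
        if (length(e)) {
          emb_store[[ri]][[slot]][[as.character(si)]] <<- e
          match_idx[[ri]][[slot]] <<- c(match_idx[[ri]][[slot]], si)
        }
      }
    }
  }
  get_embs <- function(ri, slot, si) {
    emb_store[[ri]][[slot]][[as.character(si)]]
  }

  reactions <- list()
  rxn_seen <- new.env(parent = emptyenv())
  record <- function(ri, r_idx, combos) {
    # combos: list of product index vectors (one per embedding combo)
    if (!length(combos)) return(invisible(NULL))
    keys <- vapply(combos, function(p) paste(sort(p), collapse = ","), character(1))
    tab <- table(keys, useNA = "no")
    tab_names <- names(tab)
    tab <- as.integer(tab)
    denom <- prod(rule_auto[[ri]])
    if (rule_identical_pair[ri] && length(r_idx) == 2L && r_idx[1] == r_idx[2]) {
      denom <- denom * 2
    }
    for (ki in seq_along(tab_names)) {
      k <- tab_names[ki]
      prods <- if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer(0)
      key <- paste0(ri, "|", paste(sort(r_idx), collapse = ","), "|", k)
      if (!is.null(rxn_seen[[key]])) next
      rxn_seen[[key]] <- TRUE
      reactions[[length(reactions) + 1L]] <<- list(
        rule = rules[[ri]]$name, rule_i = ri,
        reactants = sort(r_idx), products = prods,
        rate = rules[[ri]]$rate, mult = as.numeric(tab[ki]) / denom,
        tag = rules[[ri]]$tag)
    }
  }

  apply_combo <- function(ri, gidx) {
    gs <- graphs[gidx]
    if (length(gidx) == 2L && gs[[1]]$comp != gs[[2]]$comp) return(invisible(NULL))
    combos <- list()
    if (length(gidx) == 1L) {
      for (e1 in get_embs(ri, 1L, gidx[1])) {
        prods <- apply_rule(rules[[ri]], gs, list(e1), types)
        combos[[length(combos) + 1L]] <- vapply(prods, add_species, integer(1))
      }
    } else {
      es1 <- get_embs(ri, 1L, gidx[1])
      es2 <- get_embs(ri, 2L, gidx[2])
      for (e1 in es1) for (e2 in es2) {
        prods <- apply_rule(rules[[ri]], gs, list(e1, e2), types)
        combos[[length(combos) + 1L]] <- vapply(prods, add_species, integer(1))
      }
    }
    record(ri, gidx, combos)
  }

  for (si in seq_len(n_seed)) scan_species(si)
  frontier <- seq_len(n_seed)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    n_before <- length(labels)
    f0 <- frontier[1L]
    for (ri in seq_along(rules)) {
      np <- length(rules[[ri]]$reactants)
      if (np == 1L) {
        for (si in intersect(match_idx[[ri]][[1L]], frontier)) apply_combo(ri, si)
      } else {
        m1 <- match_idx[[ri]][[1L]]
        m2 <- match_idx[[ri]][[2L]]
        if (rule_identical_pair[ri]) {
          # unordered pairs from one match list, at least one frontier member
          for (a in m1[m1 >= f0]) {
            for (b in m1) {
              if (b >= f0 && b < a) next
              apply_combo(ri, c(a, b))
            }
          }
        } else {
          for (a in m1[m1 >= f0]) for (b in m2) apply_combo(ri, c(a, b))
          for (a in m1[m1 < f0]) for (b in m2[m2 >= f0]) apply_combo(ri, c(a, b))
        }
      }
    }
    if (!quiet) message("iteration ", iter, ": ", length(labels), " species, ",
                        length(reactions), " reactions")
    if (length(labels) == n_before) { converged <- TRUE; break }
    if (length(labels) > max_species) break
    frontier <- (n_before + 1L):length(labels)
    for (si in frontier) scan_species(si)
  }
  if (!converged) warning("network generation hit a cap before reaching a fixed point")

  amounts <- numeric(length(labels))
  amount_params <- rep(NA_character_, length(labels))
  for (s in model$seeds) {
    idx <- label_idx[[canonical_label(s, types)]]
    amounts[idx] <- attr(s, "amount") %||% 0
    amount_params[idx] <- attr(s, "amount_param") %||% NA_character_
  }

  net <- structure(list(
    species = tibble::tibble(
      index = seq_along(labels), label = labels,
      compartment = vapply(graphs, function(g) g$comp, character(1)),
      amount0 = amounts, amount_param = amount_params),
    graphs = graphs,
    reactions = reactions,
    rules = rules,
    types = types,
    params = model$params,
    observables = model$observables,
    converged = converged,
    iterations = iter), class = "reaction_network")
  net$obs_weights <- observable_weights(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pattern_key <- function(p) {
  paste(p$comp, paste(p$mol, collapse = "."),
        paste(unlist(p$sites), collapse = ","),
        paste(unlist(p$pstate), collapse = ","),
        paste(unlist(p$pbond), collapse = ","))
}

rate_resolvable <- function(rate, params) {
  suppressWarnings(!is.na(as.numeric(rate))) || rate %in% params$name
}

# observable weight matrix: rows = observables, cols = species
observable_weights <- function(net) {
  obs <- net$observables
  if (!length(obs)) return(NULL)
  W <- matrix(0, nrow = length(obs), ncol = length(net$graphs),
              dimnames = list(vapply(obs, function(o) o$name, character(1)), NULL))
  for (oi in seq_along(obs)) {
    for (p in obs[[oi]]$patterns) {
      for (si in seq_along(net$graphs)) {
        n <- count_embeddings(p, net$graphs[[si]], net$types)
        if (n > 0L) {
          W[oi, si] <- W[oi, si] +
            if (identical(obs[[oi]]$type, "species")) 1 else n
        }
      }
    }
  }
  W
}

#' Species and reaction counts of a generated network
#'
#' @param net A `reaction_network`.
#' @param directed If `TRUE` (default) reversible rules count as two directed
#'   reactions; if `FALSE` a forward/reverse pair arising from one reversible
#'   rule and connecting the same species counts once.
#' @return Named numeric vector `c(species = , reactions = )`.
#' @export
network_counts <- function(net, directed = TRUE) {
  n_rxn <- length(net$reactions)
  if (!directed) {
    all_keys <- vapply(net$reactions, function(rx) {
      paste(rx$rule, paste(rx$reactants, collapse = ","),
            paste(rx$products, collapse = ","), sep = "|")
    }, character(1))
    rev_of <- stats::setNames(
      vapply(net$rules, function(r) r$rev_of, character(1)),
      vapply(net$rules, function(r) r$name, character(1)))
    n <- 0L
    for (rx in net$reactions) {
      fwd <- rev_of[[rx$rule]]
      if (!is.na(fwd)) {
        mirror <- paste(fwd, paste(rx$products, collapse = ","),
                        paste(rx$reactants, collapse = ","), sep = "|")
        if (mirror %in% all_keys) next
      }
      n <- n + 1L
    }
    n_rxn <- n
  }
  c(species = nrow(net$species), reactions = n_rxn)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      length(x$reactions), " directed reactions",
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Tidy a reaction network
#'
#' @param x A `reaction_network`.
#' @param ... Unused.
#' @return A tibble of reactions: rule, reactant/product canonical labels,
#'   rate parameter, statistical multiplicity.
#' @method tidy reaction_network
#' @export
tidy.reaction_network <- function(x, ...) {
  tibble::tibble(
    rule = vapply(x$reactions, function(r) r$rule, character(1)),
    reactants = vapply(x$reactions, function(r)
      paste(x$species$label[r$reactants], collapse = " + "), character(1)),
    products = vapply(x$reactions, function(r)
      paste(x$species$label[r$products], collapse = " + "), character(1)),
    rate = vapply(x$reactions, function(r) r$rate, character(1)),
    multiplicity = vapply(x$reactions, function(r) r$mult, numeric(1)),
    tag = vapply(x$reactions, function(r) r$tag, character(1)))
}

#' @method glance reaction_network
#' @export
glance.reaction_network <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_reactions_directed = length(x$reactions),
    converged = x$converged,
    iterations = x$iterations)
}
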