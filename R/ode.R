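# ODE compilation: the generated mass-action network plus the cascade and
# calcium closures become one right-hand-side evaluator over the state
# vector [network species | cascade | calcium]. Free ligands (solution VEGF
# and TSP1) are clamped boundary states in nM set by the protocol; all other
# network states are copies per cell.

# indices of single-molecule unbound surface species of a given type
find_free_ligand <- function(net, type) {
  hit <- which(vapply(net$graphs, function(g) {
    length(g$mol) == 1L && g$mol == type && all(g$bond[[1]] == 0L) &&
      g$comp == "surface"
  }, logical(1)))
  if (length(hit) != 1L) stop("cannot locate free ", type, " species")
  hit
}

# per-species molecule-type composition matrix (types x species)
species_composition <- function(net) {
  tn <- names(net$types)
  M <- matrix(0L, nrow = length(tn), ncol = length(net$graphs),
              dimnames = list(tn, NULL))
  for (si in seq_along(net$graphs)) {
    tb <- table(net$graphs[[si]]$mol)
    M[names(tb), si] <- as.integer(tb)
  }
  M
}

#' Compile the coupled ODE system
#'
#' Builds a deterministic right-hand-side evaluator (and its Jacobian
#' structure) for the reaction network coupled to the ERK cascade and
#' calcium modules. Every reaction rate must resolve against `params`.
#'
#' @param net A `reaction_network`.
#' @param params Parameter tibble (network constants plus downstream
#'   constants; see [default_params()]).
#' @param downstream If `FALSE`, only the network states are integrated
#'   (no cascade/calcium coupling).
#' @param sphk1_blocked,cib1_blocked Cascade block switches.
#' @return An `ode_system` list with `rhs(t, y, ...)`, initial state,
#'   state names, observable weights, and index bookkeeping.
#' @export
build_ode <- function(net, params, downstream = TRUE,
                      sphk1_blocked = FALSE, cib1_blocked = FALSE) {
  n_net <- nrow(net$species)
  rx <- net$reactions
  n_rx <- length(rx)
  k <- vapply(rx, function(r) rate_value(r$rate, params), numeric(1))
  mult <- vapply(rx, function(r) r$mult, numeric(1))
  i1 <- vapply(rx, function(r) r$reactants[1], integer(1))
  i2 <- vapply(rx, function(r) {
    if (length(r$reactants) > 1L) r$reactants[2] else NA_integer_
  }, integer(1))
  bi <- which(!is.na(i2))
  i2v <- i2[bi]
  km <- k * mult
  # stoichiometry (net species x reactions)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (j in seq_len(n_rx)) {
    st <- numeric(0)
    tab_r <- table(rx[[j]]$reactants)
    tab_p <- table(rx[[j]]$products)
    idx <- union(names(tab_r), names(tab_p))
    for (nm in idx) {
      v <- (if (nm %in% names(tab_p)) tab_p[[nm]] else 0) -
        (if (nm %in% names(tab_r)) tab_r[[nm]] else 0)
      if (v != 0) {
        trip_i <- c(trip_i, as.integer(nm)); trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, v)
      }
    }
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_net, n_rx))
  clamp <- c(find_free_ligand(net, "VEGF"), find_free_ligand(net, "TSP1"))
  W <- net$obs_weights
  w_pR2 <- if (!is.null(W) && "pR2" %in% rownames(W)) W["pR2", ] else
    rep(0, n_net)

  y0_net <- net$species$amount0
  # seed amounts declared as parameter references follow the parameter set
  if ("amount_param" %in% names(net$species)) {
    ref <- which(!is.na(net$species$amount_param))
    for (i in ref) {
      j <- match(net$species$amount_param[i], params$name)
      if (!is.na(j)) y0_net[i] <- params$value[j]
    }
  }
  state_names <- paste0("s", seq_len(n_net))
  cp <- if (downstream) cascade_pars(params) else NULL
  calp <- if (downstream) calcium_pars(params) else NULL
  rc <- if (downstream) calcium_rest_constants(calp) else NULL
  if (downstream) {
    y0 <- c(y0_net, cascade_rest_state(params), calcium_rest_state(params))
    state_names <- c(state_names, cascade_state_names,
                     c("Ca_c", "Ca_ER", "Jcrac"))
    ci <- n_net + seq_along(cascade_state_names)
    names(ci) <- cascade_state_names
    cai <- n_net + length(cascade_state_names) + 1:3
    names(cai) <- c("Ca_c", "Ca_ER", "Jcrac")
  } else {
    y0 <- y0_net
    ci <- cai <- NULL
  }
  names(y0) <- state_names

  rhs <- function(t, y, parms = NULL) {
    yn <- y[seq_len(n_net)]
    r <- km * yn[i1]
    if (length(bi)) r[bi] <- r[bi] * yn[i2v]
    dn <- as.numeric(S %*% r)
    dn[clamp] <- 0
    if (!downstream) return(list(dn))
    pR2 <- sum(w_pR2 * yn)
    cs <- y[ci]
    cas <- y[cai]
    dc <- cascade_rhs_(cs, pR2, cas[["Ca_c"]], cp,
                       sphk1_blocked, cib1_blocked)
    dca <- calcium_rhs_(cas, max(cs[["IP3"]], 0), calp, rc)
    list(c(dn, dc, dca))
  }

  structure(list(
    rhs = rhs, y0 = y0, state_names = state_names,
    n_net = n_net, clamp = clamp, obs_weights = W,
    comp_matrix = species_composition(net),
    cascade_idx = ci, calcium_idx = cai,
    net = net, params = params, downstream = downstream),
    class = "ode_system")
}

# analytic Jacobian of the pure-network part (mass action): used for
# verification and optionally by the stiff solver when downstream = FALSE
network_jacobian <- function(sys, y) {
  net <- sys$net
  n <- sys$n_net
  rx <- net$reactions
  J <- matrix(0, n, n)
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    kv <- rate_value(r$rate, sys$params) * r$mult
    re <- r$reactants
    st <- tabulate_signed(re, r$products, n)
    if (length(re) == 1L) {
      dr <- kv
      J[, re[1]] <- J[, re[1]] + st * dr
    } else {
      J[, re[1]] <- J[, re[1]] + st * kv * y[re[2]]
      J[, re[2]] <- J[, re[2]] + st * kv * y[re[1]]
    }
  }
  J[sys$clamp, ] <- 0
  J
}

tabulate_signed <- function(re, pr, n) {
  st <- numeric(n)
  for (i in re) st[i] <- st[i] - 1
  for (i in pr) st[i] <- st[i] + 1
  st
}
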