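# Interaction rules: parsing of the BNGL-subset rule grammar, derivation of
# graph-rewrite actions by differencing the two sides, and application of a
# rule to matched species.
#
# Rule grammar (one line):
#   [label:] lhs (-> | <->) rhs rate[, reverse_rate] [exclude_reactants(i,pat,...)]
# where lhs/rhs are '+'-separated pattern strings (see pattern()), '0' denotes
# the empty side (degradation products), and molecules appear in the same
# order on both sides. Spaces are required around '+' and the arrow and are
# forbidden inside patterns and modifiers.

new_rule <- function(name, reactants, actions, rate, tag = "normal",
                     excludes = list(), rev_of = NA_character_) {
  structure(list(name = name, reactants = reactants, actions = actions,
                 rate = rate, tag = tag, excludes = excludes,
                 rev_of = rev_of),
            class = "reaction_rule")
}

# flatten pattern list into per-molecule addressing tables
flatten_pats <- function(pats) {
  mol <- character(0); where <- list()
  for (ri in seq_along(pats)) {
    for (mi in seq_along(pats[[ri]]$mol)) {
      mol <- c(mol, pats[[ri]]$mol[mi])
      where[[length(where) + 1L]] <- c(r = ri, m = mi)
    }
  }
  list(mol = mol, where = where)
}

# endpoint pairs of the named bonds in a pattern list, in flat-molecule
# coordinates: list of c(flat_i, slot_i, flat_j, slot_j)
flat_bond_pairs <- function(pats) {
  fl <- flatten_pats(pats)
  # collect labelled endpoints
  eps <- list()
  flat <- 0L
  for (ri in seq_along(pats)) {
    p <- pats[[ri]]
    for (mi in seq_along(p$mol)) {
      flat <- flat + 1L
      for (j in seq_along(p$pbond[[mi]])) {
        lab <- p$pbond[[mi]][j]
        if (is.na(lab) || lab %in% c("0", "+")) next
        key <- paste0(ri, "#", lab)
        eps[[key]] <- c(eps[[key]], list(c(flat, j)))
      }
    }
  }
  # labels crossing reactant patterns are allowed on the product side only;
  # key by label alone there. Caller passes single-side lists, so merge by
  # bare label when a label spans patterns.
  bare <- list()
  for (key in names(eps)) {
    lab <- sub("^[0-9]+#", "", key)
    bare[[lab]] <- c(bare[[lab]], eps[[key]])
  }
  out <- list()
  for (lab in names(bare)) {
    pr <- bare[[lab]]
    if (length(pr) != 2L) stop("bond label ", lab, " not used exactly twice across side")
    a <- pr[[1]]; b <- pr[[2]]
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { tmp <- a; a <- b; b <- tmp }
    out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

# derive rewrite actions from aligned lhs/rhs pattern lists
derive_actions <- function(lhs, rhs, types) {
  actions <- list()
  if (length(rhs) == 1L && identical(rhs[[1]], "EMPTY")) {
    return(list(list(op = "delete")))
  }
  lf <- flatten_pats(lhs)
  rf <- flatten_pats(rhs)
  if (!identical(lf$mol, rf$mol)) {
    stop("rule sides list different molecules (order-aligned subset required)")
  }
  # per-flat-molecule site lists must agree
  lsites <- list(); rsites <- list()
  k <- 0L
  for (ri in seq_along(lhs)) for (mi in seq_along(lhs[[ri]]$mol)) {
    k <- k + 1L; lsites[[k]] <- lhs[[ri]]$sites[[mi]]
  }
  k <- 0L
  for (ri in seq_along(rhs)) for (mi in seq_along(rhs[[ri]]$mol)) {
    k <- k + 1L; rsites[[k]] <- rhs[[ri]]$sites[[mi]]
  }
  for (k in seq_along(lsites)) {
    if (!identical(lsites[[k]], rsites[[k]])) {
      stop("rule sides disagree on listed sites for molecule ", k)
    }
  }
  # state changes
  k <- 0L
  for (ri in seq_along(lhs)) for (mi in seq_along(lhs[[ri]]$mol)) {
    k <- k + 1L
    ls <- lhs[[ri]]$pstate[[mi]]
    # rhs flat molecule k
    rk <- rf$where[[k]]
    rs <- rhs[[rk["r"]]]$pstate[[rk["m"]]]
    for (j in seq_along(ls)) {
      if (!is.na(rs[j]) && (is.na(ls[j]) || ls[j] != rs[j])) {
        if (is.na(ls[j])) {
          stop("changed state must be specified on both sides (molecule ", k, ")")
        }
        actions[[length(actions) + 1L]] <-
          list(op = "state", flat = k, slot = j, to = rs[j])
      }
    }
  }
  # bond changes (by endpoint pairs in flat coordinates)
  lb <- flat_bond_pairs(lhs)
  rb <- flat_bond_pairs(rhs)
  key <- function(x) paste(x, collapse = ",")
  lkeys <- vapply(lb, key, character(1))
  rkeys <- vapply(rb, key, character(1))
  for (b in rb[!rkeys %in% lkeys]) {
    actions[[length(actions) + 1L]] <-
      list(op = "bind", a = b[1:2], b = b[3:4])
  }
  for (b in lb[!lkeys %in% rkeys]) {
    actions[[length(actions) + 1L]] <-
      list(op = "unbind", a = b[1:2], b = b[3:4])
  }
  # compartment change: any rhs pattern tag differing from the (single) lhs tag
  lcomp <- unique(stats::na.omit(vapply(lhs, function(p) p$comp, character(1))))
  rcomp <- unique(stats::na.omit(vapply(rhs, function(p) p$comp, character(1))))
  if (length(rcomp) > 1L) stop("product compartment tags disagree")
  if (length(rcomp) == 1L && (!length(lcomp) || lcomp != rcomp)) {
    actions[[length(actions) + 1L]] <- list(op = "comp", to = rcomp)
  }
  actions
}

split_side <- function(tokens) {
  # tokens alternate pattern-chunk, "+"
  pats <- character(0)
  i <- 1L
  repeat {
    pats <- c(pats, tokens[i])
    if (i + 1L <= length(tokens) && tokens[i + 1L] == "+") i <- i + 2L else break
  }
  list(pats = pats, used = i)
}

#' Parse one reaction rule line
#'
#' See the grammar documented at the top of the rules source; reversible
#' rules (`<->`) yield a forward and a reverse `reaction_rule`.
#'
#' @param line Rule text.
#' @param types Named molecule-type list.
#' @param tag Conservation tag: `"normal"`, `"degradation"`, or an explicit
#'   tag; rules whose product side is `0` are tagged `"degradation"`
#'   automatically.
#' @return List of `reaction_rule` objects (length 1 or 2).
#' @export
parse_rule <- function(line, types, tag = "normal") {
  raw <- trimws(line)
  name <- NA_character_
  m <- regmatches(raw, regexec("^([A-Za-z0-9_]+):\\s", raw))[[1]]
  if (length(m)) {
    name <- m[2]
    raw <- trimws(sub("^[A-Za-z0-9_]+:\\s", "", raw))
  }
  toks <- strsplit(raw, "\\s+")[[1]]
  arrow_i <- which(toks %in% c("->", "<->"))
  if (length(arrow_i) != 1L) stop("rule needs exactly one arrow: ", line)
  reversible <- toks[arrow_i] == "<->"
  lhs_toks <- toks[seq_len(arrow_i - 1L)]
  rest <- toks[(arrow_i + 1L):length(toks)]
  ls <- split_side(lhs_toks)
  if (ls$used != length(lhs_toks)) stop("trailing tokens on lhs: ", line)
  rs <- split_side(rest)
  rhs_pats_txt <- rs$pats
  rest <- rest[-seq_len(rs$used)]
  # rates
  rate_txt <- paste(rest[!grepl("^(exclude_reactants|include_reactants)\\(", rest)],
                    collapse = "")
  rates <- strsplit(gsub("\\s", "", rate_txt), ",")[[1]]
  rates <- rates[nzchar(rates)]
  if (reversible && length(rates) != 2L) {
    stop("reversible rule needs two rates: ", line)
  }
  if (!reversible && length(rates) != 1L) {
    stop("irreversible rule needs one rate: ", line)
  }
  mods <- rest[grepl("^exclude_reactants\\(", rest)]
  excludes <- list()
  for (md in mods) {
    inner <- sub("^exclude_reactants\\((.*)\\)$", "\\1", md)
    parts <- strsplit(inner, ",")[[1]]
    ridx <- as.integer(parts[1])
    for (ptxt in parts[-1]) {
      excludes[[length(excludes) + 1L]] <-
        list(reactant = ridx, pattern = pattern(ptxt, types))
    }
  }
  parse_pats <- function(txts) {
    lapply(txts, function(tx) {
      if (tx == "0") "EMPTY" else pattern(tx, types)
    })
  }
  lhs <- parse_pats(ls$pats)
  rhs <- parse_pats(rhs_pats_txt)
  if (any(vapply(lhs, identical, logical(1), "EMPTY"))) {
    stop("unsupported construct: synthesis rules (empty lhs): ", line)
  }
  if (is.na(name)) name <- paste0("rule_", substr(digest_str(raw), 1, 8))
  fwd_tag <- if (length(rhs) == 1L && identical(rhs[[1]], "EMPTY")) "degradation" else tag
  fwd <- new_rule(name, lhs, derive_actions(lhs, rhs, types), rates[1],
                  tag = fwd_tag, excludes = excludes)
  if (!reversible) return(list(fwd))
  if (identical(fwd_tag, "degradation")) stop("reversible degradation unsupported: ", line)
  rev <- new_rule(paste0(name, "_rev"), rhs, derive_actions(rhs, lhs, types),
                  rates[2], tag = tag, rev_of = name)
  list(fwd, rev)
}

# tiny stable string hash (no external deps)
digest_str <- function(x) {
  v <- utf8ToInt(x)
  h1 <- 5381; h2 <- 52711
  for (ch in v) {
    h1 <- (h1 * 33 + ch) %% 2147483629
    h2 <- (h2 * 31 + ch) %% 2147483587
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# ---- rule application -------------------------------------------------------

# merge two species graphs into one (disconnected) graph; returns merged
# graph plus molecule-index offset of the second
merge_graphs <- function(g1, g2) {
  off <- length(g1$mol)
  maxb <- 0L
  for (bv in g1$bond) if (length(bv)) maxb <- max(maxb, bv)
  b2 <- lapply(g2$bond, function(bv) ifelse(bv > 0L, bv + maxb, 0L))
  g <- new_species(g1$comp, c(g1$mol, g2$mol), c(g1$state, g2$state),
                   c(g1$bond, b2))
  list(g = g, off = off)
}

# apply a rule to concrete species given embeddings for each reactant slot.
# graphs: list of species (length = #reactants); embs: list of embeddings
# (from match_embeddings, one per slot, slot 2 offset applied here).
# Returns list of product species graphs (possibly empty for degradation).
apply_rule <- function(rule, graphs, embs, types) {
  if (length(graphs) == 2L) {
    mg <- merge_graphs(graphs[[1]], graphs[[2]])
    g <- mg$g
    emb_mol <- list(embs[[1]]$mol, embs[[2]]$mol + mg$off)
    emb_site <- list(embs[[1]]$site, embs[[2]]$site)
  } else {
    g <- graphs[[1]]
    emb_mol <- list(embs[[1]]$mol)
    emb_site <- list(embs[[1]]$site)
  }
  fl <- flatten_pats(rule$reactants)
  # resolve a flat (molecule, slot) action address to concrete (mol, site)
  resolve <- function(flat, slot) {
    w <- fl$where[[flat]]
    gi <- emb_mol[[w["r"]]][w["m"]]
    si <- emb_site[[w["r"]]][[w["m"]]][slot]
    c(gi, si)
  }
  maxb <- 0L
  for (bv in g$bond) if (length(bv)) maxb <- max(maxb, bv)
  for (a in rule$actions) {
    if (a$op == "delete") return(list())
    if (a$op == "state") {
      t <- resolve(a$flat, a$slot)
      g$state[[t[1]]][t[2]] <- a$to
    } else if (a$op == "bind") {
      ta <- resolve(a$a[1], a$a[2]); tb <- resolve(a$b[1], a$b[2])
      if (g$bond[[ta[1]]][ta[2]] != 0L || g$bond[[tb[1]]][tb[2]] != 0L) {
        stop("bind action on occupied site (rule ", rule$name, ")")
      }
      maxb <- maxb + 1L
      g$bond[[ta[1]]][ta[2]] <- maxb
      g$bond[[tb[1]]][tb[2]] <- maxb
    } else if (a$op == "unbind") {
      ta <- resolve(a$a[1], a$a[2]); tb <- resolve(a$b[1], a$b[2])
      g$bond[[ta[1]]][ta[2]] <- 0L
      g$bond[[tb[1]]][tb[2]] <- 0L
    } else if (a$op == "comp") {
      g$comp <- a$to
    }
  }
  connected_components(g)
}

# pattern self-symmetry: number of embeddings of a pattern into itself,
# treating the pattern as a concrete-enough graph
pattern_automorphisms <- function(p, types) {
  ps <- pattern_as_pseudospecies(p, types)
  if (is.null(ps)) return(1L)
  n <- count_embeddings(strip_comp(p), ps$g, ps$types)
  max(1L, n)
}

strip_comp <- function(p) { p$comp <- NA_character_; p }

# build a pseudo-species whose molecules carry exactly the pattern's listed
# sites/states/bonds, so self-embeddings can be counted with the ordinary
# matcher. Wildcard (`!+`) sites are bound to interchangeable dummy
# partners so that symmetric wildcard-bearing molecules still count as
# automorphic.
pattern_as_pseudospecies <- function(p, types) {
  mol <- character(0); state <- list(); bond <- list()
  lab_map <- new.env(parent = emptyenv()); nextb <- 0L
  dummies <- 0L
  pend_dummy <- integer(0) # bond ids waiting for a dummy partner
  for (mi in seq_along(p$mol)) {
    sn <- p$sites[[mi]]
    tname <- p$mol[mi]
    tp <- types[[tname]]
    st <- vapply(seq_along(tp$sites), function(i) NA_character_, character(1))
    bd <- integer(length(tp$sites))
    used <- logical(length(tp$sites))
    for (j in seq_along(sn)) {
      slot <- which(tp$sites == sn[j] & !used)[1]
      if (is.na(slot)) return(NULL)
      used[slot] <- TRUE
      if (!is.na(p$pstate[[mi]][j])) st[slot] <- p$pstate[[mi]][j]
      lab <- p$pbond[[mi]][j]
      if (!is.na(lab) && !lab %in% c("0", "+")) {
        got <- lab_map[[lab]]
        if (is.null(got)) {
          nextb <- nextb + 1L
          lab_map[[lab]] <- nextb
          bd[slot] <- nextb
        } else bd[slot] <- got
      } else if (!is.na(lab) && lab == "+") {
        nextb <- nextb + 1L
        bd[slot] <- nextb
        dummies <- dummies + 1L
        pend_dummy <- c(pend_dummy, nextb)
      }
    }
    mol <- c(mol, tname); state[[mi]] <- st; bond[[mi]] <- bd
  }
  types2 <- types
  if (dummies > 0L) {
    types2[[".wild"]] <- molecule_type(".wild", "x")
    for (b in pend_dummy) {
      mol <- c(mol, ".wild")
      state[[length(state) + 1L]] <- NA_character_
      bond[[length(bond) + 1L]] <- b
    }
  }
  list(g = new_species("surface", mol, state, bond), types = types2)
}
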