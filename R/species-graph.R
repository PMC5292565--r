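# Site-graph machinery: concrete species, pattern graphs, canonical labels,
# and subgraph (embedding) enumeration. A species is one connected molecular
# complex; a pattern is a partially specified graph used by rules and
# observables.
#
# Concrete species representation:
#   comp  : complex-level compartment tag ("surface" or "endo")
#   mol   : character vector of molecule type names
#   state : list, per molecule, chr vector aligned with the type's site list
#           (NA for stateless sites)
#   bond  : list, per molecule, integer vector aligned with the site list;
#           0 = free, otherwise a bond id appearing on exactly two site slots
#
# Pattern representation:
#   comp  : NA (any) or a compartment tag
#   mol   : character vector of molecule type names
#   sites : list, per molecule, chr vector of the site names the pattern
#           constrains (duplicated names select distinct site copies)
#   pstate: aligned chr vector, NA = unconstrained
#   pbond : aligned chr vector, NA = unconstrained ("?"), "0" = must be free,
#           "+" = bound to anything, "1","2",... = named pattern bond

new_species <- function(comp, mol, state, bond) {
  structure(list(comp = comp, mol = mol, state = state, bond = bond),
            class = "species_graph")
}

#' Build a concrete species graph
#'
#' @param types Named list of [molecule_type()] definitions.
#' @param mol Character vector of molecule type names in the complex.
#' @param bonds List of length-4 vectors `c(mol_i, site, mol_j, site)` naming
#'   bound site pairs; molecule entries are indices into `mol`, sites are site
#'   names (an integer may be appended to a duplicated site name as
#'   `name.2` to select a copy explicitly; otherwise the first free copy is
#'   used).
#' @param states Named list per molecule index: named character vector of
#'   site states. Unspecified stateful sites take the type's default.
#' @param comp Compartment tag, `"surface"` (default) or `"endo"`.
#' @return A `species_graph`.
#' @export
species <- function(types, mol, bonds = list(), states = list(), comp = "surface") {
  mol <- as.character(mol)
  if (!all(mol %in% names(types))) {
    stop("unknown molecule type(s): ", paste(setdiff(mol, names(types)), collapse = ", "))
  }
  st <- lapply(mol, function(m) {
    tp <- types[[m]]
    vapply(seq_along(tp$sites), function(i) {
      if (is.null(tp$states[[i]])) NA_character_ else tp$states[[i]][1]
    }, character(1))
  })
  bd <- lapply(mol, function(m) integer(length(types[[m]]$sites)))
  for (mi in seq_along(states)) {
    sv <- states[[mi]]
    if (is.null(sv)) next
    tp <- types[[mol[mi]]]
    for (sn in names(sv)) {
      idx <- which(tp$sites == sn)
      if (!length(idx)) stop("unknown site ", sn, " on ", mol[mi])
      st[[mi]][idx] <- sv[[sn]]
    }
  }
  next_id <- 1L
  pick_slot <- function(mi, sname) {
    tp <- types[[mol[mi]]]
    if (grepl("\\.", sname)) {
      base <- sub("\\..*$", "", sname)
      k <- as.integer(sub("^.*\\.", "", sname))
      idx <- which(tp$sites == base)[k]
    } else {
      idx <- which(tp$sites == sname & bd[[mi]] == 0L)[1]
    }
    if (is.na(idx)) stop("no free site ", sname, " on molecule ", mi, " (", mol[mi], ")")
    idx
  }
  for (b in bonds) {
    mi <- as.integer(b[[1]]); mj <- as.integer(b[[3]])
    si <- pick_slot(mi, b[[2]]); sj <- pick_slot(mj, b[[4]])
    bd[[mi]][si] <- next_id; bd[[mj]][sj] <- next_id
    next_id <- next_id + 1L
  }
  g <- new_species(comp, mol, st, bd)
  comps <- connected_components(g)
  if (length(comps) > 1L) stop("species graph is not connected")
  g
}

# split a (possibly disconnected) graph into its connected complexes
connected_components <- function(g) {
  n <- length(g$mol)
  if (n == 0L) return(list())
  # adjacency via shared bond ids
  ends <- bond_endpoints(g)
  comp_id <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp_id[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp_id[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- unique(c(ends$mol2[ends$mol1 == v], ends$mol1[ends$mol2 == v]))
      nb <- nb[comp_id[nb] == 0L]
      comp_id[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(cur), function(k) {
    keep <- which(comp_id == k)
    remap <- match(seq_len(n), keep)
    new_species(g$comp, g$mol[keep], g$state[keep], g$bond[keep])
  })
}

# table of bond endpoints: bond id -> (mol1, site1, mol2, site2)
bond_endpoints <- function(g) {
  m1 <- s1 <- m2 <- s2 <- ids <- integer(0)
  seen <- list()
  for (mi in seq_along(g$bond)) {
    bv <- g$bond[[mi]]
    for (si in which(bv > 0L)) {
      id <- bv[si]
      key <- as.character(id)
      if (is.null(seen[[key]])) {
        seen[[key]] <- c(mi, si)
      } else {
        ids <- c(ids, id)
        m1 <- c(m1, seen[[key]][1]); s1 <- c(s1, seen[[key]][2])
        m2 <- c(m2, mi); s2 <- c(s2, si)
        seen[[key]] <- NULL
      }
    }
  }
  if (length(seen)) stop("malformed graph: dangling half-bond")
  list(id = ids, mol1 = m1, site1 = s1, mol2 = m2, site2 = s2)
}

# ---- canonical labels -------------------------------------------------------

# cheap per-molecule invariant used to cut the ordering search
mol_signature <- function(g, types) {
  vapply(seq_along(g$mol), function(mi) {
    tp <- types[[g$mol[mi]]]
    parts <- vapply(seq_along(tp$sites), function(si) {
      paste0(tp$sites[si],
             if (!is.na(g$state[[mi]][si])) paste0("~", g$state[[mi]][si]) else "",
             if (g$bond[[mi]][si] > 0L) "!x" else "")
    }, character(1))
    paste0(g$mol[mi], "(", paste(sort(parts), collapse = ","), ")")
  }, character(1))
}

# enumerate all permutations of 1..n (n is tiny here)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# encode the graph under a fixed molecule ordering and per-molecule site
# permutation, relabelling bonds in first-encounter order (BNGL-style string)
encode_ordering <- function(g, types, order, site_perms) {
  bond_new <- new.env(parent = emptyenv())
  counter <- 0L
  mol_strs <- character(length(order))
  for (k in seq_along(order)) {
    mi <- order[k]
    tp <- types[[g$mol[mi]]]
    sp <- site_perms[[k]]
    parts <- character(length(sp))
    for (j in seq_along(sp)) {
      si <- sp[j]
      s <- tp$sites[si]
      if (!is.na(g$state[[mi]][si])) s <- paste0(s, "~", g$state[[mi]][si])
      b <- g$bond[[mi]][si]
      if (b > 0L) {
        key <- as.character(b)
        lab <- bond_new[[key]]
        if (is.null(lab)) {
          counter <- counter + 1L
          lab <- counter
          bond_new[[key]] <- lab
        }
        s <- paste0(s, "!", lab)
      }
      parts[j] <- s
    }
    mol_strs[k] <- paste0(g$mol[mi], "(", paste(parts, collapse = ","), ")")
  }
  paste0("@", g$comp, ":", paste(mol_strs, collapse = "."))
}

.vegfsig_perm_cache <- new.env(parent = emptyenv())

# site permutations to try for one molecule: identity except groups of
# same-named sites, whose slots may be permuted among themselves
site_perm_options <- function(tp) {
  key <- paste0(tp$name, "|", paste(tp$sites, collapse = ","))
  got <- .vegfsig_perm_cache[[key]]
  if (!is.null(got)) return(got)
  out <- site_perm_options_compute(tp)
  .vegfsig_perm_cache[[key]] <- out
  out
}

site_perm_options_compute <- function(tp) {
  n <- length(tp$sites)
  groups <- split(seq_len(n), tp$sites)
  groups <- groups[vapply(groups, length, integer(1)) > 1L]
  if (!length(groups)) return(list(seq_len(n)))
  base <- seq_len(n)
  opts <- list(base)
  for (gset in groups) {
    new_opts <- list()
    for (p in perms_of(length(gset))) {
      for (o in opts) {
        o2 <- o
        o2[gset] <- gset[p]
        new_opts[[length(new_opts) + 1L]] <- o2
      }
    }
    opts <- new_opts
  }
  opts
}

#' Canonical label of a species graph
#'
#' Produces a string equal for two graphs iff they are isomorphic respecting
#' molecule types, site names, internal states, bonds, and compartment.
#' Molecules are grouped by a structural signature; all orderings within
#' signature groups, and all permutations of same-named site copies, are
#' tried and the lexicographically smallest BNGL-style string is returned.
#'
#' @param g A `species_graph`.
#' @param types Named list of molecule types.
#' @return Canonical label string.
#' @export
canonical_label <- function(g, types) {
  bond_endpoints(g) # validates pairing
  n <- length(g$mol)
  if (n == 0L) stop("empty graph")
  sig <- mol_signature(g, types)
  ord0 <- order(sig, method = "radix")
  groups <- split(ord0, sig[ord0])
  groups <- groups[order(names(groups), method = "radix")]
  # candidate molecule orderings: cartesian product of within-group permutations
  orderings <- list(integer(0))
  for (gset in groups) {
    if (length(gset) == 1L) {
      orderings <- lapply(orderings, function(o) c(o, gset))
    } else {
      ps <- perms_of(length(gset))
      new_ord <- vector("list", length(orderings) * length(ps))
      z <- 0L
      for (o in orderings) for (p in ps) {
        z <- z + 1L
        new_ord[[z]] <- c(o, gset[p])
      }
      orderings <- new_ord
    }
  }
  site_opts <- lapply(seq_len(n), function(mi) site_perm_options(types[[g$mol[mi]]]))
  best <- NULL
  for (ord in orderings) {
    # per-position site permutation options for this ordering
    per_pos <- lapply(ord, function(mi) site_opts[[mi]])
    combo_counts <- vapply(per_pos, length, integer(1))
    total <- prod(combo_counts)
    for (ci in seq_len(total)) {
      idx <- ci - 1L
      sel <- integer(length(ord))
      for (k in seq_along(ord)) {
        sel[k] <- (idx %% combo_counts[k]) + 1L
        idx <- idx %/% combo_counts[k]
      }
      sp <- lapply(seq_along(ord), function(k) per_pos[[k]][[sel[k]]])
      enc <- encode_ordering(g, types, ord, sp)
      if (is.null(best) || enc < best) best <- enc
    }
  }
  best
}

# ---- patterns ---------------------------------------------------------------

new_pattern <- function(comp, mol, sites, pstate, pbond) {
  structure(list(comp = comp, mol = mol, sites = sites,
                 pstate = pstate, pbond = pbond),
            class = "pattern_graph")
}

#' Parse a BNGL-style pattern string
#'
#' Supported syntax: `Mol(site,site~STATE,site!1,site!+,site!?)` molecules
#' joined by `.` (same complex), with an optional leading `@surface:` or
#' `@endo:` compartment tag. A listed site with no bond mark must be free;
#' `!+` requires a bond to anything; `!?` lifts the bond constraint; `!n`
#' names a bond shared by exactly two sites in the pattern.
#'
#' @param text Pattern string.
#' @param types Named list of molecule types (for validation).
#' @return A `pattern_graph`.
#' @export
pattern <- function(text, types) {
  text <- gsub("[[:space:]]", "", text)
  comp <- NA_character_
  if (grepl("^@", text)) {
    comp <- sub("^@([A-Za-z]+):.*$", "\\1", text)
    text <- sub("^@[A-Za-z]+:", "", text)
    if (!comp %in% c("surface", "endo")) stop("unknown compartment: ", comp)
  }
  mol_txt <- strsplit_top(text)
  mol <- character(0); sites <- list(); pstate <- list(); pbond <- list()
  for (mt in mol_txt) {
    m <- regmatches(mt, regexec("^([A-Za-z0-9_]+)\\((.*)\\)$", mt))[[1]]
    if (!length(m)) {
      m2 <- regmatches(mt, regexec("^([A-Za-z0-9_]+)$", mt))[[1]]
      if (!length(m2)) stop("cannot parse pattern molecule: ", mt)
      m <- c(m2[1], m2[2], "")
    }
    mname <- m[2]
    if (!mname %in% names(types)) stop("unknown molecule type in pattern: ", mname)
    body <- m[3]
    sn <- character(0); ss <- character(0); sb <- character(0)
    if (nzchar(body)) {
      for (tok in strsplit(body, ",", fixed = TRUE)[[1]]) {
        bond <- "0"
        if (grepl("!", tok, fixed = TRUE)) {
          pieces <- strsplit(tok, "!", fixed = TRUE)[[1]]
          tok <- pieces[1]
          bond <- pieces[2]
          if (bond == "?") bond <- NA_character_
        }
        state <- NA_character_
        if (grepl("~", tok, fixed = TRUE)) {
          pieces <- strsplit(tok, "~", fixed = TRUE)[[1]]
          tok <- pieces[1]
          state <- pieces[2]
        }
        if (!tok %in% types[[mname]]$sites) {
          stop("pattern references undeclared site ", tok, " on ", mname)
        }
        if (!is.na(state)) {
          si <- which(types[[mname]]$sites == tok)[1]
          allowed <- types[[mname]]$states[[si]]
          if (is.null(allowed) || !state %in% allowed) {
            stop("pattern references undeclared state ", state, " for ",
                 mname, ".", tok)
          }
        }
        sn <- c(sn, tok); ss <- c(ss, state); sb <- c(sb, bond)
      }
    }
    mol <- c(mol, mname)
    sites[[length(sites) + 1L]] <- sn
    pstate[[length(pstate) + 1L]] <- ss
    pbond[[length(pbond) + 1L]] <- sb
  }
  p <- new_pattern(comp, mol, sites, pstate, pbond)
  validate_pattern_bonds(p)
  p
}

# split on "." at top level (no parentheses nesting issues since sites can't
# contain dots inside parens -- but guard anyway)
strsplit_top <- function(text) {
  depth <- 0L
  out <- character(0)
  cur <- ""
  for (ch in strsplit(text, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "." && depth == 0L) {
      out <- c(out, cur); cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

validate_pattern_bonds <- function(p) {
  labs <- unlist(p$pbond)
  labs <- labs[!is.na(labs) & !labs %in% c("0", "+")]
  if (length(labs)) {
    tab <- table(labs)
    if (any(tab != 2L)) {
      stop("pattern bond label(s) not used exactly twice: ",
           paste(names(tab)[tab != 2L], collapse = ", "))
    }
  }
  invisible(p)
}

# ---- embedding enumeration --------------------------------------------------

#' Enumerate embeddings of a pattern into a species
#'
#' Finds every injective map of the pattern's molecules (and of each pattern
#' molecule's constrained sites onto distinct same-named site copies) into
#' the species that satisfies all state and bond constraints. The count of
#' embeddings is the statistical factor used in mass-action rate laws.
#'
#' @param p A `pattern_graph`.
#' @param g A `species_graph`.
#' @param types Molecule type list.
#' @return List of embeddings; each has `mol` (int vector) and `site`
#'   (list of int vectors aligned with the pattern's site lists).
#' @export
match_embeddings <- function(p, g, types) {
  if (!is.na(p$comp) && p$comp != g$comp) return(list())
  np <- length(p$mol)
  ng <- length(g$mol)
  if (np > ng) return(list())
  res <- list()
  mol_map <- integer(np)
  site_map <- vector("list", np)
  used <- logical(ng)

  try_sites <- function(pi, gi) {
    # assign pattern sites of molecule pi to distinct site slots of g mol gi
    tp <- types[[g$mol[gi]]]
    psn <- p$sites[[pi]]
    k <- length(psn)
    if (k == 0L) return(list(integer(0)))
    slots_by_name <- split(seq_along(tp$sites), tp$sites)
    assigns <- list(integer(0))
    for (j in seq_len(k)) {
      cand <- slots_by_name[[psn[j]]]
      new_assigns <- list()
      for (a in assigns) {
        for (s in setdiff(cand, a)) {
          # state constraint
          if (!is.na(p$pstate[[pi]][j]) && !identical(g$state[[gi]][s], p$pstate[[pi]][j])) next
          # local bond constraint (free / bound-any)
          pb <- p$pbond[[pi]][j]
          if (!is.na(pb)) {
            if (pb == "0" && g$bond[[gi]][s] != 0L) next
            if (pb == "+" && g$bond[[gi]][s] == 0L) next
            if (!pb %in% c("0", "+") && g$bond[[gi]][s] == 0L) next
          }
          new_assigns[[length(new_assigns) + 1L]] <- c(a, s)
        }
      }
      assigns <- new_assigns
      if (!length(assigns)) return(list())
    }
    assigns
  }

  check_pattern_bonds <- function(upto) {
    # verify every pattern bond with both endpoints mapped among mols 1..upto
    for (pi in seq_len(upto)) {
      pbv <- p$pbond[[pi]]
      for (j in seq_along(pbv)) {
        lab <- pbv[j]
        if (is.na(lab) || lab %in% c("0", "+")) next
        # find partner endpoint
        for (pk in seq_len(upto)) {
          jj <- which(p$pbond[[pk]] == lab & !(pk == pi & seq_along(p$pbond[[pk]]) == j))
          if (length(jj)) {
            gi <- mol_map[pi]; gk <- mol_map[pk]
            bi <- g$bond[[gi]][site_map[[pi]][j]]
            bk <- g$bond[[gk]][site_map[[pk]][jj[1]]]
            if (bi == 0L || bi != bk) return(FALSE)
            if (gi == gk && site_map[[pi]][j] == site_map[[pk]][jj[1]]) return(FALSE)
          }
        }
      }
    }
    TRUE
  }

  recurse <- function(pi) {
    if (pi > np) {
      res[[length(res) + 1L]] <<- list(mol = mol_map, site = site_map)
      return(invisible(NULL))
    }
    for (gi in which(!used & g$mol == p$mol[pi])) {
      sas <- try_sites(pi, gi)
      if (!length(sas)) next
      mol_map[pi] <<- gi
      used[gi] <<- TRUE
      for (sa in sas) {
        site_map[[pi]] <<- sa
        if (check_pattern_bonds(pi)) recurse(pi + 1L)
      }
      used[gi] <<- FALSE
    }
  }
  recurse(1L)
  res
}

#' Count embeddings of a pattern in a species
#'
#' @inheritParams match_embeddings
#' @return Integer embedding count.
#' @export
count_embeddings <- function(p, g, types) {
  length(match_embeddings(p, g, types))
}
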