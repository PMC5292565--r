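# Model file input/output: a BNGL-compatible subset with sections
# parameters / molecule types / seed species / observables / reaction rules,
# plus a complex-level compartment tag extension (@surface:/@endo:) and
# exclude_reactants() rule modifiers. Anything else raises an explicit
# "unsupported construct" error naming the offending line.

#' Read a model-definition file (BNGL subset)
#'
#' @param file Path to the model file.
#' @return A model list: `types` (molecule types), `seeds` (species graphs
#'   carrying `amount` attributes), `rules`, `params` (tibble `name`,
#'   `value`), `observables`.
#' @export
read_model <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]

  section <- NA_character_
  known_sections <- c("parameters", "molecule types", "seed species",
                      "observables", "reaction rules")
  params <- list()
  type_list <- list()
  seed_txt <- list()
  obs <- list()
  rule_txt <- list()

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln %in% c("begin model", "end model")) next
    m <- regmatches(ln, regexec("^begin\\s+(.*)$", ln))[[1]]
    if (length(m)) {
      if (!m[2] %in% known_sections) {
        stop("unsupported construct at line ", lineno[i], ": ", ln)
      }
      section <- m[2]
      next
    }
    if (grepl("^end\\s+", ln)) { section <- NA_character_; next }
    if (is.na(section)) stop("unsupported construct at line ", lineno[i], ": ", ln)
    switch(section,
      "parameters" = {
        pm <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s+(.+)$", ln))[[1]]
        if (!length(pm)) stop("unsupported construct at line ", lineno[i], ": ", ln)
        params[[pm[2]]] <- safe_eval(pm[3], params, lineno[i])
      },
      "molecule types" = {
        type_list[[length(type_list) + 1L]] <- parse_molecule_type(ln, lineno[i])
      },
      "seed species" = {
        seed_txt[[length(seed_txt) + 1L]] <- list(text = ln, line = lineno[i])
      },
      "observables" = {
        obs[[length(obs) + 1L]] <- list(text = ln, line = lineno[i])
      },
      "reaction rules" = {
        rule_txt[[length(rule_txt) + 1L]] <- list(text = ln, line = lineno[i])
      })
  }
  types <- molecule_type_set(type_list)

  seeds <- lapply(seed_txt, function(s) {
    pm <- regmatches(s$text, regexec("^(\\S+)\\s+(\\S+)$", s$text))[[1]]
    if (!length(pm)) stop("unsupported construct at line ", s$line, ": ", s$text)
    is_ref <- pm[3] %in% names(params)
    amt <- if (is_ref) params[[pm[3]]] else
      suppressWarnings(as.numeric(pm[3]))
    if (is.na(amt)) stop("unresolvable seed amount at line ", s$line)
    g <- tryCatch(pattern_to_species(pattern(pm[2], types), types),
                  error = function(e) stop("bad seed at line ", s$line, ": ",
                                           conditionMessage(e), call. = FALSE))
    attr(g, "amount") <- amt
    if (is_ref) attr(g, "amount_param") <- pm[3]
    g
  })

  observables <- lapply(obs, function(o) {
    pm <- regmatches(o$text,
                     regexec("^(Molecules|Species)\\s+(\\S+)\\s+(.+)$", o$text))[[1]]
    if (!length(pm)) stop("unsupported construct at line ", o$line, ": ", o$text)
    pats <- lapply(strsplit(trimws(pm[4]), "\\s+")[[1]], pattern, types = types)
    list(name = pm[3], type = tolower(pm[2]), patterns = pats,
         text = o$text)
  })

  rules <- list()
  for (rt in rule_txt) {
    rl <- tryCatch(parse_rule(rt$text, types),
                   error = function(e) stop("unsupported construct at line ",
                                            rt$line, ": ", conditionMessage(e),
                                            call. = FALSE))
    for (r in rl) rules[[length(rules) + 1L]] <- r
    rules[[length(rules) - length(rl) + 1L]]$text <- rt$text
  }

  ptab <- tibble::tibble(name = names(params),
                         value = unlist(params, use.names = FALSE))
  list(types = types, seeds = seeds, rules = rules, params = ptab,
       observables = observables)
}

# restricted arithmetic evaluator for parameter expressions
safe_eval <- function(expr_txt, params, line) {
  e <- tryCatch(parse(text = expr_txt)[[1]],
                error = function(err) stop("unsupported construct at line ",
                                           line, ": ", expr_txt, call. = FALSE))
  check <- function(x) {
    if (is.numeric(x)) return(invisible(TRUE))
    if (is.name(x)) {
      if (!as.character(x) %in% names(params)) {
        stop("unresolvable parameter reference '", x, "' at line ", line,
             call. = FALSE)
      }
      return(invisible(TRUE))
    }
    if (is.call(x)) {
      op <- as.character(x[[1]])
      if (!op %in% c("+", "-", "*", "/", "^", "(")) {
        stop("unsupported construct at line ", line, ": ", expr_txt, call. = FALSE)
      }
      for (k in 2:length(x)) check(x[[k]])
      return(invisible(TRUE))
    }
    stop("unsupported construct at line ", line, ": ", expr_txt, call. = FALSE)
  }
  check(e)
  eval(e, envir = params, enclos = baseenv())
}

parse_molecule_type <- function(ln, line) {
  m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\((.*)\\)$", ln))[[1]]
  if (!length(m)) {
    m2 <- regmatches(ln, regexec("^([A-Za-z0-9_]+)$", ln))[[1]]
    if (!length(m2)) stop("unsupported construct at line ", line, ": ", ln)
    return(molecule_type(m2[2]))
  }
  sites <- character(0); states <- list()
  if (nzchar(m[3])) {
    for (tok in strsplit(m[3], ",", fixed = TRUE)[[1]]) {
      parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
      sites <- c(sites, parts[1])
      if (length(parts) > 1L) states[[parts[1]]] <- parts[-1]
    }
  }
  molecule_type(m[2], sites, states)
}

# convert a fully specified pattern to a concrete species graph
pattern_to_species <- function(p, types) {
  mol <- p$mol
  state <- list(); bond <- list()
  lab_map <- new.env(parent = emptyenv()); nextb <- 0L
  for (mi in seq_along(mol)) {
    tp <- types[[mol[mi]]]
    st <- vapply(seq_along(tp$sites), function(i) {
      if (is.null(tp$states[[i]])) NA_character_ else tp$states[[i]][1]
    }, character(1))
    bd <- integer(length(tp$sites))
    used <- logical(length(tp$sites))
    for (j in seq_along(p$sites[[mi]])) {
      slot <- which(tp$sites == p$sites[[mi]][j] & !used)[1]
      if (is.na(slot)) stop("site ", p$sites[[mi]][j], " over-specified on ", mol[mi])
      used[slot] <- TRUE
      if (!is.na(p$pstate[[mi]][j])) st[slot] <- p$pstate[[mi]][j]
      lab <- p$pbond[[mi]][j]
      if (!is.na(lab) && lab == "+") stop("seed species may not use wildcard bonds")
      if (!is.na(lab) && lab != "0") {
        got <- lab_map[[lab]]
        if (is.null(got)) { nextb <- nextb + 1L; lab_map[[lab]] <- nextb; bd[slot] <- nextb }
        else bd[slot] <- got
      }
    }
    state[[mi]] <- st; bond[[mi]] <- bd
  }
  comp <- if (is.na(p$comp)) "surface" else p$comp
  g <- new_species(comp, mol, state, bond)
  if (length(connected_components(g)) != 1L) stop("seed species must be connected")
  g
}

# render a pattern back to its normalized text
render_pattern <- function(p) {
  mols <- vapply(seq_along(p$mol), function(mi) {
    parts <- vapply(seq_along(p$sites[[mi]]), function(j) {
      s <- p$sites[[mi]][j]
      if (!is.na(p$pstate[[mi]][j])) s <- paste0(s, "~", p$pstate[[mi]][j])
      lab <- p$pbond[[mi]][j]
      if (is.na(lab)) s <- paste0(s, "!?")
      else if (lab == "+") s <- paste0(s, "!+")
      else if (lab != "0") s <- paste0(s, "!", lab)
      s
    }, character(1))
    paste0(p$mol[mi], "(", paste(parts, collapse = ","), ")")
  }, character(1))
  txt <- paste(mols, collapse = ".")
  if (!is.na(p$comp)) txt <- paste0("@", p$comp, ":", txt)
  txt
}

render_molecule_type <- function(tp) {
  parts <- vapply(seq_along(tp$sites), function(i) {
    if (is.null(tp$states[[i]])) tp$sites[i]
    else paste0(tp$sites[i], "~", paste(tp$states[[i]], collapse = "~"))
  }, character(1))
  paste0(tp$name, "(", paste(parts, collapse = ","), ")")
}

#' Write a model back to the BNGL subset
#'
#' Inverse of [read_model()] on the supported subset: reading the written
#' file reproduces the same types, seeds, parameter values, observables and
#' rules.
#'
#' @param model Model list as returned by [read_model()].
#' @param file Output path.
#' @export
write_model <- function(model, file) {
  out <- c("begin model", "begin parameters")
  out <- c(out, sprintf("  %s %.17g", model$params$name, model$params$value))
  out <- c(out, "end parameters", "begin molecule types")
  out <- c(out, paste0("  ", vapply(model$types, render_molecule_type, character(1))))
  out <- c(out, "end molecule types", "begin seed species")
  for (s in model$seeds) {
    amt <- attr(s, "amount_param") %||%
      sprintf("%.17g", attr(s, "amount") %||% 0)
    out <- c(out, sprintf("  %s %s", species_to_text(s, model$types), amt))
  }
  out <- c(out, "end seed species", "begin observables")
  for (o in model$observables) {
    out <- c(out, sprintf("  %s %s %s",
                          if (o$type == "molecules") "Molecules" else "Species",
                          o$name,
                          paste(vapply(o$patterns, render_pattern, character(1)),
                                collapse = " ")))
  }
  out <- c(out, "end observables", "begin reaction rules")
  i <- 1L
  while (i <= length(model$rules)) {
    r <- model$rules[[i]]
    if (!is.null(r$text)) out <- c(out, paste0("  ", r$text))
    i <- i + 1L
  }
  out <- c(out, "end reaction rules", "end model")
  writeLines(out, file)
  invisible(file)
}

# species graph rendered with every site listed (free sites bare)
species_to_text <- function(g, types) {
  mols <- vapply(seq_along(g$mol), function(mi) {
    tp <- types[[g$mol[mi]]]
    parts <- vapply(seq_along(tp$sites), function(si) {
      s <- tp$sites[si]
      if (!is.na(g$state[[mi]][si])) s <- paste0(s, "~", g$state[[mi]][si])
      if (g$bond[[mi]][si] > 0L) s <- paste0(s, "!", g$bond[[mi]][si])
      s
    }, character(1))
    paste0(g$mol[mi], "(", paste(parts, collapse = ","), ")")
  }, character(1))
  txt <- paste(mols, collapse = ".")
  if (!identical(g$comp, "surface")) txt <- paste0("@", g$comp, ":", txt)
  txt
}

#' Export a generated network as SBML Level 3
#'
#' Writes species (with compartment and initial amount), rate-constant
#' parameters, and mass-action reactions (statistical multiplicity folded
#' into the kinetic law) as an SBML Level 3 Version 2 core document.
#'
#' @param net A `reaction_network`.
#' @param params Optional parameter tibble overriding `net$params`.
#' @param file Output path.
#' @export
write_sbml <- function(net, file, params = NULL) {
  params <- params %||% net$params
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "rule_network")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cn in unique(net$species$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cn, constant = "true",
                        spatialDimensions = "3", size = "1")
  }
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    xml2::xml_add_child(
      sps, "species", id = paste0("s", i), name = net$species$label[i],
      compartment = net$species$compartment[i],
      initialAmount = format(net$species$amount0[i]),
      hasOnlySubstanceUnits = "true", boundaryCondition = "false",
      constant = "false")
  }
  prs <- xml2::xml_add_child(mdl, "listOfParameters")
  used <- unique(vapply(net$reactions, function(r) r$rate, character(1)))
  for (pn in used) {
    val <- rate_value(pn, params)
    xml2::xml_add_child(prs, "parameter", id = pn, value = format(val),
                        constant = "true")
  }
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    rn <- xml2::xml_add_child(rxs, "reaction", id = paste0("r", j),
                              reversible = "false")
    if (length(rx$reactants)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (si in unique(rx$reactants)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("s", si),
                            stoichiometry = format(sum(rx$reactants == si)),
                            constant = "true")
      }
    }
    if (length(rx$products)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (si in unique(rx$products)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("s", si),
                            stoichiometry = format(sum(rx$products == si)),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "ci", rx$rate)
    cn <- xml2::xml_add_child(ap, "cn", format(rx$mult))
    cn
    for (si in rx$reactants) xml2::xml_add_child(ap, "ci", paste0("s", si))
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

rate_value <- function(rate, params) {
  v <- suppressWarnings(as.numeric(rate))
  if (!is.na(v)) return(v)
  i <- match(rate, params$name)
  if (is.na(i)) stop("unresolvable rate reference: ", rate)
  params$value[i]
}
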