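#' Declare a molecule type
#'
#' A molecule type names a molecule and its binding/modification sites.
#' Site names may repeat to declare symmetric, interchangeable copies of the
#' same site (e.g. the two receptor-binding arms of a VEGF homodimer); the
#' engine treats bonds on same-named sites as exchangeable when deciding
#' whether two complexes are isomorphic.
#'
#' @param name Molecule name (identifier).
#' @param sites Character vector of site names (duplicates allowed for
#'   symmetric sites).
#' @param states Named list mapping a site name to the character vector of
#'   its allowed internal states (e.g. `list(Y1175 = c("U", "P"))`). Sites
#'   absent from the list carry no internal state. The first listed state is
#'   the default used when a seed species leaves it unspecified.
#' @return An object of class `molecule_type`.
#' @examples
#' molecule_type("VEGFR2", c("L", "C", "Y1175", "cd"),
#'               states = list(Y1175 = c("U", "P")))
#' @export
molecule_type <- function(name, sites = character(), states = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sites <- as.character(sites)
  bad <- setdiff(names(states), sites)
  if (length(bad)) {
    stop("states declared for unknown site(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(states))) stop("duplicate state declarations")
  st <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    if (sites[i] %in% names(states)) {
      v <- as.character(states[[sites[i]]])
      if (length(v) < 1L) stop("state list for site ", sites[i], " is empty")
      st[[i]] <- v
    }
  }
  structure(list(name = name, sites = sites, states = st),
            class = "molecule_type")
}

#' @export
print.molecule_type <- function(x, ...) {
  parts <- vapply(seq_along(x$sites), function(i) {
    if (is.null(x$states[[i]])) x$sites[i]
    else paste0(x$sites[i], "~", paste(x$states[[i]], collapse = "~"))
  }, character(1))
  cat(x$name, "(", paste(parts, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Assemble molecule types into a named set
#' @param types List of [molecule_type()] objects.
#' @return Named list keyed by molecule name.
#' @export
molecule_type_set <- function(types) {
  nms <- vapply(types, function(t) t$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate molecule type names")
  stats::setNames(types, nms)
}
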