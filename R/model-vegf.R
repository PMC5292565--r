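# Packaged VEGF-VEGFR2 / TSP1-CD47 model: ruleset + calibrated parameters +
# generated network, cached per session (generation takes ~15 s).

.vegfsig_cache <- new.env(parent = emptyenv())

#' Load the packaged VEGF-TSP1 model
#'
#' Reads the packaged ruleset, generates the reaction network (cached for
#' the session), and attaches the calibrated downstream parameter set.
#'
#' @param params Optional parameter tibble (defaults to [default_params()]).
#' @param model_file Optional alternative ruleset file.
#' @param refresh Force regeneration of the cached network.
#' @return A `vegf_model` list: `net` (reaction network), `params`.
#' @export
vegf_model <- function(params = NULL, model_file = NULL, refresh = FALSE) {
  model_file <- model_file %||%
    system.file("extdata", "vegf_tsp1_model.bngl", package = "vegfsig")
  key <- paste0("net::", model_file)
  net <- .vegfsig_cache[[key]]
  if (is.null(net) || refresh) {
    mdl <- read_model(model_file)
    net <- generate_network(mdl)
    .vegfsig_cache[[key]] <- net
  }
  params <- params %||% default_params(model_file = model_file)
  structure(list(net = net, params = params), class = "vegf_model")
}

#' @export
print.vegf_model <- function(x, ...) {
  cts <- network_counts(x$net)
  cat("<vegf_model> ", cts[1], " species, ", cts[2],
      " directed reactions, ", nrow(x$params), " parameters\n", sep = "")
  invisible(x)
}
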