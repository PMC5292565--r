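# Model-file reading/writing and SBML export.

minimal_model_text <- c(
  "begin model",
  "begin parameters",
  "  kon 0.1",
  "  koff 2*0.5",
  "  L0 100",
  "end parameters",
  "begin molecule types",
  "  L(r)",
  "  R(l,y~U~P)",
  "end molecule types",
  "begin seed species",
  "  L(r) L0",
  "  R(l,y~U) 50",
  "end seed species",
  "begin observables",
  "  Molecules bound L(r!+)",
  "end observables",
  "begin reaction rules",
  "  bind: L(r) + R(l) <-> L(r!1).R(l!1) kon, koff",
  "end reaction rules",
  "end model")

test_that("a minimal model file parses to the hand-built structure", {
  f <- withr::local_tempfile(fileext = ".bngl")
  writeLines(minimal_model_text, f)
  mdl <- read_model(f)
  expect_named(mdl$types, c("L", "R"))
  expect_equal(mdl$types$R$sites, c("l", "y"))
  expect_equal(mdl$types$R$states[[2]], c("U", "P"))
  expect_equal(param_get(tibble::tibble(name = mdl$params$name,
                                        value = mdl$params$value), "koff"), 1)
  expect_length(mdl$seeds, 2)
  expect_equal(attr(mdl$seeds[[1]], "amount"), 100)
  expect_equal(attr(mdl$seeds[[1]], "amount_param"), "L0")
  expect_length(mdl$rules, 2) # reversible -> two directed rules
  expect_equal(mdl$observables[[1]]$name, "bound")
})

test_that("write/read round-trips the supported subset", {
  f1 <- withr::local_tempfile(fileext = ".bngl")
  writeLines(minimal_model_text, f1)
  mdl <- read_model(f1)
  f2 <- withr::local_tempfile(fileext = ".bngl")
  write_model(mdl, f2)
  mdl2 <- read_model(f2)
  expect_equal(mdl$params, mdl2$params)
  expect_equal(names(mdl$types), names(mdl2$types))
  expect_equal(lapply(mdl$types, unclass), lapply(mdl2$types, unclass))
  lab <- function(m) vapply(m$seeds, canonical_label, character(1),
                            types = m$types)
  expect_equal(lab(mdl), lab(mdl2))
  net1 <- generate_network(mdl)
  net2 <- generate_network(mdl2)
  expect_identical(net1$species$label, net2$species$label)
})

test_that("unsupported constructs fail with the offending line", {
  f <- withr::local_tempfile(fileext = ".bngl")
  writeLines(c("begin model", "begin functions", "end functions", "end model"), f)
  expect_error(read_model(f), "unsupported construct at line 2")
  writeLines(c("begin model", "begin parameters", "  k exp(2)",
               "end parameters", "end model"), f)
  expect_error(read_model(f), "unsupported construct at line 3")
  writeLines(c("begin model", "begin molecule types", "  A(x)",
               "end molecule types", "begin reaction rules",
               "  syn: 0 -> A(x) k1", "end reaction rules", "end model"), f)
  expect_error(read_model(f), "line 6")
})

test_that("the packaged ruleset parses and reports its counts", {
  net <- cache_get("full_net", test_model()$net)
  cts <- network_counts(net)
  expect_true(net$converged)
  expect_gt(cts["species"], 100)
  expect_gt(cts["reactions"], 1000)
})

test_that("SBML export of the toy model is well-formed and complete", {
  net <- generate_network(toy_binding_model())
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "sbml")
  ns <- xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, "//species")
  expect_length(sp, 3)
  rx <- xml2::xml_find_all(doc, "//reaction")
  expect_length(rx, 2)
  # every kinetic law references its rate parameter
  kl <- xml2::xml_find_all(doc, "//kineticLaw//ci")
  expect_true(all(c("kon", "koff") %in% trimws(xml2::xml_text(kl))))
  # species references resolve
  ids <- xml2::xml_attr(sp, "id")
  refs <- xml2::xml_attr(xml2::xml_find_all(doc, "//speciesReference"),
                         "species")
  expect_true(all(refs %in% ids))
})
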