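# Synthetic fitting/validation data: simulates the parameterization panels
# (receptor decay, surface decay, pVEGFR2, pPLC-gamma, calcium, pERK1/2,
# surface binding, dose-response curves) under a known parameter set,
# samples them on fixture grids, and applies an observation-noise model, so
# fitting and recovery studies run without any external download.

#' Observation-noise model
#'
#' @param type `"additive"` (gaussian, constant sigma) or `"proportional"`
#'   (gaussian, sigma scaled by the signal).
#' @param sigma Noise scale (>= 0).
#' @param seed RNG seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(type = c("additive", "proportional"), sigma = 0,
                        seed = 1) {
  type <- match.arg(type)
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(type = type, sigma = sigma, seed = seed),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (noise$sigma == 0) return(values)
  eps <- stats::rnorm(length(values), 0, noise$sigma)
  if (noise$type == "additive") values + eps
  else values * (1 + eps)
}

# panel registry: each entry builds a noiseless fit_dataset from a model +
# parameter set
panel_registry <- function() {
  tc <- function(name, observable, prot, grid, normalize = "none", ...) {
    list(name = name, observable = observable, protocol = prot, grid = grid,
         normalize = normalize, type = "timecourse", ...)
  }
  std_grid <- c(0, 2, 5, 10, 20, 30, 45, 60, 90, 120, 150, 180)
  short_grid <- c(0, 1, 2, 3.5, 5, 7.5, 10, 15, 20, 30, 40)
  dose_grid <- c(1, 2, 4, 6, 10, 20, 50, 200, 1000)
  list(
    total_r2 = tc("total_r2", "R2_frac",
                  vegf_protocol(50, duration = 180, dt = 1), std_grid),
    total_r2_no_nrp1 = c(tc("total_r2_no_nrp1", "R2_frac",
                            nrp1_ko_protocol(), std_grid), list(downstream = FALSE)),
    surface_r2 = tc("surface_r2", "R2_surf_frac",
                    vegf_protocol(50, duration = 180, dt = 1), std_grid),
    pr2 = tc("pr2", "pR2_frac", vegf_protocol(50, duration = 40, dt = 0.5),
             short_grid),
    pplcg = tc("pplcg", "pPLCg", vegf_protocol(50, duration = 40, dt = 0.5),
               short_grid, normalize = "max"),
    ca_norm = tc("ca_norm", "Ca_c", vegf_protocol(50, duration = 40, dt = 0.5),
                 short_grid, normalize = "max"),
    ca_raw = tc("ca_raw", "Ca_c", vegf_protocol(50, duration = 40, dt = 0.5),
                short_grid),
    perk = tc("perk", "pERK", vegf_protocol(50, duration = 40, dt = 0.5),
              short_grid),
    perk_sphk1_block = c(tc("perk_sphk1_block", "pERK",
                            vegf_protocol(50, duration = 40, dt = 0.5),
                            short_grid), list(sphk1_blocked = TRUE)),
    vegf_binding = list(name = "vegf_binding", observable = "VEGF_bound",
                        protocol = function(d) vegf_protocol(vegf_pM = d,
                                                             duration = 10,
                                                             dt = 1),
                        grid = dose_grid * 10, normalize = "max",
                        type = "dose_response", downstream = FALSE),
    pr2_dose = list(name = "pr2_dose", observable = "pR2",
                    protocol = function(d) vegf_protocol(vegf_pM = d,
                                                         duration = 30, dt = 1),
                    grid = dose_grid, normalize = "max",
                    type = "dose_response"),
    perk_dose = list(name = "perk_dose", observable = "pERK",
                     protocol = function(d) vegf_protocol(vegf_pM = d,
                                                          duration = 30, dt = 1),
                     grid = dose_grid, normalize = "max",
                     type = "dose_response"))
}

nrp1_ko_protocol <- function() {
  pr <- vegf_protocol(50, duration = 180, dt = 1)
  pr$events <- dplyr::bind_rows(
    pr$events,
    tibble::tibble(time = 0, action = "set_seed", target = "NRP1", value = 0))
  pr
}

#' Names of the available synthetic panels
#' @return Character vector.
#' @export
panel_names <- function() names(panel_registry())

#' Generate synthetic fitting datasets
#'
#' Simulates each requested panel under `params`, samples the fixture grid,
#' applies the noise model, and returns ready-to-fit datasets plus a
#' manifest.
#'
#' @param model Model object.
#' @param params Parameter tibble (the "true" parameters).
#' @param panels Panel names (subset of [panel_names()], default all).
#' @param noise A [noise_model()].
#' @param rtol,atol Solver tolerances.
#' @return List: `datasets` (list of [fit_dataset()]), `manifest` (tibble).
#' @export
generate_datasets <- function(model, params = NULL, panels = panel_names(),
                              noise = noise_model(sigma = 0),
                              rtol = 1e-6, atol = 1e-8) {
  params <- params %||% model$params
  reg <- panel_registry()
  bad <- setdiff(panels, names(reg))
  if (length(bad)) stop("unknown panel(s): ", paste(bad, collapse = ", "))
  set.seed(noise$seed)
  datasets <- list()
  for (pn in panels) {
    spec <- reg[[pn]]
    ds <- fit_dataset(spec$name, spec$observable, spec$protocol, spec$grid,
                      values = rep(0, length(spec$grid)),
                      normalize = spec$normalize, type = spec$type)
    extra <- spec[intersect(names(spec), c("downstream", "sphk1_blocked"))]
    pred <- do.call(predict_dataset,
                    c(list(model, ds, params, rtol = rtol, atol = atol),
                      extra))
    ds$values <- apply_noise(pred, noise)
    ds$sim_args <- extra
    datasets[[pn]] <- ds
  }
  manifest <- tibble::tibble(
    panel = panels,
    observable = vapply(datasets, function(d) d$observable, character(1)),
    type = vapply(datasets, function(d) d$type, character(1)),
    n_points = vapply(datasets, function(d) length(d$grid), integer(1)),
    normalize = vapply(datasets, function(d) d$normalize, character(1)),
    noise_type = noise$type, sigma = noise$sigma, seed = noise$seed)
  list(datasets = datasets, manifest = manifest)
}

#' Write synthetic datasets to CSV with a JSON manifest
#'
#' @param gen Result of [generate_datasets()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_datasets <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in gen$datasets) {
    utils::write.csv(data.frame(grid = ds$grid, value = ds$values),
                     file.path(dir, paste0(ds$name, ".csv")),
                     row.names = FALSE)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(gen$manifest, mp, dataframe = "rows", auto_unbox = TRUE)
  invisible(mp)
}

# ---- stand-alone calcium simulator (used for fast recovery studies) -------

#' Simulate the calcium module in isolation
#'
#' Integrates the three-state calcium module under a prescribed IP3 drive,
#' without the receptor network. Used for parameter-recovery experiments on
#' the CRAC constants.
#'
#' @param params Parameter tibble.
#' @param times Output times (s).
#' @param ip3_fn Function of time (s) returning IP3 (uM); default a step to
#'   1.5 uM at t = 60 s.
#' @return Tibble: `time`, `Ca_c`, `Ca_ER`, `Jcrac`.
#' @export
simulate_calcium <- function(params, times = seq(0, 1200, by = 2),
                             ip3_fn = function(t) ifelse(t >= 60, 1.5, 0)) {
  cp <- calcium_pars(params)
  rc <- calcium_rest_constants(cp)
  y0 <- calcium_rest_state(params)
  rhs <- function(t, y, p) {
    list(calcium_rhs_(y, ip3_fn(t), cp, rc))
  }
  sol <- deSolve::lsoda(y0, times, rhs, rtol = 1e-8, atol = 1e-10)
  tibble::tibble(time = sol[, 1], Ca_c = sol[, "Ca_c"],
                 Ca_ER = sol[, "Ca_ER"], Jcrac = sol[, "Jcrac"])
}

#' Parameter-recovery experiment
#'
#' Generates a noiseless (or noisy) synthetic calcium trace under the true
#' parameters, perturbs the chosen parameters, and refits them with the
#' pattern search; reports per-parameter relative errors.
#'
#' @param params True parameter tibble.
#' @param fit_names Parameters to recover. The default pair is the
#'   identifiable CRAC subset: in the physiological store range the steady
#'   current behaves as `Icrac_bar * (K_crac / Ca_ER)^h`, so the amplitude
#'   and half-point are only jointly identified; with `K_crac` held at its
#'   declared value, `Icrac_bar` and `tau_crac` are individually
#'   recoverable.
#' @param perturb Multiplicative start perturbation.
#' @param noise A [noise_model()].
#' @param max_eval Search budget.
#' @return List: `fit` (fit_result), `errors` (named relative errors),
#'   `true`, `start`.
#' @export
recovery_experiment <- function(params,
                                fit_names = c("Icrac_bar", "tau_crac"),
                                perturb = 2, noise = noise_model(sigma = 0),
                                max_eval = 400) {
  true_vals <- param_get(params, fit_names)
  times <- seq(0, 900, by = 2)
  target <- simulate_calcium(params, times)$Ca_c
  set.seed(noise$seed)
  target <- apply_noise(target, noise)
  i <- match(fit_names, params$name)
  fn <- function(x) {
    p2 <- params
    p2$value[i] <- x
    pred <- tryCatch(simulate_calcium(p2, times)$Ca_c,
                     error = function(e) NULL)
    if (is.null(pred)) return(1e6)
    sum((pred - target)^2)
  }
  start <- true_vals * perturb
  lower <- true_vals / 20
  upper <- true_vals * 20
  fit <- direct_search(fn, start, lower, upper, log10_space = TRUE,
                       max_eval = max_eval, seed = noise$seed)
  errors <- abs(fit$par - true_vals) / true_vals
  names(errors) <- fit_names
  list(fit = fit, errors = errors,
       true = stats::setNames(true_vals, fit_names),
       start = stats::setNames(start, fit_names))
}
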