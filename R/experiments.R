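# In-silico experiments: fold-change scans of the TSP1 inhibition
# mechanisms (enhanced VEGFR2 degradation, phosphatase recruitment),
# two-dimensional mechanism surfaces, CRAC-inhibition studies, CD47-level
# scans, therapy simulations (TSP1 inhibition, CD47 depletion), and
# threshold detection on the resulting curves.

#' Scalar metrics of a stimulation trajectory
#'
#' @param tr A `trajectory`.
#' @param vegf_onset Time of VEGF addition (minutes); the `*_10min` metrics
#'   are measured 10 minutes after it.
#' @return Named numeric vector: `max_pR2` (fraction-total), `pR2_10min`,
#'   `max_Ca` (uM), `dCa` (rise over baseline), `max_pERK`, `pERK_10min`.
#' @export
trajectory_metrics <- function(tr, vegf_onset = 0) {
  at <- function(col, t) {
    stats::approx(tr$time, tr[[col]], xout = t, rule = 2)$y
  }
  c(max_pR2 = max(tr$pR2_frac),
    pR2_10min = at("pR2_frac", vegf_onset + 10),
    max_Ca = max(tr$Ca_c),
    dCa = max(tr$Ca_c) - tr$Ca_c[1],
    max_pERK = max(tr$pERK),
    pERK_10min = at("pERK", vegf_onset + 10))
}

#' TSP1 mechanism parameter overrides
#'
#' Applies the two hypothesized TSP1/CD47 mechanisms as fold-changes over
#' the base trafficking constants: enhanced degradation of endosomal
#' complexes carrying TSP1-engaged CD47, and enhanced dephosphorylation
#' (surface and endosomal) of receptors in such complexes.
#'
#' @param params Parameter tibble.
#' @param fold_deg Degradation fold (>= 0).
#' @param fold_dephos Dephosphorylation fold (>= 0).
#' @return Updated tibble.
#' @export
tsp1_mechanism_params <- function(params, fold_deg = 1, fold_dephos = 1) {
  param_set(params,
            kdeg_tsp = param_get(params, "kdeg") * fold_deg,
            kdp_s_tsp = param_get(params, "kdp_s") * fold_dephos,
            kdp_e_tsp = param_get(params, "kdp_e") * fold_dephos)
}

#' Fold-change scan of a TSP1 inhibition mechanism
#'
#' Runs the TSP1-then-VEGF protocol at each fold value and collects
#' trajectory metrics.
#'
#' @param model Model object.
#' @param mechanism `"degradation"` or `"dephosphorylation"`.
#' @param folds Fold grid (sorted, positive).
#' @param tsp1_nM TSP1 concentration.
#' @param tsp1_pre TSP1 pre-incubation (minutes; 0 = simultaneous).
#' @param params Parameter tibble.
#' @param other_fold Fold applied to the other mechanism (default 1).
#' @param rtol,atol Solver tolerances.
#' @return Tibble: `fold` plus the [trajectory_metrics()] columns; failed
#'   grid points carry `NA` metrics.
#' @export
scan_fold <- function(model, mechanism = c("degradation", "dephosphorylation"),
                      folds = 10^seq(0, 2, length.out = 25), tsp1_nM = 2,
                      tsp1_pre = 10, params = NULL, other_fold = 1,
                      rtol = 1e-6, atol = 1e-8) {
  mechanism <- match.arg(mechanism)
  if (is.unsorted(folds) || any(folds <= 0)) stop("folds must be sorted and positive")
  params <- params %||% model$params
  prot <- tsp1_vegf_protocol(tsp1_nM, tsp1_pre = tsp1_pre, dt = 0.5)
  rows <- lapply(folds, function(f) {
    p2 <- if (mechanism == "degradation") {
      tsp1_mechanism_params(params, fold_deg = f, fold_dephos = other_fold)
    } else {
      tsp1_mechanism_params(params, fold_deg = other_fold, fold_dephos = f)
    }
    tr <- tryCatch(run_protocol(model, prot, params = p2, rtol = rtol,
                                atol = atol),
                   error = function(e) NULL)
    if (is.null(tr)) {
      return(tibble::tibble(fold = f, max_pR2 = NA_real_, pR2_10min = NA_real_,
                            max_Ca = NA_real_, dCa = NA_real_,
                            max_pERK = NA_real_, pERK_10min = NA_real_))
    }
    m <- trajectory_metrics(tr, vegf_onset = tsp1_pre)
    tibble::tibble(fold = f, !!!as.list(m))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scan_result", class(out))
  attr(out, "mechanism") <- mechanism
  attr(out, "x") <- "fold"
  out
}

#' Two-dimensional mechanism surface
#'
#' Metric landscape over a TSP1-concentration grid crossed with a
#' mechanism-fold grid (or two mechanism folds when
#' `x = "fold_dephos"`).
#'
#' @param model Model object.
#' @param x_grid,y_grid Grids. `x` is TSP1 (nM) unless `x_name` says
#'   otherwise; `y` is the mechanism fold.
#' @param x_name `"tsp1_nM"` or `"fold_dephos"`.
#' @param mechanism Mechanism scanned on `y_grid`.
#' @param metric Metric column (default `"max_pERK"`).
#' @param tsp1_nM TSP1 concentration when `x_name = "fold_dephos"`.
#' @param tsp1_pre Pre-incubation minutes.
#' @param params Parameter tibble.
#' @param rtol,atol Solver tolerances.
#' @return Long tibble `x`, `y`, `value` with axis metadata attributes.
#' @export
surface_2d <- function(model, x_grid, y_grid, x_name = "tsp1_nM",
                       mechanism = "degradation", metric = "max_pERK",
                       tsp1_nM = 2, tsp1_pre = 10, params = NULL,
                       rtol = 1e-6, atol = 1e-8) {
  params <- params %||% model$params
  rows <- list()
  for (xv in x_grid) for (yv in y_grid) {
    p2 <- if (x_name == "fold_dephos") {
      tsp1_mechanism_params(params,
                            fold_deg = if (mechanism == "degradation") yv else 1,
                            fold_dephos = xv)
    } else if (mechanism == "degradation") {
      tsp1_mechanism_params(params, fold_deg = yv)
    } else {
      tsp1_mechanism_params(params, fold_dephos = yv)
    }
    cc <- if (x_name == "tsp1_nM") xv else tsp1_nM
    prot <- tsp1_vegf_protocol(cc, tsp1_pre = tsp1_pre, dt = 0.5)
    tr <- tryCatch(run_protocol(model, prot, params = p2, rtol = rtol,
                                atol = atol),
                   error = function(e) NULL)
    val <- if (is.null(tr)) NA_real_ else
      trajectory_metrics(tr, vegf_onset = tsp1_pre)[[metric]]
    rows[[length(rows) + 1L]] <- tibble::tibble(x = xv, y = yv, value = val)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "x_name") <- x_name
  attr(out, "y_name") <- paste0("fold_", mechanism)
  attr(out, "metric") <- metric
  out
}

#' Threshold criterion
#'
#' @param type `"inhibition"` (metric falls below `frac` of control) or
#'   `"recovery"` (metric rises to at least `frac` of control).
#' @param frac Fraction of the control metric (defaults: 0.05 for
#'   inhibition, 0.5 for recovery).
#' @return A `threshold_criterion`.
#' @export
threshold_criterion <- function(type = c("inhibition", "recovery"),
                                frac = NULL) {
  type <- match.arg(type)
  frac <- frac %||% if (type == "inhibition") 0.05 else 0.5
  if (frac <= 0 || frac >= 1) stop("criterion fraction must be in (0, 1)")
  structure(list(type = type, frac = frac), class = "threshold_criterion")
}

#' Locate the threshold crossing of a scan curve
#'
#' Finds the first grid point satisfying the criterion, verifies the curve
#' is monotone in the criterion's direction past the crossing, and
#' optionally refines the bracket by bisection using a fresh evaluator.
#'
#' @param xs Grid (sorted).
#' @param ys Metric values along the grid.
#' @param control Control metric value the criterion is relative to.
#' @param criterion A [threshold_criterion()].
#' @param eval_fn Optional `function(x) -> metric` used for bisection
#'   refinement.
#' @param rel_tol Relative bracket width at which bisection stops
#'   (default 0.02).
#' @return List: `threshold` (NA if the criterion is never met in range),
#'   `bracket`, `crossed` (logical).
#' @export
find_threshold <- function(xs, ys, control, criterion = threshold_criterion(),
                           eval_fn = NULL, rel_tol = 0.02) {
  ok <- is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  target <- criterion$frac * control
  hit <- if (criterion$type == "inhibition") ys < target else ys >= target
  if (!any(hit)) {
    return(list(threshold = NA_real_, bracket = c(NA_real_, NA_real_),
                crossed = FALSE))
  }
  i <- which(hit)[1]
  if (i == 1) {
    return(list(threshold = xs[1], bracket = c(NA_real_, xs[1]),
                crossed = TRUE))
  }
  # monotonicity in the criterion's direction past the crossing
  post <- ys[i:length(ys)]
  tol <- 0.05 * max(abs(ys))
  mono_ok <- if (criterion$type == "inhibition") {
    all(diff(post) <= tol)
  } else all(diff(post) >= -tol)
  if (!mono_ok) stop("scan curve is not monotone past the crossing")
  lo <- xs[i - 1]; hi <- xs[i]
  if (!is.null(eval_fn)) {
    while ((hi - lo) / max(hi, .Machine$double.eps) > rel_tol) {
      mid <- (lo + hi) / 2
      ym <- eval_fn(mid)
      sat <- if (criterion$type == "inhibition") ym < target else ym >= target
      if (sat) hi <- mid else lo <- mid
    }
  }
  list(threshold = hi, bracket = c(lo, hi), crossed = TRUE)
}

#' TSP1-inhibition therapy scan
#'
#' Models therapeutic TSP1 inhibition by reducing the applied TSP1
#' concentration; TSP1 and VEGF are added simultaneously and the combined
#' mechanism (default 10-fold degradation, 51-fold dephosphorylation) is
#' active.
#'
#' @param model Model object.
#' @param inhibition Grid of inhibition fractions in `[0, 1]`.
#' @param tsp1_nM Uninhibited TSP1 concentration.
#' @param fold_deg,fold_dephos Combined mechanism folds.
#' @param params Parameter tibble.
#' @param rtol,atol Solver tolerances.
#' @return Tibble: `inhibition` plus trajectory metrics.
#' @export
tsp1_inhibition_scan <- function(model, inhibition = seq(0, 1, by = 0.05),
                                 tsp1_nM = 2, fold_deg = 10, fold_dephos = 51,
                                 params = NULL, rtol = 1e-6, atol = 1e-8) {
  params <- tsp1_mechanism_params(params %||% model$params,
                                  fold_deg, fold_dephos)
  rows <- lapply(inhibition, function(inh) {
    prot <- tsp1_vegf_protocol(tsp1_nM * (1 - inh), tsp1_pre = 0,
                               vegf_dur = 50, dt = 0.5)
    tr <- run_protocol(model, prot, params = params, rtol = rtol, atol = atol)
    tibble::tibble(inhibition = inh,
                   !!!as.list(trajectory_metrics(tr, vegf_onset = 0)))
  })
  dplyr::bind_rows(rows)
}

#' CD47-depletion therapy scan
#'
#' Models CD47 knockdown by scaling the CD47 seed amount; TSP1 and VEGF
#' are added simultaneously under the combined mechanism.
#'
#' @inheritParams tsp1_inhibition_scan
#' @param depletion Grid of depletion fractions in `[0, 1]`.
#' @return Tibble: `depletion` plus trajectory metrics.
#' @export
cd47_depletion_scan <- function(model, depletion = seq(0, 1, by = 0.05),
                                tsp1_nM = 2, fold_deg = 10, fold_dephos = 51,
                                params = NULL, rtol = 1e-6, atol = 1e-8) {
  params <- tsp1_mechanism_params(params %||% model$params,
                                  fold_deg, fold_dephos)
  rows <- lapply(depletion, function(dep) {
    prot <- tsp1_vegf_protocol(tsp1_nM, tsp1_pre = 0, vegf_dur = 50, dt = 0.5)
    prot$events <- dplyr::bind_rows(
      prot$events,
      tibble::tibble(time = 0, action = "set_seed", target = "CD47",
                     value = 1 - dep))
    tr <- run_protocol(model, prot, params = params, rtol = rtol, atol = atol)
    tibble::tibble(depletion = dep,
                   !!!as.list(trajectory_metrics(tr, vegf_onset = 0)))
  })
  dplyr::bind_rows(rows)
}

#' CRAC-channel inhibition study
#'
#' Scans the CRAC current amplitude and activation time constant under the
#' standard VEGF protocol, reporting peak and end-of-protocol (plateau)
#' calcium and pERK1/2.
#'
#' @param model Model object.
#' @param amp_frac Amplitude fractions of the base current.
#' @param tau_factor Factors applied to the activation time constant.
#' @param duration Protocol duration (minutes).
#' @param params Parameter tibble.
#' @param rtol,atol Solver tolerances.
#' @return Tibble: `quantity` (amplitude/tau), `factor`, `max_Ca`,
#'   `plateau_Ca`, `max_pERK`, `plateau_pERK`.
#' @export
crac_inhibition_study <- function(model, amp_frac = c(1, 0.5, 0.25, 0.1, 0),
                                  tau_factor = c(0.2, 1, 5, 25),
                                  duration = 40, params = NULL,
                                  rtol = 1e-6, atol = 1e-8) {
  params <- params %||% model$params
  base_amp <- param_get(params, "Icrac_bar")
  base_tau <- param_get(params, "tau_crac")
  one <- function(quantity, fac, p2) {
    tr <- run_protocol(model, vegf_protocol(50, duration = duration, dt = 0.5),
                       params = p2, rtol = rtol, atol = atol)
    tibble::tibble(quantity = quantity, factor = fac,
                   max_Ca = max(tr$Ca_c), plateau_Ca = tr$Ca_c[nrow(tr)],
                   max_pERK = max(tr$pERK), plateau_pERK = tr$pERK[nrow(tr)])
  }
  rows <- c(
    lapply(amp_frac, function(f) {
      one("amplitude", f, param_set(params, Icrac_bar = base_amp * f))
    }),
    lapply(tau_factor, function(f) {
      one("tau", f, param_set(params, tau_crac = base_tau * f))
    }))
  dplyr::bind_rows(rows)
}

#' CD47 surface-level scan
#'
#' Maximum pERK1/2 under 2 nM TSP1 as CD47 surface density varies;
#' densities are converted to per-cell counts with the declared cell
#' surface area.
#'
#' @param model Model object.
#' @param density_per_um2 CD47 densities (receptors per square micron).
#' @param fold_deg,fold_dephos Mechanism folds (defaults 10/51).
#' @param tsp1_nM TSP1 concentration.
#' @param params Parameter tibble.
#' @param rtol,atol Solver tolerances.
#' @return Tibble: `density`, `cd47_per_cell`, trajectory metrics.
#' @export
cd47_level_scan <- function(model, density_per_um2 = c(0, 1, 2.2, 3.5, 5, 7, 10),
                            fold_deg = 10, fold_dephos = 51, tsp1_nM = 2,
                            params = NULL, rtol = 1e-6, atol = 1e-8) {
  if (any(density_per_um2 < 0)) stop("densities must be non-negative")
  params <- tsp1_mechanism_params(params %||% model$params,
                                  fold_deg, fold_dephos)
  area <- param_get(params, "cell_area_um2")
  rows <- lapply(density_per_um2, function(d) {
    count <- density_to_count(d, area)
    p2 <- param_set(params, CD47_0 = count)
    prot <- tsp1_vegf_protocol(tsp1_nM, tsp1_pre = 0, vegf_dur = 50, dt = 0.5)
    tr <- run_protocol(model, prot, params = p2, rtol = rtol, atol = atol)
    tibble::tibble(density = d, cd47_per_cell = count,
                   !!!as.list(trajectory_metrics(tr, vegf_onset = 0)))
  })
  dplyr::bind_rows(rows)
}

#' Dose-response scan
#'
#' Peak pVEGFR2 and pERK1/2 across a VEGF dose grid, with switch location
#' detected as the first dose whose peak response reaches half the
#' saturating response.
#'
#' @param model Model object.
#' @param doses_pM Sorted positive dose grid (pM).
#' @param duration Exposure duration (minutes).
#' @param params Parameter tibble.
#' @param switch_frac Fraction of the saturating peak defining the switch.
#' @param rtol,atol Solver tolerances.
#' @return Tibble with attribute `switch_pM` (per response column).
#' @export
dose_response <- function(model, doses_pM = c(1, 2, 3, 4, 5, 6, 8, 12, 20,
                                              50, 200, 1000),
                          duration = 30, params = NULL, switch_frac = 0.5,
                          rtol = 1e-6, atol = 1e-8) {
  if (is.unsorted(doses_pM) || any(doses_pM <= 0)) {
    stop("dose grid must be sorted and positive")
  }
  params <- params %||% model$params
  rows <- lapply(doses_pM, function(d) {
    tr <- run_protocol(model, vegf_protocol(vegf_pM = d, duration = duration,
                                            dt = 1),
                       params = params, rtol = rtol, atol = atol)
    tibble::tibble(dose_pM = d, max_pR2 = max(tr$pR2),
                   max_pERK = max(tr$pERK), max_Ca = max(tr$Ca_c))
  })
  out <- dplyr::bind_rows(rows)
  sw <- vapply(c("max_pR2", "max_pERK"), function(col) {
    sat <- out[[col]][nrow(out)]
    i <- which(out[[col]] >= switch_frac * sat)[1]
    if (is.na(i)) NA_real_ else out$dose_pM[i]
  }, numeric(1))
  attr(out, "switch_pM") <- sw
  out
}

#' Plot a fold-change scan
#' @param object A `scan_result`.
#' @param metric Metric column.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, metric = "max_pERK", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fold, .data[[metric]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(attr(object, "mechanism"), " fold-change"),
                  y = metric)
}
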