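# Stimulation protocols and trajectory simulation. A protocol is an ordered
# event table: ligand additions (clamped solution concentrations), parameter
# fold-changes, and seed-amount overrides (receptor depletion/knockout),
# integrated with a stiff solver restarted at each event time.

#' Build a stimulation protocol
#'
#' @param duration Total duration (minutes).
#' @param events Tibble with columns `time` (minutes, non-decreasing),
#'   `action` (`"set_ligand"`, `"set_param"`, `"scale_param"`,
#'   `"set_seed"`), `target` (ligand molecule name, parameter name, or seed
#'   species type), `value`.
#' @param dt Output grid spacing (minutes).
#' @return A `protocol` object.
#' @export
protocol <- function(duration, events = NULL, dt = 0.25) {
  if (is.null(events)) {
    events <- tibble::tibble(time = numeric(0), action = character(0),
                             target = character(0), value = numeric(0))
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) && is.unsorted(events$time)) {
    stop("event times must be non-decreasing")
  }
  if (any(events$action == "scale_param" & events$value <= 0)) {
    stop("fold scalings must be > 0")
  }
  structure(list(duration = duration, events = events, dt = dt),
            class = "protocol")
}

#' Standard TSP1-then-VEGF stimulation protocol
#'
#' TSP1 is applied at time zero, followed by VEGF after a pre-incubation
#' period (defaults: 2 nM TSP1 for 10 min, then 50 ng/ml VEGF for 40 min).
#' Set `tsp1_pre = 0` for simultaneous addition.
#'
#' @param tsp1_nM TSP1 concentration (nM).
#' @param tsp1_pre TSP1 pre-incubation (minutes).
#' @param vegf_ng_ml VEGF concentration (ng/ml).
#' @param vegf_dur VEGF exposure duration (minutes).
#' @param vegf_mw VEGF molar mass used for the ng/ml conversion.
#' @param dt Output grid spacing (minutes).
#' @return A `protocol`.
#' @export
tsp1_vegf_protocol <- function(tsp1_nM = 2, tsp1_pre = 10, vegf_ng_ml = 50,
                               vegf_dur = 40, vegf_mw = 44000, dt = 0.25) {
  ev <- tibble::tibble(
    time = c(0, tsp1_pre),
    action = "set_ligand",
    target = c("TSP1", "VEGF"),
    value = c(tsp1_nM, ligand_conc(vegf_ng_ml, "ng/ml", "nM", mw = vegf_mw)))
  if (tsp1_pre == 0) ev <- ev[order(ev$time), ]
  protocol(tsp1_pre + vegf_dur, ev, dt = dt)
}

#' VEGF-only stimulation protocol
#'
#' @param vegf_ng_ml VEGF concentration (ng/ml); use `vegf_nM`/`vegf_pM` to
#'   specify molar units directly.
#' @param duration Duration (minutes).
#' @param vegf_nM,vegf_pM Alternative dose specifications.
#' @param vegf_mw Molar mass for the ng/ml conversion.
#' @param dt Output grid spacing (minutes).
#' @return A `protocol`.
#' @export
vegf_protocol <- function(vegf_ng_ml = 50, duration = 180, vegf_nM = NULL,
                          vegf_pM = NULL, vegf_mw = 44000, dt = 0.5) {
  conc <- if (!is.null(vegf_nM)) vegf_nM
  else if (!is.null(vegf_pM)) vegf_pM / 1000
  else ligand_conc(vegf_ng_ml, "ng/ml", "nM", mw = vegf_mw)
  protocol(duration,
           tibble::tibble(time = 0, action = "set_ligand",
                          target = "VEGF", value = conc),
           dt = dt)
}

#' Ligand unit conversions
#'
#' Invertible conversions among ng/ml, nM and pM (mass units require the
#' declared molar mass) and to absolute copy numbers given a volume.
#'
#' @param x Concentration value(s).
#' @param from,to Units: `"ng/ml"`, `"nM"`, `"pM"`.
#' @param mw Molar mass (g/mol), needed for `"ng/ml"`.
#' @return Converted value(s).
#' @export
ligand_conc <- function(x, from, to, mw = 44000) {
  to_nM <- switch(from,
    "nM" = x,
    "pM" = x / 1000,
    "ng/ml" = x * 1000 / mw,
    stop("unknown unit: ", from))
  switch(to,
    "nM" = to_nM,
    "pM" = to_nM * 1000,
    "ng/ml" = to_nM * mw / 1000,
    stop("unknown unit: ", to))
}

#' Ligand concentration to per-cell copy number
#'
#' @param conc Concentration.
#' @param units `"nM"`, `"pM"`, or `"ng/ml"`.
#' @param volume_L Accessible medium volume per cell (litres).
#' @param mw Molar mass (g/mol) for mass units.
#' @return Copies per cell.
#' @export
ligand_to_copy_number <- function(conc, units, volume_L = 1e-9, mw = 44000) {
  nM <- ligand_conc(conc, units, "nM", mw = mw)
  nM * 1e-9 * volume_L * 6.02214076e23
}

#' Receptor surface density to per-cell count
#' @param per_um2 Receptors per square micron.
#' @param area_um2 Cell surface area (square microns).
#' @return Copies per cell.
#' @export
density_to_count <- function(per_um2, area_um2 = 1400) per_um2 * area_um2

#' @rdname density_to_count
#' @param count Copies per cell.
#' @export
count_to_density <- function(count, area_um2 = 1400) count / area_um2

#' Run a stimulation protocol
#'
#' Compiles the ODE system from the model and integrates it over the
#' protocol with a stiff solver (`deSolve::lsodes`), restarting at each
#' event time. Seed and parameter events at time zero are applied before
#' the initial state is formed.
#'
#' @param model A `vegf_model` (see [vegf_model()]) or a raw
#'   `reaction_network`.
#' @param prot A `protocol`.
#' @param params Optional parameter tibble override.
#' @param rtol,atol Solver tolerances.
#' @param downstream Couple the cascade/calcium modules (default `TRUE`).
#' @param sphk1_blocked,cib1_blocked Cascade block switches.
#' @return A `trajectory` tibble: `time` (minutes), observables, cascade
#'   and calcium states, plus fraction-total receptor columns normalized to
#'   the time-zero total.
#' @export
run_protocol <- function(model, prot, params = NULL, rtol = 1e-8,
                         atol = 1e-12, downstream = TRUE,
                         sphk1_blocked = FALSE, cib1_blocked = FALSE) {
  net <- if (inherits(model, "reaction_network")) model else model$net
  params <- params %||%
    (if (inherits(model, "reaction_network")) net$params else model$params)
  ev <- prot$events
  # time-zero seed/parameter events applied before compilation
  if (nrow(ev)) {
    for (r in which(ev$time <= 0 & ev$action == "set_param")) {
      params <- do.call(param_set,
                        c(list(params), stats::setNames(list(ev$value[r]), ev$target[r])))
    }
    for (r in which(ev$time <= 0 & ev$action == "scale_param")) {
      params <- do.call(param_scale,
                        c(list(params), stats::setNames(list(ev$value[r]), ev$target[r])))
    }
  }
  sys <- build_ode(net, params, downstream = downstream,
                   sphk1_blocked = sphk1_blocked, cib1_blocked = cib1_blocked)
  y <- sys$y0
  if (nrow(ev)) {
    for (r in which(ev$time <= 0 & ev$action == "set_seed")) {
      y <- scale_seed(sys, y, ev$target[r], ev$value[r])
    }
  }
  seg_bounds <- sort(unique(c(0, ev$time[ev$time > 0], prot$duration)))
  seg_bounds <- seg_bounds[seg_bounds <= prot$duration]
  if (max(seg_bounds) < prot$duration) seg_bounds <- c(seg_bounds, prot$duration)
  out_all <- NULL
  diagnostics <- list()
  for (si in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[si]; t1 <- seg_bounds[si + 1L]
    # apply events scheduled at t0
    if (nrow(ev)) {
      rows <- which(abs(ev$time - t0) < 1e-12 & (ev$time > 0 | t0 == 0))
      for (r in rows) {
        act <- ev$action[r]
        if (act == "set_ligand") {
          y[ligand_index(sys, ev$target[r])] <- ev$value[r]
        } else if (act %in% c("set_param", "scale_param") && t0 > 0) {
          fn <- if (act == "set_param") param_set else param_scale
          params <- do.call(fn, c(list(params),
                                  stats::setNames(list(ev$value[r]), ev$target[r])))
          sys <- build_ode(net, params, downstream = downstream,
                           sphk1_blocked = sphk1_blocked,
                           cib1_blocked = cib1_blocked)
        } else if (act == "set_seed" && t0 > 0) {
          y <- scale_seed(sys, y, ev$target[r], ev$value[r])
        }
      }
    }
    times <- unique(c(seq(t0, t1, by = prot$dt), t1)) * 60 # minutes -> s
    sol <- deSolve::lsodes(y = y, times = times, func = sys$rhs,
                           rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("solver failure in segment [", t0, ",", t1, "] min; last good time ",
           signif(max(sol[, 1]) / 60, 4), " min")
    }
    diagnostics[[si]] <- attr(sol, "istate")
    y <- sol[nrow(sol), -1]
    names(y) <- sys$state_names
    keep <- if (si < length(seg_bounds) - 1L) -nrow(sol) else TRUE
    out_all <- rbind(out_all, if (identical(keep, TRUE)) sol else sol[keep, , drop = FALSE])
  }
  trajectory_tibble(out_all, sys, rtol = rtol, atol = atol,
                    diagnostics = diagnostics)
}

ligand_index <- function(sys, target) {
  if (target == "VEGF") sys$clamp[1]
  else if (target == "TSP1") sys$clamp[2]
  else stop("unknown ligand: ", target)
}

# scale all network species amounts containing a molecule type (depletion /
# knockout); value is the retained fraction of the current amount
scale_seed <- function(sys, y, type, frac) {
  if (!type %in% rownames(sys$comp_matrix)) stop("unknown molecule type: ", type)
  has <- which(sys$comp_matrix[type, ] > 0)
  has <- setdiff(has, sys$clamp)
  y[has] <- y[has] * frac
  y
}

trajectory_tibble <- function(sol, sys, rtol, atol, diagnostics) {
  tm <- sol[, 1] / 60
  out <- tibble::tibble(time = tm)
  W <- sys$obs_weights
  yn <- sol[, 1 + seq_len(sys$n_net), drop = FALSE]
  if (!is.null(W)) {
    for (oi in seq_len(nrow(W))) {
      out[[rownames(W)[oi]]] <- as.numeric(yn %*% W[oi, ])
    }
  }
  if (sys$downstream) {
    for (nm in names(sys$cascade_idx)) {
      out[[nm]] <- sol[, 1 + sys$cascade_idx[[nm]]]
    }
    for (nm in names(sys$calcium_idx)) {
      out[[nm]] <- sol[, 1 + sys$calcium_idx[[nm]]]
    }
  }
  if ("R2_total" %in% names(out) && out$R2_total[1] > 0) {
    tot0 <- out$R2_total[1]
    out$R2_frac <- out$R2_total / tot0
    if ("R2_surf" %in% names(out)) out$R2_surf_frac <- out$R2_surf / tot0
    if ("pR2" %in% names(out)) out$pR2_frac <- out$pR2 / tot0
  }
  attr(out, "solver") <- list(rtol = rtol, atol = atol,
                              diagnostics = diagnostics)
  attr(out, "sys") <- sys
  class(out) <- c("trajectory", class(out))
  out
}

#' Plot a trajectory
#'
#' @param object A `trajectory`.
#' @param vars Columns to plot (default: pR2 fraction, calcium, pERK).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, vars = c("pR2_frac", "Ca_c", "pERK"),
                                ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(object[, c("time", vars)],
                              -"time", names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}
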