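# Calcium cycling: IP3-receptor release from the ER, SERCA and
# plasma-membrane pumps, rapid-equilibrium buffering in both compartments,
# and the store-operated CRAC current with first-order activation dynamics.

#' Steady-state CRAC current as a function of ER calcium
#'
#' A Hill function of ER calcium with fixed exponent: full activation when
#' stores are empty, half current when `Ca_ER` equals `K_crac`, and steep
#' shut-off as stores fill.
#'
#' @param ca_er ER calcium (uM), non-negative.
#' @param p Named list or tibble-derived list with `Icrac_bar` (uM/s),
#'   `K_crac` (uM), `hill_crac`.
#' @return Current (uM/s).
#' @export
crac_steady_current <- function(ca_er, p) {
  if (any(ca_er < 0)) stop("Ca_ER must be non-negative")
  h <- p$hill_crac
  p$Icrac_bar * p$K_crac^h / (p$K_crac^h + ca_er^h)
}

#' CRAC current relaxation
#'
#' First-order approach of the carried current `J` to its steady-state
#' value `I` with time constant `tau`.
#'
#' @param J Current state (uM/s).
#' @param I Steady-state target current (uM/s).
#' @param tau Activation time constant (s), positive.
#' @return dJ/dt (uM/s^2).
#' @export
crac_dynamics <- function(J, I, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  (I - J) / tau
}

# rapid-buffer factor: fraction of an incremental calcium flux that stays
# free, for a single buffer with capacity B and dissociation constant K
buffer_factor <- function(ca, B, K) {
  1 / (1 + B * K / (K + ca)^2)
}

# calcium parameter sub-list from a parameter tibble
calcium_pars <- function(params) {
  nm <- c("Ca0", "CaER0", "vol_ratio", "Bc_tot", "Kb_c", "Ber_tot", "Kb_er",
          "kip3r", "Kip3", "Kact", "Vserca", "Kserca", "Vpm", "Kpm",
          "Icrac_bar", "K_crac", "hill_crac", "tau_crac")
  as.list(stats::setNames(param_get(params, nm), nm))
}

# leak and basal-influx constants that pin the resting state: with no IP3 the
# ER leak balances SERCA at (Ca0, CaER0) and plasma-membrane influx balances
# extrusion plus the small resting CRAC current
calcium_rest_constants <- function(cp) {
  jserca0 <- cp$Vserca * cp$Ca0^2 / (cp$Kserca^2 + cp$Ca0^2)
  kleak <- jserca0 / (cp$CaER0 - cp$Ca0)
  jpm0 <- cp$Vpm * cp$Ca0^2 / (cp$Kpm^2 + cp$Ca0^2)
  jcrac0 <- crac_steady_current(cp$CaER0, cp)
  vin <- jpm0 - jcrac0
  if (vin < 0) stop("resting CRAC current exceeds PM extrusion; increase Vpm")
  list(kleak = kleak, vin = vin)
}

#' Calcium module right-hand side
#'
#' State balance: cytosolic calcium gains IP3R release, ER leak and the CRAC
#' current plus basal influx, and loses SERCA uptake and plasma-membrane
#' extrusion; the ER mirrors the exchange terms scaled by the volume ratio.
#' Both balances are scaled by rapid-equilibrium buffer factors.
#'
#' @param state Named numeric vector `c(Ca_c=, Ca_ER=, Jcrac=)` (uM, uM, uM/s).
#' @param ip3 IP3 drive (uM).
#' @param params Parameter tibble (see [default_params()]).
#' @param pm_fluxes If `FALSE`, plasma-membrane influx/efflux and CRAC are
#'   zeroed (closed-cell setting for conservation audits).
#' @return Named derivative vector.
#' @export
calcium_rhs <- function(state, ip3, params, pm_fluxes = TRUE) {
  cp <- calcium_pars(params)
  calcium_rhs_(state, ip3, cp, calcium_rest_constants(cp), pm_fluxes)
}

# fast path: prepared parameter and rest-constant lists
calcium_rhs_ <- function(state, ip3, cp, rc, pm_fluxes = TRUE) {
  ca <- state[["Ca_c"]]; caer <- state[["Ca_ER"]]; J <- state[["Jcrac"]]
  ca_p <- max(ca, 0); caer_p <- max(caer, 0)
  h_ip3 <- ip3^2 / (cp$Kip3^2 + ip3^2)
  h_act <- ca_p / (cp$Kact + ca_p)
  j_ip3r <- cp$kip3r * h_ip3 * h_act * (caer - ca)
  j_leak <- rc$kleak * (caer - ca)
  j_serca <- cp$Vserca * ca_p^2 / (cp$Kserca^2 + ca_p^2)
  j_pm <- cp$Vpm * ca_p^2 / (cp$Kpm^2 + ca_p^2)
  icrac <- crac_steady_current(caer_p, cp)
  bc <- buffer_factor(ca_p, cp$Bc_tot, cp$Kb_c)
  ber <- buffer_factor(caer_p, cp$Ber_tot, cp$Kb_er)
  pm_in <- if (pm_fluxes) J + rc$vin else 0
  pm_out <- if (pm_fluxes) j_pm else 0
  dca <- bc * (j_ip3r + j_leak - j_serca + pm_in - pm_out)
  dcaer <- ber * cp$vol_ratio * (j_serca - j_ip3r - j_leak)
  dJ <- crac_dynamics(J, icrac, cp$tau_crac)
  c(Ca_c = dca, Ca_ER = dcaer, Jcrac = dJ)
}

# total exchangeable calcium (free + buffered, cytosol + ER in cytosolic
# volume units); conserved when plasma-membrane fluxes are off
calcium_total <- function(state, params) {
  cp <- calcium_pars(params)
  ca <- state[["Ca_c"]]; caer <- state[["Ca_ER"]]
  bound_c <- cp$Bc_tot * ca / (cp$Kb_c + ca)
  bound_er <- cp$Ber_tot * caer / (cp$Kb_er + caer)
  (ca + bound_c) + (caer + bound_er) / cp$vol_ratio
}

# resting calcium state consistent with the fixed-point construction
calcium_rest_state <- function(params) {
  cp <- calcium_pars(params)
  c(Ca_c = cp$Ca0, Ca_ER = cp$CaER0,
    Jcrac = crac_steady_current(cp$CaER0, cp))
}
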