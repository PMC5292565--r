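# Coarse-grained signal transduction from phosphorylated VEGFR2 to ERK1/2:
# PLC-gamma -> (IP3, PKC), the SphK1/S1P positive-feedback loop gated by
# calcium through CIB1, and the Ras/Raf/MEK/ERK cascade. All cycles conserve
# their protein totals; no synthesis or degradation occurs in this layer.

#' PLC-gamma phosphorylation rate at phosphorylated VEGFR2
#'
#' Michaelis-Menten-type lumped reaction: recruitment of PLC-gamma to the
#' phosphorylated receptor, phosphorylation and release, saturating in free
#' PLC-gamma.
#'
#' @param pR2 Phosphorylated VEGFR2 (copies per cell), non-negative.
#' @param PLCg Free (unphosphorylated) PLC-gamma (uM), non-negative.
#' @param kpPLCg Catalytic constant (uM per copy per s).
#' @param KmPLCg Michaelis constant (uM).
#' @return Rate (uM/s).
#' @export
plcg_rate <- function(pR2, PLCg, kpPLCg, KmPLCg) {
  if (any(pR2 < 0) || any(PLCg < 0)) stop("inputs must be non-negative")
  kpPLCg * pR2 * PLCg / (KmPLCg + PLCg)
}

#' Ras activation rate by S1P
#'
#' Saturating (Michaelis-Menten-type) activation of Ras by S1P; S1P acts
#' catalytically and is not consumed. The returned value is the maximal
#' GDP-to-GTP conversion rate at the given S1P level; in the full system it
#' is distributed over the available RasGDP fraction so the Ras total is
#' conserved and RasGDP cannot go negative.
#'
#' @param RasGDP Inactive Ras (uM), non-negative (carried for the flux
#'   scaling; the saturable rate itself depends only on S1P).
#' @param S1P Sphingosine-1-phosphate (uM), non-negative.
#' @param kS1PRas Maximal rate (uM/s).
#' @param KmS1PRas Half-saturation constant (uM).
#' @return Rate (uM/s).
#' @export
ras_rate <- function(RasGDP, S1P, kS1PRas, KmS1PRas) {
  if (any(RasGDP < 0) || any(S1P < 0)) stop("inputs must be non-negative")
  kS1PRas * S1P / (S1P + KmS1PRas)
}

cascade_par_names <- c(
  "PLCg_tot", "kpPLCg", "KmPLCg", "kdpPLCg", "kIP3", "kIP3deg",
  "PKC_tot", "kPKC", "kdPKC",
  "SphK1_tot", "kSphK_erk", "kdSphK", "ktrans", "koff_m",
  "CIB1_tot", "Kd_CIB", "kS1P", "kS1Pdeg",
  "kS1PRas", "KmS1PRas", "Ras_tot", "kGAP",
  "Raf_tot", "kRafRas", "kRafPKC", "VdRaf", "KmdRaf", "hill_cib",
  "MEK_tot", "kMEK", "kdMEK", "ERK_tot", "kERK", "kdERK")

cascade_pars <- function(params) {
  as.list(stats::setNames(param_get(params, cascade_par_names),
                          cascade_par_names))
}

cascade_state_names <- c("PLCg", "pPLCg", "IP3", "PKC", "aPKC",
                         "SphK1", "pSphK1", "SphK1m", "S1P",
                         "RasGDP", "RasGTP", "Raf", "aRaf",
                         "MEK", "aMEK", "ERK", "pERK")

# resting cascade state: everything in its inactive pool
cascade_rest_state <- function(params) {
  cp <- cascade_pars(params)
  st <- stats::setNames(numeric(length(cascade_state_names)),
                        cascade_state_names)
  st["PLCg"] <- cp$PLCg_tot
  st["PKC"] <- cp$PKC_tot
  st["SphK1"] <- cp$SphK1_tot
  st["RasGDP"] <- cp$Ras_tot
  st["Raf"] <- cp$Raf_tot
  st["MEK"] <- cp$MEK_tot
  st["ERK"] <- cp$ERK_tot
  st
}

#' Cascade right-hand side
#'
#' @param state Named vector over [cascade_state_names].
#' @param pR2 Phosphorylated VEGFR2 drive (copies per cell).
#' @param ca Cytosolic calcium (uM), gates CIB1-mediated SphK1 translocation.
#' @param params Parameter tibble.
#' @param sphk1_blocked If `TRUE`, SphK1 phosphorylation is zeroed
#'   (pharmacological SphK1 inhibition).
#' @param cib1_blocked If `TRUE`, the CIB1 calcium switch is zeroed.
#' @return Named derivative vector.
#' @export
cascade_rhs <- function(state, pR2, ca, params,
                        sphk1_blocked = FALSE, cib1_blocked = FALSE) {
  cascade_rhs_(state, pR2, ca, cascade_pars(params), sphk1_blocked,
               cib1_blocked)
}

# fast path: prepared parameter list
cascade_rhs_ <- function(state, pR2, ca, cp,
                         sphk1_blocked = FALSE, cib1_blocked = FALSE) {
  s <- function(n) state[[n]]
  d <- stats::setNames(numeric(length(cascade_state_names)),
                       cascade_state_names)
  pos <- function(x) max(x, 0)

  v_plcg <- plcg_rate(pos(pR2), pos(s("PLCg")), cp$kpPLCg, cp$KmPLCg)
  v_dplcg <- cp$kdpPLCg * s("pPLCg")
  d["PLCg"] <- v_dplcg - v_plcg
  d["pPLCg"] <- v_plcg - v_dplcg

  d["IP3"] <- cp$kIP3 * pos(s("pPLCg")) - cp$kIP3deg * s("IP3")

  v_pkc <- cp$kPKC * pos(s("pPLCg")) * pos(s("PKC"))
  v_dpkc <- cp$kdPKC * s("aPKC")
  d["PKC"] <- v_dpkc - v_pkc
  d["aPKC"] <- v_pkc - v_dpkc

  v_sphk <- if (sphk1_blocked) 0 else
    cp$kSphK_erk * pos(s("pERK")) * pos(s("SphK1"))
  cib_ca <- if (cib1_blocked) 0 else
    cp$CIB1_tot * pos(ca)^cp$hill_cib /
      (cp$Kd_CIB^cp$hill_cib + pos(ca)^cp$hill_cib)
  v_trans <- cp$ktrans * cib_ca * pos(s("pSphK1"))
  v_back <- cp$koff_m * s("SphK1m")
  v_dsphk <- cp$kdSphK * s("pSphK1")
  d["SphK1"] <- v_dsphk - v_sphk
  d["pSphK1"] <- v_sphk - v_dsphk - v_trans + v_back
  d["SphK1m"] <- v_trans - v_back

  d["S1P"] <- cp$kS1P * pos(s("SphK1m")) - cp$kS1Pdeg * s("S1P")

  v_ras <- ras_rate(pos(s("RasGDP")), pos(s("S1P")), cp$kS1PRas, cp$KmS1PRas) *
    pos(s("RasGDP")) / cp$Ras_tot
  v_gap <- cp$kGAP * s("RasGTP")
  d["RasGDP"] <- v_gap - v_ras
  d["RasGTP"] <- v_ras - v_gap

  v_raf <- (cp$kRafRas * pos(s("RasGTP")) + cp$kRafPKC * pos(s("aPKC"))) *
    pos(s("Raf"))
  v_draf <- cp$VdRaf * pos(s("aRaf")) / (cp$KmdRaf + pos(s("aRaf")))
  d["Raf"] <- v_draf - v_raf
  d["aRaf"] <- v_raf - v_draf

  v_mek <- cp$kMEK * pos(s("aRaf")) * pos(s("MEK"))
  v_dmek <- cp$kdMEK * s("aMEK")
  d["MEK"] <- v_dmek - v_mek
  d["aMEK"] <- v_mek - v_dmek

  v_erk <- cp$kERK * pos(s("aMEK")) * pos(s("ERK"))
  v_derk <- cp$kdERK * s("pERK")
  d["ERK"] <- v_derk - v_erk
  d["pERK"] <- v_erk - v_derk

  d
}
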