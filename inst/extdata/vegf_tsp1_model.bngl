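# VEGF-VEGFR2 / TSP1-CD47 receptor-layer model (BNGL subset).
# Ligands (free VEGF, free TSP1) are boundary species clamped by the
# protocol, in nM; receptors and surface complexes are copies per cell.
# Rate constants touching a free ligand are per-nM; surface-surface coupling
# constants are per-(molecule/cell). Parameter values are the packaged
# calibrated set (see params_calibrated.csv for the downstream modules).
begin model
begin parameters
  # ligand-receptor binding (per nM per s)
  kon_v_r2    0.01
  koff_v_r2   0.003
  kon_v_r1    0.002
  koff_v_r1   0.003
  kon_n_vsol  1.0e-6
  koff_n_v    2.0e-5
  kon_t_c     0.1
  koff_t_c    2.6e-3
  # surface-surface coupling (per molecule/cell per s)
  kdim        5.0e-4
  kundim      0.01
  kdim_het    2.0e-4
  kundim_het  0.05
  kc          2.0e-5
  kuc         0.05
  kclose      0.5
  kcc_in      1.0
  kon_n_vsurf 2.5e-7
  kon_n_r1    1.0e-5
  koff_n_r1   0.01
  kon_c_r2    1.0e-3
  koff_c_r2   0.01
  # phosphorylation cycle (per s)
  kphos       1.0
  kdp_s       8.0
  kdp_e       0.26
  fold_dephos 1
  kdp_s_tsp   kdp_s*fold_dephos
  kdp_e_tsp   kdp_e*fold_dephos
  # trafficking (per s)
  kint        4.0e-2
  krec_nrp    0.756
  krec        1.24e-3
  kdeg        1.43e-3
  fold_deg    1
  kdeg_tsp    kdeg*fold_deg
  # seed amounts (copies per cell; ligands nM)
  R2_0        6000
  R1_0        1000
  NRP1_0      20000
  CD47_0      7000
  VEGF_0      0
  TSP1_0      0
end parameters
begin molecule types
  VEGF(r,r,n)
  VEGFR2(L,C,Y1175~U~P,cd)
  VEGFR1(L,C,nb)
  NRP1(v)
  CD47(vr,t)
  TSP1(c)
end molecule types
begin seed species
  VEGF(r,r,n) VEGF_0
  TSP1(c) TSP1_0
  VEGFR2(L,C,Y1175~U,cd) R2_0
  VEGFR1(L,C,nb) R1_0
  NRP1(v) NRP1_0
  CD47(vr,t) CD47_0
end seed species
begin observables
  Molecules pR2 VEGFR2(Y1175~P)
  Molecules R2_total VEGFR2()
  Molecules R2_surf @surface:VEGFR2()
  Molecules R2_endo @endo:VEGFR2()
  Molecules pR2_surf @surface:VEGFR2(Y1175~P)
  Molecules pR2_endo @endo:VEGFR2(Y1175~P)
  Species VEGF_bound VEGF(r!+)
  Molecules CD47_total CD47()
  Molecules CD47_tsp1 CD47(t!+)
end observables
begin reaction rules
  # VEGF binding from solution (receptor coupling state unrestricted)
  vr2_bind: @surface:VEGF(r,r,n) + @surface:VEGFR2(L) <-> @surface:VEGF(r!1,r,n).VEGFR2(L!1) kon_v_r2, koff_v_r2
  vr1_bind: @surface:VEGF(r,r,n) + @surface:VEGFR1(L) <-> @surface:VEGF(r!1,r,n).VEGFR1(L!1) kon_v_r1, koff_v_r1
  # NRP1-presented VEGF binding to VEGFR2 (surface coupling)
  vr2_nrp_bind: @surface:VEGF(r,r,n!+) + @surface:VEGFR2(L) <-> @surface:VEGF(r!1,r,n!+).VEGFR2(L!1) kon_n_vsurf, koff_v_r2
  # ligand-mediated receptor dimerization (second-arm cross-linking of two
  # uncoupled receptors; the coupling bond forms in a separate step below)
  vr2_dim: @surface:VEGF(r!1,r).VEGFR2(L!1,C) + @surface:VEGFR2(L,C) <-> @surface:VEGF(r!1,r!2).VEGFR2(L!1,C).VEGFR2(L!2,C) kdim, kundim
  vr12_dim: @surface:VEGF(r!1,r).VEGFR2(L!1,C) + @surface:VEGFR1(L,C) <-> @surface:VEGF(r!1,r!2).VEGFR2(L!1,C).VEGFR1(L!2,C) kdim_het, kundim_het
  vr21_dim: @surface:VEGF(r!1,r).VEGFR1(L!1,C) + @surface:VEGFR2(L,C) <-> @surface:VEGF(r!1,r!2).VEGFR1(L!1,C).VEGFR2(L!2,C) kdim_het, kundim_het
  vr11_dim: @surface:VEGF(r!1,r).VEGFR1(L!1,C) + @surface:VEGFR1(L,C) <-> @surface:VEGF(r!1,r!2).VEGFR1(L!1,C).VEGFR1(L!2,C) kdim_het, kundim_het
  # ligand-independent coupling-site engagement within a bridged dimer
  cc22: VEGF(r!1,r!2).VEGFR2(L!1,C).VEGFR2(L!2,C) <-> VEGF(r!1,r!2).VEGFR2(L!1,C!3).VEGFR2(L!2,C!3) kcc_in, kuc
  cc12: VEGF(r!1,r!2).VEGFR2(L!1,C).VEGFR1(L!2,C) <-> VEGF(r!1,r!2).VEGFR2(L!1,C!3).VEGFR1(L!2,C!3) kcc_in, kuc
  cc11: VEGF(r!1,r!2).VEGFR1(L!1,C).VEGFR1(L!2,C) <-> VEGF(r!1,r!2).VEGFR1(L!1,C!3).VEGFR1(L!2,C!3) kcc_in, kuc
  # intra-complex ring closure: ligand bound on one arm of a pre-dimer
  # bridges to the partner receptor
  close22: @surface:VEGF(r!1,r).VEGFR2(L!1,C!2).VEGFR2(C!2,L) <-> @surface:VEGF(r!1,r!3).VEGFR2(L!1,C!2).VEGFR2(C!2,L!3) kclose, kundim
  close12: @surface:VEGF(r!1,r).VEGFR2(L!1,C!2).VEGFR1(C!2,L) <-> @surface:VEGF(r!1,r!3).VEGFR2(L!1,C!2).VEGFR1(C!2,L!3) kclose, kundim_het
  close21: @surface:VEGF(r!1,r).VEGFR1(L!1,C!2).VEGFR2(C!2,L) <-> @surface:VEGF(r!1,r!3).VEGFR1(L!1,C!2).VEGFR2(C!2,L!3) kclose, kundim_het
  close11: @surface:VEGF(r!1,r).VEGFR1(L!1,C!2).VEGFR1(C!2,L) <-> @surface:VEGF(r!1,r!3).VEGFR1(L!1,C!2).VEGFR1(C!2,L!3) kclose, kundim_het
  # ligand-independent pre-dimerization of free receptors
  pre22: @surface:VEGFR2(L,C) + @surface:VEGFR2(L,C) <-> @surface:VEGFR2(L,C!1).VEGFR2(L,C!1) kc, kuc
  pre12: @surface:VEGFR1(L,C) + @surface:VEGFR2(L,C) <-> @surface:VEGFR1(L,C!1).VEGFR2(L,C!1) kc, kuc
  pre11: @surface:VEGFR1(L,C) + @surface:VEGFR1(L,C) <-> @surface:VEGFR1(L,C!1).VEGFR1(L,C!1) kc, kuc
  # NRP1 interactions (single competitive site on NRP1)
  nrp_vsol: @surface:NRP1(v) + @surface:VEGF(r,r,n) <-> @surface:NRP1(v!1).VEGF(r,r,n!1) kon_n_vsol, koff_n_v
  nrp_vsurf: @surface:NRP1(v) + @surface:VEGF(r!+,n) <-> @surface:NRP1(v!1).VEGF(r!+,n!1) kon_n_vsurf, koff_n_v
  nrp_r1: @surface:NRP1(v) + @surface:VEGFR1(nb) <-> @surface:NRP1(v!1).VEGFR1(nb!1) kon_n_r1, koff_n_r1
  # CD47 pre-association with VEGFR2; TSP1 engagement of CD47
  cd47_r2: @surface:CD47(vr) + @surface:VEGFR2(cd) <-> @surface:CD47(vr!1).VEGFR2(cd!1) kon_c_r2, koff_c_r2
  tsp_cd47: @surface:TSP1(c) + @surface:CD47(t) <-> @surface:TSP1(c!1).CD47(t!1) kon_t_c, koff_t_c
  # trans-autophosphorylation in VEGF-bridged VEGFR2 homodimers; dephosphorylation
  phos: VEGF(r!1,r!2).VEGFR2(L!1).VEGFR2(L!2,Y1175~U) -> VEGF(r!1,r!2).VEGFR2(L!1).VEGFR2(L!2,Y1175~P) kphos
  # dephosphorylation is compartment-resolved: phosphatase access is high at
  # the plasma membrane and low in the endosome, so sustained signaling comes
  # from internalized receptors
  dephos_s: @surface:VEGFR2(Y1175~P) -> @surface:VEGFR2(Y1175~U) kdp_s exclude_reactants(1,CD47(t!+))
  dephos_e: @endo:VEGFR2(Y1175~P) -> @endo:VEGFR2(Y1175~U) kdp_e exclude_reactants(1,CD47(t!+))
  # enhanced dephosphorylation in complexes carrying TSP1-engaged CD47; the
  # one/two-copy split keeps the per-receptor rate independent of how many
  # CD47 copies are engaged (so fold 1 is exactly neutral)
  dephos_s_tsp1: @surface:VEGFR2(Y1175~P).CD47(t!+) -> @surface:VEGFR2(Y1175~U).CD47(t!+) kdp_s_tsp exclude_reactants(1,CD47(t!+).CD47(t!+))
  dephos_s_tsp2: @surface:VEGFR2(Y1175~P).CD47(t!+).CD47(t!+) -> @surface:VEGFR2(Y1175~U).CD47(t!+).CD47(t!+) kdp_s_tsp
  dephos_e_tsp1: @endo:VEGFR2(Y1175~P).CD47(t!+) -> @endo:VEGFR2(Y1175~U).CD47(t!+) kdp_e_tsp exclude_reactants(1,CD47(t!+).CD47(t!+))
  dephos_e_tsp2: @endo:VEGFR2(Y1175~P).CD47(t!+).CD47(t!+) -> @endo:VEGFR2(Y1175~U).CD47(t!+).CD47(t!+) kdp_e_tsp
  # trafficking of VEGF/VEGFR2/VEGFR2 complexes
  intern: @surface:VEGF(r!1,r!2).VEGFR2(L!1).VEGFR2(L!2) -> @endo:VEGF(r!1,r!2).VEGFR2(L!1).VEGFR2(L!2) kint
  rec_nrp: @endo:VEGF(n!1).NRP1(v!1) -> @surface:VEGF(n!1).NRP1(v!1) krec_nrp
  rec: @endo:VEGF(n) -> @surface:VEGF(n) krec
  deg: @endo:VEGF(n) -> 0 kdeg exclude_reactants(1,CD47(t!+))
  deg_nrp: @endo:VEGF(n!+) -> 0 kdeg exclude_reactants(1,CD47(t!+))
  deg_tsp1: @endo:VEGF().CD47(t!+) -> 0 kdeg_tsp exclude_reactants(1,CD47(t!+).CD47(t!+))
  deg_tsp2: @endo:VEGF().CD47(t!+).CD47(t!+) -> 0 kdeg_tsp
end reaction rules
end model
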