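name,value,units,lower,upper,description
PLCg_tot,1,uM,0.1,10,total PLC-gamma
kpPLCg,3e-4,uM/(molecule.s),5e-9,5e-5,PLC-gamma phosphorylation catalytic constant (per pVEGFR2 copy)
KmPLCg,1,uM,0.01,100,Michaelis constant of PLC-gamma phosphorylation
kdpPLCg,0.05,1/s,1e-4,1,PLC-gamma dephosphorylation rate
kIP3,0.1,1/s,1e-3,10,IP3 production rate per pPLC-gamma
kIP3deg,0.05,1/s,5e-4,5,IP3 turnover rate
PKC_tot,1,uM,0.1,10,total PKC
kPKC,0.05,1/(uM.s),3e-3,30,PKC activation by the pPLC-gamma/DAG arm
kdPKC,0.02,1/s,2e-4,2,PKC deactivation rate
SphK1_tot,1,uM,0.1,10,total sphingosine kinase 1
kSphK_erk,0.027,1/(uM.s),5e-3,50,SphK1 phosphorylation by pERK1/2 (positive feedback)
kdSphK,0.5,1/s,2e-4,2,pSphK1 dephosphorylation rate
ktrans,0.1,1/(uM.s),0.02,200,CIB1-mediated membrane translocation of pSphK1
koff_m,0.3,1/s,2e-4,2,membrane SphK1 return rate
CIB1_tot,1,uM,0.1,10,total CIB1
Kd_CIB,0.25,uM,0.003,30,calcium dissociation constant of the CIB1 myristoyl switch
kS1P,0.3,1/s,2e-3,20,S1P production by membrane SphK1
kS1Pdeg,0.3,1/s,5e-4,5,S1P turnover rate
kS1PRas,0.4,uM/s,2e-3,20,maximal Ras activation rate by S1P
KmS1PRas,0.5,uM,0.002,20,Michaelis constant of Ras activation by S1P
Ras_tot,0.5,uM,0.05,5,total Ras
kGAP,0.2,1/s,5e-4,5,RasGTP hydrolysis rate
Raf_tot,0.5,uM,0.05,5,total Raf
kRafRas,2.5,1/(uM.s),0.02,200,Raf activation by RasGTP
kRafPKC,0.0013,1/(uM.s),2e-4,2,direct (feedback-independent) Raf activation by active PKC
MEK_tot,1,uM,0.1,10,total MEK
kMEK,1,1/(uM.s),0.02,200,MEK activation by active Raf
kdMEK,0.2,1/s,5e-4,5,MEK deactivation rate
ERK_tot,1,uM,0.1,10,total ERK1/2
kERK,1.5,1/(uM.s),0.02,200,ERK activation by active MEK
kdERK,0.3,1/s,5e-4,5,ERK deactivation rate
Ca0,0.1,uM,0.01,1,resting cytosolic calcium
CaER0,400,uM,40,4000,resting ER calcium
vol_ratio,10,1,1,100,cytosol to ER volume ratio
Bc_tot,220,uM,22,2200,cytosolic rapid buffer capacity
Kb_c,10,uM,1,100,cytosolic buffer dissociation constant
Ber_tot,2200,uM,220,22000,ER rapid buffer capacity
Kb_er,500,uM,50,5000,ER buffer dissociation constant
kip3r,0.065,1/s,2e-5,0.2,IP3 receptor maximal release scale
Kip3,0.6,uM,0.005,50,IP3 half-activation of IP3R
Kact,0.25,uM,0.003,30,cytosolic calcium half-activation of IP3R
Vserca,10,uM/s,0.01,100,SERCA maximal pump rate
Kserca,0.25,uM,0.0015,15,SERCA half-activation
Vpm,6,uM/s,0.2,2000,plasma-membrane extrusion maximal rate
Kpm,0.35,uM,0.003,30,plasma-membrane pump half-activation
Icrac_bar,1.74e4,uM/s,174,1.74e6,CRAC current amplitude
K_crac,22,uM,4.5,4500,ER-calcium half-inhibition of CRAC steady current
hill_crac,4.2,1,4.2,4.2,CRAC Hill exponent (fixed)
tau_crac,2,s,0.02,200,CRAC activation time constant
cell_area_um2,1400,um^2,1400,1400,cell surface area used for receptors-per-area conversions
VEGF_mw,44000,g/mol,44000,44000,declared molar mass of the VEGF-A165 homodimer
hill_cib,4,1,1,8,Hill coefficient of the CIB1 calcium switch
VdRaf,0.05,uM/s,2e-4,2,maximal Raf deactivation rate (saturable phosphatase)
KmdRaf,0.05,uM,5e-4,5,Michaelis constant of Raf deactivation
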