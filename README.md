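# vegfsig

Rule-based modeling of VEGF–VEGFR2 signaling and its inhibition by
thrombospondin-1 (TSP1) acting through CD47, in R.

VEGF binding to VEGFR2 drives angiogenic signaling through receptor
dimerization, trans-autophosphorylation, and trafficking
(internalization, NRP1-dependent recycling, degradation), feeding a
coarse-grained cascade from PLCγ through PKC and the calcium-gated
SphK1/S1P/Ras positive-feedback loop to ERK1/2, together with an
IP3R/SERCA/CRAC calcium module. TSP1, an endogenous angiogenesis
inhibitor, engages CD47 pre-associated with VEGFR2; the package models
its two hypothesized inhibition mechanisms — enhanced degradation of
endosomal receptor complexes and phosphatase recruitment (enhanced
receptor dephosphorylation) — as fold-changes on the corresponding rate
constants of TSP1-engaged complexes.

The receptor layer is written as site-graph rules (a BNGL-compatible
subset): molecules declare binding/modification sites, rules rewrite
bonds and states, and the full reaction network is enumerated
automatically with canonical-label deduplication and mass-action
statistical factors. The packaged ruleset generates 558 species and
4347 directed reactions, which compile (with the cascade and calcium
closures) into one stiff ODE system. On top sit:

- timed stimulation protocols (e.g. 2 nM TSP1 for 10 min, then
  50 ng/ml VEGF),
- derivative-free parameter fitting (generalized pattern search in
  log10 space),
- global sensitivity analysis by partial rank correlation coefficients
  (PRCC) over uniform 0.01×–50× parameter ranges,
- the in-silico experiments: mechanism fold-change scans with threshold
  detection, two-dimensional TSP1/mechanism surfaces, CRAC-inhibition
  studies, and therapy simulations (TSP1 inhibition, CD47 depletion),
- a synthetic-data generator for the parameterization panels, used for
  fitting and parameter-recovery studies.

The downstream parameter file shipped with the package
(`inst/extdata/params_calibrated_synthetic.csv`) is a calibrated,
synthetic parameter set: the supplementary parameter table of the
published model was not available, so the constants were re-fitted
against the published anchor values (recycling rates, base degradation rate, CD47
density, CRAC amplitude and Hill exponent, calcium amplitude, ERK switch
dose, receptor decay fractions). Figure-level thresholds are therefore
reproduced approximately; see the methods vignette for which ones and
how closely.

## Worked example

```r
library(vegfsig)

model <- vegf_model()            # parses the ruleset, generates the network
model
#> <vegf_model> 558 species, 4347 directed reactions, 93 parameters

# 50 ng/ml VEGF for 30 min; trajectory of observables and module states
tr <- run_protocol(model, vegf_protocol(50, duration = 30, dt = 1))
round(trajectory_metrics(tr), 3)
#>    max_pR2  pR2_10min     max_Ca        dCa   max_pERK pERK_10min
#>      0.471      0.280      0.362      0.262      0.615      0.613

# TSP1 enhanced-degradation fold scan (2 nM TSP1, then VEGF)
sc <- scan_fold(model, "degradation", folds = c(1, 5, 20, 80))
sc[, c("fold", "max_pR2", "max_pERK")]
#> # A tibble: 4 × 3
#>    fold max_pR2 max_pERK
#>   <dbl>   <dbl>    <dbl>
#> 1     1  0.474     0.615
#> 2     5  0.333     0.600
#> 3    20  0.184     0.467
#> 4    80  0.0735    0.140
```

`max_pR2` is peak phosphorylated VEGFR2 as a fraction of the time-zero
receptor total; `max_Ca`/`dCa` are peak cytosolic calcium and its rise
over the 0.1 µM baseline (µM); `max_pERK` is peak active ERK1/2 (µM, of
a 1 µM total). In the scan, increasing the degradation rate of
TSP1-engaged receptor complexes progressively suppresses receptor
phosphorylation and, past a threshold, ERK1/2 activation.

## Command line

A thin CLI over the same functions is installed at
`inst/cli/vegfsig`:

```sh
inst/cli/vegfsig generate-network --out results/net
inst/cli/vegfsig simulate --vegf 50 --duration 60 --out results/traj.csv
inst/cli/vegfsig scan --mechanism degradation --out results/scan.csv
inst/cli/vegfsig export-sbml --out results/model.xml
```

Every invocation writes a `.runlog.json` with the subcommand, options,
seed, and a configuration hash.
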