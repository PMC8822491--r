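# autoxkin

Kinetics of antioxidant-inhibited lipid peroxidation in micelles and
liposomes: a mechanistic simulator of oxygen-uptake traces plus the
inference pipeline that turns such traces into the standard kinetic
summary — induction periods, stoichiometric factors, inhibition rate
constants, kinetic chain lengths, and antioxidant synergy metrics.

## The problem and who it is for

Chain-breaking antioxidant activity in membrane-mimetic systems is
measured by following O₂ consumption during azo-initiated peroxidation of
methyl linoleate (MeLin) dispersed in Triton X-100 micelles or DMPC
liposomes. Injecting a phenolic antioxidant produces an induction period
τ, after which the chain reaction resumes. The kinetic workhorses are

- the induction-period relation **τ = n [ArOH]₀ / Rᵢ**, which, once Rᵢ is
  calibrated with a reference antioxidant of known stoichiometry (PMHC,
  the α-tocopherol analogue, n = 2), yields the stoichiometric factor n —
  the number of peroxyl radicals trapped per antioxidant molecule;
- the integrated inhibited-rate law
  **Δ[O₂]ₜ = −(k_p [LH]/k_inh) · ln(1 − t/τ)**, whose slope against
  −ln(1 − t/τ) gives the inhibition rate constant k_inh;
- the kinetic chain length **ν_inh = R_inh / Rᵢ** and the slow-down
  factor R_ox/R_inh, which separate genuine inhibition from mere
  retardation;
- the mixture relation **n_co = Rᵢ (τ_mix − τ_ref)/[co]** for
  co-antioxidant stoichiometry and hyper-additive (synergistic)
  inhibition.

The package is for kineticists who want to (a) re-derive every quantity of
a published inhibition table that follows from the printed induction
periods, (b) simulate the full reaction network — including phenoxyl
coupling to trapping-competent dimers (the resveratrol mechanism, n > 2)
and co-antioxidant regeneration (tocopherol recycling) — and (c) validate
trace-analysis code against synthetic Clark-electrode data with known
ground truth.

## Worked example

```r
library(autoxkin)

# 1. Desk re-derivation of published table quantities
head(desk_derivations(), 3)
#>   quantity   medium pH value printed
#> 1    n_RSV liposome  6  5.59     5.6
#> 2    n_RSV  micelle  6  4.78     4.9
#> 3    n_RSV liposome  7  3.44     3.4

# 2. Simulate a PMHC run with the experimental protocol and analyse it
sys <- liposome_system(pH_label = 6, R_i = 2.3e-9,
                       antioxidants = list(antioxidant("PMHC", 1e-6, 7.9e3)))
tr <- generate_trace(sys, noise = noise_model(sigma = 0.2e-6, seed = 1),
                     t_end = 4000)
tr
#> <o2_trace> 801 points, t = [0, 4000] s, uptake max 0.0008132 M, injection at 908.25 s
#>   medium=liposome, pH=6, R_i=2.3e-09, LH0=0.00274, k_p=41, O2_0=0.001, ...
#>   compounds: PMHC (1e-06 M)

estimate_tau(tr, seed = 1)
#> <tau_fit> tau = 505.3 s (sd 5.58), slopes 8.98e-08 -> 1.36e-07 M/s
```

The first block reproduces the published stoichiometric factors from
printed induction periods alone (value vs printed column). The second
simulates the protocol — antioxidant injected after 10% O₂ depletion at
908 s — and recovers an induction period of 505 s with a bootstrap SD of
about 6 s; the induction-phase and post-induction uptake rates
(0.09 → 0.14 µM/s) feed the slow-down classification, and
`estimate_kinh()`/`analyze_experiment()` complete the per-run metrics row.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write their
tables under `results/`:

1. `01_desk_tables.R` — re-derives every desk-derivable table quantity
   (stoichiometric factors, co-antioxidant stoichiometries, kinetic chain
   lengths, additivity sums) and reports the deviation from print.
2. `02_generate_benchmark.R` — generates the 50-trace synthetic benchmark
   (2 media × 5 pH × 5 settings, 1 µM loadings, σ = 0.2 µM noise) with its
   ground-truth table.
3. `03_recovery.R` — reads the traces back from disk, runs the complete
   inference pipeline, and scores parameter recovery against the truth.
4. `04_synergy.R` — demonstrates mechanistic co-antioxidant synergy:
   additive induction periods without regeneration, hyper-additive ones
   when regeneration outruns phenoxyl self-decay (k_r ≥ 2k_TO).

The methods vignette
(`vignettes/inhibited-autoxidation-kinetics.Rmd`) documents the model,
the estimator design, parameter provenance, and the limits of what the
synthetic benchmark can certify.

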