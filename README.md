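# recoverymics

Quantifying the balance of neutral (stochastic) and selective
(deterministic) processes in the recovery of microbial communities after
an environmental disturbance — built around the design of a yellow-perch
cadmium-exposure experiment: three exposure regimes (control, constant
CC, variable CV), three habitats (tank water, skin, gut), eight tanks,
and seven timepoints spanning an exposure phase (T0–T3) and a recovery
phase (TR1–T5).

It is written for microbial ecologists who have an OTU count table, a
sample design, and a rooted phylogeny, and who want to ask: did the
disturbed communities return to the control configuration, and was the
reassembly neutral or selective?

## What it computes

**Sloan neutral community model.** Under neutral assembly the local
relative abundance of a taxon with metacommunity abundance *p* follows
Beta(*Nmp*, *Nm*(1−*p*)), so its occurrence frequency at detection limit
*d* reads is

&nbsp;&nbsp;&nbsp;&nbsp;*F*(*p*; *m*, *N*, *d*) = 1 − *I*<sub>d/N</sub>(*Nmp*, *Nm*(1−*p*)),

with *I* the regularized incomplete beta function, *N* the reads per
sample, and *m* the migration (immigration) rate — the model's single
fitted parameter. `fit_ncm()` estimates *m* by bounded nonlinear least
squares of observed against predicted occurrence, reports *R*² (with
*R*² > 0.5 read as support for predominant neutrality), and classifies
every OTU against the 95% Wilson band around its prediction: `neutral`,
`above` (over-occurring, e.g. host-selected), or `below`
(under-occurring, e.g. patchily dominant host specialists).

**Beta diversity and permutation tests.** Generalized UniFrac
(`gunifrac()`, abundance exponent α, default 0.5) plus one-factor
PERMANOVA, multivariate dispersion homogeneity, and MRPP
(`permanova()`, `betadisper()`, `mrpp()`), all with the (1+b)/(1+B)
permutation convention, seeded streams, optional exact enumeration at
small n, and Benjamini–Hochberg control across pairwise contrasts.

**Alpha diversity, differential abundance, networks.** Richness,
Shannon, effective numbers and Pielou evenness; per-taxon rank tests
with BH control; Spearman sample-correlation networks with FDR edge
filtering, betweenness and eigenvector centrality
(`build_network()`, `betweenness_centrality()`,
`eigenvector_centrality()`).

**A ground-truth simulator.** `simulate_experiment()` +
`perch_recovery_preset()` generate the full factorial design by an
explicit Moran (death–replacement–immigration) process with per-taxon
selection: cadmium modeled as suppression of susceptible resident taxa
on a per-regime severity schedule, and Mycoplasma-like host-selected
strains that colonize fish patchily and never fit the neutral model.
Every downstream claim in the package is validated against this known
truth.

**The verdict.** `run_full_analysis()` orchestrates everything into
report tables (divergence grid, neutral-fraction summary, centrality
shifts, trajectories) and `recovery_trajectory()` flags each treatment
`recovered` when its terminal PERMANOVA contrast against control is
non-significant after BH adjustment.

## Worked example

Simulate 200 neutral communities at migration rate 0.3 and fit the
model back:

```r
library(recoverymics)

pool <- make_source_pool(300, "lognormal", list(sigma = 2), seed = 11)
cfg  <- sim_config(S = 300, n_samples = 200, N_local = 1000, m = 0.3,
                   depth = 2000, mode = "stationary", seed = 5)
tab  <- simulate_neutral_community(pool, cfg)
tab
#> count_table: 200 samples x 300 OTUs, total reads 4e+05

fit_ncm(tab)
#> Sloan neutral community model fit
#>   m = 0.2935  N = 2000.0  R2 = 0.990  (200 samples, 295 OTUs fitted, 5 never detected)
#>   classes: 237 neutral / 42 above / 16 below
```

The fitted migration rate recovers the simulated 0.3, the high *R*²
supports neutrality, and ~80% of OTUs sit inside the 95% band — the
baseline against which treated communities are compared: selection
pushes taxa out of the band and drags the neutral percentage down.

The `analysis/` directory holds the numbered workflow over the full
factorial design:

```sh
Rscript analysis/01_simulate.R       # synthetic study + ground truth -> results/data
Rscript analysis/02_neutral_model.R  # per-stratum NCM fits + neutral fractions
Rscript analysis/03_diversity_beta.R # alpha diversity + divergence grid
Rscript analysis/04_networks.R       # per-cell networks + centrality shifts
Rscript analysis/05_recovery.R       # trajectories + terminal recovery verdicts
```

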