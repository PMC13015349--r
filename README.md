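# spfit

Lineage-barcode fitness inference and stationary-phase performance
decomposition for experimental evolution in serial batch culture.

## The problem

When microbes are evolved by serial transfer, the time between
transfers sets how long each growth cycle dwells in stationary phase.
Barcode lineage tracking makes the consequences measurable: sequencing
a barcoded pool through several growth cycles gives every lineage a
frequency trajectory, and the trajectory's slope relative to the pool
is the lineage's fitness. By assaying the same pool of evolved clones
in regimes that differ only in cycle length — 2, 4, 6, 8 or 10 days
between transfers in glycerol/ethanol medium, 1–5 days in glucose —
the fitness a clone gains from each *extra interval* of stationary
phase can be isolated, and questions like "does doing well in early
stationary phase cost you later?" become regression problems.

`spfit` is for researchers running (or simulating) such experiments.
It provides:

* a **synthetic-data generator**: phase-structured lineage phenotypes
  with a configurable early/late stationary-phase trade-off,
  growth-cycle population dynamics with transfer bottlenecks and
  Dirichlet-multinomial sequencing noise, beneficial-mutation supply,
  FASTQ read emission, and dual-index hopping on a primer grid with
  deliberately empty combinations;
* **barcode counting**: whitelist perfect-match extraction at fixed
  read coordinates, UMI dereplication, Shannon-diversity trajectories;
* **index-hopping correction**: rate estimation from empty index
  combinations and per-barcode count correction;
* **fitness inference**: `lineage_fitness()`, a self-consistent
  estimator of per-cycle lineage fitness relative to the population
  mean, with the usual modelling methods (`coef`, `summary`,
  `predict`, `simulate`, `residuals`, `plot`);
* **performance decomposition**: per-hour performance within
  growth-cycle intervals with full error propagation, replicate
  averaging and ancestor-relative changes;
* **trade-off and parallelism statistics**: Pearson trade-off tests
  with a shared-fitness collision guard, variant verification, per-gene
  and per-pathway clone counts, and clone-percentage arithmetic.

## The model

Fitness is defined per growth cycle: the expected log fold change of
lineage *i* over an interval of Δc cycles is Δc·(s\_i − s̄(t)), with
s̄(t) the population mean fitness. The estimator solves

    s_i  = Σ_t w_it [ log(f_i(t+1)/f_i(t))/Δc_t + s̄(t) ] / Σ_t w_it
    s̄(t) = log Σ_i f_i(t) exp(s_i)

self-consistently, with w\_it the harmonic mean of endpoint read
counts. Only relative fitness is identified; the gauge is pinned to a
reference set (marked neutrals or the aggregated ancestor). Performance
in a growth-cycle interval is then

    performance = (fitness_A − fitness_B) / d      [hour⁻¹]

for regimes A, B separated by d hours of cycle length, with errors
√(e_A² + e_B²)/d, replicate-mean errors (1/n)√Σe², and changes in
performance computed against the ancestor.

## Worked example

Simulate 200 adaptive clones (plus neutral spike-ins and ancestors)
whose late stationary-phase effects are coupled to their early effects
with slope −0.5, run the five Gly/Eth assay regimes in triplicate,
decompose fitness into interval performances, and test the early/late
trade-off:

```r
library(spfit)
ph  <- sample_phenotypes(220, tradeoff_config(fraction_adaptive = 200/220), seed = 1)
pan <- simulate_fitness_panel(
  ph, assay_regimes()[c("GE_2day", "GE_4day", "GE_6day", "GE_8day", "GE_10day")],
  seed = 1)
perf <- performance_table(pan$fitness)
adaptive <- ph$lineage_id[ph$is_adaptive]
tradeoff(perf[perf$clone %in% adaptive, ], "GE_earliest_d2_4", "GE_late_d6_10")
```

```
<tradeoff> GE_late_d6_10 vs GE_earliest_d2_4 (all clones): n = 200
  Pearson r = -0.682 (R2 = 0.465), slope = -0.512, p = 1.02e-28
```

The regression slope recovers the generative coupling (−0.5): clones
that gained the most performance in days 2–4 of stationary phase lost
the most in days 6–10. The correlation strength matches the
generator's theoretical r ≈ −0.7, and the metric pair was chosen by
the collision guard — earliest (2–4) vs late (6–10) share no
underlying fitness assay, so the correlation cannot be an artifact of
shared measurement noise.

A thin command-line front end over the same functions is in
`inst/cli/spfit-cli.R` (subcommands `count`, `diversity`,
`hop-estimate`, `hop-correct`, `fit`, `perf`).

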