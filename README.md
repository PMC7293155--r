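# soclearn

Evolution of social learning in density-regulated, age-structured
populations.

## What this package is for

Most models of the evolution of social learning ignore demography: who is
alive, how old they are, and what keeps the population at a finite size.
Yet the way a population is regulated — whether crowding suppresses
*births* or *survival* — reshapes the age structure, the timing of
reproduction, and therefore the value of copying others versus exploring
for oneself. `soclearn` is for modellers in cultural evolution, life-history
theory and evolutionary ecology who want to study that interaction with a
controlled, reproducible tool.

The package has two layers:

1. **Analytic demography.** A two-age-class (juvenile/adult) discrete-time
   model with baseline per-step survival `s` and per-adult birth
   probability `b`, under one of two pure regulation regimes. Writing
   `N_t` for the total population,

   - *fertility regulation*: `N0' = N1 · b·e^(−δ·N_t)`, `N1' = (N0+N1)·s`,
     with equilibrium `N̂ = log(b·s/(1−s))/δ`;
   - *mortality regulation*: `N0' = N1 · b`, `N1' = (N0+N1)·s·e^(−γ·N_t)`,
     with equilibrium `N̂ = log(s·(1+b))/γ`.

   Lifetimes are geometric, so an expected lifespan `L̂` corresponds to
   `s = 1 − 1/L̂`. Given targets `(N̂, L̂, δ)` the package derives the
   unique matched parameter set `(s, b, γ)` such that **both** regimes
   share identical baseline vital rates and an identical equilibrium size —
   the controlled-comparison device that lets you attribute differences to
   the regulation mode alone.

2. **Individual-based simulator.** Agents carry a heritable learning
   propensity `ξ ∈ [0,1]`. Each step runs birth-and-mutation (offspring
   `ξ` perturbed by `Normal(0, μ_ξ)`, clamped), learning (juveniles learn
   individually with probability `ξ` — inventing the currently adaptive
   behaviour with probability `w` at a once-only survival cost `c` — or
   copy a random adult), survival-and-ageing, and environmental
   stochasticity (with probability `u` the environment changes and every
   individual becomes non-adapted). Adapted individuals survive with
   probability `σ·s` and reproduce with probability `β·b` (`σ, β > 1`).

On top sit observables (adaptation by age class, effective vital rates,
switch-aligned birth-timing curves), a factorial sweep driver with
seed-paired replicates, and a small CLI.

## Worked example

Derive a matched parameter set for a long-lived target demography and run
one simulation under mortality regulation:

```r
library(soclearn)

derive_matched_parameters(n_hat = 500, lifespan = 7.5, delta = 1/1000)
#> Matched demographic parameters
#>   target equilibrium size N^ : 500
#>   expected lifespan L^       : 7.5 steps
#>   baseline survival s        : 0.866667
#>   baseline fertility b       : 0.253649
#>   fertility regulation delta : 0.001
#>   mortality regulation gamma : 0.000165916

cfg <- sim_config(n_hat = 500, lifespan = 7.5, delta = 1/1000,
                  mode = "mortality", u = 0.01, w = 0.9, cost = 0.05,
                  seed = 42)
fit <- run_sim(cfg)
summary(fit)
#> Run summary (5000 post-burn-in steps)
#>   mean xi            : 0.1254
#>   mean census        : 1075.5322
#>   mean prop. adapted : 0.8357
#>   mean eff. fertility: 0.2750
#>   mean eff. survival : 0.7845
#>   environment switches: 72
```

Reading the output: over the last 5000 of 7000 steps the population evolved
a low reliance on individual learning (mean `ξ ≈ 0.13` — mostly copying),
84% of individuals carried the adaptive behaviour, and the census settled
around 1076 — above the neutral `N̂ = 500`, because adaptation raises the
vital rates. The realized survival frequency (0.78) sits *below* the
baseline `s = 0.867`: mortality regulation compresses realized lifespans.
Running the same configuration with `mode = "fertility"` yields a much
higher mean `ξ`, the package's central contrast. `plot(fit)` shows the
census, adaptation, `ξ` and effective-vital-rate trajectories with the
environment switches marked.

Sweeps follow the same pattern programmatically
(`build_grid(grid_spec(...))`, `run_sweep()`, `contrast()`), or from the
shell via the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "soclearn", package = "soclearn"))') \
  derive --nhat 500 --lifespan 7.5 --delta 0.001 --json
```

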