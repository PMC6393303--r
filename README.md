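# clampkin

Pre-steady-state kinetics and equilibrium binding analysis for
clamp-stimulated DNA polymerase. The package targets the experimental logic
used to show that the PCNA sliding clamp does more than confer processivity
on DNA polymerase δ — it accelerates the catalytic step itself: quench-flow
burst kinetics of single-nucleotide incorporation, processive run-off
extension under a heparin trap, and tight-binding fluorescence titrations of
polymerase on template/primer DNA. It is written for enzyme kineticists who
want to simulate these assays, fit them, and validate every fitting stage by
seeded parameter recovery, since the underlying raw traces (gel images,
fluorimeter output) are typically not published numerically.

## What it computes

**Burst-phase kinetics.** Quench-flow time courses of fractional primer
extension are fit to

    [Product](t) = A (1 − e^(−k_fast t)) + (1 − A)(1 − e^(−k_slow t))

where the fast phase reports catalysis by the preformed polymerase·DNA
complex (rate `k_fast`, amplitude `A` = fraction of DNA pre-bound in a
productive complex) and the slow phase carries polymerase binding followed
by catalysis. At saturating enzyme the one-phase form `1 − e^(−kt)` applies.
Fits are bounded nonlinear least squares (`A ∈ [0,1]`, rates ≥ 0), with an
option to hold `k_fast` at its saturating-enzyme value and read bound-DNA
fractions out of subsaturating curves.

**Mechanism simulation.** The minimal four-step incorporation scheme —
DNA·Pol association (k1), dNTP binding (k2), an open→closed conformational
change (k3), chemistry (k4), each reversible — is integrated as a
mass-action ODE system (stiff-capable `lsoda`, rtol 1e-8), with dNTP treated
as constant by default (assays run at saturating 250 μM).

**Processive extension.** An n-step chain (per-step rate `k_step`,
dissociation `k_off`, heparin trap = absorbing dissociated state) with the
censored-Poisson/Erlang closed forms, an independent master-equation ODE
route, and a seeded Gillespie sampler as stochastic oracle. Primer-band
disappearance decays at the total hazard `k_step + k_off`, which is what a
single-exponential fit of `1 − primer fraction` recovers.

**Binding titrations.** Sequential two-site equilibrium
(D + E ⇌ DE, DE + E ⇌ DE₂; macroscopic K1, K2) solved exactly with ligand
depletion; anisotropy `r = (I_VV − G·I_VH)/(I_VV + 2G·I_VH)` and relative
total intensity predicted per species; stoichiometry read off tight-binding
titrations by continuous piecewise-linear (segmented) regression — the final
breakpoint sits at `stoichiometry × [DNA]`.

## Worked example

Simulate one noisy saturating-enzyme burst experiment and refit it:

```r
library(clampkin)
cond <- study_conditions("burst_30C")       # truth: A = 1, k = 40 /s
cfg  <- generator_config("burst", cond$truth, cond$grid, cond$sigma,
                         replicates = 20, seed = 1)
recover_parameters(cfg, n_phases = 1)
#> recovery over 20 replicates (truth = 40)
#>   median estimate      : 40.07
#>   IQR of estimates     : 1.636
#>   median |rel. error|  : 2.04%
```

The median refit rate (40.07 s⁻¹) recovers the generating burst rate of
40 s⁻¹ to ~2% under 0.02 absolute Gaussian noise on 25 log-spaced quench
times — the precision the protocol supports.

Read binding stoichiometry off a tight-binding titration (50 nM DNA):

```r
cond  <- study_conditions("titration")
curve <- make_titration(generator_config("titration", cond$truth,
                                         cond$grid, cond$sigma,
                                         replicates = 1, seed = 51))
segmented_fit(curve, 2, signal = "intensity")
#> segmented fit (2 segments, intensity channel)
#>   breakpoints (nM): 100.59
#>   stoichiometry  : 2.012
#>   RSS            : ...
```

The breakpoint at ~100 nM enzyme against 50 nM DNA reads a 2:1
polymerase:DNA stoichiometry.

The numbered drivers under `analysis/` run the full workflow — mechanism
simulation, the 30 °C and 12 °C burst recovery panels, titration
stoichiometry at two DNA concentrations, and processive-extension product
distributions — and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_mechanism.R
Rscript analysis/02_burst_recovery.R --seed 1
Rscript analysis/03_binding_stoichiometry.R --seed 1
Rscript analysis/04_processive_extension.R --seed 1
```

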