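---
title: "Models and methods: burst kinetics, processive extension, and tight-binding titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampkin)
```

This vignette is the package's account of the science it implements: the
kinetic and binding models, the estimators, the synthetic-data conventions
behind every recovery experiment, and the numerical and design choices that
were genuinely open.

## The experimental problem

A replicative polymerase held on DNA by a sliding clamp can be faster for
two distinct reasons: it stays on longer (processivity), or each catalytic
cycle is intrinsically faster. Distinguishing the two requires
pre-steady-state (burst) kinetics on preformed complexes, single processive
cycles isolated with a polymerase trap, and — as a precondition for
interpreting any burst amplitude — knowing how much polymerase it takes to
saturate the DNA. The package implements all three layers as simulators
plus estimators, so each analysis can be validated end-to-end on data with
known ground truth.

## The four-step incorporation scheme

Single-nucleotide incorporation is modelled as

$$\mathrm{DNA}_n + \mathrm{Pol}
  \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}}
  \mathrm{DNA}_n{\cdot}\mathrm{Pol}
  \underset{k_{-2}}{\overset{k_2[\mathrm{dNTP}]}{\rightleftharpoons}}
  \mathrm{DNA}_n{\cdot}\mathrm{Pol}{\cdot}\mathrm{dNTP}
  \underset{k_{-3}}{\overset{k_3}{\rightleftharpoons}}
  \mathrm{DNA}_n{\cdot}\mathrm{Pol}^*{\cdot}\mathrm{dNTP}
  \underset{k_{-4}}{\overset{k_4}{\rightleftharpoons}}
  \mathrm{DNA}_{n+1}{\cdot}\mathrm{Pol}^*{\cdot}\mathrm{PPi}$$

integrated as mass-action ODEs (`simulate_scheme()`). Units are fixed
package-wide: seconds, nM, s^-1, and nM^-1 s^-1 for the two second-order
steps. Choices worth stating:

* **Integrator.** `deSolve::lsoda` with rtol 1e-8, atol 1e-12. The rate
  constants span second-order binding through ~500 s^-1 chemistry, so a
  stiff-capable adaptive method is required; total DNA and polymerase are
  conserved to better than 1e-9 relative along every trajectory (tested).
* **dNTP is pseudo-first-order by default.** The assays run at 250 μM dNTP
  against ≤ 500 nM enzyme, so depletion is negligible; `deplete_dntp =
  TRUE` enables explicit consumption.
* **One catalytic unit.** Although two polymerase molecules occupy the DNA
  at saturation, the kinetics operate on the saturated complex as a single
  catalytic unit; the second molecule is given no kinetic role because the
  burst experiments only interrogate the saturated regime.
* **Temperature is a label.** 30 °C and 12 °C parameter sets are distinct
  truths, not an Arrhenius model — no temperature-dependence data exist to
  calibrate one.

With enzyme and dNTP pre-bound and both forward rates equal, the scheme
has the two-step Erlang closed form
$P(t) = 1 - (1 + kt)e^{-kt}$, which the ODE reproduces to 1e-6 — the
analytic anchor for the integrator. When $k_3$ and $k_4$ are well
separated, the fitted single-exponential rate of product formation
approaches the slower step; at 10-fold separation it sits measurably below
it (a composite $\approx k_3 k_4/(k_3+k_4)$), which is worth remembering
when reading "the observed rate is $k_3$" claims.

## Burst-phase fitting

`fit_exponential()` fits

$$[\mathrm{Product}](t) = A\,(1 - e^{-k_\mathrm{fast}t})
  + (1-A)\,(1 - e^{-k_\mathrm{slow}t})$$

by bounded nonlinear least squares (`minpack.lm::nlsLM`; $A \in [0,1]$,
rates ≥ 0). Design choices:

* **Starting values.** $k_\mathrm{fast}$ starts at the reciprocal of the
  time to half-maximal signal and $A$ at the signal near three times that
  time — robust across the three decades (6–500 s^-1) these assays span.
* **Phase labelling and ties.** Phases are relabelled after fitting so
  $k_\mathrm{fast} \ge k_\mathrm{slow}$ always holds. If the two free
  phases converge to within a factor of 3 — or the two-phase Jacobian is
  singular because the data carry no second phase — the one-phase fit is
  reported with `multiphase_unresolved = TRUE` rather than pretending two
  phases were resolved.
* **Weighting.** Unweighted by default (replicate errors are rarely
  published); a per-point `sigma` column switches to $1/\sigma^2$ weights.
* **Amplitude as bound fraction.** With $k_\mathrm{fast}$ fixed from the
  saturating-enzyme condition, the refit amplitude of a subsaturating
  curve estimates the fraction of DNA pre-bound in a productive complex
  (`amplitude_to_bound_fraction()`); round-trip tests generate amplitudes
  from the two-site binding model and recover them within 0.05 at noise
  sd 0.02.

## The processive-extension chain

Run-off extension of an n-nucleotide template run (n = 20 in the standard
conditions) is a sequential chain: at each position the polymerase
incorporates at $k_\mathrm{step}$ (translocation folded in — the
observables cannot separate it) or dissociates at $k_\mathrm{off}$. Under
a heparin trap dissociated polymerase never rebinds, so each molecule
stalls at its current length. With $r = k_\mathrm{step} + k_\mathrm{off}$
the closed forms are

* bound at length $j<n$: $e^{-rt}(k_\mathrm{step}t)^j/j!$,
* stalled at $j$:
  $(k_\mathrm{off}/r)(k_\mathrm{step}/r)^j\,P(\mathrm{Erlang}_{j+1}\le rt)$,
* full length: $(k_\mathrm{step}/r)^n\,P(\mathrm{Erlang}_n \le rt)$,

reducing to the censored Poisson distribution at $k_\mathrm{off}=0$.
`chain_occupancy()` uses these; an independent master-equation ODE route
(`chain_occupancy_ode()`, also handling rebinding when the trap is off)
and a seeded Gillespie sampler (`gillespie_chain()`) cross-check it — three
routes to the same distribution, compared in the tests to 1e-8 (analytic
vs ODE) and within Monte-Carlo error (stochastic).

Two consequences the analyses rely on:

* **Primer disappearance.** The unextended-primer band decays at the total
  hazard $r$, independent of processivity. `fit_primer_disappearance()`
  fits $A(1-e^{-kt})$ with free amplitude: at $k_\mathrm{off}=0$ this is
  the plain single exponential and $k = k_\mathrm{step}$; with
  dissociation the band saturates at $k_\mathrm{off}/r$ and the fit
  returns exactly $r$ — i.e. the recovered "catalytic rate" is biased up
  by $k_\mathrm{off}$ when dissociation competes. The bias is a property
  of the observable, not the estimator, and is why the recovered rate is
  reported as a *minimal* catalytic rate.
* **Modal product length.** At $k_\mathrm{off}=0$ the mode is
  $\lfloor k_\mathrm{step}t \rfloor$; at 10 ms a ~430 s^-1 chain peaks at
  4 nt while a ~150 s^-1 chain peaks at 1–2 nt, which is the operational
  signature of a catalytic-rate defect visible at every time point. At
  integer $k_\mathrm{step}t$ the Poisson has an exact two-way tie;
  `modal_length()` breaks ties toward the shorter product and flags them.
  Run-off mass is censored at the full-length product, which therefore
  accumulates the upper tail.

## Two-site binding and stoichiometry

Titrations are modelled with macroscopic sequential constants
($D+E \rightleftharpoons DE$, $K_1$; $DE+E \rightleftharpoons DE_2$,
$K_2$) because equilibrium data cannot distinguish independent-site
binding from DNA-induced dimerization; the macroscopic description covers
both. The free-enzyme concentration is the root of the cubic mass balance,
solved by safeguarded bisection to near machine precision (and checked
against a brute-force bisection oracle in the tests). No attempt is made
to *estimate* $K_1$, $K_2$ from tight-binding curves — in the
stoichiometric regime they are unidentifiable, which is precisely why the
readout is a breakpoint, not a binding constant.

Signals: each species carries an anisotropy ($r_\mathrm{free}, r_1, r_2$)
and a relative fluorescence yield ($1, q_1, q_2$). Observed anisotropy is
the intensity-weighted species average (physically correct when binding
quenches the fluorophore); relative total intensity is the yield-weighted
species average. A mole-fraction weighting mode exists for comparison.

**Why the stoichiometry readout uses the intensity channel.** Relative
intensity is linear in species concentrations, so in the tight limit it is
exactly piecewise linear in total enzyme with its final corner at
$2\times[\mathrm{DNA}]$. Intensity-weighted anisotropy is a *ratio* of
concentration combinations: under quenching it bows within segments, and a
two-segment fit of the bowed curve reads the intersection high (≈2.13 for
a true 2.0 under the default 40% total quench — the analysis drivers print
both channels so the bias is visible). `segmented_fit()` therefore defaults
to anisotropy only for generic curves; the stoichiometry recovery path
(`recover_parameters(kind = "titration")`) fits the intensity channel.

Segmented fitting itself: continuous piecewise-linear least squares with
candidate breakpoints at the midpoints between consecutive titration
points (resolution-matched), followed by continuous refinement within the
bracketing interval; a breakpoint is *resolved* only if it is interior and
cuts the residual sum of squares by more than 20% over one fewer segment —
exactly linear data come back flagged `unresolved`. Softer corners (as
$K_1, K_2$ rise toward the concentration scale, e.g. at higher salt) are
reproduced as monotonically growing relative residuals of the two-segment
fit.

A detail worth knowing about the chemistry: a clean 1:1 plateau ("all DE")
requires $K_2/K_1 \gg 1$, not merely both constants tight. With
$K_1 = K_2$ the 1:1 point disproportionates into equal thirds of
$D$, $DE$ and $DE_2$ — a classic property of equal macroscopic constants.

## Synthetic data: what it emulates, and what it does not

All recovery experiments run on data from `make_burst_timecourse()`,
`make_titration()` and `make_gel_lanes()`, pure functions of
(truth, grid, sigma, seed). Conventions:

* additive Gaussian noise on fraction-extended and
  anisotropy/intensity observables; multiplicative log-normal noise on
  individual band intensities — matching quantified-gel and fluorimeter
  error character. The true experimental noise magnitudes are unpublished,
  so the defaults (sd 0.02 on fractions, 0.002 on anisotropy, log-sd 0.05
  on bands) are stated conventions, repeated in every recovery report.
* default grids: 25 log-spaced quench times, 1 ms–2 s (30 °C panel) or
  2 ms–1 s (12 °C panel); 12 quench times 1–100 ms for lane series;
  16-point titration grids 0–400 nM.
* fractions are clipped to [-0.05, 1.05], the window real quantification
  produces.

The canonical truths live in `study_conditions()`: 40 s^-1 saturating
burst; the 12 °C panel at 183, 55 and 6 s^-1; the 20-step chain at
350 s^-1; the tight titration at 50 nM DNA. Two generator parameters are
not fixed by any published number and were set once: the slow phase of the
12 °C clamp conditions (5 s^-1, a plausible binding-limited phase;
amplitude 0.9) — the no-clamp condition uses the stated amplitude 0.5 and
slow phase 1.5 s^-1 — and the titration signal levels
($r$ = 0.05/0.125/0.20, $q$ = 1/0.8/0.6, FAM-typical).

What passing recovery tests shows: the estimators are unbiased and
precise *under these noise and sampling conventions*. What they cannot
show: robustness to gel-quantification artefacts (band overlap, smearing,
background subtraction), instrument drift in titrations, or model
misspecification such as sequence-dependent incorporation rates or
exonuclease activity — all outside the generator's vocabulary (the
modelled enzyme is exonuclease-dead by construction).

## Problem sizes and precision of the standard runs

Recovery runs use 20 replicates (100 in the rate-range property test);
Gillespie oracles use 2×10^4–5×10^4 molecules. One practical caveat
surfaced by the panel recoveries: for the weakly separated no-clamp
condition (biphasic, $k_\mathrm{fast}/k_\mathrm{slow} = 4$, amplitude
0.5), single-replicate estimates of $k_\mathrm{fast}$ scatter with ~25%
standard deviation, so a 20-replicate median still moves ±8% between seed
sets even though the estimator is unbiased (checked at 100 replicates).
Medians of well-separated conditions (40, 183, 350 s^-1) are stable to
1–3%.

## Known limitations

* The chain folds translocation into $k_\mathrm{step}$; if translocation
  were separately rate-limiting the per-step waiting time would be
  Erlang-2 rather than exponential, sharpening the length distributions.
* $k_\mathrm{off}$ under trap conditions is a free parameter — nothing in
  the emulated observables pins it, so chain simulations expose it rather
  than assume a value.
* No global multi-curve fitting across enzyme concentrations (the
  amplitude analysis deliberately conditions on the saturating-enzyme
  fast rate instead), and no estimation of absolute binding constants
  from tight-binding curves.
* Gel lanes enter as band-intensity tables; image quantification is out of
  scope.
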