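---
title: "The craswitch model: single-cell metabolism, expression noise, and selection at substrate switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The craswitch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craswitch)
```

## The biological problem

*E. coli* growing on glucose runs glycolysis; growing on acetate requires the
reverse flux, gluconeogenesis. The switch between the two regimes is gated by
the transcription factor Cra: fructose-1,6-bisphosphate (fbp), a proxy for
glycolytic flux, inhibits Cra; active Cra induces the acetate assimilation
machinery. When the carbon source changes from glucose to acetate, a cell
either manages to ignite the gluconeogenic circuit — and grows — or it stays
locked in a nongrowing state. Because the decision depends on the number of
Cra molecules a cell happens to carry, *noise* in Cra expression reshapes the
fraction of a population that resumes growth, and with it the severity of the
population bottleneck at every substrate switch. `craswitch` simulates this
system cell by cell and provides the evolutionary experiment designs built on
it: competitive fitness assays, bottleneck statistics, fitness landscapes
over Cra–fbp binding strengths, allele competitions and invasion/fixation
experiments.

## The single-cell model

Metabolism is condensed into four reactions, each catalysed by one enzyme
whose copy number is an explicit, stochastic integer:

* **Gi** — glucose incorporation, glucose → fbp (1:1),
* **Ai** — acetate incorporation, 2 acetate → 1 pep (one carbon lost as CO2),
* **Lg** — lower glycolysis, 2 pep → 1 fbp,
* **An** — anabolism, fbp → biomass with yield c = 0.0896 g per mmol fbp.

Each cell integrates, over every scheduler interval (default one minute),

$$\frac{d\,\mathrm{pep}}{dt} = \tfrac12 J_{Ai} - J_{Lg} - \mu\,\mathrm{pep},
\qquad
\frac{d\,\mathrm{fbp}}{dt} = J_{Gi} + \tfrac12 J_{Lg} - J_{An} - \mu\,\mathrm{fbp},
\qquad
\frac{dB}{dt} = \mu B,$$

with $\mu = c\,J_{An}$. Gi, Ai and Lg follow Michaelis–Menten kinetics in
their substrate; every rate is proportional to the catalysing enzyme's
concentration (copies per mass, normalised to 100 copies per newborn). An
follows a two-state MWC law, activated allosterically by pep:

$$J_{An} = V_{An}\,\phi_{An}\;
\frac{f\,(1+f)^{\,n-1}}{(1+f)^{\,n} + L/(1+\mathrm{pep}/K_{pep})^{\,m}},
\qquad f = \mathrm{fbp}/K_{fbp}.$$

We allow the pep-activation exponent $m$ to differ from the fbp cooperativity
$n$ (a heterotropic-activation generalisation of the symmetric MWC form;
defaults $n = 2$, $m = 3$). During calibration no parameter set with $m = n$
could satisfy all three structural requirements at once — monostable growth
on glucose, bistability on acetate across the allele range of Cra–fbp
dissociation constants (0.05–0.1 mmol/g), and a growing state reachable from
a single Ai expression burst — whereas decoupling the exponents makes the
corner of parameter space well-behaved.

Regulation enters through three algebraic layers evaluated per cell:
Hill repression of Cra by fbp
($\mathrm{Cra}_A = \mathrm{Cra}\,K^{n_{Cra}}/(\mathrm{fbp}^{n_{Cra}}+K^{n_{Cra}})$,
$n_{Cra}=2$), Michaelis–Menten occupancy of the Ai promoter by the active-Cra
*concentration* ($P_{bound} = (\mathrm{Cra}_A/B)/(\mathrm{Cra}_A/B +
K_{CraA,DNA})$), and a regulated transcription rate
$\alpha_{Ai} = \alpha_{on} P_{bound}$ (the unbound promoter is fully off).

## Stochastic expression

Proteins are produced in bursts: mRNAs arrive as a Poisson process with rate
$k_1 = \alpha\,(\mu B/B_0 + \gamma_p)$ and each mRNA yields a geometric
number of proteins on $\{0, 1, 2, \dots\}$ with mean $\beta$. The rate
couples transcription to growth so that the expected protein amount per unit
mass stays constant over the cell cycle (dilution is twice as fast just
before division, and so is production). The stationary copy-number
distribution of the continuous-dilution idealisation is negative binomial
with mean $\alpha\beta$ and variance $\alpha\beta(\beta+1)$; expression noise
is tuned through $\eta^2 = 1/\alpha$, $\beta = \bar{x}\,\eta^2$, which for a
mean of 100 Cra copies spans standard deviations of 14 ($\eta^2 = 10^{-2}$)
to 316 ($\eta^2 = 10$) molecules.

The geometric burst law on $\{0,1,\dots\}$ (success probability
$1/(1+\beta)$) is chosen deliberately: it is the unique geometric
parameterisation whose production/dilution balance is *exactly*
NB$(\alpha,\beta)$ with Fano factor $\beta + 1$. A shifted geometric on
$\{1,2,\dots\}$ with the same mean would give Fano factor $\beta$.

One subtlety is worth recording. In the explicit cell-cycle model —
production compensating dilution, division at doubled mass, binomial
partitioning — the stationary newborn copy-number variance solves
$V = \tfrac14\!\left(V + \alpha\beta(2\beta+1)\right) + \tfrac14\,(2\alpha\beta)$,
so the newborn squared coefficient of variation is

$$\mathrm{CV}^2 = \frac{2\beta + 3}{3\,\alpha\beta},$$

asymptotically **two thirds** of the negative-binomial value
$(\beta+1)/(\alpha\beta)$. The unit tests assert this exact law; the nominal
$\eta^2$ labels used throughout (0.01 … 10) should therefore be read as the
continuous-dilution parameterisation, with realised newborn noise about a
third lower. Division partitions every molecule independently to a daughter
with probability one half; active degradation (binomial survival with
probability $e^{-\gamma_p \Delta t}$) is available but off by default, as
most *E. coli* proteins are stable.

## Population and environment

The population lives in a virtual chemostat: fresh medium carrying either
10 mM glucose or 20 mM acetate flows in at dilution rate $D$, spent medium
and cells flow out at the same rate. Each one-minute step applies, in order:
(i) per-cell ODE integration plus the substrate balance (exact exponential
relaxation toward the influx concentration, minus the summed cellular
uptake converted to concentration by $\kappa$, the inverse culture volume);
(ii) stochastic protein production; (iii) random washout with survival
probability $e^{-D\Delta t}$; (iv) division of every cell that has doubled
its newborn mass $B_0 = 3\times10^{-13}$ g. All randomness flows through R's
RNG, so `set.seed()` replays any run bit for bit.

Schedules: constant substrate, a single glucose→acetate switch (default at
48 h), periodic alternation (default period 48 h), or random epochs with
exponentially distributed lengths. Runs can stop at a horizon, on extinction
or on allele fixation.

## The calibrated default parameter set

The kinetic constants of the four reactions are not fixed by first
principles here; the shipped defaults (`default_kinetics()`) are a
**calibration** with the following targets, in priority order:

1. the deterministic circuit (below) is bistable on 20 mM acetate for
   Cra–fbp dissociation constants 0.05–0.1 mmol/g and monostable growing on
   10 mM glucose, with the nongrowing state collapsing as binding weakens
   (gone by 0.125 mmol/g);
2. cells at the mean Cra copy number (100) sit near the switching threshold
   on acetate, so that Cra expression noise matters;
3. after a glucose→acetate switch, the population minimum and the recovery
   time are ordered across Cra noise levels $\eta^2 = 10^{-2}\dots10^{1}$
   (noisier populations suffer milder bottlenecks and recover faster), with
   a roughly 2:1 recovery-time ratio between the least and most noisy
   populations.

Choices worth explaining:

* **Dilution rate D = 0.08 h⁻¹.** The stochastic glucose→acetate switch is a
  race: a cell must fire its first Ai expression burst while residual fbp
  still powers growth-coupled transcription. That race takes 10–20 h at
  these kinetics. D sets the washout residence time (1/D); at much higher D
  no noise level recovers, at much lower D the bottleneck ordering washes
  out. 0.08 h⁻¹ keeps both effects.
* **κ = 3.4×10⁸ mM/mmol** (culture volume ≈ 3 nL), putting the glucose
  carrying capacity near 5000 cells for the standard 2000-cell inoculum.
  With fixed influx concentrations and the 4:1 acetate:fbp stoichiometry,
  the acetate capacity is necessarily half the glucose capacity; placing the
  glucose capacity well above the inoculum keeps acetate-phase populations
  in the low thousands.
* **K_CraA_DNA = 6.5×10¹⁴ molecules/g.** At 100 active Cra per newborn the
  promoter is ~34% occupied: mean cells are marginal, high-Cra cells ignite
  reliably, low-Cra cells cannot sustain growth. This single constant places
  the switching threshold.

## Deterministic bistability

`find_steady_states()` analyses the (pep, fbp) subsystem of one cell at
newborn mass with enzymes at their mean copy numbers. The Cra→Ai feedback is
closed by the regulated quasi-steady Ai mean,
$\bar{Ai}(\mathrm{fbp}) = \alpha_{on} P_{bound}(\mathrm{fbp})\,\beta_{Ai}$ —
freezing Ai at a fixed number would cut the loop and destroy the high-fbp
fixed point. Roots come from damped Newton iteration started on a log-spaced
grid; stability from the eigenvalues of the numerical Jacobian. With default
parameters: one growing state on glucose (μ ≈ 0.42 h⁻¹, fbp ≈ 11 mmol/g,
pep ≈ 0) and two stable states on acetate — nongrowing (μ ≈ 0.02 h⁻¹, fbp ≈
0.43, pep ≈ 0.02) and growing (μ ≈ 0.25 h⁻¹, fbp ≈ 0.014, pep ≈ 0.45) —
separated by a saddle.

The stochastic simulation is *more* pessimistic than this reduction: a real
cell arriving from glucose has exactly zero Ai molecules, not the fractional
quasi-steady mean, so its fbp drains past the nominal nongrowing fixed point
and it freezes at low μ until (and unless) a first burst fires. This
discreteness gap is the mechanistic heart of the model: it is what makes the
switch probabilistic and Cra-copy-number dependent.

## Experiment designs and their statistics

* `run_competition_assay()` — two subpopulations (1000 cells each) share one
  chemostat for 2 d glucose + 2 d acetate; relative fitness is
  $w = \ln\!\big((N_1/N_0)\,/\,(N_1'/N_0')\big)$, antisymmetric and zero at
  equal growth. Replicates in which either side goes extinct report `w = NA`
  and are excluded from means with a warning.
* `bottleneck_stats()` — carrying capacity is the mean population size over
  the last 12 h of the trajectory; recovery time is the first post-minimum
  entry into capacity × (1 − 5%). Trajectories that never re-enter the band
  are censored, not dropped silently.
* `growth_rate_distribution()` — bimodality is judged by occupancy of the
  two deterministic basins (threshold: 10% of the growing-state μ, a value
  inside the gap between the modes), not by kernel-density mode counting;
  both modes must hold ≥1% of cells.
* `lineage_dwell_times()` — maximal runs above/below the same threshold;
  the first and last run of every lineage are censored by the observation
  window and excluded from the means.
* `run_allele_competition()` / `run_fixation_experiment()` — two alleles
  (default wild type 0.05, beneficial 0.07 mmol/g) under 48 h periodic
  switching until fixation or loss, with per-step bottleneck minima per
  allele recorded during the first acetate epoch, four-day fitness measured
  from simulation start, and a configurable hard time cap (censored
  replicates are reported as such).
* `run_lineages()` — a fixed cohort with no washout, one daughter kept at
  random per division, at constant substrate concentration (a dynamic pool
  shared by non-interacting lineages would be depleted inconsistently).

## What the simulations do and do not show

The synthetic populations reproduce the mechanism of interest: bistable
growth on acetate, unimodal growth on glucose, noise-ordered bottleneck
minima and recovery times, a positive fitness effect of Cra noise in
fluctuating environments, amplification of a beneficial allele's fitness by
noise, a strong correlation between allele fitness and the log bottleneck
size ratio, and noise-enhanced fixation of a rare beneficial allele.

Quantitatively, with the shipped calibration the noise ladder is steeper
than in real populations of this kind: the fitness advantage of the
noisiest over intermediate-noise populations is of order 1–2 on the log
scale (rather than ~0.2), and lineage dwell times in the growing and
nongrowing states on acetate are of order 30 h rather than hundreds of
hours. Both trace to the promoter occupancy being Michaelis–Menten while
bistability pins its dissociation constant into the unsaturated regime,
which makes the growing state sensitive to downward Cra fluctuations. The
package reports these statistics as computed; none of the defaults are
tuned per experiment.

A related population-level consequence: because nongrowing cells neither
divide nor resist washout, the nongrowing mode of the growth-rate
distribution on acetate is transient — prominent through the bottleneck and
recovery, then eroded exponentially at the dilution rate once the growing
subpopulation has rebuilt carrying capacity. Snapshots for bimodality are
therefore taken shortly after recovery; in the reference system the
nongrowing mode persists far longer.

Real *E. coli* features deliberately outside the model: genome-scale
metabolism (the biomass yield is a fixed constant), explicit mRNA species,
cell-size regulation beyond divide-at-doubling, spatial structure, and any
cell–cell interaction other than competition for the shared substrate pool.

## Numerical choices

Per-cell ODEs are integrated with an adaptive Cash–Karp 4/5 Runge–Kutta
scheme (relative tolerance 10⁻⁸, absolute tolerance 10⁻⁹ on concentrations
and 10⁻⁹·B₀ on masses); protein counts and external substrate are frozen
within a step (operator splitting in the scheduler's order). Metabolite
pools are clipped at zero only for sub-tolerance undershoots. The substrate
balance uses the exact exponential solution of the linear inflow/outflow
part, so an empty chemostat relaxes to the influx concentration with no
discretisation error; a cellular uptake debit that would overdraw the pool
by more than 1% aborts the run (the step is too coarse), smaller overdraws
are clipped with a counter. Division retains overshoot mass (a cell of mass
2.1 B₀ splits into two of 1.05 B₀). Fixation is declared when the competing
allele's count reaches zero at a step boundary.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run scaled-down versions of the
experiment designs — populations of a few hundred to two thousand cells,
3–10 replicates, horizons of 2–5 simulated days, with κ rescaled in
proportion to population size. These sizes were chosen as the smallest at
which the qualitative contrasts (bistability, bottleneck ordering, fitness
signs) are stable across seeds; the full-scale designs (50 replicates,
2000–5000 cells, multi-week horizons) run with the same code by changing
`replicates`, `n0` and `kappa`.
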