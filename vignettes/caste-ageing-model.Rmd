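---
title: "The casteage model: evolving caste-specific ageing in social insect colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The casteage model: evolving caste-specific ageing in social insect colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteage)
```

## The question and the model

Queens of advanced eusocial insects can outlive their workers by orders of
magnitude even though the two castes share a genome. `casteage` implements an
individual-based simulation asking whether such lifespan divergence requires
caste-specific extrinsic mortality, or whether it emerges from reproductive
division of labour alone when mutations have antagonistically pleiotropic
effects within and between castes.

The simulated world is a fixed number `N` of colony slots. Each colony is
monogynous: one singly-mated diploid queen (haplodiploid genetics: females
diploid, males haploid) plus a roster of sterile workers. Every individual
carries a gene-regulatory network represented as `4k` real regulatory values
— intrinsic survival and fecundity for each caste at each of `k` age classes
— in the fixed block order queen survival, queen fecundity, worker survival,
worker fecundity. Diploids carry two copies; the allelic values interact
additively and the sum is pushed through a logistic to the trait scale:
survival `1/(1+e^{-x})`, fecundity `m/(1+e^{-x})`. Queens express only the
queen blocks, workers only the worker blocks; worker fecundity is carried
but never expressed in the dynamics (workers are sterile), which makes it a
built-in neutrality control.

### One time step

1. **Reproduction.** A queen of age `a` with fecundity `f_a` and `w` workers
   forages a fraction `z = max(0, 1 - (1+w)/(1+f_a))` of her time, lays
   `E = f_a (1-z)` eggs, and the colony gathers `R = z + w` resources
   (queens and workers forage equally well). Expected offspring is
   `F = ER/(E+R)`; the realised count is Poisson(`F`). Every diploid egg is
   accompanied by one haploid (male) egg carrying a fresh maternal gamete.
   Note that the allocation rule is the egg–resource balance point: `z`
   equalises `E` and `R` (clamped at 0 when workers already outnumber the
   egg potential). It is the maximiser of the limiting offspring function
   `min(E, R)`, not of the smooth `ER/(E+R)`, whose argmax lies at smaller
   `z` whenever `f_a > 1`; the test suite checks the rule against a
   grid-search maximisation of `min(E, R)`.
2. **Survival and ageing.** Workers always forage (`z = 1`), so their
   extrinsic death probability is `h_ext`; a queen is exposed only through
   her own foraging, `d_ext = 1-(1-h_ext)^z` — a lone founding queen
   (semiclaustral founding) must forage and is exposed, a well-staffed queen
   is shielded. Each individual survives a Bernoulli trial with probability
   `s_a(C) (1-d_ext)` and dies deterministically on completing age class
   `k`.
3. **Collapse.** A queenless colony loses its queen and workers. Its egg
   pools stay available to this step's requeening draw and die with the
   colony at the end of the step if not withdrawn.
4. **Requeening.** Each vacant slot is refounded by an egg drawn from a
   source colony sampled proportionally to per-colony hatching-egg counts
   (egg-weighted), withdrawn as a new age-1 queen and mated to a uniformly
   random male from this step's male pool. Males mature and die within the
   step.
5. **Hatching.** Eggs laid last step become age-1 workers in their natal
   colony; this step's eggs move to the hatching pool (one step of
   development).

Extinction (no queens and no eggs anywhere) halts the run with the step
recorded; so does an empty male pool at a required mating.

### Mutation

A transmitted network mutates with probability `mu`, at most once per
transmission, and a mutation is a single draw from a `4k`-dimensional
multivariate normal added to all positions at once: mean `b` in every
coordinate (the deleterious bias) and covariance `Sigma` set by the
scenario. Both gametes of a diploid egg — the maternal gamete and the copy
of the stored sperm — pass through the mutation step independently, as does
each male egg; re-mutating repeated uses of stored sperm is the literal
per-transmission reading and keeps every transmission channel identically
distributed.

The five scenarios place correlation `rho` (default -0.8) between a
mutation's effects on: nothing (`baseline`); the same trait in the same
caste `delay` age classes apart (`WCWT`); queen fecundity and queen survival
`delay` age classes later (`WCBT`); queen and worker survival at the same
age (`BCWT`); queen fecundity and worker survival at the same age (`BCBT`).
Worker fecundity never carries correlated effects. The scenario matrix `P`
is built by `build_partial_correlation()` and is symmetric with unit
diagonal by construction (one-sided insertions are always mirrored).

### From scenario matrix to covariance

`partial_to_covariance()` reads `P` as the target correlation structure of
mutational effects and sets `Sigma = sigma^2 * C`, with `C` the nearest
valid correlation matrix to `P`. For the pairwise-disjoint patterns (`WCBT`,
`BCWT`, `BCBT`) `P` is already positive definite and the requested `rho`
passes through exactly. The `WCWT` band (chains of ages `a, a+delay,
a+2*delay, ...`) is infeasible at `|rho| = 0.8` — a chain with -0.8 on
every link has minimum eigenvalue `1 - 0.8 * 2cos(pi/5) < 0` — so it is
projected by Higham-style alternating projections (eigenvalue clipping at
`1e-8`, diagonal renormalisation by congruence, 100-iteration cap, explicit
failure if the floor is not reached). The projection is recorded on the
architecture object (`repair$fired`, Frobenius distance moved, iterations)
and realised `WCWT` correlations land near -0.65: users can always see when
the realised architecture differs from the nominal one.

A precision-matrix (Gaussian graphical model) reading of `P` was considered
and rejected. The two conventions coincide for every feasible pattern the
scenarios use (identity; disjoint 2x2 blocks, where inverting
`[[1, -rho], [-rho, 1]]`-type precision blocks returns correlation `rho`
exactly), but for the infeasible `WCWT` band the repaired precision matrix
has its smallest eigenvalue pinned at the clipping floor, its inverse is
dominated by the corresponding near-null directions, and the realised
correlations degenerate to exactly +/-1 — deterministic antagonism, which
is not a usable mutational architecture.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `N` | colony slots | 1000 | fixed population size (slots, not individuals) |
| `T` | time steps | 10^6 | horizon of the full-scale experiment |
| `k` | age classes | 20 | also the maximum lifespan, in steps |
| `h_ext` | extrinsic hazard while foraging | 0 / 0.2 | age-independent; workers always exposed |
| `mu` | mutation probability per transmission | 0.005 | at most one event per transmission |
| `b` | mean mutational effect | -0.2 | per coordinate, every coordinate |
| `sigma` | sd of mutational effects | 0.4 | diagonal of `Sigma` is `sigma^2` |
| `rho` | scenario correlation | -0.8 | sweepable in [-1, 1] |
| `delay` | delayed-effect offset | 5 | age classes; sweepable 3-10 |
| `m` | maximum fecundity per age class | 5 | fecundity scale of the logistic |
| `init_value` | founder genetic value | 5 | see below |

### The founder value

The founder level is the one initial condition the model statement leaves
open (castes merely start identical). It cannot be low: a lone semiclaustral
founding queen with survival 0.5 and fecundity `m/2` (the `init_value = 0`
start) expects well under one lifetime offspring, so any such population
crashes within a few steps. The default `init_value = 5` (allelic sum 10:
survival ~0.99995, fecundity ~`m`) starts founders senescence-free at the
trait optimum — the classic mutation-accumulation setup, in which every
age-specific decline that later appears is evolved rather than seeded. The
saturation of the logistic also matters dynamically: near the optimum a
whole-network mutation event is almost neutral and can accumulate, while
populations seeded at intermediate survival (e.g. 0.98) sit where every
event carries a several-percent fitness cost and is purged, freezing the
founder state.

### Why the evolutionary dynamics work

Because one mutation event touches all `4k` coordinates with a common
deleterious bias, selection acts on whole networks (gametes transmit whole
networks by default; a free-recombination flag exists for sensitivity
checks). Coordinates under strong selection — queen survival and fecundity
at the ages that queens actually reach, worker survival at the young ages
that dominate the workforce — hold near saturation, while weakly selected
coordinates (old-age worker survival, and worker fecundity entirely) slide
downward under the `mu * b` mutation pressure and drift. The evolved curves
therefore stay near 1 up to a caste-specific cliff age, which is the
headline queen-worker divergence pattern the acceptance tests check in
scaled-down form.

## Design choices at points the model statement leaves open

- **Within-step order** (reproduce, survive/age, collapse, requeen, hatch):
  lets "eggs in the colonies" at requeening be the hatching cohort laid one
  step earlier, and makes the queen's extrinsic exposure reflect the `z`
  she actually used this step.
- **Eggs at collapse.** Members (queen, workers) die with the colony; the
  egg pools of a colony that collapsed this step remain eligible for this
  step's requeening draw, then die. New colonies are founded by "an egg
  from a random colony", and restricting the draw to surviving colonies
  makes a mutation-free population — which is perfectly synchronised,
  every queen dying of max age in the same step — deterministically
  extinct at step `k`.
- **Requeening fallback.** If no hatching eggs exist anywhere, the draw
  falls back to eggs laid this step (counted and reported as
  `requeen_fallback`); without it, small or fully-synchronised populations
  die of a bookkeeping accident rather than biology.
- **Male eggs** equal realised diploid offspring in number (one haploid egg
  whenever a diploid egg is laid), each a fresh mutated maternal gamete;
  males are pure gene carriers living one step, and a colony's males
  outlive its collapse within that step.
- **Egg intensities.** `E` is a real-valued intensity feeding the Poisson
  through `F`; eggs are only discretised when realised.
- **Seeds.** One RNG stream per replicate; grid replicate seeds are derived
  from the master seed by a fixed hash of (scenario, `h_ext`, `rho`,
  `delay`, replicate), so results are addressed by cell, not by execution
  order.

## Problem sizes

`sim_preset("full")` is the headline configuration (N = 1000, T = 10^6, 20
replicates per cell) and is sized for cluster hardware. `sim_preset("desk")`
(N = 120, T = 1.5e5, 5 replicates) is the package's working scale: T is
chosen where the checkpointed life expectancies stop trending (the
`quasi_equilibrium` flag, which requires < 2% relative change over the final
10% of steps, operationalises the visual criterion), and N is as large as
keeps a full scenario grid in the minutes range on one CPU. Desk-scale results are directional at best. The within-replicate
queen-worker divergence is robust (both castes share each replicate's drift
history), but evolved worker lifespan is dominated by drift of the
near-neutral old-age survival coordinates — replicate-to-replicate spreads
of several age classes persist even at a few hundred colonies — so
between-scenario contrasts of five-replicate medians are not reliably
resolved below the full scale. Evolved magnitudes also sit closer to the
founder state than a 10^6-step equilibrium would.

```{r desk-example, eval = FALSE}
# the desk-scale baseline contrast (a few minutes on one CPU)
grid <- run_grid(scenarios = "baseline", h_ext = c(0, 0.2), preset = "desk",
                 master_seed = 1)
compare_castes(grid)
autoplot(grid)
```

## What the simulator emulates — and what it does not

The generator reproduces the study conditions: monogynous, singly-mated,
semiclaustral colonies of a haplodiploid species with sterile workers, a
fixed number of colony slots, one-step egg development, one-step males, and
biased, correlated whole-network mutations. It does not emulate polygyny or
polyandry, worker reproduction, task polymorphism (all workers forage full
time), spatial structure, resource stochasticity, density dependence beyond
the fixed slot count, or explicit regulatory-network topology (the
"network" is operationally a trait-value vector). Passing desk-scale tests
therefore says the mechanism produces the claimed directional effects under
these idealisations — not that real colonies are quantitatively described.

## Numerical and degenerate-input behaviour

Logistic expression saturates gracefully for large allelic sums; `sigma` of
exactly 0 is rejected (use a small positive value to emulate a pure bias).
`h_ext = 1` is allowed in the simulator (the foraging-death formula is
continuous there) and produces an annual life cycle of first-year queens;
the scalar helper `foraging_death_prob()` enforces `h_ext < 1` as
documented. Covariance matrices are used through a symmetric eigenvalue
square root, so exact positive semi-definiteness (including the projected
`WCWT` matrix with an eigenvalue at the floor) is sampleable without
jitter. Weighted requeening uses one cumulative-sum pass with a guard for
the final bin, and is exported (`sample_weighted_index()`) so the exact
simulator code path can be audited statistically. Invariant checking
(`check_invariants = TRUE`) makes the core stop on any violation of slot
count, monogyny or age bounds; it is on in the test suite and off by
default for speed.

## Statistics exported, statistics omitted

`summarize_replicate()` reports, per caste: life expectancy as the area
under the discrete survivorship curve built from the population-mean
intrinsic survival probabilities (`sum over a of prod(s_1..s_a)`, maximum
`k`; extrinsic mortality deliberately excluded), lifetime fecundity as the
survivorship-unweighted sum of mean age-specific fecundities (maximum
`k*m`), and both as proportions of their maxima — the exact table a
proportion-scale analysis (beta regression with post-hoc contrasts)
consumes. Those inferential steps are ordinary off-the-shelf statistics and
are intentionally not re-implemented here.

## Known limitations

- The curve-of-means convention (life expectancy of the mean survival
  curve) differs from the mean of per-individual life expectancies when
  genetic variance is high; both conventions agree at the low standing
  variance these populations maintain, and only the former is implemented.
- Whether allelic values combine by sum or mean before the logistic is a
  scale convention; sum is implemented, and a mean-convention population is
  identical after halving all genetic values.
- The quasi-equilibrium flag is an operationalisation of a visual
  criterion; it is reported, never enforced.
- Desk-scale magnitudes are not the 10^6-step equilibrium values; only
  directions and orderings should be read from them.
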