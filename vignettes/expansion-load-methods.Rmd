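---
title: "Simulating expansion load during range expansions and range shifts"
author: "shiftload package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating expansion load during range expansions and range shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftload)
```

## The problem

Populations colonizing new territory do so through a thin front of small,
recently founded demes. Genetic drift is strong there: deleterious variants
can "surf" the wave of advance and fix, so fitness erodes along the axis of
spread — *expansion load*. A specialist species tracking a moving climate
niche is in a worse position still: its habitat window *shifts*, opening new
demes at the leading edge while extinguishing demes at the trailing edge, so
there is no large, high-fitness core to resupply the front. This package
simulates both situations with an individual-based, forward-time model, and
pairs the simulator with a small analytic model of fitness evolution at the
front.

Two selection regimes are contrasted. Under **soft selection**, population
regulation is unaffected by mean fitness: selection acts only through
relative parentage success within demes, so a loaded population is smaller
in fitness but not in numbers. Under **hard selection**, the demographic
parameters themselves scale with mean fitness, so load shrinks populations,
which strengthens drift, which deepens load — a feedback that can drive a
range-shifting species extinct.

## The individual-based model

Diploid, monoecious individuals occupy a stepping-stone landscape of demes
(default one row of 300). Generations are discrete and non-overlapping; one
generation applies, in order:

1. **Migration** — each individual emigrates with probability `m` (default
   0.1), to a uniformly chosen adjacent deme; moves targeting off-grid or
   uninhabitable demes are cancelled (reflective boundaries, and burn-in
   confinement to the seed region).
2. **Reproduction with selection** — within each deme the offspring number
   is Poisson with mean `N*R/(1 + N*(R-1)/K)` (Beverton–Holt logistic,
   `R = 2`, `K = 100`); each offspring draws two parents with probability
   proportional to fitness and receives one gamete from each. Under hard
   selection, `K` and `R` are first scaled by mean fitness (below).
3. **Mutation** — each individual receives a Poisson(`U = 0.1`) number of
   mutation events at uniformly chosen (haplotype, selected locus)
   positions. Mutation is one-way: an event on an already-derived copy does
   nothing. Optional neutral loci mutate at their own per-copy rate.

Fitness is multiplicative over 1000 bi-allelic selected loci (900
deleterious, 100 beneficial): a heterozygote contributes `1 + h*s`, a
derived homozygote `1 + s`, with `|s| = 0.005` and `h = 0.5` (additive) or
`h = 0` (recessive) in the core scenarios. Loci recombine freely (each locus
inherits from either parental haplotype with probability 1/2) or, for the
linkage scenarios, not at all. Runs begin with a 4000-generation burn-in of
the seed region (the five left-most columns) during which beneficial
mutation events are discarded — otherwise every beneficial locus would fix
before spread begins — and mean fitness is re-referenced to 1 at burn-in
end so that scenarios are comparable.

A range **expansion** opens the whole landscape at burn-in end. A range
**shift** moves a constant-width window (5 columns) forward by one column
every `T` generations — speed `v = 1/T` — killing the trailing column as the
leading one opens; the window advances at the start of a generation, so a
newly opened deme can be colonized the same generation, and parks at the far
end of the landscape (the recovery phase).

## Hard-selection scaling and mating: two calibration choices

Two micro-decisions of the model are not fixed by the description above, and
both matter quantitatively. The package fixes them by calibration against
two emergent, independently known quantities: the dispersal-limited
expansion speed (≈ 0.25 demes/generation at the default demography) and the
load-limited hard-selection expansion speed (≈ 0.176).

* **Mating.** With self-fertilization allowed, a lone migrant can found a
  deme by itself and expansions run at ~0.33 demes/generation; requiring
  two distinct parents (the package default, `selfing = FALSE`) yields
  ~0.27. The option remains available.
* **Hard-selection scaling.** `K_eff = K*w` is uncontroversial, but the
  growth parameter can scale as `R_eff = w*R` (default,
  `hardGrowth = "linear"`) or `log R_eff = w*log R` (`"log"`), and `w` can
  be absolute mean fitness (default, `hardReference = "absolute"`, so the
  standing load of roughly `exp(-0.9*U)` ≈ 0.91 already depresses the
  demography) or fitness re-referenced to 1 at burn-in end (`"relative"`).
  Only the linear/absolute combination reproduces both the slowed hard
  expansion (~0.18 demes/generation) and the collapse of fast hard shifts;
  the log/relative combination leaves hard selection almost
  indistinguishable from soft selection at these parameter values.

Reported fitness statistics are always relative to the burn-in reference,
regardless of the demographic scaling.

## The analytic front model

Between two colonization events (`T` generations apart) selection acts
within the front deme; each colonization then samples `F = K*m/2` founders
(5 by default). A mutation present at frequency `p0 = 1/(2F)` at the front
fixes with the diffusion probability

    p(sT, F, p0) = (1 - exp(-2*F*s*T*p0)) / (1 - exp(-2*F*s*T)),

implemented in `fixationProb()` (continuous at `s = 0`, where it equals
`p0`). The expected log-fitness change per deme travelled sums, over the
deleterious and beneficial classes, mutational input times fixation
probability times effect:

    delta(v) = sum_c n_c * s_c * p(s_c*T, F, p0),   n_c = K*T*u_c,

with `u_c` the per-haploid-genome rate of class `c` (`phi*U/2` and
`(1-phi)*U/2`). Expanding `delta` for small `s*T` shows the loss per deme is
maximised at the critical speed `v* = s*(2F-1)/(2*phi-1)` — 0.05625 at
default parameters (`criticalSpeedClosedForm()`), with the exact numerical
maximiser about 20% slower (`criticalSpeedNumeric()`). Below the zero-load
speed — `zeroLoadSpeed()`, ≈ 0.021 — beneficial fixations outweigh
deleterious ones and the front gains fitness per deme travelled.

Both printed anchors (`v*` and the zero-load speed) are independent of the
prefactor of `n_c`, which the model description does not pin down. The
whole-deme convention `n_c = K*T*u_c` is kept for `perDemeFitnessChange()`
and the decomposition table, where only the shape in `v` matters. The
coupled fitness-census recursion `hardSelectionTrajectory()` instead scales
the input to the founder group (`2F` copies, i.e. a factor `m` smaller):
that choice places the per-deme loss at `v = 0.2` near the value realized
by the simulator (about -6e-4 versus -9e-4 per deme), which is the scale a
credible extinction model needs. Under its declared extinction criterion —
the front census at a colonization epoch falls below `F` — the recursion
collapses once fitness crosses the demographic threshold `w ~ 0.5` where
`R_eff = w*R` reaches 1, at essentially every shift speed; the
individual-based runs, in contrast, collapse stochastically earlier and at
higher fitness for faster shifts.

## What the simulator reproduces, and where it deviates

At fast shift speeds the simulated per-deme fitness loss tracks the
founder-scaled analytic model well, and the emergent headline behaviours
are reproduced: dispersal-limited soft expansions at ≈ 0.25-0.28
demes/generation, load-slowed hard expansions at ≈ 0.18, and extinction of
`v = 0.2` hard shifts with front fitness still above 0.75.

At slow speeds (`T` of tens of generations) the simulated front behaves
differently from the analytic serial-founder picture: migration during the
long interval between window steps mixes the newly founded front deme back
into the five-deme window, selection regains efficacy, and beneficial
sweeps can outweigh deleterious surfing — simulated slow shifts *gain*
fitness where the analytic model (and the original study's simulations)
lose it. Three consequences should be kept in mind when interpreting
slow-shift output of this package: the speed of maximal per-deme loss comes
out nearer 0.1 than 0.05; the simulated equilibrium (no-net-change) speed
is faster than 1/40 rather than near 1/60 (additive) or 1/84 (recessive);
and recessive hard expansions cross a 300-deme landscape within 5000
generations instead of stalling near deme 240. No variant of the described
life cycle that we explored (step order, offspring distribution, mating
system, boundary handling, hard-selection scaling) changes the sign of the
slow-shift balance.

## Neutral diversity

Neutral loci are bi-allelic with one-way mutation, like the selected ones;
their per-copy rate defaults to 5e-5 (the same rate per copy that
`U = 0.1` implies across 1000 selected loci) since no separate value is
part of the model description. A 500-individual seed metapopulation then
equilibrates near expected heterozygosity 0.075, and a `v = 0.2` shift ends
its recovery phase near 0.06 — the model cannot sustain the 0.125-0.2
levels that would require a severalfold higher input (and a mutation model
without absorbing fixation of the derived allele). Heterozygosity output is
therefore best used comparatively (shift vs expansion, front vs core), not
as an absolute level; `neutralRate` is a config key.

## Numerical and design notes

* **Bit-packed genotypes.** Haplotypes are stored 64 loci per machine word;
  gametes are formed with word-wide random recombination masks and fitness
  is computed by iterating set bits, so whole-landscape runs over thousands
  of generations take seconds.
* **Determinism.** Each run consumes a single seeded random stream; the
  same configuration and seed reproduce records bit-for-bit. Burn-ins can
  be cloned (`cloneSim()`) to branch several scenarios off one ancestral
  population — used for paired speed comparisons in `sweepSpeeds()`.
* **Fitness floor.** Per-locus factors are clamped at 1e-6 (relevant only
  for extreme exponential-DFE draws); occurrences are counted and
  retrievable via `clampedFactorCount()`.
* **Front identification.** The front is the forward-most column with at
  least 10 residents (falling back to the forward-most occupied column), so
  a single wandering migrant does not define the front; the threshold is an
  argument of `frontAndCore()`.
* **Fit windows.** Loss rates per generation and per deme are fitted over
  post-burn-in generations 100-2000 and only while the front is moving,
  avoiding both the initial transient and the late phase in which the 100
  beneficial loci begin to saturate.
* **Extinct replicates** truncate: aggregation (`runReplicates()`) reports
  per-generation means and twice the standard error over the replicates
  still alive, with their number in column `n`.
* **Speeds** are reciprocals of integer step intervals; conventionally
  rounded labels (0.066 for 1/15) are accepted within 2%.
* **Scale used in the shipped checks.** The automated checks run reduced
  designs chosen to finish on a desk machine: landscapes of 40-300 demes,
  2-10 replicates per scenario, horizons of 1400-5000 post-burn-in
  generations; the full-scale design (300 demes, 10 replicates, burn-in
  4000, horizon 5000) is one flag away in every preset
  (`presetConfigs(..., fullScale = TRUE)`).

## Known limitations

* The slow-shift regime deviates from the serial-founder analytic model as
  described above; conclusions about speeds slower than ~0.04
  demes/generation should rely on the analytic module, not the simulator,
  or on an independent implementation.
* The analytic model is additive-effect; applying it to recessive scenarios
  is qualitative at best.
* Only free recombination and complete linkage are supported (no genetic
  map), matching the two regimes the model description contemplates.
* 2-D landscapes are supported (rows > 1, column-wise windows) but the
  shipped calibrations and checks are 1-D.
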