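---
title: "Mass-balance food-web models and network indices with fwb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance food-web models and network indices with fwb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwb)
```

## The model

`fwb` implements the static trophic mass-balance model used throughout
fisheries and river ecosystem assessment (the Ecopath family). A system
is partitioned into functional groups — detritus pools, primary
producers, invertebrate guilds, fish feeding guilds, apex predators —
and two identities are imposed on each living group over an annual
cycle.

The production balance says that everything a group produces is either
eaten, caught, exported, accumulated, or dies to detritus:

$$ (P/B)_i \, B_i \, EE_i \;=\; Y_i + \sum_j B_j \,(Q/B)_j\, DC_{ij}
   + NM_i + BA_i $$

where $B$ is biomass (g/m^2 wet weight), $P/B$ and $Q/B$ the annual
production and consumption per unit biomass, $DC_{ij}$ the proportion of
prey $i$ in predator $j$'s diet (columns sum to 1), $Y$ catch, $NM$ net
migration, $BA$ biomass accumulation, and $EE$ the ecotrophic
efficiency — the fraction of production that is used within or removed
from the system; $(1 - EE)$ of production flows to detritus.

The energy balance partitions each consumer's intake:

$$ Q_i = P_i + R_i + UC_i \, Q_i $$

with respiration $R$ closing the budget and $UC$ the unassimilated
fraction. Given a diet matrix and, per living group, all but one of
$\{B, EE\}$, the unknowns solve a linear system (`fw_balance()`). In the
field-survey mode emulated here, biomasses are measured and every $EE$
is solved for. Solved $EE > 1$ marks an over-consumed group; it is
reported and flagged, never clamped, because inspection and adjustment
of inputs is part of the workflow.

### Balancing diagnostics and diet adjustment

`fw_diagnose()` screens the standard plausibility constraints: gross
efficiency $GE = P/Q$ inside (0.1, 0.3), $GE$ below net efficiency,
respiration/assimilation below 1, production/respiration below 1. The
production/respiration constraint is applied to consumers only: a
producer-dominated system violates it trivially, so for producers it is
reported but never enforced.

`fw_adjust_diet()` rebalances over-consumed prey the way practitioners
do by hand: each diet entry on a prey with $EE > 1$ is reduced by a
small multiplicative step proportional to the overshoot, and the freed
diet fraction is redistributed over the predator's remaining prey (to
detritus when there is none). One numerical subtlety: if the overshoot
is measured against $EE = 1$ exactly, the iteration has its fixed point
*at* 1 and approaches balance asymptotically without ever reaching it.
The overshoot is therefore measured against a target marginally below 1
(default 0.999), which crosses the balance threshold in finitely many
steps (about 85 iterations from $EE = 7.5$ at the default step 0.1).
Note that redistribution necessarily increases predation pressure on
the remaining prey, so their $EE$ can rise during adjustment; the
procedure guarantees monotone relief of the offending prey and
termination at all $EE \le 1$, not global monotonicity of every $EE$.

## Trophic structure

Fractional trophic levels put producers and detritus at 1 and each
consumer at one plus the diet-weighted mean level of its prey, solved
as a linear system so diet cycles and cannibalism are exact
(`fw_trophic_levels()`). Diet imported from outside the system is
assigned level 1 (and producer-origin in the spine): there is no
information about its true level, and this convention keeps the spine
mass-conserving.

The Lindeman spine (`fw_lindeman()`) apportions every group's activity
onto discrete levels I, II, ... by the canonical aggregation: the share
of a consumer's intake arriving through diet paths of length $k$ sits at
level $k + 1$. Producer-origin and detritus-origin chains are tracked
separately and combined. Per-level transfer efficiency is the fraction
of a level's inflow passed upward as predation plus catch/export.
Material circulating in diet loops beyond the level cap (default 8) is
reported as a remainder with a warning — on acyclic webs the remainder
is identically zero. Conservation (inflow = outflow components) holds
exactly at consumer levels II and above; at level I a detritus pool may
accumulate surplus when its inflow is not fully consumed, which is a
feature of the budget, not a leak.

The "mean transfer efficiency" over levels II–IV is geometric by
default, matching the convention of the established software; an
arithmetic option is exposed because the choice is not universal.

## System indices

`fw_statistics()` assembles the standard comparison table: flow sums
(total system throughput TST = consumption + exports + respiration +
flows to detritus), maturity ratios (TPP/TR, TPP/TB, TB/TST, net system
production), cycling (Finn's cycling index, mean and straight-through
path lengths, predator cycling index with detritus removed),
connectance, system omnivory, Shannon diversity of biomass shares (a
flow-based variant is behind a flag), and the information indices
(ascendency $A$, development capacity $C$, and $A/C$, in flowbits,
log base 2).

Cycling is computed by input-output analysis: with
$G_{ij} = T_{ij}/\text{inflow}_j$ and $L = (I - G)^{-1}$, compartment
$i$ recycles $\text{inflow}_i (L_{ii} - 1)/L_{ii}$. Two conventions
coexist in the literature for the denominator of the cycling index; the
package uses the sum of compartmental throughputs (inflows including
imports, with producer gross production counted as an import to the
producer compartment), which makes the two-compartment worked example in
the test suite exact, while the path lengths use the TST defined above.
Both choices are stated here because published tables are not always
reconstructible from their own components, and cross-study comparisons
should check which convention was printed.

Mixed trophic impacts follow the classical direct-impact matrix
$q_{ij} = DC_{ij} - F_{ij}$ (prey share of the predator's diet minus
predator share of the prey's total predation; a detritus pool's "diet"
is its normalized inflow), propagated over all interaction paths by
$M = (I - q)^{-1} - I$. Keystoneness is
$KS_i = \log_{10}[\epsilon_i (1 - p_i)]$ with $\epsilon_i$ the
root-sum-square of group $i$'s impacts on the other living groups and
$p_i$ its share of living biomass, so low-biomass strong interactors
score near or above zero.

## Uncertainty

Input provenance is scored by the pedigree index (`fw_pedigree()`): the
unweighted mean over living groups of per-parameter confidence scores
in [0, 1].

`fw_monte_carlo()` propagates input uncertainty the resampling way:
each of `n_total` runs (default 10,000) redraws every scored parameter
from a normal distribution centred on its input with the stated
relative error, truncated positive, renormalizes perturbed diet
columns, re-solves, and accepts the run when the solve succeeds, every
$EE \le 1$, and no consumer respires negatively. Among accepted runs
the `n_keep` (default 200) with the smallest sum of squared
standardized input deviations are retained — the acceptance literature
speaks of "best-fitting scenarios" without fixing a criterion, and
closeness to the base inputs is our interpretation, documented as such.
A stricter screen that also requires gross efficiencies inside
(0.1, 0.3) is available via `physiology = TRUE`; it is off by default
because a run that merely shifts a ratio across a soft plausibility
band is not mass-imbalanced, and the acceptance rate against the
$EE \le 1$ boundary then admits a closed-form check (a normal tail
probability) that the test suite exercises at `n_total` = 20,000.
Determinism: a single seed generates one substream per run index, so
results are bit-reproducible and independent of evaluation order.

## The synthetic web generator

Field data for a real river cannot ship with a package, so
`fw_generate()` builds webs with the statistical structure of degraded
subtropical river food webs, and all pipeline stages are validated on
them. The defaults were chosen once to land the generated systems in
the magnitude ranges published for such rivers and are not tuning
knobs:

* roster of 16 groups: one detritus pool; phytoplankton, periphyton and
  macrophytes; zooplankton, gastropods, bivalves, shrimps and insect
  larvae; six fish feeding guilds from detritivore to piscivore; an
  apex softshell turtle;
* producer biomass around 10 g/m^2 with $P/B$ 20–60 /yr (total primary
  production roughly 600–2000 g/m^2/yr), biomass declining by half per
  trophic guild level; consumer gross efficiencies drawn inside
  (0.1, 0.3);
* diets drawn from a Dirichlet over strictly lower guild levels
  (level-2 consumers may also take detritus); detritivorous guilds feed
  predominantly on detritus (75–90%), filter/collector invertebrates
  take a 25–50% detrital supplement;
* consumer biomasses assigned bottom-up, capped so cumulative demand
  never exceeds 90% of any prey's production — every ground-truth
  ecotrophic efficiency is therefore below 0.9 by construction and
  `fw_balance()` must recover it to machine precision;
* a final pass scales detritus feeders toward consuming ~80% of the
  detrital inflow (subject to the same caps), reproducing the high
  detrital utilization that published river models show.

What the generator does *not* emulate: seasonal dynamics, import/export
through river flow, age structure, and empirically estimated $P/B$–$Q/B$
regressions. Tests passing on generated webs therefore demonstrate
correctness of the arithmetic and the stated invariants, not predictive
skill on any real river.

### Disturbance scenarios

`fw_degrade()` stylizes the three degradation pressures seen along
polluted subtropical rivers. *Industrial* pollution truncates the web
from the top — the removal cutoff descends from the pristine maximum
consumer level to trophic level 3 at full intensity (a fully impacted
zone keeps no piscivores or carnivores) — and scales pollution-tolerant
detritivore biomass up by $1 + 4 \times$ intensity, capped by the spare
production of every prey so the degraded web still balances.
*Overfishing* adds catch proportional to production on the top-quartile
trophic levels. *Invasion* inserts a high-biomass exotic consumer at
trophic level 2 with no predators, feeding on the producers' spare
(unutilized) production so its own production is entirely redundant
($EE = 0$); a detritus-feeding invader was considered and rejected
because the detritus–invader–detritus loop it creates *increases*
recycling, which is the opposite of the flow-redundancy signature the
scenario is meant to emulate. Increasing intensity drives the maturity
indices (cycling, omnivory, connectance, mean transfer efficiency)
downward; for the industrial scenario the cycling index is only weakly
monotone, because removing top consumers strips acyclic throughput
while any feasible detritivore response adds cyclic flow — the
direction of the net effect is web-dependent, and on some webs the
index can tick up by under one percent.

## Worked example

```{r example}
m <- fw_example_web()
b <- fw_balance(m)
b$budget[, c("name", "B", "P", "Q", "R", "EE")]
fw_lindeman(b)$combined[1:3, c("level", "inflow", "to_next", "TE")]
st <- fw_statistics(b)
c(TST = st$TST, TPP = st$TPP, CI = st$CI)
```

## Numerical choices and limitations

* Solver: dense QR on the unknown-biomass system; singularity and
  negative solved biomass are hard errors naming the groups involved.
* Tolerances: diet columns must sum to 1 within 1e-6; columns off by at
  most 1e-3 are renormalized with a warning (field tables are
  hand-rounded); balance residuals are checked at 1e-9 relative.
* Undefined quantities (transfer efficiency of an empty level, P/R at
  zero respiration, ratios with zero denominators) are `NA` sentinels,
  never zeros.
* Problem sizes: tests run webs of up to 16 groups, 20 generator
  seeds, and Monte Carlo ensembles up to 20,000 runs of a three-group
  fixture; all are chosen so the full suite completes in a few
  minutes while leaving the statistical checks with comfortable power.
* Not implemented (out of scope): temporal simulation, spatial
  dynamics, multi-stanza age structure, primary-production-required
  footprints, and ordination statistics.
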