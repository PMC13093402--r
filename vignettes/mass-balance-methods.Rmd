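---
title: "Mass-balanced food-web models and network indices: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balanced food-web models and network indices: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnoweb)
```

## The model

`limnoweb` implements the steady-state trophic mass balance used
throughout fisheries ecosystem modelling (the Ecopath family). An
ecosystem is a set of functional groups -- consumers, producers, and a
detritus pool. For every living group $i$ the production budget closes:

$$B_i \left(\tfrac{P}{B}\right)_i EE_i \;=\;
  \sum_j B_j \left(\tfrac{Q}{B}\right)_j DC_{ij} \;+\; EX_i,$$

where $B$ is biomass (t/km^2^), $P/B$ the production rate (/yr; equal
to total mortality $Z$ at steady state), $Q/B$ the consumption rate
(/yr), $DC_{ij}$ the proportion of prey $i$ in consumer $j$'s diet
(column-stochastic), $EX_i$ fishery landings plus biomass accumulation
and net migration (t/km^2^/yr), and $EE_i$ the ecotrophic efficiency --
the fraction of production used inside the system or harvested. Each
group supplies either $B$ or $EE$; `balance_model()` fills the other.

**Solver.** The balance is linear in every unknown biomass, including
cannibalism terms on the diagonal, so all unknown biomasses come from
one linear solve (`solve()` on the dense system) and unknown
efficiencies follow by substitution. The result is therefore exact to
machine precision and independent of group order; there is no
iteration, damping or tie-breaking. A structurally unsolvable pattern
(for example two unknown-biomass groups whose equations are linearly
dependent) surfaces as a singular system and is reported as such. A
solved $EE \notin [0,1]$ does not abort: the model is returned flagged
`unbalanced` with the offending groups named, which is exactly the
state `auto_balance()` acts on.

**Derived statistics.** With unassimilated fraction $GS$ (default 0.2
for consumers -- the conventional value for fish and the value that
closes the bundled lake model's published respiration and
flow-to-detritus columns): assimilation $A = Q(1-GS)$, respiration
$R = A - P$, net efficiency $NE = P/A$, and flow to detritus
$FD = GS\,Q + (1-EE)P$ (egestion plus mortality not captured by
predation or fishery). A producer contributes $FD = (1-EE)P$ and, with
$P/B$ interpreted as net production, respires nothing. Detritus has no
production of its own: its "production" for efficiency purposes is its
total inflow $\sum FD$, so detritus $EE$ is the consumed share of that
inflow. Consumers with $P > A$ are thermodynamically impossible and are
flagged.

## The bundled lake model

`kaptai_model()` returns a 15-group model of Kaptai Lake (Bangladesh):
ten fish groups, Whisker Shrimp, Insects/larvae, Zooplankton,
Phytoplankton and Detritus, with landings converted from whole-lake
tonnes over the 583 km^2^ water surface. Three editorial choices matter
and are deliberate:

* **The diet matrix is carried verbatim, not renormalised.** The
  published columns sum to 1 within print rounding (0.999--1.0023).
  Renormalising would look tidier but demonstrably moves the solved
  values *away* from the published ones (the Snakehead biomass solves
  to 0.0720 verbatim versus 0.0719 renormalised, against a published
  0.073), so `validate_model()` accepts a configurable diet-sum
  tolerance (default 0.005, the print-rounding scale) and machine-built
  webs are validated at 1e-9.
* **The Whisker Shrimp landing is back-derived.** It is absent from the
  published catch table; the balance identity
  $landings = EE \cdot B \cdot P/B - predation$ with the published
  $B = 0.135$, $P/B = 3.16$, $EE = 0.982$ yields 0.2114 t/km^2^/yr,
  which also reproduces the published total catch of 10.865.
* **Detritus biomass is fixed at the published 1 t/km^2^.** The
  empirical detritus-stock estimator (`detritus_biomass()`, with
  euphotic depth $E = 2.5 \times$ Secchi depth) is provided as an
  estimator only, because its primary-production input is not published.

One published life-history row (*Channa punctata*) fails the internal
consistency check $Z = M + F$ by 0.6/yr; `check_life_history()` flags
it rather than silently repairing it.

## Trophic decomposition and the Lindeman spine

Fractional trophic levels solve the linear fixed point
$TL_i = 1 + \sum_q DC_{qi} TL_q$ with producers and detritus pinned at
1 (one exact solve; cycles handled by the inverse). The omnivory index
is the diet-weighted variance of prey levels.

For the spine, each group's flows are apportioned onto integer levels
by the standard flow-fraction recursion: producers and detritus are
100% level I; a consumer's level-$(k{+}1)$ fraction is the diet-weighted
sum of its prey's level-$k$ fractions. Two conventions here are load
bearing:

* **Cannibalism is not a between-level transfer.** Self-loops are
  removed and the diet column renormalised before computing fractions,
  and self-predation is excluded from the level flows, as trophic
  aggregation conventionally does. This is not cosmetic: with the
  dominant zooplankton self-loop left in, the level II to III flow in
  the lake model would read roughly double the published value.
* **Truncation.** The recursion is carried until the remaining tail is
  below 1e-12 and folded into the top reported level (seven by
  default), so fraction rows sum to one exactly.

Transfer efficiency at a level is (flow passed to the next level +
exports and catch at that level) / throughput entering the level;
respiration and detritus losses are the inefficiency. Producer-origin
and detritus-origin pathways are tracked by running the same recursion
from each level-I source separately; the two origin tables sum to the
total. The summary "mean TE" is the geometric mean over levels II--IV
(configurable), the energetically dominant part of the spine.

## Whole-system indices

`build_flow_network()` assembles all balance terms into one
compartment-flow object. Total system throughput is the standard
decomposition
$TST = \sum Q + \sum exports + \sum respiration + \sum FD$.
Boundary conventions:

* Exports are landings plus the unconsumed detritus surplus.
* **Primary production is internal, not an import.** It is the
  producers' throughflow and reaches the network through their
  outflows. The import row of the information indices holds genuine
  diet imports only (zero in the bundled model). This choice, with one
  export sink and one dissipation sink, reproduces the published
  ascendancy/overhead split (32.09% / 67.91%); treating production as a
  boundary import instead would push ascendancy above 50%.

**Cycling.** Finn's index uses input--output analysis: with
$G_{ij} = T_{ij}/T_j$ the direct inflow fractions and
$Q = (I-G)^{-1}$, compartment $j$ recycles $(q_{jj}-1)/q_{jj}$ of its
throughflow; FCI is the cycled share of TST in percent. The tests
cross-check the inversion against an independent truncated walk-sum
$\sum_k G^k$. Finn's mean path length is
$TST / (exports + respiration)$.

**Structure indices.** Connectance is realised diet links over
$N_{living}^2$ (the directed-graph alternative $L/(N(N-1))$ is
selectable). Shannon biomass diversity uses natural logarithms over
living-biomass shares. The system omnivory index is the consumer
omnivory weighted by log consumption; this documented convention yields
0.083 on the lake model, whereas the source software printed 0.166 --
none of the defensible weightings we evaluated (unweighted mean 0.221,
floored log weights 0.146) reproduces that figure, so it is reported
under the package's own convention and excluded from acceptance
checking. The pedigree (data-quality) index is provided as a scaffold
for user-supplied scores only; no per-parameter scores are published
for the bundled model, so no value is asserted.

## Impacts, keystoneness, overlap

The mixed trophic impact matrix accumulates all direct and indirect
effects: the direct net impact of $a$ on $b$ is $b$'s diet share of $a$
minus $a$'s share of the predation-plus-catch pressure on $b$, and
$MTI = (I-q)^{-1} - I$, equal to the path-sum $\sum_{k\ge1} q^k$ when
the spectral radius is below one (the tests verify this equivalence; a
chain with 100% diet shares and no fishery sits exactly on the unit
radius, which is why the test webs carry landings). The fleet enters as
an extra consumer whose diet is the landings composition.

Keystoneness follows the $\varepsilon$-based definition: total impact
$\varepsilon_i = \sqrt{\sum_{j \ne i} m_{ij}^2}$ (self-impact and fleet
column excluded), relative total impact $\varepsilon_i / \max
\varepsilon$, and $KS_i = \log_{10}[\varepsilon_i (1 - p_i)]$ with
$p_i$ the living-biomass share; an unpenalised variant is selectable.
Pianka overlap is the normalised inner product of diet columns (prey
overlap) or predation-mortality profiles (predator overlap); the 0.2
display threshold used in published overlap plots is a reporting
filter, not part of the statistic.

## Automatic rebalancing

`auto_balance()` implements iterative diet adjustment: take the worst
$EE > 1$ offender (ties by group order), find the predator contributing
most to its predation, remove `step_fraction` (default 10%) of that
diet entry, and redistribute it over the predator's other prey with
weights $(DC^{max}_j - \overline{DC}_j)/\sum(\cdot)$, where max and
mean are taken across that prey's realised diet shares over all
predators in the current matrix. The source procedure does not pin down
this ensemble; our reading (prey with headroom below their observed
maximum absorb more) is documented here, configurable in step size, and
makes no claim of bit-equivalence with any particular software's
internal routine. Columns remain exactly stochastic and predator
consumption totals untouched; the audit records every edit and the EE
trajectory.

## The synthetic-web generator

`generate_web()` emulates the *structure* of the lake model -- one or
more producers, a detritus pool, layered consumers with sparse
column-stochastic diets, cannibalism loops -- with known ground truth.
Defaults: 8 consumers in 3 layers, diet sparsity 0.4, cannibalism
probability 0.15, $P/Q$ drawn in $[0.05, 0.3]$ (bracketing the
0.043--0.257 observed in the lake model), EE targets in $[0.3, 0.95]$.
Biomasses are set top-down so each group's EE equals its target
exactly, with landings absorbing slack (biologically: fishing
pressure); detritivory per consumer is capped at 0.15 -- below the 0.2
unassimilated fraction -- so the detritus budget always closes. What
the generator does **not** emulate: real species' rate magnitudes by
taxon, import flows, multi-detritus pools, seasonal or spatial
structure. Passing recovery tests on these webs therefore demonstrates
the solver's correctness on the model class, not the field accuracy of
any particular parameterisation.

## Problem sizes and numerics

All bundled analyses run on the 15-group model in well under a second;
the synthetic validation sweeps 100 webs of 6--14 groups. Tolerances:
the balance residual is checked at 1e-9 relative, recovery of masked
parameters at 1e-6 relative (observed: ~1e-15), oracle equivalences at
1e-8. Published-value comparisons use the precision the source prints,
widened only where print-rounded diet columns propagate (documented per
test). Known limitations: no uncertainty propagation on inputs, no
dynamic (time- or space-resolved) simulation, and no attempt to
reproduce indices whose inputs are unpublished (pedigree score, loss in
production index).
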