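---
title: "Process-graph methods for agroecosystem pest management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-graph methods for agroecosystem pest management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepgraph)
```

## The model

A socioecological process graph (SEP-graph) is a directed bipartite graph
with two node classes. *Materials* (M-type nodes) are species, life stages,
population states, resources and ecosystem services; each is a raw material
(supplied from outside the system), an intermediate, or a terminal product.
*Operating units* (O-type nodes) are ecological processes — growth,
reproduction, herbivory, predation, parasitism, a pesticide application —
that consume their input materials and produce their output materials in
fixed ratios per unit of *operating level*, up to a capacity bound. Because
the graph is bipartite, two processes can only interact through a shared
material, and two materials only through a shared process.

A *solution structure* is a subset of units, together with exactly the
materials incident to them, that satisfies the five structural axioms of
process network synthesis:

* **S1** every required product is represented in the structure;
* **S2** a material of the structure is an external input if and only if no
  unit of the structure produces it;
* **S3** every unit of the structure is defined in the problem;
* **S4** every unit has a directed path to a product;
* **S5** every material of the structure touches at least one of its units.

S5 holds by construction in `solution_structure()`; S3 is enforced as a
precondition; `check_axioms()` reports S1/S2/S4 violations. Products are
*optional by default*: S1 is evaluated against a caller-supplied
required-product set (default empty), so the empty "null" structure is a
legal configuration of an ecosystem in which nothing is demanded. This
matters for ecological use, where one output (here, the infestation level)
is an observable to be reported rather than a goal to be met.

## The algorithms

**MSG** (`msg()`) computes the maximal structure — the unique largest
sub-network containing every axiom-consistent structure — by fixed-point
pruning: delete units with no directed path to a product, units with an
input that is neither raw nor producible by the remaining units, and
materials left touching nothing; repeat to convergence. If a required
product is unattainable the problem is infeasible and the empty network is
returned with a warning.

**SSG** (`ssg()`) enumerates *all* solution structures by recursive decision
mapping. A frontier of materials awaiting production is processed in
lexicographic id order; for the next material the algorithm branches over
every admissible non-empty subset of its candidate producers (binary-counter
order), bans the rejected producers for the remainder of the branch, and
closes over the input requirements of newly admitted units. With optional
products the enumeration repeats over every subset of achievable products
and deduplicates. Determinism of the branching order gives a reproducible
structure numbering. A final axiom check guards every emitted structure.

**Flow LP** (`optimize_structure()`). For a fixed structure the operating
levels \(x_j \ge 0\) solve

\[
\max \sum_p w_p\, f_p \quad \text{s.t.}\quad
f_m = \sum_j (b_{mj} - a_{mj})\,x_j,\;
0 \le x_j \le \mathrm{cap}_j,
\]

with intermediate net flows \(f_m = 0\) (exact mode) or \(f_m \ge 0\)
(surplus mode, the default), product net flows \(\ge\) any required flow,
and raw materials drawn freely from outside. Surplus mode is the default
because ecological services can dissipate: a plant-health service consumed
by nothing in a particular configuration should not render that
configuration infeasible. The LP is solved by an internal dense two-phase
simplex with Bland's rule — deterministic, exact on these tiny systems
(at most a dozen variables and a few dozen rows), and validated in the test
suite against an independent solver.

**ABB** (`abb()`) ranks structures by best-first branch-and-bound over unit
include/exclude decisions. The bound at a partial decision is the LP with
all excluded units fixed at zero and everything else free in
\([0, \mathrm{cap}]\); completions only add exclusions, so the bound is
admissible, and an infeasible relaxation prunes the subtree. Ties in the
objective are broken lexicographically on the sorted unit-id set, which
keeps rankings reproducible; a consequence worth knowing is that a tie can
resolve to a structure carrying an extra unit at level zero when its id
sorts earlier. When neither a finite `n_best` nor a required flow can prune
anything, the search degenerates (by design) to exhaustive leaf
enumeration.

## The potato-CPB case study

The bundled model describes a potato farm threatened by invasion of the
Colorado potato beetle (CPB): 29 materials and 11 processes, 40 bipartite
nodes in all. The potato side couples reproduction (buds + vegetative
reproduction → foliage + plant health) to tuberization (foliage + health →
tuber yield). The pest side chains establishment of the invader → eggs →
larvae → pupae → adults → a reproducing population whose infestation
process consumes foliage. Control enters three ways: an egg parasitoid
(*Edovum puttleri*), an egg/larva/adult predator (*Oplomus dichrous*), and
thiamethoxam dosing, which delivers the control service while consuming the
pest's overall health *and* the health of both natural enemies (neonicotinoid
non-target toxicity).

### Rates

All rates are dimensionless fractions of the healthy-system optimum
(`potato_cpb_rates()`), in keeping with capacity-type fuzzy scores rather
than absolute population counts:

* `yield_loss = 0.8` — fraction of yield lost under a full uncontrolled
  infestation (anchored to the reported ~82% maximum loss figure);
* `max_infestation = 0.961538` — the infestation level the foliage can
  express at the tolerable-defoliation threshold; this is the one purely
  calibrated value, fixed once against the published uncontrolled-farm
  equilibrium;
* `parasitoid_egg = 0.9` — mean CPB egg mortality from parasitism/probing;
* `predator_egg/larva/adult = 0.6 / 0.27 / 0.1` — stage-specific
  consumption by the predator (0.97 of the cohort overall);
* `toxicity_cpb = 0.77`, `toxicity_enemy = 1` — thiamethoxam-induced
  mortality of the CPB and of either natural enemy.

### Objective and equilibrium convention

The case model maximises the *joint* terminal flows with weights
`{Tuber = 1, Level_of_Infestation = 1, Control = 0}`, and control scenarios
demand `Control >= 1` as a required flow rather than rewarding it. Two
modelling facts force this choice. First, the infestation level is an
outcome of pest pressure, not a management goal; giving it zero weight
would let the optimiser simply switch the pest off and report an uninfested
farm even with no control in place. Weighting it equally with yield (any
weight above the 0.8 yield-loss coupling behaves identically) makes the
pest run at its structural capacity — the LP optimum is then the
*adversarial equilibrium* of the configured ecosystem. Second, rewarding
control flow in the objective would favour stacking both biocontrol agents
for the extra service units even though the second agent adds no pest
suppression once the first is established; demanding the service instead
(deliver full control, then see what the ecosystem settles to) reproduces
the observed single-agent optima and the absence of any dual-agent gain.

### Scenarios

Scenarios gate which external inputs exist (`potato_cpb_scenarios()`).
Curative scenarios supply the pest's full life-cycle capacities before
control acts; preventative scenarios withhold the capacities that early
deployment denies the pest — everything past the egg stage for the egg
parasitoid, reproduction and infestation for the predator (whose prey
spectrum spans all stages), establishment's sequelae for pre-emptive
dosing. Ten scenarios (nine management narratives plus the null system)
yield ten distinct optimal structures; the enumeration of *all*
axiom-consistent sub-networks of the ungated maximal structure is larger,
as it also contains configurations no narrative selects (e.g. a parasitoid
released on a farm with no potato).

```{r}
suite <- run_all_scenarios()
suite$table[, c("SolutionStructure", "Tuber", "Level_of_Infestation", "Control")]
```

Reading the equilibria: predator biocontrol keeps yield at 0.976 with
infestation 0.03 — it outperforms the parasitoid (0.920 / 0.1) because it
attacks three life stages instead of one — and both dominate curative
chemical control (0.816 / 0.23), which additionally eradicates the natural
enemies it could have partnered with. Preventative action of any kind
preserves the full yield. The uncontrolled farm equilibrates at 23% of its
potential with near-maximal infestation.

## The synthetic instance generator

`generate_instance()` produces layered random networks (raws →
intermediates → products) with a planted chain of units that is guaranteed
axiom-consistent and produces every product; extra units and arcs are added
with probability `extra_arc_prob`, capacities are uniform on (0, 1], and
everything derives from one seed. The generator emulates the combinatorial
shape of synthesis problems — branching producer choices, dead-end units,
shared intermediates — which is what the enumeration and ranking algorithms
are sensitive to. It does not emulate ecological rate structure (no trophic
loops, no calibrated magnitudes), so passing its property tests validates
algorithmic correctness, not ecological realism, which is carried by the
case study.

Test problem sizes are kept at 3–12 units (where brute-force enumeration of
all unit subsets is an exact oracle) with 200 seeded instances in the
acceptance sweep and smaller sweeps elsewhere; these sizes make every
oracle comparison exact while keeping the default suite fast.

## Numerical choices and limitations

* LP tolerances: simplex pivot tolerance 1e-9; flow invariants asserted to
  1e-9; objective ties for ranking collapsed at 1e-9 before the
  lexicographic tie-break.
* Unbounded LPs (a unit with infinite capacity on an open objective path)
  are reported as an error asking for a capacity bound; the case model is
  fully bounded.
* Kind declarations (`raw`/`intermediate`/`product`) are validated at the
  network level (a declared raw may never be produced), while structure-level
  raw-ness is re-derived per S2; an unproducible non-raw input is a hard S2
  violation, which is what makes brute-force filtering and SSG agree.
* The framework is static: structures are equilibrium snapshots, with no
  population dynamics, no seasonality, and no spatial heterogeneity.
* Economic cost, alternate host plants, and climate-dependent rate
  modulation are out of scope; rates are scenario constants.
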