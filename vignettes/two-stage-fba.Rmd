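---
title: "Two-stage flux balance analysis for drug-target identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage flux balance analysis for drug-target identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmed)
```

## The model

Classic flux balance analysis (FBA) treats a metabolic network at steady
state: with the combined stoichiometric matrix $\mathbf{S}$ and flux vector
$\mathbf{v}$, it asks for $\mathbf{S}\mathbf{v} = 0$ under capacity bounds
and a linear objective. `fluxmed` works with a bipartite representation —
metabolites and reactions are both nodes — and augments the flux variables
with an explicit *mass flow* $x_i$ per metabolite $C_i$: the total rate at
which $C_i$ is turned over,

$$x_i \;=\; \sum_j s_{i,j}\, v_j \;=\; \sum_j t_{j,i}\, v_j,$$

where $s_{i,j}$ is the coefficient of $C_i$ as a reactant of reaction $R_j$
and $t_{j,i}$ its coefficient as a product. The consumption-side equality is
imposed for every metabolite that is consumed at all, the production-side
equality for every metabolite that is produced at all; for intermediates
both hold, which *is* the steady-state balance. Mass flows matter clinically
because healthy reference intervals (think blood levels) are naturally
stated per metabolite, not per reaction.

Two linear programs are then solved.

**Pathologic state.** After removing reactions whose catalyzing enzymes are
inhibited by the disease, maximize the weighted mass flow of biomass
metabolites,

$$\max \sum_i w_i x_i
\quad\text{s.t.}\quad
0 \le v_j \le U_j,\;\; 0 \le x_i \le q_i,$$

plus the mass-flow equalities above. The solution $(\mathbf{v}^0,
\mathbf{x}^0)$ describes the diseased system running at full tilt. The
disease-causing compounds are those whose $x^0_i$ falls outside a healthy
range $[a_i, b_i]$.

**Medication state.** Force each disease compound $i \in P$ into its range
(hard constraints $a_i \le x_i \le b_i$) and penalize every other ranged
metabolite $i \in N$ through goal-programming deviation variables
$d_i^+ \ge x_i - b_i$, $d_i^- \ge a_i - x_i$, $d_i^\pm \ge 0$:

$$\min \sum_{i \in N} \left(d_i^+ + d_i^-\right).$$

The optimum is the *side effect*: the smallest total excursion of healthy
metabolites that any medication achieving the cure must cause. A side effect
of zero means the disease is curable without collateral disturbance.
Healthy bounds are closed intervals; a published half-open range such as
$0 \le x < 1$ is representable in an LP only as $[0, 1]$, and that is how it
is modelled.

**Targets.** Reactions with $|v^1_j - v^0_j|$ above tolerance (absolute,
default $10^{-6}$; fluxes within one scenario share a scale) form a
subnetwork together with their reactants and products. Compounds that no
subnetwork reaction produces enter from outside the system and are deleted
in a single pass; the reactions left with no reactants are the *sources* of
the flux adjustment, and their enzymes are the reported drug targets. The
flux change $\Delta v_j$ is a dose proxy, signed: $\Delta v_j < 0$ calls for
inhibition, $\Delta v_j > 0$ for activation — the method itself is agnostic,
so the report labels the mode and interprets no further.
`verify_targets()` closes the loop: re-solving the pathologic program with
only the target fluxes pinned must reproduce the medication state's side
effect.

## Worked example

The bundled illustrative network has 12 metabolites and 8 reactions, biomass
weight 1 on C8, C9, C11, C12, and every flux capped at $U_j = 10$ with
uncapped mass flows:

```{r toy}
toy <- toy_network()
toy$network
```

One printed equation in the source of this example, R7, has the impossible
left side "C6 + 3 C6"; the unique stoichiometry under which every published
flux and mass-flow vector balances is `C6 + 3 C7 -> 2 C11 + 3 C12`, which
the fixture uses (C7 is otherwise produced but never consumed). This is a
deliberate, documented correction, not a silent fix.

```{r pipeline}
res <- fba_drug_targets(toy$network, toy$config, toy$scenario1)
res
```

C11 and C12 are the disease compounds (scenario 1 ranges: C9, C10, C11 in
[10, 15], C12 in [0, 1]). The pipeline reproduces the published analysis:
side effect $11/3 \approx 3.667$, carried entirely by C10 dropping to
$19/3 \approx 6.33$, and targets R2, R3, R4 with required fluxes 1, 0, 0.
Under the alternative ranges of scenario 2 the same targets cure with side
effect 0:

```{r scenario2}
res2 <- fba_drug_targets(toy$network, toy$config, toy$scenario2)
res2$medication$side_effect
res2$report$targets$reaction
```

## Numerical choices

**Engine.** Both programs are solved by a dense two-phase simplex with
Bland's smallest-index pivoting, implemented in the package. The problems
this method meets are small (tens of variables; a genome-scale pathway of a
few dozen reactions is still trivial for a dense tableau), and Bland's rule
buys two properties worth more than speed here: no cycling on the highly
degenerate optima these models produce, and bit-for-bit reproducible vertex
selection. Feasibility uses an artificial-variable phase 1; infeasible
disease ranges are then diagnosed by relaxing one hard range at a time and
naming the culprits. Solver tolerance is $10^{-9}$; all scientific
assertions in the test-suite are made at $10^{-6}$ absolute.

**Degenerate optima and the tie-break.** Both LPs routinely have alternate
optima (in the example, any $v_{R3} + 2 v_{R4} = 20$ is pathologically
optimal). A solution-set-preserving second stage fixes the objective at its
optimum and re-optimizes total flux $\sum_j v_j$ — by default *maximizing*
it, reporting the most active flux routing consistent with the optimum.
This choice reproduces the example's published vertices exactly on both
stages; the minimizing variant (sparsest routing) is available as
`tie_break = "min_total_flux"`, and `"none"` returns the raw simplex
vertex. Note that coordinates that are not unique at the optimum remain
convention-dependent under any tie-break; analyses should lean on the
unique ones (the package's tests check aggregates like
$v_{R3} + 2 v_{R4}$ for the degenerate pair). If the tie-break stage is
itself unbounded (possible when all $U_j = \infty$), the first-stage vertex
is returned unchanged.

**Redundant rows.** For intermediates, the pair of mass-flow equalities
already implies mass balance; an explicitly labelled balance row is still
kept in the LP description because it makes infeasibility reports readable,
but it is dropped before the engine, which does not pivot on dependent
equality rows.

**Medication degeneracy.** When the side-effect optimum is 0, the
medication state is essentially unconstrained among cures, and the
tie-broken vertex need not resemble the pathologic state.
`solve_medication(maximize_biomass = TRUE)` inserts a lexicographic
biomass-maximization stage between the side-effect optimum and the flux
tie-break — a multi-objective extension that anchors the medication state
to the most productive cure. It is off by default because the core method
defines the medication state by side effect alone.

## The synthetic-network generator

Property-style tests need a stream of solvable instances.
`generate_network()` builds layered acyclic networks: metabolites are
partitioned into layers, each reaction consumes 1–3 metabolites from one
non-final layer and produces 1–3 in strictly later layers, with integer
coefficients (default 1–3) and a common flux cap (default 10, matching the
worked example's scale). Layer construction makes the bipartite digraph
acyclic, so a strictly positive flux exists; this is still verified by
solving the pathologic LP and resampling on failure.
`plant_disease_scenario()` then marks the busiest sink as disease-causing
with a healthy range at 50% of its pathologic flow — mirroring how the
worked example was built — and derives a ground-truth superset of
admissible targets by reverse reachability from the disease compound to
the network's source reactions.

What the generator does *not* emulate: reversible loops, currency
metabolites shared across the whole network, realistic degree
distributions, or compartments. Green property tests therefore demonstrate
correctness of the optimization and graph machinery on well-posed acyclic
instances, not biological fidelity on genome-scale reconstructions. Tests
run the generator at 9–11 metabolites and 6–8 reactions with fixed seeds —
comfortably inside the regime where every optimum can be cross-checked
independently.

## Degenerate and edge inputs

* Exchange reactions may have an empty side; a reaction empty on both sides
  is rejected.
* Reversible reactions are split into `_fwd`/`_bwd` pairs before any matrix
  is built; the split is idempotent.
* Isolated metabolites are kept (with a warning) and pinned to $x_i = 0$,
  tolerating partially curated pathway files.
* Duplicate metabolite terms within one side of an equation are summed;
  coefficients may be any positive reals, since lumped reactions produce
  fractional stoichiometry and the LP treats them uniformly.
* An inhibited enzyme matching no reaction warns rather than errors.
* Metabolites without a healthy-range entry behave as $[0, \infty)$ and
  contribute nothing to the side effect.

## Limitations

The method reasons in mass flows, not concentrations: it identifies where
flux must change and by how much, and leaves the mapping from $\Delta v$ to
physical dose to enzyme-kinetic or pharmacokinetic modelling. Target sets
inherit the non-uniqueness of LP optima — a different tie-break can yield a
different (equally optimal) medication state and hence a different changed
set; the reported one is reproducible, not exclusive. Pruning is the
single-pass rule by design (`iterative_prune = TRUE` exposes the fixed-point
variant). SBML, compartments and gene–protein–reaction rules are out of
scope; the interchange formats are the flat reaction TSV and the YAML
scenario file.
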