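# fluxmed — two-stage FBA for drug-target identification

`fluxmed` finds candidate drug targets in metabolic networks for
*non-pathogenic* diseases — metabolic disorders where therapy must adjust
the patient's own enzymes rather than kill a pathogen. It is aimed at
systems-biology and computational-pharmacology users who have a curated
reaction list for a disease-related pathway and clinically motivated
healthy ranges for key metabolites.

## The method

A network of $m$ metabolites and $n$ irreversible reactions is held as a
bipartite digraph with reactant matrix $S = [s_{i,j}]_{m\times n}$ and
product matrix $T = [t_{j,i}]_{n\times m}$. Besides the usual fluxes
$v_j$, every metabolite carries a mass flow
$x_i = \sum_j s_{i,j} v_j = \sum_j t_{j,i} v_j$ (both equalities hold for
intermediates, which enforces steady state). Two LPs are solved:

1. **Pathologic LP** — after deleting reactions whose enzymes the disease
   inhibits, maximize $\sum_i w_i x_i$ (weights on biomass metabolites)
   subject to $0 \le v_j \le U_j$, $0 \le x_i \le q_i$ → state
   $(\mathbf v^0, \mathbf x^0)$.
2. **Medication LP** — force each disease-causing compound $i \in P$ into
   its healthy range $a_i \le x_i \le b_i$ and minimize the **side
   effect** $\sum_{i\in N}(d_i^+ + d_i^-)$, the summed deviation of all
   other ranged metabolites from their healthy ranges
   ($d_i^+ \ge x_i - b_i$, $d_i^- \ge a_i - x_i$) → state
   $(\mathbf v^1, \mathbf x^1)$.

Reactions with $v^1_j \ne v^0_j$ (beyond tolerance) form a subnetwork;
after deleting compounds the subnetwork does not produce, the reactions
left without reactants are the sources of the adjustment: their enzymes
are the drug targets, and $\Delta v_j = v^1_j - v^0_j$ is a dose proxy.
`verify_targets()` re-solves the pathologic LP with only those fluxes
pinned and confirms the same side effect.

## Worked example

The bundled 12-metabolite / 8-reaction network (`toy_network()`) has
biomass weights 1 on C8, C9, C11, C12 and all flux caps at 10. One caveat
baked into the fixture: the published form of reaction R7 ("C6 + 3 C6 →
…") is stoichiometrically impossible; the fixture uses the unique
correction `C6 + 3 C7 -> 2 C11 + 3 C12` under which every published flux
and mass-flow vector balances exactly (see `?toy_network`).

```r
library(fluxmed)
toy <- toy_network()
res <- fba_drug_targets(toy$network, toy$config, toy$scenario1)
res
#> Two-stage FBA drug-target analysis
#> pathologic objective: 91.25
#> Drug-target report
#>   side effect: 3.667
#>   changed reactions (6): R2, R3, R4, R6, R7, R8
#>   targets:
#>     R2  required flux 1  (dv -2.75, inhibition)  enzymes: E2
#>     R3  required flux 0  (dv -10, inhibition)  enzymes: E3
#>     R4  required flux 0  (dv -5, inhibition)  enzymes: E4
#>   verification: side effect 3.666667, disease ranges met
```

Scenario 1 declares C11 and C12 disease-causing (healthy ranges: C9, C10,
C11 in [10, 15], C12 in [0, 1]). Reading the output: the diseased optimum
produces biomass mass flow 91.25 with C11 at 22.5 and C12 at 33.75, both
out of range. The cheapest cure drives them to 13.33 and 1 by adjusting
the fluxes of R2, R3, R4 down to 1, 0, 0 — at the cost of C10 falling to
6.33, i.e. a total side effect of 11/3 ≈ 3.667. Re-solving with only
those three fluxes fixed reproduces the same side effect, confirming the
three enzymes suffice. Under scenario 2's ranges the same targets cure
with side effect 0:

```r
res2 <- fba_drug_targets(toy$network, toy$config, toy$scenario2)
res2$medication$side_effect
#> [1] 0
```

Models can also come from files: a reaction TSV
(`reaction_id  equation  enzymes  flux_upper`, see
`inst/extdata/toy_network.tsv`) and a YAML scenario
(`inst/extdata/toy_scenario1.yaml`) read by `read_network()` /
`read_scenario()`. A command-line front end with `pathologic`,
`medication`, `targets`, `pipeline` and `fixtures` subcommands lives at
`inst/cli/fluxmed.R`.

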