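# auxoDesign

Constraint-based design of **auxotrophy-dependent microbial biosensors**
and **growth- or proxy-coupled chemical-producing strains** on metabolic
network models.

Combinatorial metabolic engineering screens mutant libraries for strains
that over-produce a chemical; for most chemicals there is no cheap readout.
A biosensor strain solves this: an engineered auxotroph whose growth in a
producer's spent medium reports the chemical's concentration. For the
readout to be trustworthy the sensor must be *ultra-auxotrophic* for the
sensed chemical C — able to grow on a reference medium M plus C, and unable
to grow on **any** medium lacking C, even one containing every other
nutrient the organism can import (ordinary auxotrophs often escape through
salvage routes, e.g. tryptophan auxotrophs growing on indole).

Given a model with stoichiometric matrix *S*, flux bounds and a biomass
reaction (steady state *S·v = 0*, *lb ≤ v ≤ ub*), the package searches for
a reaction-knockout pattern *y* (at most *k* zeros) via a bi-level program:

* **outer**: max growth on M∪{C} over *y* and a flux vector satisfying the
  knockout bounds *lb·y ≤ v ≤ ub·y*;
* **inner**: the maximal growth on rich-minus-C under the same *y* must be
  (numerically) zero.

The inner level is replaced by its LP dual with big-M linearization of
dual-times-binary products, giving a single MILP solved with GLPK. The same
machinery yields the strain-design family: **OptKnock** (max target
secretion at growth-optimal flux, via strong duality), **RobustKnock**
(max–min guaranteed secretion over alternative growth optima, via a second
dualization), and **OptKnock-proxy / RobustKnock-proxy**, which couple a
target chemical to the secretion of a *proxy* metabolite that has a
biosensor, instead of to biomass. Alternative optimal knockout sets are
enumerated with integer cuts, and every design is re-verified by plain FBA
solves independent of the MILP.

## Worked example

A synthetic network with one synthesis route to the sensed chemical C plus
an importable salvage precursor — the motif that defeats classic
auxotrophs:

```r
library(auxoDesign)
net <- generateToy(toySpec(routes = 1, salvage = TRUE, motif = "bypass",
                           decoys = 1, seed = 3))
sensor <- designBiosensor(net, "C", mediumKind = "minimal", k = 3)
sensor
#> BiosensorDesign for C [minimal medium]
#>   knockouts:       PRD, SYN1, TP
#>   growth with C:   10
#>   growth without C: 0
#>   verified:        TRUE
```

All three C-producing reactions must go — the two synthesis routes *and*
the salvage transporter; with `k = 2` the search is infeasible (a single
cut leaves a strain that still grows on rich medium without C). `growth
with C` (10, the full C uptake) is confirmed by an independent FBA solve,
as is the zero growth without C. `yieldSensitivity(net, sensor)` classifies
this sensor as yield-insensitive: its biomass per unit C is identical under
poor and rich supplementation, so biomass reads out concentration directly.

Producer-strain design on a network where a C-only route and a
target-co-producing route tie for optimal growth:

```r
producer <- generateToy(toySpec(routes = 1, motif = "bypass", seed = 14))
med <- makeMedium(producer, "minimal", carbonSource = "A",
                  defaultUptake = 8)
robustKnock(producer, "D", med, k = 0)   # wild type
#> CouplingDesign: D coupled to biomass
#>   knockouts:       (none)
#>   max rate:        8
#>   guaranteed rate: 0
robustKnock(producer, "D", med, k = 1)
#> CouplingDesign: D coupled to biomass
#>   knockouts:       SYN1
#>   max rate:        8
#>   guaranteed rate: 7.999999
#>   growth floor:    0.1
```

The wild type *can* secrete 8 units of D at optimal growth but guarantees
nothing (an alternative optimum secretes none). Knocking out the C-only
route forces growth through the co-producing reaction: 8 units of D per
unit time are now guaranteed at any growth-optimal flux distribution,
while biomass stays above the 0.1 viability floor.

Every design method is checked against exhaustive oracles
(`bruteForceBiosensor()`, `bruteForceCoupling()`) that enumerate all
knockout subsets with nested FBA solves.

A thin command-line wrapper ships in `inst/scripts/auxodesign.R`
(subcommands `design-biosensor`, `enumerate`, `verify`, `sensitivity`,
`optknock`, `robustknock`, `optknock-proxy`, `robustknock-proxy`,
`matrix`, `toygen`); every run writes a `resolved_config.yaml` from which
it can be reproduced exactly.

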