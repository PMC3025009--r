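---
title: "Designing ultra-auxotrophic biosensors and growth-coupled producer strains"
author: "auxoDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ultra-auxotrophic biosensors and growth-coupled producer strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxoDesign)
```

## The problem

Combinatorial metabolic engineering screens large mutant libraries for
strains that secrete a chemical of interest. Most chemicals have no easily
detected signature, so screening is the bottleneck. One way around it is a
*biosensor strain*: an engineered auxotroph whose growth depends on the
presence of the chemical, so that the biomass it accumulates in a producer's
spent medium reports the chemical's concentration.

Ordinary auxotrophy is not enough. A strain that cannot synthesize chemical
$C$ may still grow without $C$ by importing a precursor and converting it
(tryptophan auxotrophs, for instance, can grow on indole). A usable sensor
must be **ultra-auxotrophic**: it grows on a reference medium $M$
supplemented with $C$, and it cannot grow on *any* medium lacking $C$ — even
one containing every other nutrient the organism can take up. This package
finds knockout sets that enforce ultra-auxotrophy on a constraint-based
metabolic model, and extends the same machinery to growth-coupled and
proxy-coupled production-strain design (the OptKnock / RobustKnock family).

## The constraint-based model

A metabolic network with $n$ metabolites and $m$ reactions is described by
its stoichiometric matrix $S \in \mathbb{R}^{n\times m}$. A steady-state
flux vector $v \in \mathbb{R}^m$ (mmol gDW$^{-1}$ h$^{-1}$) satisfies

$$ S\,v = 0, \qquad lb \le v \le ub, $$

where the bounds encode irreversibility ($lb_j = 0$), enzyme capacity, and
medium composition: each exchange reaction carries one metabolite across the
system boundary, with uptake as negative flux (bounded below by minus the
uptake capacity) and secretion as positive flux. Flux balance analysis (FBA)
maximizes one flux — typically the biomass drain $v_{\text{gr}}$ — over this
polytope.

A knockout pattern is a binary vector $y$ over candidate reactions
($y_i = 0$: knocked out), constrained by a budget
$\sum_i (1-y_i) \le k$; a knocked-out reaction has both bounds forced to
zero ($lb_i\,y_i \le v_i \le ub_i\,y_i$). Candidates exclude exchange
reactions (removing a boundary flux is a medium change, not a mutation) and
the biomass reaction.

## The bi-level design programs

**Biosensor (ultra-auxotrophy).** Find $y$ and an outer flux vector $v$
maximizing growth on $M \cup \{C\}$, subject to: the *inner* problem —
maximal growth of a flux vector $u$ under the same $y$ on rich-minus-$C$
(every transportable nutrient open except $C$) — attains at most zero.

**OptKnock sense.** Find $y$ maximizing target secretion $v_{\text{EX}_d}$
where $v$ must be an optimum of the inner objective (growth for
OptKnock, proxy secretion for OptKnock-proxy) under a biomass viability
floor. This is the *optimistic* value over alternative inner optima.

**RobustKnock sense.** Maximize over $y$ the *minimum* of target secretion
over all inner-optimal flux vectors — the guaranteed rate.

### Single-level reformulation

All three shapes are reduced to one mixed-integer linear program by LP
duality, built from a single generic dualization routine:

* Each level's LP is held with its knockout-dependent bounds as rows whose
  right-hand side is affine in $y$. Dualizing gives dual-feasibility rows
  plus a dual objective containing products $w\,y$ of duals and binaries,
  which are linearized exactly with auxiliary variables bounded by a big-$M$
  box ($w \in [-M, M]$, default $M = 1000$, which must dominate every
  attainable flux magnitude; checked at build time).
* *No-growth cap*: by weak duality, the existence of a dual-feasible point
  with dual objective $\le \varepsilon$ forces the inner maximum below
  $\varepsilon$; no inner primal variables are needed at all.
* *Inner-optimality*: the shared primal $v$ plus dual feasibility plus the
  row $c^\top v \ge$ (dual objective) pins $v$ to the inner-optimal face
  (the reverse inequality is weak duality, hence automatic).
* *Guaranteed sense*: the minimization of target secretion over that pinned
  face — an LP in $(v, \text{first-stage duals})$ for fixed $y$ — is
  dualized a second time with the same routine; maximizing the negated
  second dual objective jointly over $y$ yields the max–min value. The MILP
  additionally carries a primal feasibility copy of the flux LP, so
  patterns that cannot meet the viability floor are excluded by constraints
  rather than mispriced by box-capped duals.

### Verification and enumeration

Duality-based MILPs have two classic failure modes: a dual optimum outside
the big-$M$ box, and (for the max–min shape) infeasible level problems that
bounded duals price arbitrarily. The package therefore never reports a MILP
value directly:

* every biosensor design is re-checked by two independent FBA solves
  (growth on $M \cup \{C\}$, growth on rich-minus-$C$), and every coupling
  design is re-scored by nested FBA (inner optimum, then best and worst
  target secretion on its face);
* a pattern whose MILP value disagrees with its FBA score is excluded by an
  integer cut and the MILP re-solved, until the MILP bound meets the best
  verified pattern.

Alternative optimal knockout sets are enumerated the same way: after each
returned design, an integer cut
$\sum_{i \in K} y_i + \sum_{i \notin K} (1-y_i) \ge 1$ removes exactly that
pattern. Iterating to infeasibility enumerates the full feasible design set,
which on small instances provably equals exhaustive enumeration (the
regression suite checks this on a 20-network battery).

Among maximal-objective patterns the search prefers the fewest knockouts
(a second solve with the objective pinned and $\sum_i y_i$ maximized).
Remaining ties between equally small, equally good sets are broken by the
solver; enumeration is the deterministic way to obtain all optima.

## Yield sensitivity of a sensor

The biomass a sensor accumulates converts chemical concentration into
signal. With rich supplementation the conversion factor is fixed, but under
a minimal base medium the producer's other secreted metabolites can change
the sensor's biomass yield per unit $C$. `yieldSensitivity()` fixes the $C$
uptake on a grid (default 10 points up to the uptake bound), maximizes
growth under (a) minimal and (b) rich supplementation, and compares the two
yield curves pointwise. Both curves pass through the origin (the strain is
ultra-auxotrophic), are nondecreasing and concave (LP monotonicity in a
relaxed bound). A sensor is *insensitive* — reliable even in poor spent
medium — when the yields agree within 1% relative tolerance (the literature
reports the dichotomy without a threshold; 1% separates the exactly-equal
case from genuine saturation effects).

## Numerical choices

* **Solver.** All LPs and MILPs are written in CPLEX LP format and solved
  with the GLPK command-line solver (`glpsol`), which is free, exact for
  these problem sizes, and deterministic. Per-solve overhead is ~3 ms.
* **Zero growth** means dual objective $\le$ `zeroTolerance` ($10^{-6}$ in
  flux units; exact zero is unattainable in floating point). The cap row is
  rescaled to unit coefficient magnitude — mixing $10^{-6}$ right-hand
  sides with big-$M$ coefficients destabilizes MIP preprocessing — and a
  scaled cap below the solver's feasibility tolerance is posed as exactly
  0, with the solver's row tolerance providing the effective epsilon. The
  two-FBA verification then re-checks no-growth against `zeroTolerance`
  independently.
* **Viability.** A biosensor must reach growth $\ge 10^{-3}$ with its
  chemical present (`growthThreshold`; "maximal growth" alone could accept
  biologically meaningless designs). Coupling designs enforce biomass
  $\ge$ `minGrowth` (default 0.1, the conventional threshold of
  growth-coupled design methods) on the shared flux vector, hence at both
  levels.
* **Big-M certification.** Flux magnitudes and the value of the inner dual
  objective are certified to stay inside $0.99\,M$. Raw dual variables on
  degenerate rays (zero objective contribution) may legitimately sit on the
  box; they carry no information, and the FBA verification loop, not the
  dual values, establishes correctness of accepted designs.
* **Inner-optimal face.** The nested-FBA scorer fixes the inner optimum
  with an absolute-plus-relative slack of $10^{-7}$; with the small-integer
  stoichiometry used throughout the test fixtures this slack is far below
  the spacing of distinct optima.
* **Media.** A minimal medium opens the core-nutrient set declared by the
  model plus one carbon source; a rich medium opens every transportable
  chemical (a metabolite with both an exchange reaction and an interior
  connection). Opened exchanges default to 10 mmol gDW$^{-1}$ h$^{-1}$
  uptake, the de-facto convention for genome-scale E. coli models.

## The synthetic-network generator

`generateToy()` emits small networks with planted structure, the basis of
every regression battery:

* one or more parallel synthesis routes from the carbon source to the
  sensed chemical $C$ (the minimal biosensor cut must sever all of them);
* optionally an importable salvage precursor with a transport reaction into
  $C$ — the motif that makes classic auxotrophs fail ultra-auxotrophy and
  forces a double knockout (the tryptophan/indole situation);
* production motifs for a target $D$ and proxy $X$: a `coproduct` motif
  (one reaction emits both — hard-wired coupling) and a `bypass` motif
  (a $C$-only route that knockouts can divert into a co-producing route,
  plus a proxy-only branch competing with a target-plus-proxy branch);
* inert decoy branches that enlarge the candidate set without changing the
  answers.

Capacities are small integers (3–9) derived arithmetically from the seed,
so networks are bit-identical across platforms and oracle comparisons are
free of float sensitivity. `bruteForceBiosensor()` and
`bruteForceCoupling()` solve the same design problems by exhaustive subset
enumeration over plain FBA solves (refusing more than 15 candidates); they
share no code path with the MILP beyond the LP solver itself.

What the toys do **not** emulate: compartments, cofactor and energy
balancing, thousands of coupled reactions, alternate optima arising from
large degenerate subnetworks, and non-integer stoichiometry (biomass
equations in genome-scale models). Passing the battery therefore
establishes the algebraic correctness of the reformulations and the design
logic, not numerical robustness at genome scale, where looser tolerances
and a larger `bigM` (the genome-scale bound convention is 1000, so `bigM`
must exceed it) are expected to matter.

## Problem sizes in the shipped suites

The regression and acceptance batteries use 20 seeded networks of 8–14
reactions with up to 9 knockout candidates, budgets $k \le 3$ for the
biosensor enumeration and $k \le 2$ for the coupling oracles (exhaustive
enumeration over $\binom{9}{\le 2}$ subsets with three LP solves each).
The full suite runs in well under a minute on one core; these sizes were
chosen so the exhaustive oracles remain exact rather than sampled.

## Known limitations

* Knockouts are at reaction level; gene–protein–reaction rules are carried
  for reporting only, so one "knockout" may require several gene deletions
  or hit shared enzymes.
* The guaranteed (max–min) MILP bound can in principle *under*-estimate if
  every dual optimum lies outside the big-$M$ box; the verify-and-cut loop
  detects over-estimates exactly but under-estimates only through the
  oracle batteries. Increase `bigM` if designs seem to vanish at genome
  scale.
* Enumeration to exhaustion is exponential in the feasible design count;
  use `maxAlternatives` on large models.
* FBA's usual caveats apply: predictions are stoichiometric potentials,
  silent on kinetics and regulation.
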