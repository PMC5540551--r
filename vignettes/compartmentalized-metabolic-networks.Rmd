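---
title: "Methods: compartmentalized metabolic networks at metagenome scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmentalized metabolic networks at metagenome scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacomp)
```

## The modeling problem

A soil (or any environmental) microbial community can be modeled as a single
*meta-organism*: one genome-scale metabolic network pooling every reaction
annotated in the metagenome, with no boundaries between member organisms.
Because such communities contain eukaryotes, the meta-organism is
*compartmentalized*: species and reactions are assigned to the cytoplasm
(`c`), mitochondrion (`m`), nucleus (`n`), peroxisome (`x`) and the
extracellular space (`e`), connected by transport reactions, with exchange
reactions linking the extracellular pool to the environment. The same
metabolite in two compartments is two distinct species (`NAD@c` and `NAD@m`
are different nodes, different matrix rows, different dead-end candidates).

`metacomp` implements the five analysis stages downstream of annotation:

1. **Reconstruction** — assemble the draft from reaction/metabolite tables,
   remove reactions containing *generic* compounds (DNA, RNA, proteins,
   glycans, unspecified lipids: anything without a fixed elemental formula),
   verify elemental/charge balance with automatic proton–water repair, and
   set reaction directionality from the standard transformed Gibbs energy.
2. **Compartmentalization** — consensus localization from CELLO-style
   probability scores and reference compartmentalized models, pruning of
   negligibly supported compartments, per-compartment duplication of
   reactions and species, and injection of transport/exchange templates.
3. **Curation** — dead-end (non-produced / non-consumed) species detection
   as a mixed-integer program, and minimal gap filling from a candidate
   reaction database, in the three-step compartmentalized order.
4. **Flux balance analysis** — maximize a biogeochemical objective
   `Z = c'v` subject to `S v = 0` and bounds.
5. **Topology** — metabolite-graph metrics, power-law degree exponents, and
   centrality/PCA ranking of metabolites.

All optimization (LP and MILP) is solved with the HiGHS solver from scipy,
driven through reticulate; HiGHS is deterministic for a fixed problem, which
keeps gap fills and flux distributions reproducible.

## Reconstruction conventions

* Metabolite charges and formulas refer to an intracellular pH of 7.2; the
  package consumes them as given and never recomputes protonation states.
* Balance checking computes the net elemental vector and net charge of each
  reaction. An imbalance expressible as an integer combination of H⁺ and
  H₂O (the two species most often omitted from database equations) is
  repaired automatically and recorded; anything else is flagged
  `unbalanced` but retained — dropping reactions silently would bias every
  downstream stage. A `strict` mode drops them. One-sided exchange
  reactions are boundary pseudo-reactions and are reported as `boundary`,
  not checked.
* Directionality: reactions without a Gibbs energy are reversible (bounds
  −1000 to 100 mmol gDW⁻¹ h⁻¹); `ΔrG′ ≤ −T` makes a reaction irreversible
  forward (0 to 100); `ΔrG′ ≥ +T` flips the written orientation and then
  makes it irreversible. The threshold `T` defaults to 30 kJ/mol — a common
  working cutoff for calling thermodynamic irreversibility — and is
  configurable because no single published value is canonical. Only
  metabolic reactions are touched: transport and exchange reactions carry
  no thermodynamic annotation and keep their constructed directionality.

## Compartment assignment

The consensus rule is a union: a reaction is assigned every compartment
whose localization score reaches `min_score` (default 0.3) **plus** every
compartment any reference model places it in. An empty union falls back to
the top-scoring compartment, ties broken by the fixed priority
c > m > n > x > e. Union semantics is deliberately permissive: in a
community, homologous enzymes from different members genuinely occupy
different compartments, and a false extra copy is cheaper than a false gap
(a wrongly missing reaction creates dead ends; a wrongly duplicated one is
pruned by flux analysis).

Compartments attracting fewer than `min_reactions` reactions (default 25)
are discarded — at metagenome scale a compartment supported by a handful of
reactions is an annotation artifact, and keeping it would only manufacture
gaps. Their reactions are reassigned to the best-scoring surviving
compartment (fallback: cytoplasm). The cytoplasm and extracellular space
can never be pruned, as they anchor exchange with the environment.

Transport/exchange templates are injected only when *every* species they
reference already exists in the network: injection never invents
metabolites. Injected templates default to reversible unless written
otherwise, since curated transport collections rarely annotate direction
per carrier.

## Dead-end detection: the MILP and its semantics

A species is **producible** when it can be reached from the uptake boundary
by a chain of reaction firings, each of whose substrates is itself
producible, with every production event carrying at least `ε` flux under
accumulation-relaxed mass balance (`Σⱼ Sᵢⱼ vⱼ ≥ 0`). **Consumability** is
the same property on the direction-reversed network. A dead end is a
species that fails either test.

The MILP (one per direction) has flux variables `v`, a binary producer
indicator `w_t` per (species, producing reaction) pair, a binary `x_i` per
species, and a continuous certification level `ℓ_i ∈ [0, |species|]`:

* `Σⱼ Sᵢⱼ vⱼ ≥ 0` (accumulation allowed),
* `Sᵢⱼ vⱼ ≥ ε − M(1 − w_t)` (an active producer carries at least ε;
  `ε = 0.001`, `M = 1000` by default, with the per-term big-M widened when
  bounds and coefficients require it),
* `w_t ≤ x_s` for every substrate `s` of the producing direction,
* `ℓ_i ≥ ℓ_s + 1` whenever `w_t` certifies `i` (big-M linearized),
* `x_i ≤ Σ_t w_t`, maximize `Σ x_i`.

The level variables make the certification relation acyclic. Without them,
a flux-only formulation certifies any self-sustaining internal cycle (two
reactions converting A to B and back can carry ε flux at steady state with
no connection to the boundary), and "producible" would depend on cycle
structure in a way that is neither intended by dead-end analysis nor
checkable by an independent method. With them, the MILP's producible set
equals, by construction, the seeded fixpoint closure that
`gapfind_reachability()` computes in pure R — which is exactly what makes
the dual-route equivalence test in the suite meaningful rather than
circular: two implementations of one well-defined semantics, one algebraic
and solver-based, one combinatorial.

Two implementation notes. First, the block builder applies logical
presolve: the `w → x` implication closure is propagated once and every
indicator outside it is fixed to zero. This is ordinary MILP domain
propagation (the solver still certifies optimality of the reduced problem)
and turns pathological instances — e.g. proving that *nothing* is
consumable in a network with many cycles — from minutes into milliseconds.
Second, a tiny parsimony penalty on `Σ w` breaks ties between equivalent
certification forests so the solver does not enumerate them.

The ε-flux layer means a certification chain must be realizable within the
bounds; with pathway depths and stoichiometric coefficients in realistic
ranges (`M/ε = 10⁶` of headroom) this never binds, but extremely long
chains of strongly contracting stoichiometry could in principle make the
MILP stricter than the combinatorial closure.

## Gap filling

Given dead-end targets and a candidate database, the fill MILP couples a
production block and a consumption block (reversed network) through shared
binary selection variables `y_r`, requiring each target to become *both*
producible and consumable — resolving only one half would merely move the
dead end. Per-target solutions minimize `Σ y_r`; ties between equally small
fills are broken lexicographically by reaction id through an infinitesimal
preference term. Exhaustive subset search (`gapfill_exhaustive()`) certifies
minimality on small instances. Batch mode maximizes the number of resolved
targets first and parsimony second (weight `|db| + 1` per target, so no
amount of parsimony sacrifices a resolvable target); compartment batches
keep metagenome-scale runs tractable where per-target MILPs would not be.

`curate_compartmentalized()` runs the three-step order: (1) fill
cytoplasmic gaps from the database; (2) add cytoplasm–inner exchange
reactions (database transport templates whose species all exist, plus
automatic `m@c ⇌ m@K` templates) — most inner-compartment gaps are copies
of metabolites the cytoplasm can already make, so an exchange is the
correct one-reaction fix; (3) fill each remaining compartment separately
with the database instantiated in that compartment. The search space is
candidate database plus exchange templates only; relaxing the
directionality of existing reactions is deliberately excluded from the
repertoire. Reconnection percentages are reported over the pre-curation
species universe so before/after are comparable.

## Flux balance analysis

Bounds follow the policy (0, 100) for irreversible and (−1000, 100)
mmol gDW⁻¹ h⁻¹ for reversible reactions; `build_problem()` keeps stored
per-reaction bounds by default (so capacity overrides survive) and can
re-apply a policy wholesale. Objectives are biogeochemical: the shipped
template library covers nitrogen-cycle, sulfur-cycle, TCA-related and
fatty-acid-elongation reaction blocks, written in the package's equation
dialect; multi-reaction objectives use unit weights. The generic electron
acceptor written as "A" in some templates maps to oxidized ferredoxin by
default and is overridable. `exclude_reactions()` (bounds forced to zero)
is the knockout primitive used for the compartment-coupling experiments.

Under degenerate alternative optima the active-flux census is
solver-dependent, so `solve_fba(stabilize = TRUE)` adds a second stage that
fixes `Z` and minimizes `Σ|v|`, making active-flux fractions reproducible.
The activity tolerance defaults to 1e-6, the LP noise floor.

The toy fixtures encode the two compartment-coupling phenomena at
mechanism level. In `toy_fatty_acid_model()` mitochondrial elongation
consumes acetyl-CoA produced only in the cytoplasm; excluding the
`TACOA` transport forces the objective to zero. In `toy_tca_model()`
citrate synthesis runs in both compartments with per-compartment enzyme
capacity 1, cytosolic precursor routes of capacity 2, and at most one unit
of pyruvate entering the mitochondrion; the optima order strictly as
with-exchanges (2) > without-exchanges (1.5) > flattened single-copy
build (1). Only this ordering is a claim — the magnitudes are properties
of the chosen toy capacities, not of any real community.

## Topology

The metabolite graph has one node per species and a directed edge from
every substrate to every product of each reaction (both directions for
reversible reactions; one-sided exchanges contribute no edge). Currency
metabolites are retained: protons, water and ATP are precisely the hubs
whose connectivity the degree exponents describe. Degree counts parallel
links from different reactions separately — `P(k)` is the probability that
a metabolite takes part in exactly `k` incoming (or outgoing) conversions —
while clustering and path metrics use the collapsed simple graph, and the
"edge count" centrality keeps multiplicities.

The discrete power-law exponent is estimated by maximum likelihood under
the zeta-normalized model on `k ≥ k_min` (default 1), with a log–log
regression slope and its r² reported as diagnostics. Path metrics are
averaged over reachable ordered pairs (metagenome graphs are not strongly
connected); the radius takes the minimum eccentricity over nodes with full
reach, falling back to the largest strongly connected component.
Metabolite ranking combines in/out degree, edge count, betweenness and the
absolute species loading on the first two principal components of the
column-centered (unscaled) stoichiometric matrix, by mean rank —
unit-variance scaling would flatten exactly the hub structure the PCA is
meant to surface.

## The synthetic generator

The generator fabricates the full input bundle with recorded ground truth:

* **Chemistry**: metabolites share one monomer formula (CH₂O, charge 0)
  and core reactions are unit conversions, so every non-generic reaction is
  exactly mass- and charge-balanced by construction and the balance checker
  can be held to a zero-imbalance standard.
* **Connectivity**: a spine gives every metabolite a producer rooted in an
  uptake exchange, and one secretion outlet per terminal strongly connected
  component of the conversion digraph guarantees every metabolite can be
  drained — the baseline draft has no dead ends, so every dead end observed
  after `plant_gaps()` is attributable to the removal key.
* **Degree structure**: per-node in/out degree budgets are drawn from
  discrete power laws with the target exponents `γ_in`, `γ_out`. A digraph
  forces equal mean in- and out-degree, so the heavier-tailed side is
  truncated at the cutoff equalizing the two means — the standard
  finite-size reconciliation of unequal exponents. With
  `n_reactions = NULL` the sampled budgets determine the reaction count and
  the realized degrees follow the planted laws without thinning; exponent
  recovery studies use that mode with irreversible conversions, because a
  reversible conversion adds a reverse edge and mixes the two
  distributions, leaving neither exponent independently plantable. Planted
  exponents (1.8 in, 2.0 out) are recovered within ±0.15 at 2000
  metabolites across seeds.
* **Gap planting** removes reactions whose removal provably induces new
  dead ends (verified by the reachability closure), preferring localized
  cascades so no single removal blankets the network; the removed set is
  the recovery key and, with decoys, the candidate database.
* **Localization scores** are Dirichlet draws concentrated on the
  ground-truth compartment (concentration 25 by default — informative but
  noisy, with occasional off-target argmax as in real subcellular
  predictors); reference assignments cover 30% of reactions; the
  compartment mixture is cytoplasm-dominated (72/17/7/4%), matching the
  usual prokaryote-heavy ranking c ≫ m > n > x.

What the generator does **not** emulate: real stoichiometric diversity
(cofactor coupling, multi-substrate reactions), annotation noise (wrong EC
assignments, fragmented genes), shared currency hubs, or taxonomic
structure. Passing the suite therefore demonstrates algorithmic
correctness — solver-oracle agreement, minimality, recovery of planted
structure — not that any biological conclusion drawn from a real
metagenome would be right.

## Problem sizes and runtime choices

The suite exercises: solver-versus-oracle agreement on 100 random networks
of 15–40 reactions; fill minimality on planted instances with ≤ 12
candidates (exhaustive certification); full compartmentalized curation at
500 reactions; exponent recovery at 2000 metabolites × 10 seeds; LP-versus-
vertex-enumeration on ≤ 8-reaction fixtures (3⁸ basis patterns). These
sizes were chosen so each property is checked against an exact independent
oracle where one exists; the algorithms themselves have no special-casing
at these scales.

## Known limitations

* Gap detection semantics is seeded reachability; workflows that *want*
  self-sustaining cycles counted as produced (the purely flux-based
  reading) would need the level constraints dropped, which the formulation
  isolates but the interface does not currently expose.
* Balance repair only spans H⁺/H₂O; other systematically omitted species
  (e.g. electrons in half-reactions) are flagged, not repaired.
* The SBML layer targets lossless round-tripping of this package's model
  content through SBML Level 3 core plus package annotations; it does not
  validate against, or import, the fbc extension of third-party models.
* Localization consensus treats scores and reference models symmetrically
  (union); there is no confidence weighting between evidence sources.
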