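---
title: "Seeds, scopes and minimal precursor sets: the methods behind seedscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeds, scopes and minimal precursor sets: the methods behind seedscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscope)
```

## The problem

Obligate endosymbiotic bacteria live on drastically reduced genomes and
survive by importing metabolites from their host cell and, in systems with
several co-resident symbionts, from each other. Given curated small-molecule
metabolic networks of two such organisms, `seedscope` answers three
questions topologically, without any flux or kinetic modelling:

1. **What must each organism import?** (the *seeds* of its network)
2. **Who can supply what?** (seed classification against the partner's
   producible metabolites and host/diet lists)
3. **Which subsets of the seeds suffice to build a given target
   metabolite?** (all inclusion-minimal *precursor sets*, with cycles
   handled exactly)

The answers are only as good as the reconstruction, so everything runs on a
filtered *carbon-transfer core* of the network and every destructive step
leaves an audit log.

## Two views of one network

A `metabolic_network` stores metabolites and reactions (sides as sets of
ids with positive coefficients). Two derived views drive the analyses:

* The **compound graph** (`build_compound_graph()`): an arc u → v whenever
  some reaction produces v from u; a reversible reaction contributes both
  directions. Used for seed detection, where strongly connected components
  are well defined.
* The **reaction hypergraph** (`build_hypergraph()`): one hyperarc
  (substrate set → product set) per reaction orientation. Used for
  reachability, because a reaction needs *all* of its substrates — simple
  graph paths overstate what a network can make.

Stoichiometric coefficients are deliberately dropped in both views. The
method is set-based; pruning precursor sets that are stoichiometrically
infeasible, and ranking them by attainable production rate, are separate
problems outside this package's scope.

## Filtering to the carbon core

Currency metabolites (ATP/ADP, NAD(P)H, …) create shortcuts through the
graph that say nothing about carbon flow. `filter_network()` applies three
passes in a fixed, logged order:

1. **Side-compound transformation rules** (`apply_side_compound_rules()`):
   a rule fires on a reaction when all of its left-trigger metabolites sit
   on one side and all right-triggers on the other, in either orientation;
   the matched compounds (plus configured subproducts) are then removed
   from that reaction only. Partial matches do nothing — glutamate is a
   currency metabolite in a transamination but genuine cargo elsewhere,
   which is why matching is per-reaction and rule-driven rather than a
   global blacklist. The package ships a starter table of 24 classical
   transformations (`default_side_compound_rules()`); it is configuration,
   not ground truth, and real analyses should curate it for their id space.
2. **Inorganic removal** (`remove_inorganics()`): water, proton, phosphate,
   diphosphate, ammonia, hydrogen peroxide, sulfite, sulfate and oxygen are
   removed from every reaction. Bicarbonate is *not* on the list: it
   carries carbon and can legitimately be a seed.
3. **Carbonless-reaction elimination** (`drop_carbonless_reactions()`): any
   reaction left with an empty side no longer transfers carbon between its
   sides and is dropped (reason code `NC`).

Optional manual per-reaction overrides are applied last, because whether a
metabolite is a side compound in a *specific* reaction is sometimes a
judgment call. The conservation invariant — every original occurrence is
kept, logged as removed, or inside a logged dropped reaction — is property
tested, as is idempotence of the whole pass. Metabolites whose occurrences
were all filtered away are dropped too; otherwise they would linger as
isolated nodes and resurface as spurious seeds.

`detect_disconnected_reactions()` flags reactions whose substrates nobody
produces and whose products nobody consumes. Removal is left to the analyst:
a reaction can look disconnected because of an annotation hole rather than
a false positive.

## Seeds as source components

Defining seeds as "metabolites no reaction produces" breaks on reversible
peripheral reactions: if oxaloacetate and aspartate interconvert through
one reversible reaction and nothing else produces either, each formally
produces the other, yet the pair as a whole must be fed from outside.
`identify_seeds()` therefore condenses the compound graph by strongly
connected components and reports every member of each *source component*
(no incoming arc from outside) as a seed. Multi-member source components
are kept as **alternative seed groups**: any one member could be the
actually imported compound, and downstream enumeration treats them as
genuine alternatives. SCC computation is delegated to igraph; the test
suite checks it against an O(n²) mutual-reachability oracle and checks the
condensation property that every node is reachable from some source
component.

Seed classification is deliberately shallow: `partner_produced` is a pure
topological fact (the seed appears in the product set of some hyperarc of
the partner network), while host/diet provenance and transporter
annotations enter only as user-supplied id lists. Cross-network id
reconciliation uses an explicit synonym map — no fuzzy name matching,
because a silent mismatch would corrupt the common/specific partition.

## Scope, cycles and self-generating metabolites

The **scope** of a metabolite set is the least fixpoint of "fire any
hyperarc whose substrates are all available, add its products"
(`scope()`). The reached set is order-independent; the fired sequence is
made deterministic by expanding in rounds in hyperarc order.

Plain scope under-reports in the presence of cycles. In the canonical
cycle motif (`make_cycle_motif()`, six metabolites, four reactions)

```
R1: s1 + c1 -> c2 + i     R3: i + s2 -> t
R2: c2 -> c1              R4: i -> c2
```

the scope of the seeds {s1, s2} is stuck: R1 needs c1, which only R2
makes, which needs c2, which only R1/R4 make. Chemically the pathway runs
fine: borrow one unit of c1, and the cycle returns it. A metabolite that
may be borrowed because the expansion itself reproduces it is
**self-generating**, and a set P of seeds is a **precursor set** of target
t when some self-generating set Z makes t reachable from P ∪ Z with all of
Z regenerated (produced by a fired hyperarc — mere initial presence does
not count, otherwise the condition is vacuous).

```{r cycle}
cyc <- make_cycle_motif()
hg  <- build_hypergraph(cyc$network)
scope(hg, c("s1", "s2"))$reached
maximal_self_generating_scope(hg, c("s1", "s2"))$scope$reached
```

### Anchored borrowing

One reading of "regenerated" is too weak. Take a lone reversible reaction
A ⇌ B feeding a target: with P = ∅ and Z = {A, B}, each member is formally
a product of the other orientation's firing, so the empty set would
qualify as a precursor set of everything downstream — and interconverted
pairs would never appear in any minimal solution, contradicting their
whole role as alternative seeds. The package therefore *anchors*
borrowing: a hyperarc may draw on borrowed metabolites only when at least
one of its substrates is genuinely available (a seed or an already
produced compound). Borrowed matter can join an expansion that seed-derived
matter is driving — as in the cycle motif, where s1 enters R1 alongside
the borrowed c1 — but a closed interconversion cannot bootstrap out of
nothing. In cycle-free hypergraphs anchoring changes nothing and
self-generation adds nothing: both facts are property-tested.

### Deciding existence: the greatest fixpoint

Feasible self-generating sets are closed under union (concatenate the two
certifying expansions), so existence of *some* Z is decided by the maximal
one. `maximal_self_generating_scope()` starts from Z₀ = all non-seed
vertices and repeatedly discards candidates not regenerated by the current
anchored expansion; the limit Z\* is the unique maximal feasible set, and a
target is reachable with some Z iff it is reachable with Z\*. This is an
implementation choice, not the definition: correctness is pinned by an
exhaustive brute-force oracle (below). Witnesses report the *borrowed*
subset of Z\* — the metabolites the certifying expansion consumes before
first producing, found by replaying it with lazy borrowing — so a witness
Z is empty exactly when plain scope suffices.

## Enumerating all minimal precursor sets

`enumerate_minimal_precursor_sets()` returns every inclusion-minimal
P ⊆ seeds that is a precursor set of the target, covering all alternative
production routes. Because precursor sets are closed under superset
(property-tested), the subset lattice can be traversed breadth-first by
increasing cardinality, skipping supersets of accepted solutions; every
set the traversal accepts is therefore minimal. Candidates are first
restricted to seeds that are ancestors of the target in the arc projection
of the hypergraph (plus the target itself). Output is canonically ordered
(size, then lexicographic), and a configurable `max_tests` budget returns
a row flagged `"incomplete"` rather than silently truncating.

The independent oracle, `brute_force_minimal_precursor_sets()`, enumerates
every P ⊆ seeds and for each P every candidate borrow set Z — restricted
to vertices that are products of at least one hyperarc, since nothing else
can ever be regenerated — accepting P when some Z is fully regenerated
with the target reached, then keeping the inclusion-minimal accepted sets.
It assumes none of the fixpoint theory above and is guarded to 15 seeds /
20 vertices. The acceptance suite checks exact agreement between the two
routes on 200 random instances (≤ 12 metabolites, ≤ 14 hyperarcs, ≤ 6
seeds), alongside the acyclic limit (100 instances) and scope
monotonicity/idempotence (100 instances); these sizes keep the whole suite
within a desk-scale run while staying inside the oracle's guard.

`precursor_table()` assembles one row per target with the two summary
columns used throughout the reporting: **S**, the number of minimal
precursor sets, and **P**, the size of the union of precursors across
them. `precursor_matrix()` renders the targets × seeds presence/absence
matrix; `autoplot()` draws it.

## Certifying sub-networks

`extract_subnetwork()` turns a solution into the bipartite
metabolite/reaction graph that certifies it: starting from the fired
hyperarcs, it iteratively prunes those from which the target is not
forward-reachable *unless* they are needed to regenerate a borrowed
self-generating metabolite still in use — regeneration machinery is not on
a simple path to the target, but without it the certificate is invalid.
Node roles (precursor, self-generating, intermediate, target) are
assigned from the solution; `export_subnetwork()` writes SIF or GraphML
for Cytoscape-style viewers, deterministically.

## The synthetic generator

`random_network()` exists so that every claim the package makes can be
tested against planted ground truth with no external data:

* **Nutrients** (default fraction 0.25 of metabolites) have no producing
  reaction by construction, so they are guaranteed seeds.
* **Planted regeneration cycles** embed the cycle-motif template on
  reserved metabolites fed by two nutrients, so the planted target is
  reachable only via a regenerated borrow and its unique minimal precursor
  set is known exactly.
* **Planted currency pairs** (`n_side_pairs`) add ATP/ADP to chosen
  reactions for filtering fixtures; `dag = TRUE` forces a topological
  order for acyclic instances.

Defaults (a dozen metabolites, eight reactions, arities ≤ 2, 10%
reversible) keep instances small enough for exhaustive oracles while still
exercising cycles, branching and alternative seeds. What the generator does *not*
emulate: realistic degree distributions, compartments, cofactor chemistry
or genome-scale size — a green suite says the algorithms are correct on
networks of this structure, not that a curated reconstruction of a real
organism is right. A single integer seed drives all sampling through a
locally scoped RNG, and identical spec + seed yields byte-identical SBML.

## Numerical and formatting choices

* Ids are the only identity; names are display-only. Compartments are
  ignored (single-pool assumption appropriate for bacterial small-molecule
  metabolism).
* SBML stoichiometry defaults to 1 when omitted; the `reversible`
  attribute defaults to true (the Level 2 default). Emitted SBML is Level
  3 Version 1 core.
* All output collections are canonically ordered (size, then id), so
  reports are deterministic byte-for-byte; ties in enumeration order are
  broken lexicographically.
* Degenerate inputs: an empty initial set has an empty scope; a target
  unreachable from all seeds yields an empty solution list, not an error;
  an oversized brute-force instance is a guarded error.

## Known limitations

* No stoichiometric feasibility or production-rate ranking; a minimal
  precursor set is a topological statement.
* Solutions are sets of precursors, not hyperpaths; the fired-hyperarc
  witness is one certificate, not an enumeration of routes.
* Witness Z sets are reported as borrowed, not globally minimized.
* Enumeration is exponential in the number of candidate seeds in the worst
  case; the budget turns pathological cases into flagged incomplete rows.
* Host/diet and transporter knowledge is input, never inferred.
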