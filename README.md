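# seedscope

Graph-based analysis of metabolic exchange in multi-organism symbioses:
which metabolites a reduced metabolic network must import (**seeds**), which
of those a co-resident organism could supply (**cross-feeding**), and which
subsets of the seeds suffice to synthesise a target metabolite (**minimal
precursor sets**), with exact handling of metabolic cycles.

The package is aimed at systems biologists studying endosymbiont consortia
(e.g. co-resident intracellular bacteria and their insect host), or any
setting where curated small-molecule metabolic networks must be compared
topologically, without flux or kinetic modelling.

## The methods in brief

* **Carbon-core filtering.** Reactions are stripped of currency couples
  (ATP/ADP, NAD(P)H, …) by per-reaction transformation rules, of nine
  inorganic compounds, and of reactions left without a carbon transfer —
  each removal logged, so the filtered network is auditable.
* **Seeds = source components.** The network becomes a directed compound
  graph (arc u → v when some reaction makes v from u); it is condensed by
  strongly connected components, and every member of a component with no
  incoming arc is a seed. Multi-member source components are *alternative
  seed groups*: metabolites interconverted by reversible reactions, any of
  which could be the actually imported one.
* **Precursor sets on the hypergraph.** Reachability uses directed
  hyperarcs (substrate set → product set): a reaction fires only when all
  substrates are available, and the *scope* of a seed set is the least
  fixpoint of that rule. A subset P of the seeds is a precursor set of
  target t if some set Z of *self-generating* metabolites — compounds
  borrowed inside cycles and regenerated by the expansion itself, with
  borrowing anchored to seed-driven reactions — makes t reachable from
  P ∪ Z. All inclusion-minimal P are enumerated exactly, and verified in
  the test suite against an exhaustive brute-force oracle.
* **Reporting.** Seed tables, common/specific seed partitions,
  targets × seeds matrices with the S (number of solutions) and P (number
  of distinct precursors) columns, and Cytoscape-ready SIF/GraphML exports
  of the sub-network certifying each solution.

See `vignettes/seedscope-methods.Rmd` for the full account, including why
borrowing must be anchored and how the enumeration is oracle-checked.

## Worked example

The canonical cycle fixture has six metabolites and four reactions; the
target `t` is unreachable by plain expansion from the seeds, but borrowing
the cycle metabolite `c1` (which the cycle regenerates) unlocks it:

```r
library(seedscope)

cyc <- make_cycle_motif()
hg  <- build_hypergraph(cyc$network)

scope(hg, c("s1", "s2"))$reached
#> [1] "s1" "s2"

enumerate_minimal_precursor_sets(hg, c("s1", "s2"), "t")
#> <precursor_row> target t: 1 minimal precursor set(s) [complete]
#> <precursor_solution> target t: {s1, s2}  [self-generating: c1]
```

The expansion stalls without borrowing (`reached` is just the seeds), and
the unique minimal precursor set is `{s1, s2}` with `c1` as the
self-generating witness.

A two-organism analysis on the built-in symbiosis fixture:

```r
fix   <- make_symbiosis_fixture()
rep_a <- identify_seeds(fix$a)

tidy(rep_a)
#> # A tibble: 5 × 3
#>   seed  component component_size
#>   <chr>     <int>          <int>
#> 1 asp           1              1
#> 2 bic           2              1
#> 3 e4p           3              1
#> 4 pep           4              1
#> 5 ser           5              1

compare_seed_sets(rep_a, identify_seeds(fix$b))
#> <seed_comparison> common: 3; only A: 2; only B: 2

classify_seeds(rep_a, fix$b)
#> # A tibble: 5 × 4
#>   seed  partner_produced host_or_diet transport_annotated
#>   <chr> <lgl>            <lgl>        <lgl>
#> 1 asp   FALSE            FALSE        FALSE
#> 2 bic   FALSE            FALSE        FALSE
#> 3 e4p   TRUE             FALSE        FALSE
#> 4 pep   TRUE             FALSE        FALSE
#> 5 ser   FALSE            FALSE        FALSE

precursor_matrix(precursor_table(build_hypergraph(fix$a),
                                 rep_a$seeds, c("trp", "thr")))
#> # A tibble: 2 × 8
#>   target     S     P   asp   bic   e4p   pep   ser
#>   <chr>  <int> <int> <int> <int> <int> <int> <int>
#> 1 trp        1     3     0     0     1     1     1
#> 2 thr        1     1     1     0     0     0     0
```

Organism A needs five seeds; three are shared with its partner's seed set
(the organisms compete for those), and two (`e4p`, `pep`) are producible by
the partner, so they are candidate cross-fed metabolites. Tryptophan has a
single minimal precursor set of three seeds; threonine needs only
aspartate.

A full run (filter → seeds → precursors → reports) is driven by a YAML
config through `run_pipeline()`, or from a shell via the thin wrapper
`inst/cli/seedscope.R` (`filter`, `seeds`, `precursors`, `pipeline`,
`simulate` subcommands).

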