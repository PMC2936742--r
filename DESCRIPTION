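Package: seedscope
Title: Seed Detection and Minimal Precursor Set Enumeration in Metabolic
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based analysis of metabolic exchange in multi-organism
    symbioses. Filters small-molecule metabolic networks to their
    carbon-transfer core (side-compound transformation rules, inorganic
    removal, carbonless-reaction elimination), identifies exogenously
    acquired metabolites (seeds) as source components of the strongly
    connected component condensation of the compound graph, classifies
    seeds against a partner network, and enumerates all inclusion-minimal
    precursor sets of target metabolites on a directed reaction hypergraph,
    with explicit handling of cycles via self-generating metabolites.
    Includes SBML import/export, Cytoscape-compatible sub-network exports,
    and a synthetic-network generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
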