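atp_adp_rule <- function() side_compound_rule("atp_adp", "ATP", "ADP")

test_that("a matched cofactor transformation strips the side compounds", {
  net <- metabolic_network(
    c("A", "B", "ATP", "ADP"),
    bind_reactions(reaction("R1", c("A", "ATP"), c("B", "ADP")))
  )
  res <- apply_side_compound_rules(net, atp_adp_rule())
  expect_identical(names(res$network$reactions$left[[1]]), "A")
  expect_identical(names(res$network$reactions$right[[1]]), "B")
  expect_identical(nrow(res$log), 2L)
  expect_setequal(res$log$entity_id, c("ATP", "ADP"))
  # original untouched
  expect_identical(names(net$reactions$left[[1]]), c("A", "ATP"))

  # the reversed orientation matches too
  net2 <- metabolic_network(
    c("A", "B", "ATP", "ADP"),
    bind_reactions(reaction("R1", c("A", "ADP"), c("B", "ATP")))
  )
  res2 <- apply_side_compound_rules(net2, atp_adp_rule())
  expect_identical(names(res2$network$reactions$left[[1]]), "A")
})

test_that("partial or absent triggers leave the reaction unchanged", {
  pair_rule <- side_compound_rule("nad_pair", c("NAD", "PROTON"), "NADH")
  net <- metabolic_network(
    c("A", "B", "NAD"),
    bind_reactions(reaction("R1", c("A", "NAD"), "B"))
  )
  res <- apply_side_compound_rules(net, pair_rule)
  expect_true(network_equal(res$network, net))
  expect_identical(nrow(res$log), 0L)
})

test_that("removed supersets may strip subproducts beyond the triggers", {
  rule <- side_compound_rule("coa", "ACYL-COA", "CO-A",
                             removed_left = c("ACYL-COA"),
                             removed_right = c("CO-A", "PPI"))
  net <- metabolic_network(
    c("X", "Y", "ACYL-COA", "CO-A", "PPI"),
    bind_reactions(reaction("R1", c("X", "ACYL-COA"), c("Y", "CO-A", "PPI")))
  )
  res <- apply_side_compound_rules(net, rule)
  expect_identical(names(res$network$reactions$right[[1]]), "Y")
  expect_identical(nrow(res$log), 3L)
})

test_that("inorganic removal strips the default nine and drops orphans", {
  net <- metabolic_network(
    c("A", "B", "WATER", "HCO3"),
    bind_reactions(reaction("R1", c("A", "WATER"), "B"),
                   reaction("R2", c("A", "HCO3"), "B"))
  )
  res <- remove_inorganics(net)
  expect_identical(names(res$network$reactions$left[[1]]), "A")
  # bicarbonate carries carbon and is not in the default list
  expect_identical(names(res$network$reactions$left[[2]]), c("A", "HCO3"))
  expect_false("WATER" %in% res$network$metabolites$id)
  expect_true("HCO3" %in% res$network$metabolites$id)

  clean <- make_chain_network()
  res2 <- remove_inorganics(clean)
  expect_true(network_equal(res2$network, clean))
  expect_identical(nrow(res2$log), 0L)
})

test_that("fully-inorganic reactions are emptied then dropped as carbonless", {
  net <- metabolic_network(
    c("A", "B", "WATER", "PROTON", "SULFATE", "SO3"),
    bind_reactions(reaction("R1", "A", "B"),
                   reaction("R2", c("SULFATE", "PROTON"), c("SO3", "WATER")))
  )
  step1 <- remove_inorganics(net)
  step2 <- drop_carbonless_reactions(step1$network)
  expect_identical(step2$network$reactions$id, "R1")
  expect_identical(step2$log$reason, "NC")
  expect_identical(step2$log$entity_id, "R2")
})

test_that("occurrence conservation holds across the full filtering pass", {
  for (s in 1:10) {
    gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 8,
                                         n_side_pairs = 3, seed = s))
    before <- nrow(occurrences(gen$network))
    res <- filter_network(gen$network, rules = default_side_compound_rules(),
                          inorganic_ids = inorganic_compounds())
    occ_removed <- sum(res$log$kind == "metabolite-occurrence")
    dropped_rxn <- res$log$entity_id[res$log$kind == "reaction"]
    # occurrences lost by dropping whole reactions are accounted separately
    kept_plus_removed <- nrow(occurrences(res$network)) + occ_removed +
      sum(occurrences(gen$network)$reaction_id %in% dropped_rxn) -
      sum(res$log$reaction_id %in% dropped_rxn & res$log$kind == "metabolite-occurrence")
    expect_identical(before, kept_plus_removed)
    # exactly the planted currency occurrences are removed by the rule pass
    expect_identical(sum(res$log$reason == "side-compound"),
                     gen$truth$n_side_occurrences)
  }
})

test_that("filtering is idempotent", {
  gen <- random_network(generator_spec(n_metabolites = 10, n_reactions = 8,
                                       n_side_pairs = 2, seed = 42))
  once <- filter_network(gen$network)
  twice <- filter_network(once$network)
  expect_true(network_equal(once$network, twice$network))
  expect_identical(nrow(twice$log), 0L)
})

test_that("rule and inorganic passes commute when their id sets are disjoint", {
  net <- metabolic_network(
    c("A", "B", "ATP", "ADP", "WATER"),
    bind_reactions(reaction("R1", c("A", "ATP", "WATER"), c("B", "ADP")))
  )
  ab <- remove_inorganics(apply_side_compound_rules(net, atp_adp_rule())$network)
  ba <- apply_side_compound_rules(remove_inorganics(net)$network, atp_adp_rule())
  expect_true(network_equal(ab$network, ba$network))
})

test_that("manual overrides are applied last and logged", {
  net <- metabolic_network(
    c("A", "B", "ATP", "ADP"),
    bind_reactions(reaction("R1", c("A", "ATP"), c("B", "ADP")))
  )
  keep <- tibble::tibble(reaction_id = "R1", metabolite_id = "ATP",
                         side = "left", action = "keep")
  res <- filter_network(net, rules = atp_adp_rule(), inorganic_ids = NULL,
                        overrides = keep)
  expect_true("ATP" %in% names(res$network$reactions$left[[1]]))
})

test_that("disconnected reactions are flagged but never removed", {
  net <- metabolic_network(
    c("A", "B", "C", "X", "Y"),
    bind_reactions(reaction("R1", "A", "B"),
                   reaction("R2", "B", "C"),
                   reaction("R3", "X", "Y"))
  )
  expect_identical(detect_disconnected_reactions(net), "R3")

  solo <- metabolic_network(c("X", "Y"), bind_reactions(reaction("R1", "X", "Y")))
  expect_identical(detect_disconnected_reactions(solo), "R1")

  # a reversible link into the chain keeps a reaction connected
  net2 <- metabolic_network(
    c("A", "B", "X"),
    bind_reactions(reaction("R1", "A", "B"),
                   reaction("R2", "B", "X", reversible = TRUE))
  )
  expect_identical(detect_disconnected_reactions(net2), character())
})

test_that("generic reactions split into suffixed specific reactions", {
  generic <- reaction("RXN-8972", c("lys-or-dap", "X"), "Y")
  out <- split_generic_reaction(generic, list(
    c("lys-or-dap", "LYS"), c("lys-or-dap", "DAP")
  ))
  expect_identical(out$id, c("RXN-8972BIS", "RXN-8972TER"))
  expect_setequal(names(out$left[[1]]), c("LYS", "X"))
  expect_setequal(names(out$left[[2]]), c("DAP", "X"))
  expect_identical(nrow(split_generic_reaction(generic, list())), 0L)
  expect_error(split_generic_reaction(generic, list(c("missing", "LYS"))),
               "absent")
})

test_that("the shipped starter rule table parses into valid rules", {
  rules <- default_side_compound_rules()
  expect_identical(nrow(rules), 24L)
  expect_true(all(lengths(rules$trigger_left) >= 1))
  expect_true(all(mapply(function(t, r) all(t %in% r),
                         rules$trigger_right, rules$removed_right)))
})
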