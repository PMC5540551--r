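# Hand fixtures with real formulas for the balance checker.
balance_fixture <- function() {
  mets <- data.frame(
    metabolite_id = c("glc", "g6p", "atp", "adp", "pi", "h", "h2o"),
    name = c("glucose", "glucose-6-phosphate", "ATP", "ADP",
             "phosphate", "proton", "water"),
    formula = c("C6H12O6", "C6H11O9P", "C10H12N5O13P3", "C10H12N5O10P2",
                "HO4P", "H", "H2O"),
    charge = c(0L, -2L, -4L, -3L, -2L, 1L, 0L),
    mass = c(180.16, 258.12, 503.15, 424.18, 95.98, 1.008, 18.015),
    is_generic = FALSE, stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    reaction_id = c("HEX_bad", "ATPH_ok", "ATPH_short"),
    reversible = FALSE, lower_bound = 0, upper_bound = 100,
    delta_g = NA_real_, ec_numbers = "", rtype = "metabolic",
    stringsAsFactors = FALSE
  )
  st <- rbind(
    # glucose => g6p with no phosphate donor: unbalanced, unrepairable
    data.frame(reaction_id = "HEX_bad", species_id = c("glc@c", "g6p@c"),
               coeff = c(-1, 1)),
    # ATP + H2O => ADP + Pi + H: hand element count gives exact zero
    data.frame(reaction_id = "ATPH_ok",
               species_id = c("atp@c", "h2o@c", "adp@c", "pi@c", "h@c"),
               coeff = c(-1, -1, 1, 1, 1)),
    # same reaction with H2O and H omitted: repairable by adding them
    data.frame(reaction_id = "ATPH_short",
               species_id = c("atp@c", "adp@c", "pi@c"),
               coeff = c(-1, 1, 1))
  )
  metnet(mets, rxns, st)
}

test_that("generic-reaction removal is exact and idempotent", {
  net <- mini_net(list(R1 = "A@c => B@c", R2 = "B@c => C@c",
                       R3 = "B@c => tRNA@c"))
  net$metabolites$is_generic[net$metabolites$metabolite_id == "tRNA"] <- TRUE
  out <- remove_generic_reactions(net)
  expect_equal(out$removed_ids, "R3")
  expect_setequal(out$network$reactions$reaction_id, c("R1", "R2"))
  expect_false("tRNA@c" %in% species(out$network)$species_id)
  # idempotent
  again <- remove_generic_reactions(out$network)
  expect_equal(length(again$removed_ids), 0)
  expect_equal(again$network$reactions, out$network$reactions)
  # no generic metabolites: identity
  clean <- mini_net(list(R1 = "A@c => B@c"))
  expect_equal(remove_generic_reactions(clean)$network$reactions,
               clean$reactions)
})

test_that("planted generic reactions are removed at the configured scale", {
  cfg <- generator_config(seed = 7, n_metabolites = 60, n_reactions = 100,
                          fraction_generic = 0.1, planted_gap_count = 0,
                          decoy_db_size = 0)
  gen <- generate_network(cfg)
  expect_equal(length(gen$ground_truth$generic_reactions), 10)
  out <- remove_generic_reactions(gen$network)
  expect_setequal(out$removed_ids, gen$ground_truth$generic_reactions)
})

test_that("balance checker flags, verifies and repairs correctly", {
  net <- balance_fixture()
  bad <- check_and_repair_balance(net, "HEX_bad")
  expect_equal(bad$status, "unbalanced")
  expect_false(bad$repaired)
  expect_true("P" %in% names(bad$element_imbalance))

  ok <- check_and_repair_balance(net, "ATPH_ok")
  expect_equal(ok$status, "balanced")
  expect_equal(length(ok$element_imbalance), 0)
  expect_equal(ok$charge_imbalance, 0)

  short <- check_and_repair_balance(net, "ATPH_short")
  expect_equal(short$status, "repaired")
  expect_setequal(short$repair_terms$species_id, c("h2o@c", "h@c"))
  # water on the substrate side, proton on the product side
  expect_equal(short$repair_terms$coeff[short$repair_terms$species_id == "h2o@c"], -1)
  expect_equal(short$repair_terms$coeff[short$repair_terms$species_id == "h@c"], 1)

  # missing formula -> unverifiable
  net2 <- mini_net(list(R1 = "A@c => B@c"))
  expect_equal(check_and_repair_balance(net2, "R1")$status, "unverifiable")
})

test_that("post-repair networks satisfy element and charge closure", {
  net <- balance_fixture()
  out <- balance_network(net)
  expect_equal(out$reports$status[out$reports$reaction_id == "ATPH_short"],
               "repaired")
  for (id in out$reports$reaction_id[out$reports$status %in%
                                     c("balanced", "repaired")]) {
    rep <- check_and_repair_balance(out$network, id)
    expect_equal(rep$status, "balanced")
  }
  # unbalanced reactions are retained, not dropped
  expect_true("HEX_bad" %in% out$network$reactions$reaction_id)
  # strict mode drops them
  strict <- balance_network(net, strict = TRUE)
  expect_false("HEX_bad" %in% strict$network$reactions$reaction_id)
})

test_that("directionality follows the Gibbs-energy policy", {
  net <- mini_net(list(R1 = "A@c => B@c", R2 = "A@c => B@c", R3 = "A@c => B@c"))
  net$reactions$delta_g <- c(NA, -60, 60)
  out <- assign_directionality(net, threshold = 30)
  r <- out$reactions
  # unknown -> reversible with policy bounds
  expect_true(r$reversible[1])
  expect_equal(c(r$lower_bound[1], r$upper_bound[1]), c(-1000, 100))
  # strongly exergonic -> irreversible forward
  expect_false(r$reversible[2])
  expect_equal(c(r$lower_bound[2], r$upper_bound[2]), c(0, 100))
  # strongly endergonic -> flipped and irreversible
  expect_false(r$reversible[3])
  st3 <- out$stoich[out$stoich$reaction_id == "R3", ]
  expect_equal(st3$coeff[st3$species_id == "A@c"], 1)
  expect_equal(st3$coeff[st3$species_id == "B@c"], -1)
  expect_equal(out$reactions$delta_g[3], -60)
  # bounds never widen beyond the global policy
  expect_true(all(r$lower_bound >= -1000 & r$upper_bound <= 100))
  # in-between magnitudes stay reversible
  net$reactions$delta_g <- c(-10, 10, 29.9)
  out2 <- assign_directionality(net, threshold = 30)
  expect_true(all(out2$reactions$reversible))
})
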