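test_that("generation is deterministic under the seed, to the byte", {
  cfg <- generator_config(seed = 5, n_metabolites = 50, n_reactions = 90,
                          planted_gap_count = 3, decoy_db_size = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_input_bundle(cfg, d1)
  p2 <- write_input_bundle(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("bundle file", nm))
  }
  # a different seed changes the output
  p3 <- write_input_bundle(generator_config(seed = 6, n_metabolites = 50,
                                            n_reactions = 90,
                                            planted_gap_count = 3,
                                            decoy_db_size = 5),
                           withr::local_tempdir())
  expect_false(identical(readLines(p1[["reactions"]]),
                         readLines(p3[["reactions"]])))
})

test_that("generated networks honor the configured composition", {
  cfg <- generator_config(seed = 8, n_metabolites = 60, n_reactions = 100,
                          fraction_generic = 0.1, planted_gap_count = 0,
                          decoy_db_size = 0)
  gen <- generate_network(cfg)
  gt <- gen$ground_truth
  expect_equal(length(gt$generic_reactions), 10)
  expect_equal(length(gt$core_reactions) + length(gt$generic_reactions), 100)
  # every non-scaffold reaction has a ground-truth compartment
  expect_setequal(names(gt$true_compartment), gt$core_reactions)
  # thermodynamic annotations are consistent with the directionality policy:
  # re-running the policy is a no-op
  redone <- assign_directionality(gen$network, threshold = 30)
  expect_equal(redone$reactions$reversible, gen$network$reactions$reversible)
  expect_equal(redone$stoich, gen$network$stoich)
})

test_that("every non-generic generated reaction is exactly balanced", {
  cfg <- generator_config(seed = 9, n_metabolites = 40, n_reactions = 70,
                          fraction_generic = 0.1, planted_gap_count = 0,
                          decoy_db_size = 0)
  gen <- generate_network(cfg)
  out <- balance_network(gen$network)
  core <- out$reports[!(out$reports$reaction_id %in%
                          gen$ground_truth$generic_reactions), ]
  # conversions and transports are balanced (one shared monomer formula);
  # one-sided exchanges are boundary pseudo-reactions
  expect_true(all(core$status %in% c("balanced", "boundary")))
  expect_true(all(core$status[!grepl("^EX", core$reaction_id)] == "balanced"))
  generic <- out$reports[out$reports$reaction_id %in%
                           gen$ground_truth$generic_reactions, ]
  expect_true(all(generic$status == "unverifiable"))
})

test_that("the baseline draft has no dead ends once generics are removed", {
  for (seed in c(3, 13)) {
    cfg <- generator_config(seed = seed, n_metabolites = 80,
                            n_reactions = 140, planted_gap_count = 0,
                            decoy_db_size = 0)
    net <- remove_generic_reactions(generate_network(cfg)$network)$network
    rep <- gapfind_reachability(net)
    expect_equal(length(rep$non_produced), 0)
    expect_equal(length(rep$non_consumed), 0)
  }
})

test_that("gap planting returns a faithful recovery key", {
  cfg <- generator_config(seed = 10, n_metabolites = 50, n_reactions = 90,
                          fraction_generic = 0, planted_gap_count = 0,
                          decoy_db_size = 0)
  net <- generate_network(cfg)$network
  # k = 0 is the identity
  none <- plant_gaps(net, 0)
  expect_equal(none$network$reactions, net$reactions)

  gaps <- plant_gaps(net, 5, seed = 11)
  expect_equal(nrow(gaps$removed$reactions), 5)
  rep <- gapfind_reachability(gaps$network)
  expect_true(all(gaps$induced_dead_ends %in% problem_species_pub(rep)))
  # reinserting the removed reactions restores the baseline
  healed <- gaps$network
  healed$reactions <- rbind(healed$reactions, gaps$removed$reactions)
  healed$stoich <- rbind(healed$stoich, gaps$removed$stoich)
  rep2 <- gapfind_reachability(healed)
  expect_equal(length(problem_species_pub(rep2)), 0)
})

test_that("ancillary tables encode the ground truth", {
  cfg <- generator_config(seed = 12, n_metabolites = 40, n_reactions = 70,
                          fraction_generic = 0, planted_gap_count = 0,
                          decoy_db_size = 0,
                          localization_concentration = 2000)
  gen <- generate_network(cfg)
  anc <- generate_ancillary_tables(gen$network, cfg, gen$ground_truth)
  # near-degenerate concentration: argmax equals the true compartment
  scores <- as.matrix(anc$localization[, -1])
  argmax <- colnames(scores)[max.col(scores)]
  expect_equal(argmax,
               unname(gen$ground_truth$true_compartment[anc$localization$reaction_id]))
  # decoy-free candidate database equals the removal key
  gaps <- plant_gaps(gen$network, 2, seed = 13)
  anc2 <- generate_ancillary_tables(gen$network, cfg, gen$ground_truth,
                                    removed = gaps$removed)
  expect_setequal(anc2$candidate_db$reactions$reaction_id,
                  gaps$removed$reactions$reaction_id)
  # transport templates are all transport-typed and cytoplasm-anchored
  expect_true(all(anc$transport_db$reactions$rtype == "transport"))
})
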