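test_that("gap detection matches the hand-analyzed chain fixtures", {
  # uptake -> A -> B -> C with no outlet: C (and its stranded ancestors)
  # cannot be consumed; everything is producible
  chain <- mini_net(list(EX = " <=> A@e", T1 = "A@e => A@c",
                         R1 = "A@c => B@c", R2 = "B@c => C@c"))
  rep <- gapfind(chain)
  expect_equal(rep$non_produced, character(0))
  expect_true("C@c" %in% rep$non_consumed)

  # no inlet and no exchange: A cannot be produced
  noin <- mini_net(list(R1 = "A@c => B@c", R2 = "B@c => C@c",
                        T2 = "C@c => C@e", EX2 = "C@e => "))
  rep2 <- gapfind(noin)
  expect_true("A@c" %in% rep2$non_produced)
  expect_equal(rep2$non_consumed, character(0))

  # connected cycle with exchange in and out: no gaps
  cyc <- mini_net(list(EX_in = " => A@e", T_in = "A@e => A@c",
                       R1 = "A@c => B@c", R2 = "B@c => A@c",
                       R3 = "B@c => B@e", EX_out = "B@e => "))
  rep3 <- gapfind(cyc)
  expect_equal(length(rep3$non_produced), 0)
  expect_equal(length(rep3$non_consumed), 0)

  # an unseeded internal loop is not self-certifying
  loop <- mini_net(list(R1 = "A@c => B@c", R2 = "B@c => A@c"))
  rep4 <- gapfind(loop)
  expect_setequal(rep4$non_produced, c("A@c", "B@c"))
  expect_same_gaps(rep4, gapfind_reachability(loop))
})

test_that("MILP gap detection equals the reachability oracle on random networks", {
  for (seed in 1:30) {
    net <- random_milp_network(seed)
    expect_same_gaps(gapfind(net), gapfind_reachability(net))
  }
})

test_that("gap filling picks minimal fills and reports infeasibility", {
  net <- mini_net(list(EX = " <=> A@e", T1 = "A@e => A@c",
                       R1 = "A@c => B@c", R3 = "C@c => D@c",
                       T4 = "D@c => D@e", EX4 = "D@e => "))
  # C is non-produced (and B non-consumed); db contains the missing B -> C
  db <- mini_net(list(FIX = "B@c => C@c"))
  sol <- gapfill(net, "C@c", db)[[1]]
  expect_true(sol$feasible)
  expect_equal(sol$added_reaction_ids, "FIX")

  # two routes: length-1 wins over length-2
  db2 <- mini_net(list(LONG1 = "B@c => E@c", LONG2 = "E@c => C@c",
                       ONE = "B@c => C@c"))
  sol2 <- gapfill(net, "C@c", db2)[[1]]
  expect_equal(sol2$added_reaction_ids, "ONE")

  # empty candidate set: infeasible, never dropped
  sol3 <- gapfill(net, "C@c", NULL, exchange_templates = FALSE)[[1]]
  expect_false(sol3$feasible)
})

test_that("planted gaps are recovered minimally against decoy databases", {
  cfg <- generator_config(seed = 31, n_metabolites = 40, n_reactions = 70,
                          fraction_generic = 0, planted_gap_count = 4,
                          decoy_db_size = 6)
  gen <- generate_network(cfg)
  gaps <- plant_gaps(gen$network, 4, seed = 32,
                     candidates = gen$ground_truth$core_reactions)
  anc <- generate_ancillary_tables(gen$network, cfg, gen$ground_truth,
                                   removed = gaps$removed)
  targets <- gaps$induced_dead_ends
  sols <- gapfill(gaps$network, targets, anc$candidate_db,
                  exchange_templates = FALSE)
  for (sol in sols) {
    expect_true(sol$feasible)
    oracle <- gapfill_exhaustive(gaps$network, sol$target_species,
                                 anc$candidate_db,
                                 exchange_templates = FALSE)
    expect_equal(length(sol$added_reaction_ids), oracle$size)
  }
  # with the key withheld, fills may be impossible: a db of pure dead-end
  # decoys cannot resolve anything
  empty_db <- mini_net(list(NOP = "zz9@c => zz8@c"))
  sols2 <- gapfill(gaps$network, targets[1], empty_db,
                   exchange_templates = FALSE)
  expect_false(sols2[[1]]$feasible)
})

test_that("three-step curation resolves inner gaps through exchanges", {
  # mitochondrial X is dead; cytosolic X is fully connected. Step 2 alone
  # (an X[c] <-> X[m] exchange) must fix it.
  net <- mini_net(list(EX = " <=> X@e", T1 = "X@e => X@c",
                       T2 = "X@c => Y@c", T3 = "Y@c => Y@e", EXY = "Y@e => ",
                       RM = "X@m => Y@m", TYm = "Y@m => Y@c"))
  out <- curate_compartmentalized(net, candidate_db = NULL)
  expect_equal(length(out$added$cytoplasm), 0)
  expect_true(length(out$added$exchanges) >= 1)
  expect_true(all(startsWith(out$added$exchanges, "EXC_")))
  expect_equal(length(problem_species_pub(out$after)), 0)

  # an already consistent network needs nothing
  ok <- mini_net(list(EX = " <=> A@e", T1 = "A@e <=> A@c",
                      R1 = "A@c <=> B@c", T2 = "B@c <=> B@e", EX2 = " <=> B@e"))
  out2 <- curate_compartmentalized(ok, candidate_db = NULL)
  expect_equal(length(unlist(out2$added)), 0)
  expect_equal(out2$stats$pct_before, out2$stats$pct_after)
})

test_that("shared problem metabolites are counted per compartment pair", {
  # exactly five metabolites (d1..d5) dead in both the cytoplasm and the
  # mitochondrion; their products s1..s5 stay fully connected through an
  # independent uptake
  eqs <- list()
  for (i in 1:5) {
    m <- paste0("d", i)
    eqs[[paste0("C", i)]] <- paste0(m, "@c => s", i, "@c")
    eqs[[paste0("M", i)]] <- paste0(m, "@m => s", i, "@m")
    eqs[[paste0("EXs", i)]] <- paste0(" => s", i, "@e")
    eqs[[paste0("TSin", i)]] <- paste0("s", i, "@e => s", i, "@c")
    eqs[[paste0("T2m", i)]] <- paste0("s", i, "@c => s", i, "@m")
    eqs[[paste0("TSm", i)]] <- paste0("s", i, "@m => s", i, "@e")
    eqs[[paste0("XS", i)]] <- paste0("s", i, "@e => ")
  }
  net <- mini_net(eqs)
  rep <- gapfind(net)
  expect_equal(unname(rep$common_gaps["c|m"]), 5)
})

test_that("reconnection percentages follow the connected-species definition", {
  before <- list(non_produced = paste0("s", 1:3, "@c"),
                 non_consumed = paste0("s", 4, "@c"))
  after <- list(non_produced = paste0("s", 1, "@c"),
                non_consumed = character(0))
  universe <- paste0("s", 1:10, "@c")
  st <- reconnection_percentage(before, after, universe)
  expect_equal(st$pct_before, 60)
  expect_equal(st$pct_after, 90)
  # after >= before on a full curation run
  cfg <- generator_config(seed = 41, n_metabolites = 30, n_reactions = 50,
                          fraction_generic = 0, planted_gap_count = 3,
                          decoy_db_size = 5)
  gen <- generate_network(cfg)
  gaps <- plant_gaps(gen$network, 3, seed = 42,
                     candidates = gen$ground_truth$core_reactions)
  anc <- generate_ancillary_tables(gen$network, cfg, gen$ground_truth,
                                   removed = gaps$removed)
  out <- curate_compartmentalized(gaps$network, anc$candidate_db)
  expect_true(all(out$stats$pct_after >= out$stats$pct_before))
})
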