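test_that("metabolite-graph edges follow substrate-product pairs", {
  net <- mini_net(list(R1 = "A@c + B@c => C@c", R2 = "D@c <=> E@c",
                       EX = " <=> A@e"))
  g <- build_metabolite_graph(net)
  el <- igraph::as_edgelist(g)
  edges <- paste(el[, 1], el[, 2])
  expect_setequal(edges, c("A@c C@c", "B@c C@c", "D@c E@c", "E@c D@c"))
  # the one-sided exchange contributes no inter-metabolite edge, but its
  # species is still a node
  expect_true("A@e" %in% igraph::V(g)$name)
  expect_equal(igraph::vcount(g), nrow(species(net)))
})

test_that("degree distributions count reaction-mediated links", {
  cyc <- mini_net(list(R1 = "A@c => B@c", R2 = "B@c => C@c",
                       R3 = "C@c => A@c"))
  dd <- degree_distributions(build_metabolite_graph(cyc))
  expect_equal(dd$`in`$k, 1)
  expect_equal(dd$`in`$count, 3)
  expect_equal(sum(dd$`in`$pk), 1)

  star <- mini_net(list(R1 = "H@c => L1@c", R2 = "H@c => L2@c",
                        R3 = "H@c => L3@c", R4 = "H@c => L4@c",
                        R5 = "H@c => L5@c"))
  dd2 <- degree_distributions(build_metabolite_graph(star))
  expect_setequal(dd2$out$k, c(0, 5))
  expect_equal(dd2$out$count[dd2$out$k == 5], 1)

  # parallel links from distinct reactions accumulate
  par <- mini_net(list(R1 = "A@c => B@c", R2 = "A@c => B@c"))
  dd3 <- degree_distributions(build_metabolite_graph(par))
  expect_true(2 %in% dd3$`in`$k)
})

test_that("power-law fitting recovers exact and planted exponents", {
  # exact k^-2 histogram
  k <- 1:200
  tab <- data.frame(k = k, count = round(1e6 * k^-2))
  fit <- fit_power_law(tab)
  expect_lt(abs(fit$gamma - 2), 0.05)
  expect_false(fit$poor_fit)
  # uniform degrees are flagged as a poor fit
  uni <- data.frame(k = 1:30, count = 100)
  expect_true(fit_power_law(uni)$poor_fit)
  expect_error(fit_power_law(data.frame(k = c(1, 2), count = c(3, 4))),
               "degenerate")
  # generator-planted exponents are recovered within the tolerance band
  cfg <- generator_config(seed = 51, n_metabolites = 2000, n_reactions = NULL,
                          fraction_generic = 0, reversible_fraction = 0,
                          planted_gap_count = 0, decoy_db_size = 0)
  dd <- degree_distributions(build_metabolite_graph(generate_network(cfg)$network))
  expect_lt(abs(fit_power_law(dd$`in`)$gamma - 1.8), 0.2)
  expect_lt(abs(fit_power_law(dd$out)$gamma - 2.0), 0.2)
})

test_that("global metrics match hand-computed and independent values", {
  # undirected triangle via three reversible conversions
  tri <- mini_net(list(R1 = "A@c <=> B@c", R2 = "B@c <=> C@c",
                       R3 = "A@c <=> C@c"))
  ts <- topology_summary(build_metabolite_graph(tri))
  expect_equal(ts$clustering_coefficient, 1)
  expect_equal(ts$network_diameter, 1)
  expect_equal(ts$node_count, 3)

  # directed path: mean over reachable ordered pairs
  path <- mini_net(list(R1 = "A@c => B@c", R2 = "B@c => C@c"))
  tp <- topology_summary(build_metabolite_graph(path))
  expect_equal(tp$characteristic_path_length, (1 + 1 + 2) / 3,
               tolerance = 1e-9)
  expect_equal(tp$network_diameter, 2)

  # random graph: distances against a plain Floyd-Warshall oracle
  net <- random_milp_network(77, n_mets = 10, n_rxns = 20)
  g <- build_metabolite_graph(net)
  d <- floyd_warshall(g)
  finite <- is.finite(d) & d > 0
  ts2 <- topology_summary(g)
  expect_equal(ts2$characteristic_path_length, mean(d[finite]))
  expect_equal(ts2$network_diameter, max(d[finite]))
  expect_true(ts2$network_radius <= ts2$network_diameter)
})

test_that("centrality ranking surfaces hubs and is order-invariant", {
  eqs <- list(EX = " <=> h@e")
  for (i in 1:8) {
    eqs[[paste0("R", i)]] <- paste0("h@c + s", i, "@c => p", i, "@c")
    eqs[[paste0("S", i)]] <- paste0("p", i, "@c => s", i, "@c")
  }
  eqs$HUB <- "h@e => h@c"
  net <- mini_net(eqs)
  g <- build_metabolite_graph(net)
  m <- build_stoichiometric_matrix(net)
  rk <- rank_central_metabolites(g, m)
  # the currency-style hub touches ~all reactions and must rank on top
  expect_true("h@c" %in% rk$species_id[1:3])
  expect_true(rk$edge_count[rk$species_id == "h@c"] ==
                max(rk$edge_count))

  # permuting the reaction insertion order changes nothing
  net2 <- mini_net(rev(eqs))
  rk2 <- rank_central_metabolites(build_metabolite_graph(net2),
                                  build_stoichiometric_matrix(net2))
  expect_equal(rk2$species_id, rk$species_id)
})

test_that("compartment stripping quotients onto the flat build's graph", {
  cfg <- generator_config(seed = 61, n_metabolites = 40, n_reactions = 70,
                          fraction_generic = 0, planted_gap_count = 0,
                          decoy_db_size = 0)
  gen <- generate_network(cfg)
  flat_g <- build_metabolite_graph(gen$network)
  asg <- lapply(gen$ground_truth$true_compartment, identity)
  comp <- compartmentalize_network(gen$network, asg)
  quot <- strip_compartments(build_metabolite_graph(comp))
  flat_edges <- apply(igraph::as_edgelist(strip_compartments(flat_g)), 1,
                      paste, collapse = ">")
  quot_edges <- apply(igraph::as_edgelist(quot), 1, paste, collapse = ">")
  expect_true(all(flat_edges %in% quot_edges))
})
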