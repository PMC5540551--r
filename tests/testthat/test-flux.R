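test_that("linear chains carry the uptake-limited optimum", {
  net <- mini_net(list(EX = " => A@e", T1 = "A@e => A@c", R1 = "A@c => B@c",
                       T2 = "B@c => B@e", OUT = "B@e => "),
                  ub = list(EX = 10))
  res <- solve_fba(build_problem(net, "OUT"))
  expect_equal(res$status, "optimal")
  expect_equal(res$Z, 10)
  # an objective with no route from any exchange is silent
  iso <- mini_net(list(EX = " => A@e", T1 = "A@e => A@c",
                       R9 = "P@c => Q@c", R1 = "A@c => A@e"))
  res2 <- solve_fba(build_problem(iso, "R9"))
  expect_equal(res2$Z, 0)
})

test_that("LP optima agree with brute-force vertex enumeration", {
  for (seed in 1:10) {
    net <- random_milp_network(seed, n_mets = 5, n_rxns = 8)
    # finite bounds so the polytope is bounded for the enumeration
    net$reactions$lower_bound[net$reactions$lower_bound < 0] <- -50
    obj <- net$reactions$reaction_id[nrow(net$reactions)]
    prob <- build_problem(net, obj)
    res <- solve_fba(prob)
    oracle <- lp_vertex_enumeration(as.matrix(prob$matrix$S), prob$c,
                                    prob$lb, prob$ub)
    expect_equal(res$status, "optimal")
    expect_equal(res$Z, oracle$Z, tolerance = 1e-6)
    # steady state holds at the optimum
    expect_lt(max(abs(as.numeric(prob$matrix$S %*% res$v))), 1e-6)
  }
})

test_that("bound tightening never increases the optimum", {
  net <- mini_net(list(EX = " => A@e", T1 = "A@e => A@c", R1 = "A@c <=> B@c",
                       T2 = "B@c => B@e", OUT = "B@e => "))
  prob <- build_problem(net, "OUT")
  z0 <- solve_fba(prob)$Z
  for (j in prob$matrix$reactions) {
    tight <- prob
    tight$ub[j] <- tight$ub[j] / 2
    zt <- solve_fba(tight)$Z
    expect_lte(zt, z0 + 1e-9)
  }
})

test_that("reaction exclusion is the knockout primitive", {
  net <- mini_net(list(EX = " => A@e", T1 = "A@e => A@c", R1 = "A@c => B@c",
                       SIDE = "A@c => C@c", T3 = "C@c => C@e", EXC = "C@e => ",
                       T2 = "B@c => B@e", OUT = "B@e => "),
                  ub = list(EX = 5))
  prob <- build_problem(net, "OUT")
  expect_error(exclude_reactions(prob, "NOPE"), "unknown")
  # excluding the only uptake zeroes the objective
  expect_equal(solve_fba(exclude_reactions(prob, "EX"))$Z, 0)
  # excluding a reaction outside the active optimal route leaves Z unchanged
  z <- solve_fba(prob)$Z
  expect_equal(solve_fba(exclude_reactions(prob, "SIDE"))$Z, z)
})

test_that("fatty-acid elongation requires the acetyl-CoA transport", {
  net <- toy_fatty_acid_model()
  prob <- build_problem(net, "KAS")
  with_t <- solve_fba(prob)
  expect_equal(with_t$status, "optimal")
  expect_gt(with_t$Z, 0)
  without_t <- solve_fba(exclude_reactions(prob, "TACOA"))
  expect_equal(without_t$Z, 0)
})

test_that("TCA optima order as with-exchanges > without > flattened", {
  comp <- toy_tca_model()
  prob <- build_problem(comp, c("CS_c", "CS_m"))
  z_with <- solve_fba(prob)$Z
  z_without <- solve_fba(exclude_reactions(prob, c("X_OAA", "X_ACA",
                                                   "X_OG")))$Z
  z_flat <- solve_fba(build_problem(toy_tca_model("flattened"), "CS"))$Z
  expect_gt(z_with, z_without)
  expect_gt(z_without, z_flat)
  expect_gt(z_flat, 0)
})

test_that("active-flux fractions follow the scope definition", {
  res <- structure(list(status = "optimal",
                        v = c(a = 1, b = 2, c = 0, d = 1e-9,
                              e = -3, f = 0.5, g = 0, h = 0, i = 0)),
                   class = "flux_result")
  scopes <- list(all_active = c("a", "b", "e", "f"),
                 denitrification = letters[1:9],
                 empty = character(0))
  af <- active_flux_fraction(res, scopes)
  expect_equal(unname(af["all_active"]), 100)
  expect_equal(unname(af["denitrification"]), 100 * 4 / 9, tolerance = 1e-9)
  expect_true(is.na(af["empty"]))
  # an all-zero solution activates nothing
  res0 <- structure(list(status = "optimal", v = res$v * 0),
                    class = "flux_result")
  expect_equal(unname(active_flux_fraction(res0, scopes)["all_active"]), 0)
})

test_that("the objective template library ships the documented blocks", {
  lib <- objective_library()
  expect_equal(length(lib$nitrogen_cycle), 4)
  expect_equal(length(lib$tca_related), 7)
  # three of the TCA-related templates are cross-compartment exchanges
  cross <- vapply(lib$tca_related, function(eq) {
    comp <- unique(sub("^.*@", "", parse_equation(eq)$stoich$species_id))
    length(comp) >= 2
  }, logical(1))
  expect_equal(sum(cross), 3)
  # the generic acceptor is substituted
  expect_false(any(grepl(" A ", lib$nitrogen_cycle)))
  expect_true(any(grepl("oxidized ferredoxin", lib$nitrogen_cycle)))

  # instantiation reports unresolved templates rather than failing
  net <- toy_tca_model()
  inst <- instantiate_objective(net, lib$nitrogen_cycle)
  expect_equal(length(inst$resolved), 0)
  expect_true(all(nzchar(inst$unresolved)))
  inst2 <- instantiate_objective(net, c(x = "Oxaloacetate[c] <=> Oxaloacetate[m]"))
  expect_equal(names(inst2$resolved), "x")
})

test_that("flux parsimony stabilization keeps the optimum", {
  net <- toy_tca_model()
  prob <- build_problem(net, c("CS_c", "CS_m"))
  plain <- solve_fba(prob)
  stab <- solve_fba(prob, stabilize = TRUE)
  expect_equal(stab$Z, plain$Z, tolerance = 1e-8)
  expect_lte(sum(abs(stab$v)), sum(abs(plain$v)) + 1e-6)
  expect_lt(max(abs(as.numeric(prob$matrix$S %*% stab$v))), 1e-6)
})
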