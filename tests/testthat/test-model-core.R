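write_fixture_tables <- function(net, dir) {
  paths <- c(r = file.path(dir, "r.tsv"), m = file.path(dir, "m.tsv"))
  write_network(net, paths["r"], paths["m"])
  paths
}

test_that("equation parsing handles coefficients, compartments and arrows", {
  p <- parse_equation("2 A@c + B@c <=> C@c")
  expect_true(p$reversible)
  expect_equal(p$stoich$coeff[p$stoich$species_id == "A@c"], -2)
  expect_equal(p$stoich$coeff[p$stoich$species_id == "C@c"], 1)

  # bracket compartments, multi-word ids, "< = >" style arrows
  p2 <- parse_equation("Acetyl-CoA[c] < = > Acetyl-CoA[m]")
  expect_setequal(p2$stoich$species_id, c("Acetyl-CoA@c", "Acetyl-CoA@m"))
  p3 <- parse_equation("5 H(+) + 1 nitrite = 1 hydroxylamine")
  expect_false(p3$reversible)
  expect_equal(sort(p3$stoich$species_id),
               c("H(+)@c", "hydroxylamine@c", "nitrite@c"))

  # one-sided exchange
  p4 <- parse_equation(" <=> A@e")
  expect_equal(nrow(p4$stoich), 1)
  expect_error(parse_equation("A B C"), "arrow")
})

test_that("format_equation inverts parse_equation", {
  eqs <- c("2 A@c + B@c <=> C@c", "A@e => A@c", " <=> X@e")
  for (eq in eqs) {
    p <- parse_equation(eq)
    q <- parse_equation(format_equation(p$stoich, p$reversible))
    expect_equal(q$reversible, p$reversible)
    expect_equal(q$stoich, p$stoich)
  }
})

test_that("read_network builds valid networks and rejects bad input", {
  dir <- withr::local_tempdir()
  mt <- data.frame(metabolite_id = c("A", "B", "C"), name = c("A", "B", "C"),
                   formula = NA, charge = NA, mass = NA, is_generic = FALSE)
  rt <- data.frame(reaction_id = c("R1", "R2"),
                   equation = c("A@c => B@c", "B@c => C@c"),
                   ec_numbers = c("1.1.1.1", ""), delta_g = c("", "-12"),
                   rtype = "")
  write.table(mt, file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rt, file.path(dir, "r.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  net <- read_network(file.path(dir, "r.tsv"), file.path(dir, "m.tsv"))
  expect_equal(nrow(net$reactions), 2)
  expect_equal(nrow(species(net)), 3)
  expect_equal(net$reactions$delta_g, c(NA, -12))

  # empty reaction table is fine
  write.table(rt[0, ], file.path(dir, "r0.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  net0 <- read_network(file.path(dir, "r0.tsv"), file.path(dir, "m.tsv"))
  expect_equal(nrow(net0$reactions), 0)

  # dangling metabolite reference
  rt$equation[2] <- "B@c => Q@c"
  write.table(rt, file.path(dir, "rq.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_network(file.path(dir, "rq.tsv"), file.path(dir, "m.tsv")),
               "dangling")

  # duplicate reaction ids
  rt$equation[2] <- "B@c => C@c"; rt$reaction_id[2] <- "R1"
  write.table(rt, file.path(dir, "rd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_network(file.path(dir, "rd.tsv"), file.path(dir, "m.tsv")),
               "duplicate")
})

test_that("stoichiometric matrix is deterministic and column-faithful", {
  net <- mini_net(list(R1 = "A@c => B@c", R2 = "A@c <=> B@c"))
  m <- build_stoichiometric_matrix(net)
  expect_equal(m$species, c("A@c", "B@c"))
  expect_equal(as.numeric(m$S[, "R1"]), c(-1, 1))
  # reversibility lives in bounds, not in S
  expect_equal(as.numeric(m$S[, "R2"]), as.numeric(m$S[, "R1"]))
})

test_that("tabular round trip preserves the stoichiometric matrix", {
  cfg <- generator_config(seed = 11, n_metabolites = 20, n_reactions = 30,
                          fraction_generic = 0, planted_gap_count = 0,
                          decoy_db_size = 0)
  net <- generate_network(cfg)$network
  paths <- write_fixture_tables(net, withr::local_tempdir())
  back <- read_network(paths["r"], paths["m"])
  S1 <- build_stoichiometric_matrix(net)
  S2 <- build_stoichiometric_matrix(back)
  expect_identical(S1$species, S2$species)
  expect_identical(S1$reactions, S2$reactions)
  expect_equal(as.matrix(S1$S), as.matrix(S2$S))
  # field-by-field identity of the reaction table (bounds re-derived from
  # the same policy, delta_g preserved)
  ord <- match(net$reactions$reaction_id, back$reactions$reaction_id)
  expect_equal(back$reactions$delta_g[ord], net$reactions$delta_g)
  expect_equal(back$reactions$reversible[ord], net$reactions$reversible)
})

test_that("SBML export/import round trip is lossless", {
  net <- toy_tca_model()
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(net, f)
  back <- import_sbml(f)
  expect_setequal(back$reactions$reaction_id, net$reactions$reaction_id)
  ord <- match(net$reactions$reaction_id, back$reactions$reaction_id)
  expect_equal(back$reactions$lower_bound[ord], net$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound[ord], net$reactions$upper_bound)
  expect_equal(back$reactions$rtype[ord], net$reactions$rtype)
  S1 <- build_stoichiometric_matrix(net); S2 <- build_stoichiometric_matrix(back)
  expect_equal(as.matrix(S1$S), as.matrix(S2$S))

  # compartment inventory is explicit in the document
  doc <- xml2::read_xml(f)
  comps <- xml2::xml_find_all(
    doc, ".//s:compartment", c(s = "http://www.sbml.org/sbml/level3/version1/core"))
  expect_equal(length(comps), length(unique(species(net)$compartment)))

  # reversible bounds (-1000, 100) survive
  rev_id <- net$reactions$reaction_id[net$reactions$reversible][1]
  expect_equal(back$reactions$lower_bound[back$reactions$reaction_id == rev_id],
               -1000)
  expect_equal(back$reactions$upper_bound[back$reactions$reaction_id == rev_id],
               100)
})
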