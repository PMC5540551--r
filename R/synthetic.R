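# Synthetic inputs with planted ground truth.
#
# The generator emulates the statistical shape of a metagenome-scale draft
# reconstruction: a connected, fully balanced backbone of unit conversions
# of a universal monomer, extra conversions wired so realized in/out degrees
# follow discrete power laws with chosen exponents, a cytoplasm-dominated
# compartment mixture, a configurable share of generic-compound reactions,
# and thermodynamic annotations consistent with the directionality policy.
# Everything downstream (localization scores, reference assignments,
# transport and candidate databases, planted gaps) derives from recorded
# ground truth, so every pipeline stage can be scored without external data.

#' Generator configuration
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param n_metabolites number of (non-generic) metabolites.
#' @param n_reactions number of core (non-scaffolding) reactions, generic
#'   ones included; NULL lets the sampled degree budgets decide, which is
#'   what realizes the target exponents without thinning (use for exponent
#'   recovery studies).
#' @param gamma_in,gamma_out target degree exponents of the metabolite
#'   graph.
#' @param fraction_generic share of core reactions touching a generic
#'   compound.
#' @param fraction_with_delta_g share of reversible core reactions carrying
#'   a (sub-threshold) Gibbs energy annotation.
#' @param reversible_fraction share of core reactions left reversible.
#' @param compartment_proportions named mixture over ground-truth
#'   compartments (cytoplasm-dominated, mirroring the usual ranking
#'   c >> m > n > x).
#' @param planted_gap_count reactions removed by [plant_gaps()] presets.
#' @param decoy_db_size decoy reactions added to the candidate database.
#' @param localization_concentration Dirichlet concentration of the
#'   localization scores on the true compartment.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1, n_metabolites = 300, n_reactions = 500,
                             gamma_in = 1.8, gamma_out = 2.0,
                             fraction_generic = 0.05,
                             fraction_with_delta_g = 0.4,
                             reversible_fraction = 0.45,
                             compartment_proportions = c(c = 0.72, m = 0.17,
                                                         n = 0.07, x = 0.04),
                             planted_gap_count = 10, decoy_db_size = 40,
                             localization_concentration = 25) {
  stopifnot(n_metabolites > 1,
            is.null(n_reactions) || n_reactions >= n_metabolites,
            abs(sum(compartment_proportions) - 1) < 1e-9,
            all(compartment_proportions >= 0),
            fraction_generic >= 0, fraction_generic <= 1,
            planted_gap_count >= 0, decoy_db_size >= 0)
  if (!is.null(n_reactions) && planted_gap_count > n_reactions) {
    stop("more planted gaps than reactions")
  }
  structure(as.list(environment()), class = "generator_config")
}

# inverse-CDF sample from a zeta / discrete power-law distribution
rzeta <- function(n, gamma, k_max = 1000) {
  k <- seq_len(k_max)
  p <- k^(-gamma); p <- p / sum(p)
  sample(k, n, replace = TRUE, prob = p)
}

met_ids <- function(n) sprintf("met%04d", seq_len(n))

#' Generate a synthetic draft network with ground truth
#'
#' Builds a connected draft reconstruction in the cytoplasm with an uptake
#' root and secretion of every sink, so the baseline network has no dead
#' ends; extra unit conversions steer the degree distributions towards the
#' target exponents. All metabolites share one fully specified monomer
#' formula, so every non-generic reaction is exactly mass- and
#' charge-balanced by construction.
#'
#' @param config a [generator_config()].
#' @return list with `network` (a `metnet`) and `ground_truth`: per-reaction
#'   true compartments, generic reaction ids, core reaction ids, and the
#'   target exponents.
#' @export
generate_network <- function(config) {
  set.seed(config$seed)
  nm <- config$n_metabolites
  mets <- met_ids(nm)

  # Per-node degree budgets drawn from the target discrete power laws. A
  # digraph forces mean in-degree = mean out-degree, so the heavier-tailed
  # side is truncated at the cutoff that equalizes the two means (the usual
  # finite-size reconciliation of unequal exponents); the spine consumes
  # one in-stub per node and one out-stub of its parent, so realized
  # degrees track the sampled budgets.
  zmean <- function(g, K) { k <- seq_len(K); sum(k^(1 - g)) / sum(k^(-g)) }
  kmax_in <- kmax_out <- nm
  m_in <- zmean(config$gamma_in, nm); m_out <- zmean(config$gamma_out, nm)
  matched_cutoff <- function(g, target) {
    lo <- 2L; hi <- nm
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (zmean(g, mid) < target) lo <- mid + 1L else hi <- mid
    }
    lo
  }
  if (m_in > m_out) kmax_in <- matched_cutoff(config$gamma_in, m_out)
  if (m_out > m_in) kmax_out <- matched_cutoff(config$gamma_out, m_in)
  din <- rzeta(nm, config$gamma_in, k_max = kmax_in)
  dout <- rzeta(nm, config$gamma_out, k_max = kmax_out)

  edges_from <- integer(nm - 1L); edges_to <- integer(nm - 1L)
  out_left <- dout
  for (i in 2:nm) {
    w <- pmax(out_left[seq_len(i - 1)], 0)
    parent <- if (sum(w) > 0) sample.int(i - 1, 1, prob = w) else
      sample.int(i - 1, 1)
    out_left[parent] <- out_left[parent] - 1L
    edges_from[i - 1L] <- parent; edges_to[i - 1L] <- i
  }
  in_left <- din - 1L; in_left[1] <- din[1]
  out_stubs <- sample(rep.int(seq_len(nm), pmax(out_left, 0L)))
  in_stubs <- sample(rep.int(seq_len(nm), pmax(in_left, 0L)))
  m_avail <- min(length(out_stubs), length(in_stubs))
  if (is.null(config$n_reactions)) {
    n_extra <- m_avail
    n_core <- (nm - 1L) + n_extra
    f <- config$fraction_generic
    n_generic <- round(n_core * f / (1 - f))
  } else {
    n_generic <- round(config$fraction_generic * config$n_reactions)
    n_core <- config$n_reactions - n_generic
    if (n_core < nm) stop("infeasible config: need >= n_metabolites core reactions")
    n_extra <- n_core - (nm - 1L)
  }
  if (n_extra > 0) {
    m <- min(m_avail, n_extra)
    srcs <- out_stubs[seq_len(m)]; tgts <- in_stubs[seq_len(m)]
    if (n_extra > m) {  # budgets exhausted: pad with uniform conversions
      srcs <- c(srcs, sample.int(nm, n_extra - m, replace = TRUE))
      tgts <- c(tgts, sample.int(nm, n_extra - m, replace = TRUE))
    }
    same <- srcs == tgts
    tgts[same] <- (tgts[same] %% nm) + 1L
    edges_from <- c(edges_from, srcs); edges_to <- c(edges_to, tgts)
  }
  n_conv <- length(edges_from)
  conv_ids <- sprintf("rxn%04d", seq_len(n_conv))

  # thermodynamics consistent with the T = 30 kJ/mol directionality policy
  reversible <- stats::runif(n_conv) < config$reversible_fraction
  delta_g <- rep(NA_real_, n_conv)
  irrev <- which(!reversible)
  delta_g[irrev] <- -(30 + stats::rexp(length(irrev), rate = 1 / 20))
  rev_ann <- which(reversible & stats::runif(n_conv) < config$fraction_with_delta_g)
  delta_g[rev_ann] <- stats::runif(length(rev_ann), -25, 25)

  pol <- default_bound_policy()
  reactions <- data.frame(
    reaction_id = conv_ids, reversible = reversible,
    lower_bound = ifelse(reversible, pol$reversible[1], pol$irreversible[1]),
    upper_bound = ifelse(reversible, pol$reversible[2], pol$irreversible[2]),
    delta_g = delta_g,
    ec_numbers = sprintf("%d.%d.%d.%d", sample(1:6, n_conv, TRUE),
                         sample(1:9, n_conv, TRUE), sample(1:9, n_conv, TRUE),
                         sample(1:99, n_conv, TRUE)),
    rtype = "metabolic", stringsAsFactors = FALSE
  )
  stoich <- rbind(
    data.frame(reaction_id = conv_ids,
               species_id = species_id(mets[edges_from], "c"), coeff = -1),
    data.frame(reaction_id = conv_ids,
               species_id = species_id(mets[edges_to], "c"), coeff = 1)
  )

  # generic-compound reactions: side branches into generic pseudo-compounds
  generic_ids <- character()
  if (n_generic > 0) {
    gmet <- sprintf("generic%03d", seq_len(n_generic))
    generic_ids <- sprintf("grxn%03d", seq_len(n_generic))
    src <- sample.int(nm, n_generic, replace = TRUE)
    # no thermodynamic annotation, hence reversible under the policy
    reactions <- rbind(reactions, data.frame(
      reaction_id = generic_ids, reversible = TRUE,
      lower_bound = pol$reversible[1], upper_bound = pol$reversible[2],
      delta_g = NA_real_, ec_numbers = "", rtype = "metabolic",
      stringsAsFactors = FALSE))
    stoich <- rbind(stoich,
                    data.frame(reaction_id = generic_ids,
                               species_id = species_id(mets[src], "c"), coeff = -1),
                    data.frame(reaction_id = generic_ids,
                               species_id = species_id(gmet, "c"), coeff = 1))
  } else {
    gmet <- character()
  }

  # uptake root plus one secretion outlet per terminal strongly connected
  # component of the conversion digraph: every metabolite then reaches an
  # exported one, so the non-generic draft has no dead ends (conversions are
  # unit reactions, for which consumability is exactly reachability to an
  # outlet)
  dir_from <- edges_from; dir_to <- edges_to
  if (any(reversible)) {
    dir_from <- c(dir_from, edges_to[reversible])
    dir_to <- c(dir_to, edges_from[reversible])
  }
  gconv <- igraph::graph_from_edgelist(cbind(dir_from, dir_to), directed = TRUE)
  if (igraph::vcount(gconv) < nm) {
    gconv <- igraph::add_vertices(gconv, nm - igraph::vcount(gconv))
  }
  comp <- igraph::components(gconv, mode = "strong")
  cg <- igraph::contract(gconv, comp$membership)
  cg <- igraph::simplify(cg)
  terminal <- which(igraph::degree(cg, mode = "out") == 0)
  sinks <- sort(vapply(terminal, function(k) {
    min(which(comp$membership == k))
  }, integer(1)))
  scaffold_ids <- c("EX_upt", "T_upt",
                    sprintf("T_sec%04d", sinks), sprintf("EX_sec%04d", sinks))
  scaffold <- data.frame(
    reaction_id = scaffold_ids, reversible = FALSE,
    lower_bound = 0, upper_bound = pol$irreversible[2],
    delta_g = NA_real_, ec_numbers = "",
    rtype = c("exchange", "transport",
              rep(c("transport", "exchange"), each = length(sinks))),
    stringsAsFactors = FALSE
  )
  scaffold_st <- rbind(
    data.frame(reaction_id = "EX_upt", species_id = species_id(mets[1], "e"),
               coeff = 1),
    data.frame(reaction_id = "T_upt",
               species_id = species_id(mets[1], c("e", "c")),
               coeff = c(-1, 1)),
    data.frame(reaction_id = rep(sprintf("T_sec%04d", sinks), each = 2),
               species_id = as.vector(rbind(species_id(mets[sinks], "c"),
                                            species_id(mets[sinks], "e"))),
               coeff = rep(c(-1, 1), length(sinks))),
    data.frame(reaction_id = sprintf("EX_sec%04d", sinks),
               species_id = species_id(mets[sinks], "e"), coeff = -1)
  )

  metabolites <- rbind(
    data.frame(metabolite_id = mets, name = mets, formula = "CH2O",
               charge = 0L, mass = 30.026, is_generic = FALSE,
               stringsAsFactors = FALSE),
    if (length(gmet)) data.frame(metabolite_id = gmet, name = gmet,
                                 formula = NA_character_, charge = NA_integer_,
                                 mass = NA_real_, is_generic = TRUE,
                                 stringsAsFactors = FALSE)
  )
  net <- metnet(metabolites, rbind(reactions, scaffold),
                rbind(stoich, scaffold_st),
                log = sprintf("generate_network: seed=%d", config$seed))

  truth_comp <- sample(names(config$compartment_proportions), n_conv,
                       replace = TRUE, prob = config$compartment_proportions)
  ground_truth <- list(
    core_reactions = conv_ids,
    generic_reactions = generic_ids,
    scaffold_reactions = scaffold_ids,
    true_compartment = stats::setNames(truth_comp, conv_ids),
    gamma_in = config$gamma_in, gamma_out = config$gamma_out,
    seed = config$seed
  )
  list(network = net, ground_truth = ground_truth)
}

#' Plant gaps by removing connectivity-critical reactions
#'
#' Removes `k` reactions whose individual removal provably creates at least
#' one new dead-end species (checked with the reachability closure). The
#' removed reactions are returned as the recovery key for gap filling.
#'
#' @param net a `metnet` (typically gap-free).
#' @param k number of reactions to remove.
#' @param seed RNG seed for the removal order.
#' @param candidates reaction ids eligible for removal (default: all
#'   metabolic reactions).
#' @return list with `network` (gapped), `removed` (a `metnet` holding the
#'   removed reactions), `induced_dead_ends` (new problem species).
#' @export
plant_gaps <- function(net, k, seed = 1, candidates = NULL) {
  if (k == 0) {
    return(list(network = net, removed = subset_reactions(net, character()),
                induced_dead_ends = character()))
  }
  set.seed(seed)
  if (is.null(candidates)) {
    candidates <- net$reactions$reaction_id[net$reactions$rtype == "metabolic"]
  }
  prob_cur <- problem_species(gapfind_reachability(net))
  order <- sample(candidates)
  removed <- character(); induced <- character()
  cur <- net
  # pass 1 prefers localized gaps (small dead-end cascades), so one removal
  # near the uptake root cannot blanket the network; pass 2 accepts any
  # removal that still induces something new
  cap <- max(3L, ceiling(0.05 * length(unique(net$stoich$species_id))))
  for (pass_cap in c(cap, Inf)) {
    for (id in setdiff(order, removed)) {
      if (length(removed) >= k) break
      trial <- subset_reactions(cur, setdiff(cur$reactions$reaction_id, id))
      prob <- problem_species(gapfind_reachability(trial))
      new <- setdiff(prob, prob_cur)
      if (length(new) > 0 && length(new) <= pass_cap) {
        removed <- c(removed, id)
        induced <- union(induced, new)
        cur <- trial
        prob_cur <- prob
      }
    }
  }
  if (length(removed) < k) {
    stop("could only plant ", length(removed), " of ", k, " gaps")
  }
  list(network = log_step(cur, sprintf("plant_gaps: removed %d", k)),
       removed = subset_reactions(net, removed),
       induced_dead_ends = sort(induced))
}

#' Ancillary input tables for a generated network
#'
#' Localization scores (Dirichlet draws concentrated on the ground-truth
#' compartment), reference assignments for a subset of reactions, a
#' transport database of cytoplasm-inner exchange templates for the
#' metabolites of each ground-truth compartment, and a candidate database
#' made of the removal key plus decoys.
#'
#' @param net the generated draft network.
#' @param config the [generator_config()] used.
#' @param ground_truth from [generate_network()].
#' @param removed optional `metnet` of removed reactions ([plant_gaps()]).
#' @return list: `localization` (data.frame), `reference` (data.frame),
#'   `transport_db` (`metnet`), `candidate_db` (`metnet`).
#' @export
generate_ancillary_tables <- function(net, config, ground_truth,
                                      removed = NULL) {
  set.seed(config$seed + 1L)
  core <- ground_truth$core_reactions
  comps <- names(config$compartment_proportions)
  conc <- config$localization_concentration
  alpha <- matrix(0.5, nrow = length(core), ncol = length(comps),
                  dimnames = list(core, comps))
  alpha[cbind(core, ground_truth$true_compartment[core])] <- conc
  draws <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha),
                  dimnames = dimnames(alpha))
  scores <- draws / rowSums(draws)
  localization <- data.frame(reaction_id = core, scores, check.names = FALSE,
                             stringsAsFactors = FALSE)

  ref_idx <- sort(sample(seq_along(core), max(1L, round(0.3 * length(core)))))
  reference <- data.frame(
    reaction_id = core[ref_idx],
    compartment = unname(ground_truth$true_compartment[core[ref_idx]]),
    source_model = "synthetic_reference_model",
    stringsAsFactors = FALSE
  )

  # transport templates: m@c <=> m@K for metabolites used by reactions truly
  # assigned to inner compartment K
  sp <- split_species_id(net$stoich$species_id)
  tmpl <- list()
  for (k in setdiff(comps, "c")) {
    rx_k <- core[ground_truth$true_compartment[core] == k]
    mets_k <- sort(unique(sp$metabolite_id[net$stoich$reaction_id %in% rx_k]))
    if (length(mets_k) == 0) next
    ids <- sprintf("TPT_%s_%s", mets_k, k)
    tmpl[[k]] <- list(
      reactions = data.frame(
        reaction_id = ids, reversible = TRUE,
        lower_bound = default_bound_policy()$reversible[1],
        upper_bound = default_bound_policy()$reversible[2],
        delta_g = NA_real_, ec_numbers = "", rtype = "transport",
        stringsAsFactors = FALSE),
      stoich = rbind(
        data.frame(reaction_id = ids, species_id = species_id(mets_k, "c"),
                   coeff = -1),
        data.frame(reaction_id = ids, species_id = species_id(mets_k, k),
                   coeff = 1))
    )
  }
  transport_db <- metnet(
    net$metabolites,
    do.call(rbind, lapply(tmpl, `[[`, "reactions")),
    do.call(rbind, lapply(tmpl, `[[`, "stoich"))
  )

  # candidate database: recovery key plus decoy conversions
  nd <- config$decoy_db_size
  cand_reactions <- if (!is.null(removed)) removed$reactions else
    empty_reaction_table()
  cand_stoich <- if (!is.null(removed)) removed$stoich else empty_stoich_table()
  if (nd > 0) {
    mets <- met_ids(config$n_metabolites)
    a <- sample(mets, nd, replace = TRUE)
    b <- sample(mets, nd, replace = TRUE)
    fix <- a == b
    b[fix] <- mets[(match(a[fix], mets) %% length(mets)) + 1L]
    ids <- sprintf("decoy%03d", seq_len(nd))
    cand_reactions <- rbind(cand_reactions, data.frame(
      reaction_id = ids, reversible = FALSE,
      lower_bound = 0, upper_bound = default_bound_policy()$irreversible[2],
      delta_g = NA_real_, ec_numbers = "", rtype = "metabolic",
      stringsAsFactors = FALSE))
    cand_stoich <- rbind(cand_stoich,
                         data.frame(reaction_id = ids,
                                    species_id = species_id(a, "c"), coeff = -1),
                         data.frame(reaction_id = ids,
                                    species_id = species_id(b, "c"), coeff = 1))
  }
  candidate_db <- metnet(net$metabolites, cand_reactions, cand_stoich)
  list(localization = localization, reference = reference,
       transport_db = transport_db, candidate_db = candidate_db)
}

#' Write a complete synthetic input bundle
#'
#' Emits the reaction/metabolite tables, localization scores, reference
#' assignments and the transport/candidate databases for a seeded synthetic
#' study into a directory, in the dialects the readers consume. Identical
#' seeds give byte-identical files.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_input_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_network(config)
  gaps <- plant_gaps(gen$network, config$planted_gap_count,
                     seed = config$seed + 2L,
                     candidates = gen$ground_truth$core_reactions)
  anc <- generate_ancillary_tables(gen$network, config, gen$ground_truth,
                                   removed = gaps$removed)
  paths <- c(
    reactions = file.path(dir, "reactions.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    localization = file.path(dir, "localization.tsv"),
    reference = file.path(dir, "reference_assignments.tsv"),
    transport_db = file.path(dir, "transport_db.tsv"),
    candidate_db = file.path(dir, "candidate_db.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_network(gaps$network, paths["reactions"], paths["metabolites"])
  utils::write.table(anc$localization, paths["localization"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(anc$reference, paths["reference"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(anc$transport_db, paths["transport_db"],
                file.path(dir, ".transport_mets.tsv"))
  write_network(anc$candidate_db, paths["candidate_db"],
                file.path(dir, ".candidate_mets.tsv"))
  gt <- gen$ground_truth
  gt$removed_reactions <- gaps$removed$reactions$reaction_id
  gt$induced_dead_ends <- gaps$induced_dead_ends
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

# ---- in-paper toy fixtures -------------------------------------------------

toy_metabolites <- function(ids) {
  data.frame(metabolite_id = ids, name = ids, formula = NA_character_,
             charge = NA_integer_, mass = NA_real_, is_generic = FALSE,
             stringsAsFactors = FALSE)
}

toy_reaction <- function(id, equation, lb = NULL, ub = NULL) {
  p <- parse_equation(equation)
  pol <- default_bound_policy()
  b <- if (p$reversible) pol$reversible else pol$irreversible
  if (!is.null(lb)) b[1] <- lb
  if (!is.null(ub)) b[2] <- ub
  list(
    row = data.frame(reaction_id = id, reversible = b[1] < 0,
                     lower_bound = b[1], upper_bound = b[2],
                     delta_g = NA_real_, ec_numbers = "",
                     rtype = infer_rtype(p$stoich), stringsAsFactors = FALSE),
    stoich = cbind(reaction_id = id, p$stoich)
  )
}

toy_net <- function(rxns, met_ids, log) {
  metnet(toy_metabolites(met_ids),
         do.call(rbind, lapply(rxns, `[[`, "row")),
         do.call(rbind, lapply(rxns, `[[`, "stoich")),
         log = log)
}

#' Toy fatty-acid elongation model
#'
#' Minimal compartmentalized model in which mitochondrial fatty-acid
#' elongation (the `KAS` objective reaction) consumes acetyl-CoA that is
#' produced only in the cytoplasm and reaches the mitochondrion solely
#' through the `TACOA` acetyl-CoA exchange. Excluding `TACOA` therefore
#' forces the elongation objective to zero; with it present the objective
#' is strictly positive.
#'
#' @return a `metnet`. The objective reaction is `"KAS"`; the transport to
#'   knock out is `"TACOA"`.
#' @export
toy_fatty_acid_model <- function() {
  rxns <- list(
    toy_reaction("EX_ac", " => acetate@e"),
    toy_reaction("T_ac", "acetate@e => acetate@c"),
    toy_reaction("ACS", "acetate@c + CoA@c => Acetyl-CoA@c"),
    toy_reaction("TACOA", "Acetyl-CoA@c <=> Acetyl-CoA@m"),
    toy_reaction("KAS", "Acyl-CoA@m + Acetyl-CoA@m => CoA@m + 3-Oxoacyl-CoA@m"),
    toy_reaction("OXID", "3-Oxoacyl-CoA@m => Acyl-CoA@m + formate@m"),
    toy_reaction("TCOA", "CoA@m => CoA@c"),
    toy_reaction("T_form", "formate@m => formate@c"),
    toy_reaction("T_form2", "formate@c => formate@e"),
    toy_reaction("EX_form", "formate@e => ")
  )
  toy_net(rxns, c("acetate", "CoA", "Acetyl-CoA", "Acyl-CoA", "3-Oxoacyl-CoA",
                  "formate"),
          log = "toy_fatty_acid_model")
}

#' Toy TCA compartment-coupling model
#'
#' Compartmentalized variant: citrate synthesis runs in both the cytoplasm
#' and the mitochondrion (per-compartment enzyme capacity 1), cytosolic
#' precursor routes have capacity 2 each, the mitochondrion receives at
#' most 1 unit of pyruvate, and the oxaloacetate / acetyl-CoA /
#' oxoglutarate exchanges of the objective block connect the two pools.
#' Flattened variant: single-copy pathway in the cytoplasm (the duplicate
#' pathway removed). The objective is total citrate synthase flux
#' (`CS_c` + `CS_m`, or `CS` when flattened); optima order as
#' with-exchanges > without-exchanges > flattened.
#'
#' @param variant `"compartmentalized"` or `"flattened"`.
#' @return a `metnet`. Exchange reactions to knock out: `"X_OAA"`,
#'   `"X_ACA"`, `"X_OG"`.
#' @export
toy_tca_model <- function(variant = c("compartmentalized", "flattened")) {
  variant <- match.arg(variant)
  common <- list(
    toy_reaction("EX_glc", " => glc@e"),
    toy_reaction("T_glc", "glc@e => glc@c"),
    toy_reaction("GLY", "glc@c => pyr@c"),
    toy_reaction("PDH_c", "pyr@c => Acetyl-CoA@c", ub = 2),
    toy_reaction("PC_c", "pyr@c => Oxaloacetate@c", ub = 2),
    toy_reaction("T_co2", "co2@c => co2@e"),
    toy_reaction("EX_co2", "co2@e => "),
    toy_reaction("T_glu", "glu@c => glu@e"),
    toy_reaction("EX_glu", "glu@e => ")
  )
  if (variant == "flattened") {
    rxns <- c(common, list(
      toy_reaction("CS", "Acetyl-CoA@c + Oxaloacetate@c => Citrate@c", ub = 1),
      toy_reaction("ACO", "Citrate@c => Oxoglutarate@c + co2@c"),
      toy_reaction("OGDC", "Oxoglutarate@c => glu@c")
    ))
  } else {
    rxns <- c(common, list(
      toy_reaction("CS_c", "Acetyl-CoA@c + Oxaloacetate@c => Citrate@c", ub = 1),
      toy_reaction("ACO_c", "Citrate@c => Oxoglutarate@c + co2@c"),
      toy_reaction("OGDC", "Oxoglutarate@c => glu@c"),
      toy_reaction("T_pyr", "pyr@c => pyr@m", ub = 1),
      toy_reaction("PDH_m", "pyr@m => Acetyl-CoA@m"),
      toy_reaction("PC_m", "pyr@m => Oxaloacetate@m"),
      toy_reaction("CS_m", "Acetyl-CoA@m + Oxaloacetate@m => Citrate@m", ub = 1),
      toy_reaction("ACO_m", "Citrate@m => Oxoglutarate@m + co2@m"),
      toy_reaction("OGDC_m", "Oxoglutarate@m => co2@m"),
      toy_reaction("T_co2m", "co2@m => co2@c"),
      toy_reaction("X_OAA", "Oxaloacetate@c <=> Oxaloacetate@m"),
      toy_reaction("X_ACA", "Acetyl-CoA@c <=> Acetyl-CoA@m"),
      toy_reaction("X_OG", "Oxoglutarate@c <=> Oxoglutarate@m")
    ))
  }
  toy_net(rxns, c("glc", "pyr", "Acetyl-CoA", "Oxaloacetate", "Citrate",
                  "Oxoglutarate", "co2", "glu"),
          log = paste0("toy_tca_model:", variant))
}
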