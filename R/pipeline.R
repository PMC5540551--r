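# Pipeline orchestration: reconstruct -> compartmentalize -> curate -> FBA
# -> topology, with every stage's outputs written before the next begins and
# a summary file mirroring the layouts of the standard reporting tables.

pipeline_defaults <- function() {
  list(
    input = list(reactions = NULL, metabolites = NULL, localization = NULL,
                 reference = NULL, transport_db = NULL, candidate_db = NULL),
    stages = list(reconstruct = TRUE, compartmentalize = TRUE, curate = TRUE,
                  fba = TRUE, topology = TRUE),
    reconstruction = list(directionality_threshold = 30, strict_balance = FALSE),
    compartmentalization = list(min_score = 0.3, min_reactions = 25),
    curation = list(eps = 0.001, M = 1000, detector = "milp"),
    fba = list(objective = NULL, exclude = character(), stabilize = TRUE,
               tolerance = 1e-6),
    output = list(dir = "metacomp_run")
  )
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ",
           paste(c(path, nm), collapse = "."))
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load (and validate) a pipeline configuration
#'
#' YAML key-value file; unknown keys are rejected, unset keys fall back to
#' the package defaults. A NULL `path` returns the defaults.
#'
#' @param path YAML file path, or NULL.
#' @param overrides named list merged on top (same structure).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

write_stage_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes the stages in order on the configured inputs, writing each
#' stage's artifacts (tables, SBML models, reports) into the run directory
#' before the next stage starts, plus a `summary.tsv` collecting the
#' headline numbers of every stage. Disabling `stages$compartmentalize`
#' yields the two-compartment (cytoplasm + extracellular) build from the
#' same code path.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the curated network and the per-stage
#'   results.
#' @export
run_pipeline <- function(config) {
  dir <- config$output$dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(dir, "run.log"), open = "wt")
  on.exit(close(logf))
  summary_rows <- list()
  note <- function(stage, metric, value) {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = as.character(value),
      stringsAsFactors = FALSE)
  }

  # stage 1: reconstruction
  pipeline_log(logf, "reconstruct: reading ", config$input$reactions)
  net <- read_network(config$input$reactions, config$input$metabolites)
  note("reconstruct", "initial_reactions", nrow(net$reactions))
  note("reconstruct", "initial_metabolites", nrow(net$metabolites))
  if (isTRUE(config$stages$reconstruct)) {
    rg <- remove_generic_reactions(net)
    net <- rg$network
    note("reconstruct", "generic_reactions_removed", length(rg$removed_ids))
    bal <- balance_network(net, strict = config$reconstruction$strict_balance)
    net <- bal$network
    write_stage_tsv(bal$reports, dir, "balance_reports.tsv")
    note("reconstruct", "unbalanced_reactions",
         sum(bal$reports$status == "unbalanced"))
    net <- assign_directionality(
      net, threshold = config$reconstruction$directionality_threshold)
    note("reconstruct", "reversible_reactions", sum(net$reactions$reversible))
    write_network(net, file.path(dir, "reconstructed_reactions.tsv"),
                  file.path(dir, "reconstructed_metabolites.tsv"))
  }

  # stage 2: compartmentalization
  transport_db <- if (!is.null(config$input$transport_db)) {
    read_transport_db(config$input$transport_db)
  } else NULL
  if (isTRUE(config$stages$compartmentalize)) {
    pipeline_log(logf, "compartmentalize: consensus assignment")
    loc <- if (!is.null(config$input$localization)) {
      read_localization(config$input$localization)
    } else NULL
    ref <- if (!is.null(config$input$reference)) {
      read_reference_assignments(config$input$reference)
    } else NULL
    scope <- net$reactions$reaction_id[net$reactions$rtype == "metabolic"]
    scope <- intersect(scope, c(loc$reaction_id, ref$reaction_id))
    asg <- consensus_localization(scope, loc, ref,
                                  min_score = config$compartmentalization$min_score)
    pr <- prune_compartments(asg, loc,
                             min_reactions = config$compartmentalization$min_reactions)
    if (nrow(pr$discarded) > 0) {
      write_stage_tsv(pr$discarded, dir, "discarded_compartments.tsv")
    }
    note("compartmentalize", "compartments_discarded", nrow(pr$discarded))
    net <- compartmentalize_network(net, pr$assignments)
    counts <- species_counts_by_compartment(net)
    for (k in names(counts)) {
      note("compartmentalize", paste0("species_", k), counts[[k]])
    }
  }
  if (!is.null(transport_db)) {
    inj <- inject_transport(net, transport_db)
    net <- inj$network
    note("compartmentalize", "transport_added_cyt_extracellular",
         inj$counts[["cytoplasm_extracellular"]])
    note("compartmentalize", "transport_added_cyt_inner",
         inj$counts[["cytoplasm_inner"]])
  }
  export_sbml(net, file.path(dir, "compartmentalized_model.xml"))

  # stage 3: curation
  curated <- NULL
  if (isTRUE(config$stages$curate)) {
    pipeline_log(logf, "curate: gap detection and filling")
    candidate_db <- if (!is.null(config$input$candidate_db)) {
      read_network(config$input$candidate_db, config$input$metabolites)
    } else NULL
    cur <- curate_compartmentalized(net, candidate_db, transport_db,
                                    config = config$curation)
    net <- cur$network
    curated <- cur
    write_stage_tsv(cur$before$per_compartment_counts, dir,
                    "gap_report_before.tsv")
    write_stage_tsv(cur$after$per_compartment_counts, dir,
                    "gap_report_after.tsv")
    write_stage_tsv(as.data.frame(cur$stats), dir, "curation_stats.tsv")
    if (length(cur$before$common_gaps)) {
      write_stage_tsv(
        data.frame(pair = names(cur$before$common_gaps),
                   shared_problem_metabolites = cur$before$common_gaps),
        dir, "common_gaps.tsv")
    }
    note("curate", "reactions_added",
         length(unlist(cur$added)))
    export_sbml(net, file.path(dir, "curated_model.xml"))
  }

  # stage 4: flux balance analysis
  flux <- NULL
  if (isTRUE(config$stages$fba)) {
    obj_ids <- config$fba$objective
    if (is.null(obj_ids)) {
      # default: maximize total secretion
      obj_ids <- net$reactions$reaction_id[net$reactions$rtype == "exchange" &
                                             startsWith(net$reactions$reaction_id, "EX_sec")]
    }
    obj_ids <- intersect(obj_ids, net$reactions$reaction_id)
    if (length(obj_ids) > 0) {
      pipeline_log(logf, "fba: objective over ", length(obj_ids), " reactions")
      prob <- build_problem(net, obj_ids)
      if (length(config$fba$exclude)) {
        prob <- exclude_reactions(prob,
                                  intersect(config$fba$exclude,
                                            prob$matrix$reactions))
      }
      flux <- solve_fba(prob, stabilize = isTRUE(config$fba$stabilize))
      note("fba", "status", flux$status)
      if (flux$status == "optimal") {
        note("fba", "Z", format(flux$Z, digits = 10))
        sp <- split_species_id(net$stoich$species_id)
        scopes <- c(list(network = net$reactions$reaction_id),
                    lapply(split(net$stoich$reaction_id, sp$compartment),
                           unique))
        af <- active_flux_fraction(flux, scopes,
                                   tolerance = config$fba$tolerance)
        for (k in names(af)) {
          note("fba", paste0("active_pct_", k), sprintf("%.2f", af[[k]]))
        }
        write_stage_tsv(
          data.frame(reaction_id = names(flux$v), flux = flux$v,
                     active = abs(flux$v) > config$fba$tolerance),
          dir, "fluxes.tsv")
      }
    }
  }

  # stage 5: topology
  topo <- NULL
  if (isTRUE(config$stages$topology)) {
    pipeline_log(logf, "topology: metabolite graph metrics")
    g <- build_metabolite_graph(net)
    topo <- topology_summary(g)
    for (nm in names(unclass(topo))) {
      note("topology", nm, format(topo[[nm]], digits = 6))
    }
    ranking <- rank_central_metabolites(g, build_stoichiometric_matrix(net))
    write_stage_tsv(utils::head(ranking, 50), dir, "central_metabolites.tsv")
    el <- igraph::as_edgelist(g)
    write_stage_tsv(data.frame(from = el[, 1], to = el[, 2],
                               weight = igraph::E(g)$weight),
                    dir, "metabolite_graph_edges.tsv")
  }

  write_stage_tsv(do.call(rbind, summary_rows), dir, "summary.tsv")
  pipeline_log(logf, "done")
  invisible(list(network = net, curation = curated, flux = flux,
                 topology = topo, summary = do.call(rbind, summary_rows)))
}
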