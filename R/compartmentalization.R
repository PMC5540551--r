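# Stage 2: compartment assignment, pruning, species duplication and
# transport/exchange injection.
#
# Localization evidence comes from two sources: per-reaction subcellular
# localization probability scores (CELLO-style output) and compartment
# assignments lifted from reference compartmentalized reconstructions.
# The consensus is the union of both; compartments with negligible support
# are pruned and their reactions reassigned.

#' Read a localization score table
#'
#' CELLO-style TSV: `reaction_id` column followed by one probability column
#' per compartment code. Scores per reaction must be nonnegative and sum
#' to 1 (tolerance 1e-6).
#'
#' @param path TSV path.
#' @return data.frame with `reaction_id` and score columns.
#' @export
read_localization <- function(path) {
  df <- read_tsv(path)
  score_cols <- setdiff(names(df), "reaction_id")
  bad <- setdiff(score_cols, names(DRAFT_COMPARTMENTS))
  if (length(bad)) stop("unknown compartment column(s): ", paste(bad, collapse = ","))
  s <- as.matrix(df[, score_cols, drop = FALSE])
  if (any(s < -1e-9)) stop("negative localization score")
  if (any(abs(rowSums(s) - 1) > 1e-6)) {
    stop("localization scores must sum to 1 per reaction")
  }
  df
}

#' Read a reference compartment-assignment table
#'
#' TSV columns: `reaction_id`, `compartment`, `source_model` (assignments
#' mined from reference compartmentalized reconstructions).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_reference_assignments <- function(path) {
  df <- read_tsv(path)
  if (!all(c("reaction_id", "compartment") %in% names(df))) {
    stop("reference table needs reaction_id, compartment columns")
  }
  if (!"source_model" %in% names(df)) df$source_model <- ""
  df
}

loc_score_matrix <- function(localization) {
  cols <- setdiff(names(localization), "reaction_id")
  m <- as.matrix(localization[, cols, drop = FALSE])
  rownames(m) <- localization$reaction_id
  m
}

argmax_compartment <- function(scores) {
  # ties broken by the fixed priority c > m > n > x > e (> v > l)
  best <- names(scores)[scores >= max(scores) - 1e-12]
  best[order(match(best, COMPARTMENT_PRIORITY))][1]
}

#' Consensus compartment assignment
#'
#' For each reaction the assignment is the union of (i) compartments whose
#' localization score is at least `min_score` and (ii) the reference-model
#' compartments. If the union is empty the top-scoring compartment is used,
#' ties broken by the fixed priority c > m > n > x > e. Reactions with
#' neither scores nor a reference entry are an error.
#'
#' @param reaction_ids reactions to assign.
#' @param localization data.frame from [read_localization()] (may be NULL).
#' @param reference data.frame from [read_reference_assignments()] (may be
#'   NULL).
#' @param min_score score threshold (default 0.3).
#' @return named list: reaction id -> character vector of compartments.
#' @export
consensus_localization <- function(reaction_ids, localization = NULL,
                                   reference = NULL, min_score = 0.3) {
  scores <- if (!is.null(localization)) loc_score_matrix(localization) else
    matrix(numeric(), 0, 0)
  refs <- if (!is.null(reference)) split(reference$compartment, reference$reaction_id)
  else list()
  missing <- reaction_ids[!(reaction_ids %in% rownames(scores)) &
                            !(reaction_ids %in% names(refs))]
  if (length(missing) > 0) {
    stop("no localization evidence for reaction(s): ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(reaction_ids, function(id) {
    hit <- character()
    if (id %in% rownames(scores)) {
      s <- scores[id, ]
      hit <- names(s)[s >= min_score]
    }
    hit <- union(hit, unlist(refs[[id]]))
    if (length(hit) == 0) hit <- argmax_compartment(scores[id, ])
    sort(unique(hit))
  })
  stats::setNames(out, reaction_ids)
}

#' Prune negligible compartments
#'
#' Compartments with fewer than `min_reactions` assigned reactions are
#' discarded; their reactions are reassigned to the best-scoring surviving
#' compartment (fallback: cytoplasm). The cytoplasm and the extracellular
#' space can never be pruned.
#'
#' @param assignments named list from [consensus_localization()].
#' @param localization score table (used for reassignment; may be NULL).
#' @param min_reactions pruning threshold (default 25).
#' @return list with `assignments` (pruned) and `discarded` (data.frame
#'   `compartment`, `n_reactions`).
#' @export
prune_compartments <- function(assignments, localization = NULL,
                               min_reactions = 25) {
  counts <- table(unlist(assignments))
  drop <- names(counts)[counts < min_reactions]
  if (any(drop %in% c("c", "e"))) {
    stop("pruning the cytoplasm or extracellular space is forbidden")
  }
  discarded <- data.frame(compartment = drop,
                          n_reactions = as.integer(counts[drop]),
                          stringsAsFactors = FALSE)
  if (length(drop) == 0) return(list(assignments = assignments,
                                     discarded = discarded))
  scores <- if (!is.null(localization)) loc_score_matrix(localization) else
    matrix(numeric(), 0, 0)
  surviving <- setdiff(names(counts), drop)
  assignments <- lapply(stats::setNames(names(assignments), names(assignments)),
                        function(id) {
    a <- setdiff(assignments[[id]], drop)
    if (length(a) == 0) {
      a <- "c"
      if (id %in% rownames(scores)) {
        cols <- intersect(colnames(scores), surviving)
        s <- stats::setNames(as.numeric(scores[id, cols]), cols)
        if (length(s) && max(s) > 0) a <- argmax_compartment(s)
      }
    }
    a
  })
  list(assignments = assignments, discarded = discarded)
}

#' Duplicate reactions and species into their assigned compartments
#'
#' Each reaction is copied once per assigned compartment; in the copy for
#' compartment k every non-extracellular species is re-homed to k (the same
#' metabolite in two compartments becomes two distinct species).
#' Extracellular species keep their compartment so exchange scaffolding
#' survives. With all assignments equal to `{c}` this is the degenerate
#' non-compartmentalized build.
#'
#' @param net a `metnet` (typically drafted entirely in the cytoplasm).
#' @param assignments named list: reaction id -> compartments. Reactions
#'   absent from the list keep a single cytoplasmic copy.
#' @return a compartmentalized `metnet`; per-compartment species counts are
#'   appended to the provenance log.
#' @export
compartmentalize_network <- function(net, assignments) {
  rx <- net$reactions
  rows <- list(); sts <- list()
  for (i in seq_len(nrow(rx))) {
    id <- rx$reaction_id[i]
    comps <- assignments[[id]]
    if (is.null(comps)) comps <- "c"
    st <- reaction_stoich(net, id)
    sp <- split_species_id(st$species_id)
    for (k in comps) {
      new_id <- if (length(comps) == 1 && k == "c") id else paste0(id, "_", k)
      st_k <- st
      rehome <- sp$compartment != "e"
      st_k$species_id[rehome] <- species_id(sp$metabolite_id[rehome], k)
      row <- rx[i, , drop = FALSE]
      row$reaction_id <- new_id
      row$rtype <- infer_rtype(st_k)
      rows[[length(rows) + 1L]] <- row
      sts[[length(sts) + 1L]] <- cbind(reaction_id = new_id,
                                       st_k[, c("species_id", "coeff")])
    }
  }
  out <- metnet(net$metabolites, do.call(rbind, rows), do.call(rbind, sts),
                log = net$log)
  counts <- species_counts_by_compartment(out)
  log_step(out, paste0("compartmentalize_network: species per compartment ",
                       paste(sprintf("%s=%d", names(counts), counts),
                             collapse = ", ")))
}

#' Per-compartment species counts
#'
#' The layout used to summarize how many (non-generic) metabolites live in
#' each compartment of a compartmentalized reconstruction.
#'
#' @param net a `metnet`.
#' @param exclude_generic drop generic metabolites from the counts.
#' @return named integer vector, one entry per compartment present.
#' @export
species_counts_by_compartment <- function(net, exclude_generic = TRUE) {
  sp <- species(net)
  if (exclude_generic) {
    generic <- net$metabolites$metabolite_id[net$metabolites$is_generic %in% TRUE]
    sp <- sp[!(sp$metabolite_id %in% generic), , drop = FALSE]
  }
  counts <- table(sp$compartment)
  ord <- intersect(COMPARTMENT_PRIORITY, names(counts))
  stats::setNames(as.integer(counts[ord]), ord)
}

#' Read a transport/exchange reaction database
#'
#' Same TSV dialect as the reaction table, with cross-compartment species
#' (e.g. `"X@c <=> X@m"`). Every entry must be a transport or exchange
#' reaction.
#'
#' @param path TSV path.
#' @param metabolite_table optional metabolite TSV declaring any metabolites
#'   not already known.
#' @return a `metnet` holding the templates.
#' @export
read_transport_db <- function(path, metabolite_table = NULL) {
  rt <- read_tsv(path)
  ids <- unique(unlist(lapply(rt$equation, function(eq) {
    split_species_id(parse_equation(eq)$stoich$species_id)$metabolite_id
  })))
  mt <- if (!is.null(metabolite_table)) read_tsv(metabolite_table) else
    data.frame(metabolite_id = ids, name = ids, formula = NA_character_,
               charge = NA_integer_, mass = NA_real_, is_generic = FALSE,
               stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv"); on.exit(unlink(f))
  utils::write.table(rt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- tempfile(fileext = ".tsv"); on.exit(unlink(f2), add = TRUE)
  utils::write.table(mt, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  db <- read_network(f, f2)
  bad <- db$reactions$reaction_id[!(db$reactions$rtype %in% c("transport", "exchange"))]
  if (length(bad)) {
    stop("transport db entries must be transport/exchange reactions: ",
         paste(bad, collapse = ", "))
  }
  db
}

#' Inject eligible transport and exchange reactions
#'
#' A template from the database is added iff every species it references
#' (metabolite and compartment) already exists in the network, so injection
#' never invents metabolites. Additions are reported separately for
#' cytoplasm-extracellular and cytoplasm-inner-compartment templates.
#' Monotone: growing the database never removes a previously eligible
#' addition.
#'
#' @param net a compartmentalized `metnet`.
#' @param db a `metnet` of templates (see [read_transport_db()]).
#' @return list with `network`, `added_ids`, and `counts` (named vector:
#'   `cytoplasm_extracellular`, `cytoplasm_inner`).
#' @export
inject_transport <- function(net, db) {
  have <- unique(net$stoich$species_id)
  present <- unique(net$reactions$reaction_id)
  added <- character(); kind <- character()
  for (id in db$reactions$reaction_id) {
    if (id %in% present) next
    st <- reaction_stoich(db, id)
    if (!all(st$species_id %in% have)) next
    comps <- unique(split_species_id(st$species_id)$compartment)
    row <- db$reactions[db$reactions$reaction_id == id, , drop = FALSE]
    net <- add_reactions(
      net, row, cbind(reaction_id = id, st),
      metabolites = db$metabolites[db$metabolites$metabolite_id %in%
                                     split_species_id(st$species_id)$metabolite_id, ,
                                   drop = FALSE])
    added <- c(added, id)
    kind <- c(kind, if ("e" %in% comps) "cytoplasm_extracellular" else
      "cytoplasm_inner")
  }
  counts <- c(cytoplasm_extracellular = sum(kind == "cytoplasm_extracellular"),
              cytoplasm_inner = sum(kind == "cytoplasm_inner"))
  net <- log_step(net, sprintf(
    "inject_transport: added %d (%d cytoplasm-extracellular, %d cytoplasm-inner)",
    length(added), counts[1], counts[2]))
  list(network = net, added_ids = added, counts = counts)
}

#' Unique metabolite identity set
#'
#' Compartment-stripped metabolite ids of a network. Compartmentalized and
#' non-compartmentalized builds of the same input share this set: the two
#' differ in where metabolites live, not in which metabolites exist.
#'
#' @param net a `metnet`.
#' @return sorted character vector of metabolite ids in use.
#' @export
metabolite_set <- function(net) {
  sort(unique(split_species_id(net$stoich$species_id)$metabolite_id))
}
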