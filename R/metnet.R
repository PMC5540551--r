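# Compartment vocabulary. Vacuole (v) and lysosome (l) are admissible only in
# draft assignments, before compartment pruning.
COMPARTMENTS <- c(
  c = "cytoplasm", m = "mitochondrion", n = "nucleus",
  x = "peroxisome", e = "extracellular"
)
DRAFT_COMPARTMENTS <- c(COMPARTMENTS, v = "vacuole", l = "lysosome")

# Fixed tie-break priority used wherever one compartment must be chosen.
COMPARTMENT_PRIORITY <- c("c", "m", "n", "x", "e", "v", "l")

#' Default flux bound policy
#'
#' Irreversible reactions carry bounds (0, 100) and reversible reactions
#' (-1000, 100) mmol/gDW/h.
#'
#' @return list with elements `irreversible` and `reversible`, each a
#'   numeric `c(lower, upper)` pair.
#' @export
default_bound_policy <- function() {
  list(irreversible = c(0, 100), reversible = c(-1000, 100))
}

species_id <- function(metabolite_id, compartment) {
  paste0(metabolite_id, "@", compartment)
}

split_species_id <- function(species_ids) {
  # species ids use the convention "<metabolite_id>@<compartment>"; the
  # metabolite id itself may contain anything but "@" at its tail position.
  m <- regmatches(species_ids, regexpr("@[a-z]$", species_ids))
  bad <- lengths(regmatches(species_ids, gregexpr("@[a-z]$", species_ids))) == 0
  if (any(bad)) {
    stop("malformed species id(s): ", paste(species_ids[bad], collapse = ", "))
  }
  data.frame(
    species_id = species_ids,
    metabolite_id = substr(species_ids, 1, nchar(species_ids) - 2L),
    compartment = substr(species_ids, nchar(species_ids), nchar(species_ids)),
    stringsAsFactors = FALSE
  )
}

#' Construct a compartmentalized metabolic network
#'
#' The container shared by every pipeline stage. Species are
#' metabolite-compartment pairs identified as `"<metabolite>@<compartment>"`;
#' the same metabolite in two compartments is two distinct species. Reactions
#' carry signed stoichiometry over species (negative = substrate), bounds,
#' reversibility, optional standard transformed Gibbs energy, EC numbers and
#' a type (metabolic, transport or exchange).
#'
#' @param metabolites data.frame with columns `metabolite_id`, `name`,
#'   `formula`, `charge`, `mass`, `is_generic`.
#' @param reactions data.frame with columns `reaction_id`, `reversible`,
#'   `lower_bound`, `upper_bound`, `delta_g`, `ec_numbers`, `rtype`.
#' @param stoich long-format data.frame with columns `reaction_id`,
#'   `species_id`, `coeff`.
#' @param log character vector of provenance records.
#' @param validate check invariants (default TRUE).
#' @return object of class `metnet`.
#' @export
metnet <- function(metabolites, reactions, stoich, log = character(),
                   validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoich <- as.data.frame(stoich, stringsAsFactors = FALSE)
  net <- structure(
    list(metabolites = metabolites, reactions = reactions, stoich = stoich,
         log = log),
    class = "metnet"
  )
  if (validate) validate_metnet(net)
  net
}

validate_metnet <- function(net) {
  r <- net$reactions
  if (anyDuplicated(r$reaction_id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(r$reaction_id[duplicated(r$reaction_id)]), collapse = ", "))
  }
  if (anyDuplicated(net$metabolites$metabolite_id)) {
    stop("duplicate metabolite id(s)")
  }
  if (nrow(net$stoich) > 0) {
    sp <- split_species_id(unique(net$stoich$species_id))
    missing <- setdiff(sp$metabolite_id, net$metabolites$metabolite_id)
    if (length(missing) > 0) {
      stop("dangling species reference(s): reaction stoichiometry names ",
           "undeclared metabolite(s): ", paste(missing, collapse = ", "))
    }
    unknown <- setdiff(net$stoich$reaction_id, r$reaction_id)
    if (length(unknown) > 0) {
      stop("stoichiometry rows for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    }
    bad_comp <- setdiff(sp$compartment, names(DRAFT_COMPARTMENTS))
    if (length(bad_comp) > 0) {
      stop("unknown compartment code(s): ", paste(bad_comp, collapse = ", "))
    }
  }
  counts <- table(factor(net$stoich$reaction_id, levels = r$reaction_id))
  if (any(counts == 0)) {
    stop("reaction(s) with empty stoichiometry: ",
         paste(r$reaction_id[counts == 0], collapse = ", "))
  }
  if (any(r$lower_bound > r$upper_bound)) stop("lower_bound > upper_bound")
  if (any(r$reversible != (r$lower_bound < 0))) {
    stop("reversible flag inconsistent with lower bound sign")
  }
  invisible(net)
}

#' Species table of a network
#'
#' Species are derived from the reaction stoichiometry: every
#' metabolite-compartment pair referenced by at least one reaction.
#'
#' @param net a `metnet`.
#' @return data.frame with columns `species_id`, `metabolite_id`,
#'   `compartment`, lexicographically ordered by `species_id`.
#' @export
species <- function(net) {
  ids <- sort(unique(net$stoich$species_id))
  split_species_id(ids)
}

#' @export
print.metnet <- function(x, ...) {
  sp <- species(x)
  cat("<metnet> ", nrow(x$reactions), " reactions, ", nrow(sp), " species (",
      length(unique(sp$metabolite_id)), " metabolites), compartments: ",
      paste(sort(unique(sp$compartment)), collapse = ","), "\n", sep = "")
  if (length(x$log)) cat("  log: ", paste(x$log, collapse = " | "), "\n", sep = "")
  invisible(x)
}

log_step <- function(net, msg) {
  net$log <- c(net$log, msg)
  net
}

# ---- equation dialect ------------------------------------------------------

normalize_arrow <- function(eq) {
  eq <- gsub("<\\s*=+\\s*>", " <=> ", eq)
  eq <- gsub("([^<=])=\\s*>", "\\1 => ", eq)
  eq
}

parse_side <- function(side, default_compartment) {
  side <- trimws(side)
  if (side == "") {
    return(data.frame(species_id = character(), coeff = numeric(),
                      stringsAsFactors = FALSE))
  }
  chunks <- trimws(strsplit(side, "\\s\\+\\s")[[1]])
  chunks <- chunks[chunks != ""]
  out <- lapply(chunks, function(ch) {
    coeff <- 1
    m <- regexpr("^[0-9]*\\.?[0-9]+\\s+", ch)
    if (m > 0) {
      coeff <- as.numeric(trimws(regmatches(ch, m)))
      ch <- trimws(substring(ch, attr(m, "match.length") + 1L))
    }
    # compartment suffix: "@c" or "[c]"; otherwise the default applies
    comp <- default_compartment
    if (grepl("@[a-z]$", ch)) {
      comp <- substr(ch, nchar(ch), nchar(ch))
      ch <- substr(ch, 1, nchar(ch) - 2L)
    } else if (grepl("\\[[a-z]\\]$", ch)) {
      comp <- substr(ch, nchar(ch) - 1L, nchar(ch) - 1L)
      ch <- substr(ch, 1, nchar(ch) - 3L)
    }
    if (ch == "") stop("malformed stoichiometry term: '", ch, "'")
    data.frame(species_id = species_id(ch, comp), coeff = coeff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parse a reaction equation string
#'
#' Dialect: `"2 A@c + B@c <=> C@c"`. `<=>` marks a reversible reaction,
#' `=>` (or a bare `=`) an irreversible one. Compartments are given as an
#' `@x` or `[x]` suffix; terms lacking one are placed in
#' `default_compartment`. Metabolite ids are opaque and may contain spaces.
#'
#' @param equation equation string.
#' @param default_compartment compartment code for unsuffixed terms.
#' @return list with `stoich` (data.frame `species_id`, `coeff`; substrates
#'   negative) and `reversible`.
#' @export
parse_equation <- function(equation, default_compartment = "c") {
  eq <- normalize_arrow(equation)
  reversible <- grepl("<=>", eq, fixed = TRUE)
  if (reversible) {
    sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  } else if (grepl("=>", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "=>", fixed = TRUE)[[1]]
  } else if (grepl("\\s=\\s", eq)) {
    sides <- strsplit(eq, "\\s=\\s")[[1]]
  } else {
    stop("malformed equation (no arrow): '", equation, "'")
  }
  if (length(sides) != 2) stop("malformed equation: '", equation, "'")
  lhs <- parse_side(sides[1], default_compartment)
  rhs <- parse_side(sides[2], default_compartment)
  if (nrow(lhs) == 0 && nrow(rhs) == 0) {
    stop("empty equation: '", equation, "'")
  }
  if (nrow(lhs) > 0) lhs$coeff <- -lhs$coeff
  st <- rbind(lhs, rhs)
  # merge duplicated species (e.g. a term on both sides)
  st <- stats::aggregate(coeff ~ species_id, data = st, FUN = sum)
  st <- st[abs(st$coeff) > 1e-12, , drop = FALSE]
  list(stoich = st[order(st$species_id), , drop = FALSE], reversible = reversible)
}

#' Format reaction stoichiometry as an equation string
#'
#' Inverse of [parse_equation()]; coefficients of 1 are omitted.
#'
#' @param stoich data.frame with `species_id`, `coeff`.
#' @param reversible logical.
#' @return equation string in the `"A@c => B@c"` dialect.
#' @export
format_equation <- function(stoich, reversible) {
  fmt <- function(df) {
    if (nrow(df) == 0) return("")
    df <- df[order(df$species_id), , drop = FALSE]
    co <- abs(df$coeff)
    term <- ifelse(abs(co - 1) < 1e-12, df$species_id,
                   paste(format(co, trim = TRUE, digits = 10), df$species_id))
    paste(term, collapse = " + ")
  }
  lhs <- fmt(stoich[stoich$coeff < 0, , drop = FALSE])
  rhs <- fmt(stoich[stoich$coeff > 0, , drop = FALSE])
  paste(lhs, if (reversible) "<=>" else "=>", rhs)
}

infer_rtype <- function(stoich_df) {
  sp <- split_species_id(stoich_df$species_id)
  comps <- unique(sp$compartment)
  one_sided <- all(stoich_df$coeff > 0) || all(stoich_df$coeff < 0)
  if (one_sided && all(comps == "e")) return("exchange")
  if (length(comps) >= 2) return("transport")
  "metabolic"
}

# ---- readers / writers -----------------------------------------------------

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "",
                    check.names = FALSE, comment.char = "")
}

#' Read a network from annotation tables
#'
#' @param reaction_table path to a TSV with columns `reaction_id`,
#'   `equation`, `ec_numbers` (semicolon-separated, may be empty), `delta_g`
#'   (kJ/mol, blank allowed) and `rtype` (blank = inferred).
#' @param metabolite_table path to a TSV with columns `metabolite_id`,
#'   `name`, `formula`, `charge`, `mass`, `is_generic`.
#' @param default_compartment compartment for unsuffixed equation terms.
#' @param bound_policy see [default_bound_policy()].
#' @return a [metnet] object. Reactions referencing metabolites absent from
#'   the metabolite table raise a dangling-reference error.
#' @export
read_network <- function(reaction_table, metabolite_table,
                         default_compartment = "c",
                         bound_policy = default_bound_policy()) {
  rt <- read_tsv(reaction_table)
  mt <- read_tsv(metabolite_table)
  needed <- c("metabolite_id", "name", "formula", "charge", "mass", "is_generic")
  if (!all(needed %in% names(mt))) {
    stop("metabolite table must have columns: ", paste(needed, collapse = ", "))
  }
  mt$is_generic <- as.logical(mt$is_generic)
  mt$charge <- suppressWarnings(as.integer(mt$charge))
  mt$mass <- suppressWarnings(as.numeric(mt$mass))
  if (any(!is.na(mt$mass) & mt$mass <= 0)) stop("metabolite mass must be > 0")
  if (nrow(rt) == 0) {
    return(metnet(mt, empty_reaction_table(), empty_stoich_table()))
  }
  if (!all(c("reaction_id", "equation") %in% names(rt))) {
    stop("reaction table must have columns reaction_id, equation")
  }
  parsed <- lapply(seq_len(nrow(rt)), function(i) {
    p <- tryCatch(parse_equation(rt$equation[i], default_compartment),
                  error = function(e) {
                    stop("line ", i + 1L, " (", rt$reaction_id[i], "): ",
                         conditionMessage(e), call. = FALSE)
                  })
    p
  })
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  delta_g <- if ("delta_g" %in% names(rt)) {
    suppressWarnings(as.numeric(rt$delta_g))
  } else rep(NA_real_, nrow(rt))
  ec <- if ("ec_numbers" %in% names(rt)) as.character(rt$ec_numbers) else ""
  ec[is.na(ec)] <- ""
  stoich <- do.call(rbind, Map(function(p, id) {
    cbind(reaction_id = id, p$stoich)
  }, parsed, rt$reaction_id))
  rtype <- if ("rtype" %in% names(rt)) as.character(rt$rtype) else ""
  rtype[is.na(rtype)] <- ""
  for (i in which(rtype == "")) {
    rtype[i] <- infer_rtype(parsed[[i]]$stoich)
  }
  reactions <- data.frame(
    reaction_id = as.character(rt$reaction_id),
    reversible = reversible,
    lower_bound = ifelse(reversible, bound_policy$reversible[1],
                         bound_policy$irreversible[1]),
    upper_bound = ifelse(reversible, bound_policy$reversible[2],
                         bound_policy$irreversible[2]),
    delta_g = delta_g,
    ec_numbers = ec,
    rtype = rtype,
    stringsAsFactors = FALSE
  )
  metnet(mt, reactions, stoich, log = "read_network")
}

empty_reaction_table <- function() {
  data.frame(reaction_id = character(), reversible = logical(),
             lower_bound = numeric(), upper_bound = numeric(),
             delta_g = numeric(), ec_numbers = character(),
             rtype = character(), stringsAsFactors = FALSE)
}

empty_stoich_table <- function() {
  data.frame(reaction_id = character(), species_id = character(),
             coeff = numeric(), stringsAsFactors = FALSE)
}

#' Write a network back to the tabular dialect
#'
#' @param net a `metnet`.
#' @param reaction_table,metabolite_table output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, reaction_table, metabolite_table) {
  eqs <- vapply(net$reactions$reaction_id, function(id) {
    st <- net$stoich[net$stoich$reaction_id == id, , drop = FALSE]
    format_equation(st, net$reactions$reversible[net$reactions$reaction_id == id])
  }, character(1))
  rt <- data.frame(
    reaction_id = net$reactions$reaction_id,
    equation = eqs,
    ec_numbers = net$reactions$ec_numbers,
    delta_g = ifelse(is.na(net$reactions$delta_g), "",
                     format(net$reactions$delta_g, trim = TRUE, digits = 12)),
    rtype = net$reactions$rtype,
    stringsAsFactors = FALSE
  )
  utils::write.table(rt, reaction_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$metabolites, metabolite_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(reaction_table, metabolite_table))
}

#' Build the stoichiometric matrix S
#'
#' Rows are species, columns reactions, both in lexicographic order so the
#' matrix is bit-stable across runs. `S[i, j]` is the signed coefficient of
#' species i in reaction j (negative for substrates). Reversibility lives in
#' the bounds, not in S.
#'
#' @param net a `metnet`.
#' @return object of class `stoich_matrix`: list with sparse matrix `S`
#'   (`Matrix::dgCMatrix`), `species` (row ids) and `reactions` (column ids).
#' @export
build_stoichiometric_matrix <- function(net) {
  sp <- sort(unique(net$stoich$species_id))
  rx <- sort(net$reactions$reaction_id)
  S <- Matrix::sparseMatrix(
    i = match(net$stoich$species_id, sp),
    j = match(net$stoich$reaction_id, rx),
    x = net$stoich$coeff,
    dims = c(length(sp), length(rx)),
    dimnames = list(sp, rx)
  )
  structure(list(S = S, species = sp, reactions = rx),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat("<stoich_matrix> ", length(x$species), " species x ",
      length(x$reactions), " reactions, ", length(x$S@x), " nonzeros\n",
      sep = "")
  invisible(x)
}

# Reaction accessors used across modules ------------------------------------

reaction_stoich <- function(net, reaction_id) {
  net$stoich[net$stoich$reaction_id == reaction_id, c("species_id", "coeff"),
             drop = FALSE]
}

# Subset a network to a set of reaction ids, dropping orphaned species.
subset_reactions <- function(net, reaction_ids, log_msg = NULL) {
  keep <- net$reactions$reaction_id %in% reaction_ids
  net$reactions <- net$reactions[keep, , drop = FALSE]
  net$stoich <- net$stoich[net$stoich$reaction_id %in% reaction_ids, ,
                           drop = FALSE]
  if (!is.null(log_msg)) net <- log_step(net, log_msg)
  net
}

# Append reactions (same column layout) to a network.
add_reactions <- function(net, reactions, stoich, metabolites = NULL) {
  if (!is.null(metabolites)) {
    new <- !(metabolites$metabolite_id %in% net$metabolites$metabolite_id)
    net$metabolites <- rbind(net$metabolites, metabolites[new, , drop = FALSE])
  }
  net$reactions <- rbind(net$reactions, reactions)
  net$stoich <- rbind(net$stoich, stoich)
  validate_metnet(net)
  net
}
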