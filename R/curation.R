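# Stage 3: dead-end detection (GapFind-style MILP) and minimal gap filling
# (GapFill-style MILP).
#
# Producibility semantics: a species is producible when it can be reached
# from the uptake boundary by a chain of reactions each of whose substrates
# is producible, with every production event carrying at least epsilon flux
# under accumulation-relaxed mass balance (sum_j S_ij v_j >= 0). The MILP
# couples the classic epsilon/M-linearized production indicators to
# producer-certification level variables, which excludes self-sustaining
# internal cycles with no seed from the boundary; this makes dead-end
# detection well-defined and exactly equal to the seeded fixpoint closure
# computed by gapfind_reachability(). Consumability is producibility on the
# reversed network.

default_curation_config <- function() {
  list(eps = 0.001, M = 1000, detector = "milp")
}

# Flip the admissible direction of every reaction (bounds negated and
# swapped, stoichiometry untouched): producibility on the reversed network
# is consumability on the original.
reverse_network <- function(net) {
  lb <- net$reactions$lower_bound
  net$reactions$lower_bound <- -net$reactions$upper_bound
  net$reactions$upper_bound <- -lb
  net$reactions$reversible <- net$reactions$lower_bound < 0
  net
}

# Directions available to each reaction: forward when ub > 0, backward when
# lb < 0. Returns per-direction substrate and product species index lists.
direction_table <- function(net, sp_ids) {
  out <- list()
  by_rxn <- split(net$stoich[, c("species_id", "coeff")],
                  net$stoich$reaction_id)
  for (i in seq_len(nrow(net$reactions))) {
    id <- net$reactions$reaction_id[i]
    st <- by_rxn[[id]]
    idx <- match(st$species_id, sp_ids)
    if (net$reactions$upper_bound[i] > 0) {
      out[[length(out) + 1L]] <- list(
        reaction = id, j = i, dir = 1L,
        substrates = idx[st$coeff < 0], products = idx[st$coeff > 0],
        coeffs = st$coeff, sp_idx = idx)
    }
    if (net$reactions$lower_bound[i] < 0) {
      out[[length(out) + 1L]] <- list(
        reaction = id, j = i, dir = -1L,
        substrates = idx[st$coeff > 0], products = idx[st$coeff < 0],
        coeffs = st$coeff, sp_idx = idx)
    }
  }
  out
}

# Seeded fixpoint closure: grow the producible set from reactions whose
# substrate requirements are met, starting from substrate-free directions
# (uptake exchanges). Pure R; independent of the MILP backend.
producible_closure <- function(net) {
  sp_ids <- sort(unique(net$stoich$species_id))
  dirs <- direction_table(net, sp_ids)
  producible <- rep(FALSE, length(sp_ids))
  repeat {
    changed <- FALSE
    for (d in dirs) {
      if (length(d$products) == 0) next
      if (all(producible[d$substrates]) && !all(producible[d$products])) {
        producible[d$products] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(producible, sp_ids)
}

#' Dead-end detection by reachability fixpoint
#'
#' Iteratively grows the set of producible species from the uptake boundary
#' (a reaction direction can fire once all of its substrates are producible;
#' its products then become producible) and, symmetrically on the reversed
#' network, the set of consumable species. Runs in pure R with no solver;
#' serves as the independent cross-check for [gapfind()].
#'
#' @param net a `metnet`.
#' @return a `gap_report` (see [gapfind()]).
#' @export
gapfind_reachability <- function(net) {
  prod <- producible_closure(net)
  cons <- producible_closure(reverse_network(net))
  make_gap_report(net, names(prod)[!prod], names(cons)[!cons])
}

make_gap_report <- function(net, non_produced, non_consumed) {
  sp <- species(net)
  problem <- union(non_produced, non_consumed)
  per_comp <- do.call(rbind, lapply(split(sp, sp$compartment), function(g) {
    data.frame(
      compartment = g$compartment[1],
      n_species = nrow(g),
      non_produced = sum(g$species_id %in% non_produced),
      non_consumed = sum(g$species_id %in% non_consumed),
      problem = sum(g$species_id %in% problem),
      connected = sum(!(g$species_id %in% problem)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_comp) <- NULL
  prob_sp <- split_species_id(problem)
  prob_by_comp <- split(prob_sp$metabolite_id, prob_sp$compartment)
  inner <- setdiff(names(prob_by_comp), "c")
  common <- vapply(inner, function(k) {
    length(intersect(prob_by_comp[["c"]], prob_by_comp[[k]]))
  }, integer(1))
  structure(
    list(non_produced = sort(non_produced), non_consumed = sort(non_consumed),
         per_compartment_counts = per_comp,
         common_gaps = stats::setNames(as.integer(common),
                                       if (length(inner)) paste0("c|", inner) else character()),
         species_universe = sp$species_id),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> ", length(x$non_produced), " non-produced, ",
      length(x$non_consumed), " non-consumed of ",
      length(x$species_universe), " species\n", sep = "")
  print(x$per_compartment_counts)
  invisible(x)
}

# ---- MILP construction -----------------------------------------------------

# Sparse constraint accumulator
milp_rows <- function() {
  acc <- list(i = list(), j = list(), x = list(), b = numeric(), n = 0L)
  acc
}

add_row <- function(acc, cols, vals, rhs) {
  acc$n <- acc$n + 1L
  acc$i[[acc$n]] <- rep.int(acc$n, length(cols))
  acc$j[[acc$n]] <- cols
  acc$x[[acc$n]] <- vals
  acc$b[acc$n] <- rhs
  acc
}

acc_matrix <- function(acc, ncol) {
  Matrix::sparseMatrix(i = unlist(acc$i), j = unlist(acc$j), x = unlist(acc$x),
                       dims = c(acc$n, ncol))
}

# Build the production-side MILP blocks for one network. Offsets allow two
# blocks (production + consumption on the reversed network) to share one
# variable space together with gap-fill selection variables.
#
# Variables per block: v (flux), w (per producer term), x (species
# producible), l (certification level). Constraints:
#   (a) sum_j S_ij v_j >= 0                              (accumulation relaxed)
#   (b) w_t = 1 => S_ij v_j >= eps                       (epsilon/M linearized)
#   (c) w_t <= x_s for every substrate s of the term's direction
#   (d) l_i >= l_s + 1 when w_t certifies i              (big-M on levels)
#   (e) x_i <= sum of w over i's producer terms
gap_milp_block <- function(net, eps, M, offset, candidate_ids = character(),
                           y_index = NULL) {
  sp_ids <- sort(unique(net$stoich$species_id))
  nsp <- length(sp_ids)
  rx <- net$reactions
  n <- nrow(rx)
  dirs <- direction_table(net, sp_ids)

  # producer terms: (species i, reaction j) pairs reachable in some direction
  terms <- list()
  for (d in dirs) {
    for (p in d$products) {
      terms[[length(terms) + 1L]] <- list(i = p, j = d$j,
                                          substrates = d$substrates,
                                          coeff = d$coeffs[d$sp_idx == p][1])
    }
  }
  nt <- length(terms)
  # variable layout within the block
  v_at <- offset + seq_len(n)
  w_at <- offset + n + seq_len(nt)
  x_at <- offset + n + nt + seq_len(nsp)
  l_at <- offset + n + nt + nsp + seq_len(nsp)
  nvar <- n + nt + 2L * nsp

  lb <- c(rx$lower_bound, rep(0, nt), rep(0, nsp), rep(0, nsp))
  ub <- c(rx$upper_bound, rep(1, nt), rep(1, nsp), rep(nsp, nsp))
  integer <- c(rep(FALSE, n), rep(TRUE, nt), rep(TRUE, nsp), rep(FALSE, nsp))

  # species with no producer terms can never be produced
  has_term <- rep(FALSE, nsp)
  for (t in terms) has_term[t$i] <- TRUE
  ub[n + nt + which(!has_term)] <- 0

  # logical presolve (domain propagation on the w => x implications): a
  # production indicator can only reach 1 through a chain of certifiable
  # terms, so propagate the implication closure once and fix everything
  # outside it to zero. Standard MILP preprocessing; the solver still
  # certifies the optimum on the reduced problem.
  reach <- rep(FALSE, nsp)
  repeat {
    changed <- FALSE
    for (t in terms) {
      if (!reach[t$i] && all(reach[t$substrates])) {
        reach[t$i] <- TRUE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  ub[(x_at - offset)[!reach]] <- 0
  for (t_idx in seq_len(nt)) {
    if (!all(reach[terms[[t_idx]]$substrates])) ub[n + t_idx] <- 0
  }

  acc <- milp_rows()
  # (a) -S v <= 0
  Sm <- build_stoichiometric_matrix(net)
  stopifnot(identical(Sm$species, sp_ids))
  col_of <- match(Sm$reactions, rx$reaction_id)
  Ts <- Matrix::t(Sm$S)  # reaction x species for column access
  for (i in seq_len(nsp)) {
    row <- Ts[, i]
    nz <- which(row != 0)
    acc <- add_row(acc, v_at[col_of[nz]], -row[nz], 0)
  }
  Lbig <- nsp + 1
  for (t_idx in seq_len(nt)) {
    t <- terms[[t_idx]]
    Mt <- max(M, eps - min(t$coeff * rx$lower_bound[t$j],
                           t$coeff * rx$upper_bound[t$j]))
    # (b) -S_ij v_j + Mt w_t <= Mt - eps
    acc <- add_row(acc, c(v_at[t$j], w_at[t_idx]), c(-t$coeff, Mt), Mt - eps)
    for (s in t$substrates) {
      # (c) w_t - x_s <= 0
      acc <- add_row(acc, c(w_at[t_idx], x_at[s]), c(1, -1), 0)
      # (d) l_s - l_i + (L+1) w_t <= L
      acc <- add_row(acc, c(l_at[s], l_at[t$i], w_at[t_idx]),
                     c(1, -1, Lbig + 1), Lbig)
    }
    if (t$j <= n && !is.null(y_index)) {
      cand <- y_index[[rx$reaction_id[t$j]]]
      if (!is.null(cand)) {
        # candidate terms only available when the candidate is selected
        acc <- add_row(acc, c(w_at[t_idx], cand), c(1, -1), 0)
      }
    }
  }
  # (e) x_i - sum w <= 0, plus the valid cut w_t <= x_i (an active
  # certifier implies its product is producible), which tightens the LP
  # relaxation considerably
  terms_of <- split(seq_len(nt), vapply(terms, `[[`, integer(1), "i"))
  for (i in which(has_term)) {
    tt <- terms_of[[as.character(i)]]
    acc <- add_row(acc, c(x_at[i], w_at[tt]), c(1, rep(-1, length(tt))), 0)
    for (t_idx in tt) {
      acc <- add_row(acc, c(w_at[t_idx], x_at[i]), c(1, -1), 0)
    }
  }
  # candidate flux gating: lb*y <= v <= ub*y
  if (!is.null(y_index) && length(candidate_ids)) {
    for (id in candidate_ids) {
      j <- match(id, rx$reaction_id)
      yv <- y_index[[id]]
      if (rx$upper_bound[j] > 0) {
        acc <- add_row(acc, c(v_at[j], yv), c(1, -rx$upper_bound[j]), 0)
      }
      if (rx$lower_bound[j] < 0) {
        acc <- add_row(acc, c(v_at[j], yv), c(-1, rx$lower_bound[j]), 0)
      }
    }
  }
  list(acc = acc, nvar = nvar, lb = lb, ub = ub, integer = integer,
       sp_ids = sp_ids, x_at = x_at, w_at = w_at)
}

#' Dead-end detection (GapFind-style MILP)
#'
#' Solves one mixed-integer program maximizing the number of species with an
#' active production indicator; species whose indicator cannot reach 1 are
#' non-produced. The symmetric run on the reversed network yields the
#' non-consumed set. See the package vignette for the exact formulation and
#' its relation to the reachability closure.
#'
#' @param net a `metnet`.
#' @param config list with `eps` (minimum production flux, default 0.001)
#'   and `M` (big-M flux constant, default 1000).
#' @return a `gap_report`: sorted `non_produced` and `non_consumed` species
#'   vectors, `per_compartment_counts`, and `common_gaps` (count of problem
#'   metabolite ids shared between the cytoplasm and each other
#'   compartment).
#' @export
gapfind <- function(net, config = default_curation_config()) {
  solve_side <- function(n) {
    blk <- gap_milp_block(n, config$eps, config$M, offset = 0L)
    obj <- numeric(blk$nvar)
    obj[blk$x_at] <- 1
    # tiny certification-parsimony penalty: breaks the symmetry between
    # equivalent certification forests without affecting the x optimum
    obj[blk$w_at] <- -0.5 / max(1, length(blk$w_at))
    res <- solve_milp(obj, A_ub = acc_matrix(blk$acc, blk$nvar),
                      b_ub = blk$acc$b, lb = blk$lb, ub = blk$ub,
                      integer = blk$integer, maximize = TRUE)
    if (res$status != "optimal") {
      stop("gapfind MILP did not solve to optimality (status: ", res$status,
           "); check reaction bounds")
    }
    blk$sp_ids[res$x[blk$x_at] < 0.5]
  }
  make_gap_report(net, solve_side(net), solve_side(reverse_network(net)))
}

# ---- gap filling -----------------------------------------------------------

#' Re-home candidate reactions into a compartment
#'
#' Instantiates database templates inside compartment `comp`: every
#' non-extracellular species is re-homed, and reaction ids get a `_comp`
#' suffix (unless already assigned to that compartment).
#'
#' @param db a `metnet` of candidate reactions.
#' @param comp target compartment code.
#' @return a `metnet` with the instantiated copies.
#' @export
instantiate_db <- function(db, comp) {
  if (comp == "c") return(db)
  sp <- split_species_id(db$stoich$species_id)
  rehome <- sp$compartment != "e"
  db$stoich$species_id[rehome] <- species_id(sp$metabolite_id[rehome], comp)
  db$reactions$reaction_id <- paste0(db$reactions$reaction_id, "_", comp)
  db$stoich$reaction_id <- paste0(db$stoich$reaction_id, "_", comp)
  db
}

# exchange templates m@c <=> m@K for inner-compartment target species whose
# cytoplasmic twin exists in the network
auto_exchange_templates <- function(net, targets) {
  have <- unique(net$stoich$species_id)
  tg <- split_species_id(targets)
  tg <- tg[!(tg$compartment %in% c("c", "e")), , drop = FALSE]
  tg <- tg[species_id(tg$metabolite_id, "c") %in% have, , drop = FALSE]
  if (nrow(tg) == 0) return(NULL)
  ids <- paste0("EXC_", gsub("[^A-Za-z0-9]", "_", tg$metabolite_id), "_c_",
                tg$compartment)
  keep <- !duplicated(ids)
  tg <- tg[keep, , drop = FALSE]; ids <- ids[keep]
  reactions <- data.frame(
    reaction_id = ids, reversible = TRUE,
    lower_bound = default_bound_policy()$reversible[1],
    upper_bound = default_bound_policy()$reversible[2],
    delta_g = NA_real_, ec_numbers = "", rtype = "transport",
    stringsAsFactors = FALSE
  )
  stoich <- rbind(
    data.frame(reaction_id = ids,
               species_id = species_id(tg$metabolite_id, "c"), coeff = -1),
    data.frame(reaction_id = ids, species_id = tg$species_id, coeff = 1)
  )
  mets <- data.frame(metabolite_id = unique(tg$metabolite_id),
                     stringsAsFactors = FALSE)
  list(reactions = reactions, stoich = stoich, metabolite_ids = mets$metabolite_id)
}

# merge a candidate metnet into the network, marking which ids are selectable
augment_with_candidates <- function(net, dbs) {
  cand_ids <- character()
  for (db in dbs) {
    if (is.null(db)) next
    if (inherits(db, "metnet")) {
      new <- setdiff(db$reactions$reaction_id, net$reactions$reaction_id)
      if (length(new) == 0) next
      keep_r <- db$reactions$reaction_id %in% new
      net <- add_reactions(net, db$reactions[keep_r, , drop = FALSE],
                           db$stoich[db$stoich$reaction_id %in% new, , drop = FALSE],
                           metabolites = db$metabolites)
      cand_ids <- c(cand_ids, new)
    } else {
      new <- setdiff(db$reactions$reaction_id, net$reactions$reaction_id)
      if (length(new) == 0) next
      keep_r <- db$reactions$reaction_id %in% new
      new_ids <- setdiff(db$metabolite_ids, net$metabolites$metabolite_id)
      mets <- if (length(new_ids) == 0) NULL else data.frame(
        metabolite_id = new_ids,
        name = "", formula = NA_character_, charge = NA_integer_,
        mass = NA_real_, is_generic = FALSE, stringsAsFactors = FALSE)
      net <- add_reactions(net, db$reactions[keep_r, , drop = FALSE],
                           db$stoich[db$stoich$reaction_id %in% new, , drop = FALSE],
                           metabolites = mets)
      cand_ids <- c(cand_ids, new)
    }
  }
  list(network = net, candidate_ids = sort(cand_ids))
}

gapfill_milp <- function(net, targets, candidate_ids, config, batch = FALSE) {
  # shared variable space: production block + consumption block + y
  eps <- config$eps; M <- config$M
  ncand <- length(candidate_ids)
  # y variables come first so both blocks can reference them
  y_at <- seq_len(ncand)
  y_index <- as.list(stats::setNames(y_at, candidate_ids))
  blkP <- gap_milp_block(net, eps, M, offset = ncand,
                         candidate_ids = candidate_ids, y_index = y_index)
  blkC <- gap_milp_block(reverse_network(net), eps, M,
                         offset = ncand + blkP$nvar,
                         candidate_ids = candidate_ids, y_index = y_index)
  nvar <- ncand + blkP$nvar + blkC$nvar
  lb <- c(rep(0, ncand), blkP$lb, blkC$lb)
  ub <- c(rep(1, ncand), blkP$ub, blkC$ub)
  integer <- c(rep(TRUE, ncand), blkP$integer, blkC$integer)

  ti_P <- blkP$x_at[match(targets, blkP$sp_ids)]
  ti_C <- blkC$x_at[match(targets, blkC$sp_ids)]
  if (anyNA(ti_P)) stop("target species not in network: ",
                        paste(targets[is.na(ti_P)], collapse = ", "))

  # lexicographic tie-break among equally sized fills
  pref <- (match(candidate_ids, sort(candidate_ids)) - 1) * 1e-6 /
    max(1, ncand)
  obj <- numeric(nvar)

  A1 <- acc_matrix(blkP$acc, nvar)
  A2 <- acc_matrix(blkC$acc, nvar)

  if (batch) {
    # z_t = target resolved (producible AND consumable); maximize resolved
    # targets first, parsimony of additions second
    ntar <- length(targets)
    z_at <- nvar + seq_len(ntar)
    nvar2 <- nvar + ntar
    lb <- c(lb, rep(0, ntar)); ub <- c(ub, rep(1, ntar))
    integer <- c(integer, rep(TRUE, ntar))
    acc <- milp_rows()
    for (k in seq_len(ntar)) {
      acc <- add_row(acc, c(z_at[k], ti_P[k]), c(1, -1), 0)
      acc <- add_row(acc, c(z_at[k], ti_C[k]), c(1, -1), 0)
    }
    A <- rbind(cbind(A1, Matrix::Matrix(0, nrow(A1), ntar, sparse = TRUE)),
               cbind(A2, Matrix::Matrix(0, nrow(A2), ntar, sparse = TRUE)),
               acc_matrix(acc, nvar2))
    b <- c(blkP$acc$b, blkC$acc$b, acc$b)
    obj <- numeric(nvar2)
    obj[z_at] <- ncand + 1
    obj[y_at] <- -(1 + pref)
    res <- solve_milp(obj, A_ub = A, b_ub = b, lb = lb, ub = ub,
                      integer = integer, maximize = TRUE)
    if (res$status != "optimal") stop("gapfill batch MILP failed: ", res$status)
    sel <- candidate_ids[res$x[y_at] > 0.5]
    resolved <- targets[res$x[z_at] > 0.5]
    return(list(selected = sel, resolved = resolved))
  }

  # single-target minimal fill
  lb[ti_P] <- 1; lb[ti_C] <- 1
  obj[y_at] <- 1 + pref
  A <- rbind(A1, A2)
  b <- c(blkP$acc$b, blkC$acc$b)
  res <- solve_milp(obj, A_ub = A, b_ub = b, lb = lb, ub = ub,
                    integer = integer, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  candidate_ids[res$x[y_at] > 0.5]
}

#' Minimal gap filling (GapFill-style MILP)
#'
#' For each target species, selects the smallest set of candidate-database
#' additions (plus cytoplasm-inner exchange templates when
#' `exchange_templates = TRUE`) that makes the target both producible and
#' consumable. Infeasible targets are returned with `feasible = FALSE`,
#' never dropped. Ties between equally small fills are broken
#' lexicographically by reaction id.
#'
#' @param net a `metnet`.
#' @param targets character vector of target species ids.
#' @param candidate_db a `metnet` of candidate reactions resolvable against
#'   the network (see [instantiate_db()]), or NULL for exchanges only.
#' @param config list with `eps`, `M` (see [default_curation_config()]).
#' @param exchange_templates offer automatic `m@c <=> m@K` exchange
#'   candidates for inner-compartment targets.
#' @return list of `gap_fill_solution` objects: `target_species`,
#'   `added_reaction_ids`, `added_exchange_ids`, `feasible`.
#' @export
gapfill <- function(net, targets, candidate_db = NULL,
                    config = default_curation_config(),
                    exchange_templates = TRUE) {
  ex <- if (exchange_templates) auto_exchange_templates(net, targets) else NULL
  aug <- augment_with_candidates(net, list(candidate_db, ex))
  exchange_ids <- if (!is.null(ex)) {
    intersect(aug$candidate_ids, ex$reactions$reaction_id)
  } else character()
  lapply(targets, function(tg) {
    sel <- if (length(aug$candidate_ids) == 0) NULL else {
      gapfill_milp(aug$network, tg, aug$candidate_ids, config)
    }
    if (is.null(sel)) {
      # no candidates or infeasible; check whether the target is already fine
      rep0 <- gapfind_reachability(net)
      ok <- !(tg %in% rep0$non_produced) && !(tg %in% rep0$non_consumed)
      sel <- if (ok) character() else NULL
    }
    structure(list(
      target_species = tg,
      added_reaction_ids = if (is.null(sel)) character() else
        setdiff(sel, exchange_ids),
      added_exchange_ids = if (is.null(sel)) character() else
        intersect(sel, exchange_ids),
      feasible = !is.null(sel)
    ), class = "gap_fill_solution")
  })
}

#' @export
print.gap_fill_solution <- function(x, ...) {
  cat("<gap_fill_solution> ", x$target_species, ": ",
      if (x$feasible) paste0("+", length(x$added_reaction_ids), " reactions, +",
                             length(x$added_exchange_ids), " exchanges")
      else "infeasible", "\n", sep = "")
  invisible(x)
}

#' Exhaustive minimal-fill search (oracle)
#'
#' Certifies [gapfill()] minimality on small instances by enumerating
#' candidate subsets in order of size and testing each with the reachability
#' closure. Exponential; refuses more than `max_candidates` candidates.
#'
#' @inheritParams gapfill
#' @param target one target species id.
#' @param max_candidates hard cap on the search-space size (default 15).
#' @return list with `size` (minimal subset size, NA if infeasible) and
#'   `subset` (first minimal subset in lexicographic order).
#' @export
gapfill_exhaustive <- function(net, target, candidate_db,
                               exchange_templates = TRUE,
                               max_candidates = 15) {
  ex <- if (exchange_templates) auto_exchange_templates(net, target) else NULL
  aug <- augment_with_candidates(net, list(candidate_db, ex))
  cand <- sort(aug$candidate_ids)
  if (length(cand) > max_candidates) {
    stop("exhaustive search capped at ", max_candidates, " candidates")
  }
  full <- aug$network
  base_ids <- setdiff(full$reactions$reaction_id, cand)
  ok_with <- function(subset) {
    sub <- subset_reactions(full, c(base_ids, subset))
    rep <- gapfind_reachability(sub)
    !(target %in% rep$non_produced) && !(target %in% rep$non_consumed)
  }
  for (k in 0:length(cand)) {
    combs <- if (k == 0) list(character()) else
      utils::combn(cand, k, simplify = FALSE)
    for (s in combs) if (ok_with(s)) return(list(size = k, subset = s))
  }
  list(size = NA_integer_, subset = NULL)
}

# ---- compartmentalized curation -------------------------------------------

problem_species <- function(report) {
  union(report$non_produced, report$non_consumed)
}

detect_gaps <- function(net, config) {
  if (identical(config$detector, "reachability")) gapfind_reachability(net)
  else gapfind(net, config)
}

#' Three-step curation of a compartmentalized network
#'
#' Executes the compartmentalized curation order: (1) fill the cytoplasmic
#' gaps from the candidate database; (2) add cytoplasm-inner exchange
#' reactions (database templates whose species all exist, plus automatic
#' `m@c <=> m@K` templates) to resolve inner gaps shared with the cytoplasm;
#' (3) fill the remaining gaps of each non-cytoplasmic compartment
#' separately with the database instantiated in that compartment.
#'
#' @param net a compartmentalized `metnet`.
#' @param candidate_db a `metnet` of candidate reactions (cytoplasmic
#'   templates; instantiated per compartment as needed).
#' @param transport_db optional `metnet` of transport/exchange templates
#'   considered in step 2.
#' @param config see [default_curation_config()]; `detector` chooses between
#'   the MILP (`"milp"`) and the reachability closure (`"reachability"`)
#'   for gap detection between steps.
#' @return list with `network` (curated), `stats` (a `curation_stats`
#'   data.frame of per-compartment reconnection percentages before/after),
#'   `added` (named list of reaction ids added per step), `before` and
#'   `after` gap reports.
#' @export
curate_compartmentalized <- function(net, candidate_db, transport_db = NULL,
                                     config = default_curation_config()) {
  original_species <- species(net)$species_id
  before <- detect_gaps(net, config)
  added <- list(cytoplasm = character(), exchanges = character(),
                inner = character())

  # step 1: cytoplasmic gaps against the cytoplasmic database
  rep1 <- before
  targets_c <- intersect(problem_species(rep1),
                         original_species[endsWith(original_species, "@c")])
  if (length(targets_c) > 0 && !is.null(candidate_db)) {
    aug <- augment_with_candidates(net, list(candidate_db))
    if (length(aug$candidate_ids) > 0) {
      got <- gapfill_milp(aug$network, targets_c, aug$candidate_ids, config,
                          batch = TRUE)
      added$cytoplasm <- got$selected
      net <- subset_reactions(aug$network,
                              c(net$reactions$reaction_id, got$selected))
    }
  }

  # step 2: cytoplasm <-> inner exchange reactions
  rep2 <- detect_gaps(net, config)
  inner_targets <- setdiff(problem_species(rep2),
                           species(net)$species_id[species(net)$compartment %in% c("c", "e")])
  if (length(inner_targets) > 0) {
    ex <- auto_exchange_templates(net, inner_targets)
    dbs <- list(ex)
    if (!is.null(transport_db)) {
      have <- unique(net$stoich$species_id)
      eligible <- transport_db$reactions$reaction_id[
        vapply(transport_db$reactions$reaction_id, function(id) {
          all(reaction_stoich(transport_db, id)$species_id %in% have)
        }, logical(1))]
      dbs <- c(dbs, list(subset_reactions(transport_db, eligible)))
    }
    aug <- augment_with_candidates(net, dbs)
    if (length(aug$candidate_ids) > 0) {
      got <- gapfill_milp(aug$network, inner_targets, aug$candidate_ids,
                          config, batch = TRUE)
      added$exchanges <- got$selected
      net <- subset_reactions(aug$network,
                              c(net$reactions$reaction_id, got$selected))
    }
  }

  # step 3: remaining compartments, separately
  rep3 <- detect_gaps(net, config)
  remaining <- problem_species(rep3)
  if (length(remaining) > 0 && !is.null(candidate_db)) {
    comps <- setdiff(unique(split_species_id(remaining)$compartment), "c")
    for (k in comps) {
      tg <- remaining[endsWith(remaining, paste0("@", k))]
      db_k <- if (k == "e") candidate_db else instantiate_db(candidate_db, k)
      aug <- augment_with_candidates(net, list(db_k))
      if (length(aug$candidate_ids) == 0) next
      got <- gapfill_milp(aug$network, tg, aug$candidate_ids, config,
                          batch = TRUE)
      added$inner <- c(added$inner, got$selected)
      net <- subset_reactions(aug$network,
                              c(net$reactions$reaction_id, got$selected))
    }
  }

  after <- detect_gaps(net, config)
  stats <- reconnection_percentage(before, after, original_species)
  net <- log_step(net, sprintf(
    "curate_compartmentalized: added %d cytoplasmic, %d exchange, %d inner reactions",
    length(added$cytoplasm), length(added$exchanges), length(added$inner)))
  list(network = net, stats = stats, added = added,
       before = before, after = after)
}

#' Per-compartment reconnection percentages
#'
#' A species is connected when it is neither non-produced nor non-consumed.
#' Percentages are taken over the species of the pre-curation network so
#' that before/after are comparable; empty compartments report NA.
#'
#' @param before,after `gap_report` objects.
#' @param species_universe character vector of species ids to score (e.g.
#'   the original network's species).
#' @return a `curation_stats` data.frame: `compartment`, `n_species`,
#'   `connected_before`, `connected_after`, `pct_before`, `pct_after`.
#' @export
reconnection_percentage <- function(before, after, species_universe) {
  sp <- split_species_id(species_universe)
  probB <- problem_species(before)
  probA <- problem_species(after)
  out <- do.call(rbind, lapply(split(sp, sp$compartment), function(g) {
    n <- nrow(g)
    cb <- sum(!(g$species_id %in% probB))
    ca <- sum(!(g$species_id %in% probA))
    data.frame(compartment = g$compartment[1], n_species = n,
               connected_before = cb, connected_after = ca,
               pct_before = if (n > 0) 100 * cb / n else NA_real_,
               pct_after = if (n > 0) 100 * ca / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("curation_stats", "data.frame")
  out
}
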