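# Fixture builders and independent oracles shared across the suite.

# Build a metnet from equation strings; bounds follow the default policy
# unless overridden via the ub/lb lists (reaction id -> value).
mini_net <- function(equations, ub = list(), lb = list()) {
  ids <- names(equations)
  parsed <- lapply(equations, parse_equation)
  pol <- default_bound_policy()
  rows <- do.call(rbind, lapply(ids, function(id) {
    p <- parsed[[id]]
    b <- if (p$reversible) pol$reversible else pol$irreversible
    if (!is.null(lb[[id]])) b[1] <- lb[[id]]
    if (!is.null(ub[[id]])) b[2] <- ub[[id]]
    data.frame(reaction_id = id, reversible = b[1] < 0,
               lower_bound = b[1], upper_bound = b[2], delta_g = NA_real_,
               ec_numbers = "", rtype = infer_rtype_pub(p$stoich),
               stringsAsFactors = FALSE)
  }))
  st <- do.call(rbind, lapply(ids, function(id) {
    cbind(reaction_id = id, parsed[[id]]$stoich)
  }))
  mets <- unique(sub("@[a-z]$", "", st$species_id))
  metnet(
    data.frame(metabolite_id = mets, name = mets, formula = NA_character_,
               charge = NA_integer_, mass = NA_real_, is_generic = FALSE,
               stringsAsFactors = FALSE),
    rows, st)
}

# infer_rtype is internal; reproduce the classification for fixtures
infer_rtype_pub <- function(stoich) {
  comp <- sub("^.*@", "", stoich$species_id)
  one_sided <- all(stoich$coeff > 0) || all(stoich$coeff < 0)
  if (one_sided && all(comp == "e")) return("exchange")
  if (length(unique(comp)) >= 2) return("transport")
  "metabolic"
}

# Messy random network for solver-vs-oracle batteries: unit/2 coefficients,
# cycles, reversible reactions, a few exchanges. Up to ~40 reactions.
random_milp_network <- function(seed, n_mets = 12, n_rxns = 30) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_mets))
  eqs <- list()
  n_ex <- sample(1:3, 1)
  for (i in seq_len(n_ex)) {
    m <- sample(mets, 1)
    eqs[[paste0("EX", i)]] <- paste0(" ", sample(c("<=>", "=>"), 1), " ",
                                     m, "@e")
    eqs[[paste0("TX", i)]] <- paste0(m, "@e ",
                                     sample(c("<=>", "=>"), 1), " ", m, "@c")
  }
  n_int <- n_rxns - 2 * n_ex
  for (i in seq_len(n_int)) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- sample(mets, ns); prods <- sample(setdiff(mets, subs), np)
    cs <- sample(1:2, ns, replace = TRUE); cp <- sample(1:2, np, replace = TRUE)
    lhs <- paste(ifelse(cs == 1, paste0(subs, "@c"),
                        paste(cs, paste0(subs, "@c"))), collapse = " + ")
    rhs <- paste(ifelse(cp == 1, paste0(prods, "@c"),
                        paste(cp, paste0(prods, "@c"))), collapse = " + ")
    eqs[[paste0("R", i)]] <- paste(lhs, sample(c("=>", "<=>"), 1), rhs)
  }
  mini_net(eqs)
}

# Brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing each variable at lb/ub/free and solving
# the equality system on the free block. Exact for small n.
lp_vertex_enumeration <- function(S, cvec, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  best <- -Inf; best_v <- NULL
  grid <- expand.grid(rep(list(0:2), n))  # 0 = lb, 1 = ub, 2 = free
  for (r in seq_len(nrow(grid))) {
    pick <- as.integer(grid[r, ])
    free <- which(pick == 2)
    v <- ifelse(pick == 0, lb, ub)
    v[free] <- 0
    rhs <- -as.numeric(S %*% v)
    if (length(free) > 0) {
      A <- as.matrix(S[, free, drop = FALSE])
      if (qr(A)$rank < length(free)) next  # underdetermined: not a vertex
      sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - rhs)) > tol) next
      v[free] <- sol
    } else if (max(abs(rhs)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    if (max(abs(as.numeric(S %*% v))) > tol) next
    z <- sum(cvec * v)
    if (z > best + tol) { best <- z; best_v <- v }
  }
  list(Z = best, v = best_v)
}

# All-pairs shortest paths by plain Floyd-Warshall on the adjacency of a
# directed igraph (independent of igraph's distance routines).
floyd_warshall <- function(graph) {
  n <- igraph::vcount(graph)
  d <- matrix(Inf, n, n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  d[el] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# CELLO-style score table over possibly different compartment sets per row;
# absent compartments get probability zero.
loc_table <- function(...) {
  rows <- list(...)
  comps <- unique(unlist(lapply(rows, function(r) names(r$scores))))
  df <- do.call(rbind, lapply(rows, function(r) {
    s <- stats::setNames(rep(0, length(comps)), comps)
    s[names(r$scores)] <- r$scores
    as.data.frame(as.list(s), check.names = FALSE)
  }))
  cbind(data.frame(reaction_id = vapply(rows, `[[`, character(1), "id"),
                   stringsAsFactors = FALSE), df)
}

problem_species_pub <- function(report) {
  union(report$non_produced, report$non_consumed)
}

expect_same_gaps <- function(a, b) {
  expect_identical(a$non_produced, b$non_produced)
  expect_identical(a$non_consumed, b$non_consumed)
}
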