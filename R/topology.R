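# Stage 5: metabolite-graph topology.
#
# Nodes are species and a directed edge runs from every substrate to every
# product of each reaction (both ways for reversible reactions). Currency
# metabolites are retained deliberately: protons, water and ATP are the
# hubs whose role the degree exponents describe. Parallel substrate-product
# pairs contributed by different reactions collapse to one edge for
# clustering and path metrics but are preserved in the edge-count
# centrality.

#' Build the directed metabolite graph of a network
#'
#' @param net a `metnet`.
#' @return an `igraph` graph; vertices carry the species id as `name`,
#'   edges a `weight` attribute counting how many reactions contribute the
#'   substrate-product pair.
#' @export
build_metabolite_graph <- function(net) {
  sp_ids <- sort(unique(net$stoich$species_id))
  by_rxn <- split(net$stoich[, c("species_id", "coeff")],
                  net$stoich$reaction_id)
  rev_of <- stats::setNames(net$reactions$reversible,
                            net$reactions$reaction_id)
  edges <- lapply(names(by_rxn), function(id) {
    st <- by_rxn[[id]]
    subs <- st$species_id[st$coeff < 0]
    prods <- st$species_id[st$coeff > 0]
    if (length(subs) == 0 || length(prods) == 0) return(NULL)  # exchange
    pairs <- expand.grid(from = subs, to = prods, stringsAsFactors = FALSE)
    if (rev_of[[id]]) {
      pairs <- rbind(pairs, data.frame(from = pairs$to, to = pairs$from))
    }
    pairs
  })
  edges <- edges[!vapply(edges, is.null, logical(1))]
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(sp_ids), name = sp_ids)
  if (length(edges) > 0) {
    all_pairs <- do.call(rbind, edges)
    key <- paste(all_pairs$from, all_pairs$to, sep = "\r")
    mult <- table(key)
    uniq <- all_pairs[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, rbind(match(uniq$from, sp_ids),
                                    match(uniq$to, sp_ids)))
    igraph::E(g)$weight <- as.integer(mult[paste(uniq$from, uniq$to, sep = "\r")])
  }
  g
}

#' Empirical in/out degree distributions
#'
#' The degree of a species is the number of reaction-mediated links it
#' carries: parallel links contributed by different reactions each count
#' (P(k) is the probability that a metabolite takes part in exactly k
#' incoming or outgoing conversions). Probabilities are normalized over all
#' nodes.
#'
#' @param graph an igraph from [build_metabolite_graph()].
#' @return list with elements `in` and `out`, each a `degree_distribution`
#'   data.frame (`k`, `count`, `pk`).
#' @export
degree_distributions <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  one <- function(mode) {
    d <- igraph::strength(graph, mode = mode,
                          weights = igraph::E(graph)$weight)
    tab <- table(d)
    out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
    out$pk <- out$count / sum(out$count)
    class(out) <- c("degree_distribution", "data.frame")
    out
  }
  list(`in` = one("in"), out = one("out"))
}

hurwitz_zeta <- function(s, a, terms = 64L) {
  # direct sum plus Euler-Maclaurin tail
  k <- 0:(terms - 1L)
  head <- sum((a + k)^(-s))
  N <- a + terms
  head + N^(1 - s) / (s - 1) + 0.5 * N^(-s) + s * N^(-s - 1) / 12
}

#' Fit a discrete power law to a degree distribution
#'
#' Maximum-likelihood estimate of the exponent gamma of P(k) proportional to
#' k^-gamma over k >= k_min (zeta-normalized discrete power law), with a
#' log-log least-squares estimate reported for comparison and an r-squared
#' fit diagnostic.
#'
#' @param distribution a `degree_distribution` (from
#'   [degree_distributions()]) or a data.frame with `k` and `count`.
#' @param k_min smallest degree included in the fit (default 1; zero
#'   degrees are always excluded).
#' @return list: `gamma` (MLE), `gamma_regression`, `r_squared`, `n_tail`
#'   (observations used), `k_range`, `poor_fit` (TRUE when the log-log
#'   correlation is weak).
#' @export
fit_power_law <- function(distribution, k_min = 1) {
  df <- distribution[distribution$k >= max(1, k_min), , drop = FALSE]
  if (nrow(df) < 3) stop("degenerate support: need >= 3 distinct degrees >= k_min")
  n <- sum(df$count)
  sum_logk <- sum(df$count * log(df$k))
  nll <- function(g) g * sum_logk + n * log(hurwitz_zeta(g, max(1, k_min)))
  opt <- stats::optimize(nll, interval = c(1.01, 8))
  fit <- stats::lm(log(pk) ~ log(k), data = transform(df, pk = count / n))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits trip lm

  list(gamma = opt$minimum,
       gamma_regression = -unname(stats::coef(fit)[2]),
       r_squared = r2,
       n_tail = n,
       k_range = range(df$k),
       poor_fit = r2 < 0.7)
}

#' Global topology summary
#'
#' The standard global metrics of a metabolite graph: average clustering
#' coefficient (undirected projection, nodes with degree >= 2), network
#' diameter and radius, characteristic path length (mean shortest path over
#' reachable ordered pairs of the directed graph), average neighbor count,
#' node count, and the fitted degree exponents.
#'
#' The radius convention: minimum eccentricity over nodes that reach every
#' other node; when no node has full reach, over the largest strongly
#' connected component.
#'
#' @param graph an igraph from [build_metabolite_graph()].
#' @return a `topology_summary` list.
#' @export
topology_summary <- function(graph) {
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = "ignore")
  deg <- igraph::degree(und)
  cc_local <- igraph::transitivity(und, type = "local", isolates = "NaN")
  cc <- mean(cc_local[deg >= 2], na.rm = TRUE)
  if (!is.finite(cc)) cc <- 0

  # unit path lengths: the multiplicity weights must not act as distances
  d <- igraph::distances(graph, mode = "out", weights = NA)
  finite <- is.finite(d) & d > 0
  cpl <- if (any(finite)) mean(d[finite]) else NA_real_
  diam <- if (any(finite)) max(d[finite]) else 0
  # eccentricity over reachable pairs
  full_reach <- rowSums(is.finite(d)) == ncol(d)
  radius <- if (any(full_reach)) {
    min(apply(d[full_reach, , drop = FALSE], 1, max))
  } else {
    comp <- igraph::components(graph, mode = "strong")
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    if (length(idx) > 1) {
      dd <- d[idx, idx, drop = FALSE]
      min(apply(dd, 1, function(r) max(r[is.finite(r)])))
    } else 0
  }
  fits <- tryCatch({
    dd <- degree_distributions(graph)
    list(gin = fit_power_law(dd$`in`)$gamma, gout = fit_power_law(dd$out)$gamma)
  }, error = function(e) list(gin = NA_real_, gout = NA_real_))
  structure(list(
    clustering_coefficient = cc,
    network_diameter = diam,
    network_radius = radius,
    characteristic_path_length = cpl,
    avg_neighbors = mean(deg),
    node_count = igraph::vcount(graph),
    gamma_in = fits$gin,
    gamma_out = fits$gout
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("<topology_summary>\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-28s %s\n", nm, format(x[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Rank metabolites by centrality
#'
#' Scores every species by in/out degree, total edge count (reaction
#' multiplicity included), betweenness (intermediation) and the absolute
#' loading on the first two principal components of the column-centered
#' stoichiometric matrix, then combines them by mean rank. The highest
#' ranked metabolites are the currency hubs (protons, water, ATP, ...)
#' that touch most of the network.
#'
#' @param graph igraph from [build_metabolite_graph()].
#' @param matrix `stoich_matrix` of the same network.
#' @param n_components principal components used for the PCA score
#'   (default 2).
#' @return data.frame sorted by `rank`: `species_id`, `in_degree`,
#'   `out_degree`, `edge_count`, `betweenness`, `pca_loading`, `rank`.
#' @export
rank_central_metabolites <- function(graph, matrix, n_components = 2) {
  ids <- igraph::V(graph)$name
  stopifnot(identical(sort(ids), matrix$species))
  din <- igraph::degree(graph, mode = "in")
  dout <- igraph::degree(graph, mode = "out")
  ec <- igraph::strength(graph, mode = "all", weights = igraph::E(graph)$weight)
  btw <- igraph::betweenness(graph, directed = TRUE, weights = NA)
  X <- as.matrix(matrix$S)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  load <- sqrt(rowSums(pc$x[, seq_len(k), drop = FALSE]^2))
  names(load) <- matrix$species
  df <- data.frame(
    species_id = ids,
    in_degree = as.integer(din),
    out_degree = as.integer(dout),
    edge_count = as.numeric(ec),
    betweenness = as.numeric(btw),
    pca_loading = as.numeric(load[ids]),
    stringsAsFactors = FALSE
  )
  score <- rowMeans(cbind(rank(-df$in_degree), rank(-df$out_degree),
                          rank(-df$edge_count), rank(-df$betweenness),
                          rank(-df$pca_loading)))
  df <- df[order(score, df$species_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Quotient a compartmentalized graph by compartment stripping
#'
#' Maps every species node to its metabolite id and collapses the induced
#' parallel edges. The non-compartmentalized build's graph embeds into this
#' quotient.
#'
#' @param graph igraph with species-id vertex names.
#' @return igraph over metabolite ids.
#' @export
strip_compartments <- function(graph) {
  ids <- igraph::V(graph)$name
  f <- factor(split_species_id(ids)$metabolite_id)
  g2 <- igraph::contract(graph, as.integer(f), vertex.attr.comb = "ignore")
  igraph::V(g2)$name <- levels(f)
  igraph::simplify(g2, edge.attr.comb = list(weight = "sum"),
                   remove.loops = TRUE)
}
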