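# Stage 4: flux balance analysis.
#
# Maximize Z = c'v subject to steady state S v = 0 and bounds
# lb <= v <= ub. Bounds follow the network policy: irreversible (0, 100),
# reversible (-1000, 100) mmol/gDW/h. Objectives are biogeochemical
# (nitrogen, sulfur and carbon cycle reaction sets) rather than biomass.

#' Define an objective function
#'
#' @param name objective name.
#' @param weights named numeric vector: reaction id -> weight. Multi-reaction
#'   objectives default to unit weights.
#' @return an `objective_function` object.
#' @export
objective_function <- function(name, weights) {
  if (is.character(weights)) {
    weights <- stats::setNames(rep(1, length(weights)), weights)
  }
  if (length(weights) == 0 || all(weights == 0)) {
    stop("objective needs at least one nonzero weight")
  }
  structure(list(name = name, weights = weights), class = "objective_function")
}

#' Build a flux balance problem
#'
#' @param net a `metnet`.
#' @param objective an [objective_function()] or a character vector of
#'   reaction ids (unit weights).
#' @param bound_policy NULL (default) keeps each reaction's stored bounds —
#'   which the readers set from [default_bound_policy()] — so capacity
#'   overrides survive; passing a policy list resets every reaction's
#'   bounds per its reversibility flag (the bound-variation experiment).
#' @return a `flux_problem`: stoichiometric matrix, objective vector and
#'   bounds, reactions in matrix column order.
#' @export
build_problem <- function(net, objective, bound_policy = NULL) {
  if (!inherits(objective, "objective_function")) {
    objective <- objective_function("objective", objective)
  }
  missing <- setdiff(names(objective$weights), net$reactions$reaction_id)
  if (length(missing) > 0) {
    stop("objective references absent reaction(s): ",
         paste(missing, collapse = ", "))
  }
  mat <- build_stoichiometric_matrix(net)
  ord <- match(mat$reactions, net$reactions$reaction_id)
  if (is.null(bound_policy)) {
    lb <- net$reactions$lower_bound[ord]
    ub <- net$reactions$upper_bound[ord]
  } else {
    rev <- net$reactions$reversible[ord]
    lb <- ifelse(rev, bound_policy$reversible[1], bound_policy$irreversible[1])
    ub <- ifelse(rev, bound_policy$reversible[2], bound_policy$irreversible[2])
  }
  cvec <- stats::setNames(numeric(length(mat$reactions)), mat$reactions)
  cvec[names(objective$weights)] <- objective$weights
  structure(list(matrix = mat, objective = objective, c = cvec,
                 lb = stats::setNames(lb, mat$reactions),
                 ub = stats::setNames(ub, mat$reactions)),
            class = "flux_problem")
}

#' @export
print.flux_problem <- function(x, ...) {
  cat("<flux_problem> ", length(x$matrix$species), " x ",
      length(x$matrix$reactions), ", objective '", x$objective$name, "' (",
      sum(x$c != 0), " weighted reactions)\n", sep = "")
  invisible(x)
}

#' Force reactions to zero flux
#'
#' Sets the bounds of the listed reactions to (0, 0), leaving everything
#' else untouched — the in-silico knockout used to probe compartment
#' coupling (e.g. removing an acetyl-CoA cytoplasm-mitochondrion transport).
#'
#' @param problem a `flux_problem`.
#' @param reaction_ids reactions to exclude.
#' @return the modified problem.
#' @export
exclude_reactions <- function(problem, reaction_ids) {
  unknown <- setdiff(reaction_ids, problem$matrix$reactions)
  if (length(unknown) > 0) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  }
  problem$lb[reaction_ids] <- 0
  problem$ub[reaction_ids] <- 0
  problem
}

#' Solve a flux balance problem
#'
#' Linear program solved with HiGHS. Under degenerate alternative optima the
#' returned basic solution is solver-dependent; `stabilize = TRUE` adds a
#' second stage that fixes Z and minimizes total absolute flux, making
#' active-flux counts reproducible.
#'
#' @param problem a `flux_problem`.
#' @param stabilize run the flux-parsimony second stage (default FALSE).
#' @return a `flux_result`: `Z`, `v` (named flux vector), `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`). Solver failures surface
#'   as a status, not an error.
#' @export
solve_fba <- function(problem, stabilize = FALSE) {
  S <- problem$matrix$S
  n <- ncol(S)
  res <- solve_lp(problem$c, A_eq = S, b_eq = rep(0, nrow(S)),
                  lb = problem$lb, ub = problem$ub, maximize = TRUE)
  out <- structure(list(Z = res$objective,
                        v = stats::setNames(res$x, problem$matrix$reactions),
                        status = res$status,
                        objective_name = problem$objective$name),
                   class = "flux_result")
  if (res$status != "optimal" || !stabilize) return(out)
  # stage 2: min sum |v| subject to c'v = Z; v = p - q with p, q >= 0
  Z <- res$objective
  A_eq <- cbind(S, -S)
  obj2 <- rep(1, 2 * n)
  lbp <- pmax(problem$lb, 0); ubp <- pmax(problem$ub, 0)
  lbq <- pmax(-problem$ub, 0); ubq <- pmax(-problem$lb, 0)
  A_eq <- rbind(A_eq, c(problem$c, -problem$c))
  res2 <- solve_lp(obj2, A_eq = A_eq, b_eq = c(rep(0, nrow(S)), Z),
                   lb = c(lbp, lbq), ub = c(ubp, ubq), maximize = FALSE)
  if (res2$status == "optimal") {
    v <- res2$x[seq_len(n)] - res2$x[n + seq_len(n)]
    out$v <- stats::setNames(v, problem$matrix$reactions)
    out$Z <- sum(problem$c * v)
  }
  out
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> ", x$objective_name, ": status ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", Z = ", format(x$Z, digits = 6), ", ",
        sum(abs(x$v) > 1e-6), "/", length(x$v), " active fluxes", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Active-flux fractions per scope
#'
#' Percentage of reactions within each scope carrying flux above tolerance
#' in an optimal solution — the layout used to compare how strongly an
#' objective activates the whole network, a compartment, or a pathway
#' (nitrogen fixation, nitrification, denitrification, ...).
#'
#' @param result an optimal `flux_result`.
#' @param scopes named list of reaction-id vectors.
#' @param tolerance activity threshold (default 1e-6).
#' @return named numeric vector of percentages; empty scopes give NA.
#' @export
active_flux_fraction <- function(result, scopes, tolerance = 1e-6) {
  if (result$status != "optimal") stop("result is not optimal")
  vapply(scopes, function(ids) {
    ids <- intersect(ids, names(result$v))
    if (length(ids) == 0) return(NA_real_)
    100 * sum(abs(result$v[ids]) > tolerance) / length(ids)
  }, numeric(1))
}

#' Biogeochemical objective template library
#'
#' Reaction templates for the nitrogen, sulfur and carbon (TCA-related and
#' fatty-acid elongation) objective blocks, written in the standard equation
#' dialect. The ambiguous electron-acceptor species "A" appearing in some
#' templates maps to oxidized ferredoxin by default (`acceptor` argument).
#'
#' @param acceptor metabolite name substituted for the generic acceptor "A".
#' @return named list of character vectors of template equations.
#' @export
objective_library <- function(acceptor = "oxidized ferredoxin") {
  lib <- list(
    nitrogen_cycle = c(
      nitrogen_fixation = "8 H(+) + 8 reduced ferredoxin + 16 H2O + 16 ATP + 1 dinitrogen <=> 2 NH4(+) + 1 dihydrogen + 8 A + 16 ADP + 16 phosphate",
      hydroxylamine_oxidation = "1 ubiquinone + 1 H2O + 1 hydroxylamine <=> 1 NH4(+) + 1 O2 + 1 Ubiquinol",
      nitrite_reduction = "5 H(+) + 1 nitrite + 2 ferrocytochrome c => 2 ferricytochrome c + 1 H2O + 1 hydroxylamine",
      nitrous_oxide_reduction = "2 H(+) + 2 ferrocytochrome c + 1 dinitrogen oxide <=> 2 ferricytochrome c + 1 H2O + 1 dinitrogen"
    ),
    sulfur_cycle = c(
      sulfide_oxidation_nadp = "3 H2O + 3 NADP(+) + 1 hydrogen sulfide <=> 1 H(+) + 1 sulfite + 3 NADPH",
      sulfide_oxidation_fd = "3 H2O + 3 A + 1 hydrogen sulfide => 8 H(+) + 1 sulfite + 3 reduced ferredoxin",
      sulfate_reduction = "2 H(+) + 2 ferrocytochrome c + 1 sulfate <=> 1 sulfite + 2 ferricytochrome c + 1 H2O",
      sulfate_peroxide = "1 hydrogen peroxide + 1 sulfate <=> 1 sulfite + 1 H2O + 1 O2"
    ),
    tca_related = c(
      acetate_kinase = "1 acetyl phosphate(2-) + 1 ADP <=> 1 acetate + 1 ATP",
      oxaloacetate_exchange = "Oxaloacetate[c] <=> Oxaloacetate[m]",
      acetylcoa_exchange = "Acetyl-CoA[c] <=> Acetyl-CoA[m]",
      oxoglutarate_exchange = "Oxoglutarate[c] <=> Oxoglutarate[m]",
      citrate_lyase = "Citrate + CoA <=> Acetyl-CoA + H2O + Oxaloacetate",
      pep_carboxykinase = "ATP + Oxaloacetate <=> ADP + Phosphoenolpyruvate + CO2",
      pyruvate_dh_e2 = "Acetyl-CoA + Enzyme N6-(dihydrolipoyl)lysine <=> CoA + (Dihydrolipoyllysine-residue acetyltransferase) S-acetyldihydrolipoyllysine"
    ),
    fatty_acid_elongation = c(
      acyl_coa_synthetase = "ATP + Hexadecanoic acid + CoA <=> AMP + Palmitoyl-CoA + Diphosphate",
      ketoacyl_synthase = "Acyl-CoA + Acetyl-CoA <=> CoA + 3-Oxoacyl-CoA",
      acetylcoa_exchange = "acetyl-CoA[c] <=> acetyl-CoA[m]"
    )
  )
  lapply(lib, function(block) {
    vapply(block, function(eq) gsub("(^| )A( |$)", paste0("\\1", acceptor, "\\2"), eq),
           character(1))
  })
}

#' Instantiate objective templates against a network
#'
#' Matches each template's metabolites against the network and reports which
#' templates resolve (all species present) and which do not, rather than
#' failing silently.
#'
#' @param net a `metnet`.
#' @param templates character vector of template equations (one
#'   [objective_library()] block).
#' @param default_compartment compartment for unsuffixed template terms.
#' @return list with `resolved` (named list of parsed stoichiometries) and
#'   `unresolved` (named character vector of missing-species summaries).
#' @export
instantiate_objective <- function(net, templates, default_compartment = "c") {
  have <- unique(net$stoich$species_id)
  resolved <- list(); unresolved <- character()
  for (nm in names(templates)) {
    p <- parse_equation(templates[[nm]], default_compartment)
    missing <- setdiff(p$stoich$species_id, have)
    if (length(missing) == 0) {
      resolved[[nm]] <- p
    } else {
      unresolved[nm] <- paste(missing, collapse = ", ")
    }
  }
  list(resolved = resolved, unresolved = unresolved)
}
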