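# Stage 1: draft reconstruction refinement.
#
# Three refinement steps on the annotated draft: drop reactions touching
# generic compounds (DNA, RNA, protein, glycan and lipid classes without a
# fixed elemental formula), verify mass/charge balance with automatic proton
# and water repair, and set directionality from the standard transformed
# Gibbs energy. An intracellular pH of 7.2 is assumed for all input charges
# and formulas.

#' Reference intracellular pH assumed for metabolite protonation states
#' @export
PH_INTRACELLULAR <- 7.2

#' Remove reactions containing generic metabolites
#'
#' Generic metabolites (proteins, RNA, DNA, generic lipids, glycans) lack a
#' fully specified elemental formula and cannot be balanced; every reaction
#' touching one is removed, and species orphaned by the removal are dropped
#' with it. Idempotent.
#'
#' @param net a `metnet` whose metabolite table has `is_generic` populated.
#' @return list with `network` (the filtered `metnet`) and `removed_ids`.
#' @export
remove_generic_reactions <- function(net) {
  generic <- net$metabolites$metabolite_id[net$metabolites$is_generic %in% TRUE]
  sp <- split_species_id(net$stoich$species_id)
  touch <- unique(net$stoich$reaction_id[sp$metabolite_id %in% generic])
  keep <- setdiff(net$reactions$reaction_id, touch)
  out <- subset_reactions(net, keep,
                          log_msg = sprintf("remove_generic_reactions: removed %d", length(touch)))
  list(network = out, removed_ids = touch)
}

#' Parse an elemental formula
#'
#' @param formula e.g. `"C6H12O6"`; `NA` or `""` yields `NULL`.
#' @return named numeric vector of element counts, or NULL when the formula
#'   is unspecified.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  toks <- regmatches(formula,
                     gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("unparseable formula: '", formula, "'")
  }
  el <- sub("[0-9.]+$", "", toks)
  cnt <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1
  out <- tapply(cnt, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

net_composition <- function(stoich, met_tab) {
  # total elemental and charge balance of a reaction; NULL if unverifiable
  sp <- split_species_id(stoich$species_id)
  idx <- match(sp$metabolite_id, met_tab$metabolite_id)
  if (any(is.na(idx))) return(NULL)
  forms <- lapply(met_tab$formula[idx], function(f) {
    tryCatch(parse_formula(f), error = function(e) NULL)
  })
  if (any(vapply(forms, is.null, logical(1)))) return(NULL)
  charges <- met_tab$charge[idx]
  if (any(is.na(charges))) return(NULL)
  elements <- sort(unique(unlist(lapply(forms, names))))
  elem <- stats::setNames(numeric(length(elements)), elements)
  for (i in seq_along(forms)) {
    elem[names(forms[[i]])] <- elem[names(forms[[i]])] +
      stoich$coeff[i] * forms[[i]]
  }
  list(elements = elem[abs(elem) > 1e-9],
       charge = sum(stoich$coeff * charges))
}

#' Check and repair the mass/charge balance of a reaction
#'
#' Computes the net elemental and charge totals of a reaction. When the
#' imbalance is expressible as an integer combination of protons and water
#' (the two terms most often omitted from biochemical databases), the repair
#' is applied and recorded; otherwise the reaction is flagged unbalanced but
#' never silently dropped. Missing formulas make the reaction unverifiable.
#'
#' @param net a `metnet`.
#' @param reaction_id the reaction to check.
#' @param proton_id,water_id metabolite ids of H+ and H2O in the metabolite
#'   table; they are declared on demand if absent.
#' @return a `balance_report` list: `reaction_id`, `status` (one of
#'   `"balanced"`, `"repaired"`, `"unbalanced"`, `"unverifiable"`, or
#'   `"boundary"` for one-sided exchange pseudo-reactions),
#'   `element_imbalance`, `charge_imbalance`, `repaired`, `repair_terms`
#'   (data.frame of added species/coefficients) and `stoich` (the
#'   post-repair stoichiometry).
#' @export
check_and_repair_balance <- function(net, reaction_id, proton_id = "h",
                                     water_id = "h2o") {
  st <- reaction_stoich(net, reaction_id)
  if (nrow(st) == 0) stop("unknown reaction: ", reaction_id)
  rt <- net$reactions$rtype[net$reactions$reaction_id == reaction_id]
  if (identical(rt, "exchange")) {
    # boundary pseudo-reactions exchange matter with the environment and
    # are one-sided by design; they are not checkable
    report <- list(reaction_id = reaction_id, status = "boundary",
                   element_imbalance = NULL, charge_imbalance = NA_integer_,
                   repaired = FALSE,
                   repair_terms = empty_stoich_table()[, 2:3], stoich = st)
    class(report) <- "balance_report"
    return(report)
  }
  comp <- net_composition(st, net$metabolites)
  report <- list(reaction_id = reaction_id, status = "unverifiable",
                 element_imbalance = NULL, charge_imbalance = NA_integer_,
                 repaired = FALSE, repair_terms = empty_stoich_table()[, 2:3],
                 stoich = st)
  class(report) <- "balance_report"
  if (is.null(comp)) return(report)
  report$element_imbalance <- comp$elements
  report$charge_imbalance <- comp$charge
  if (length(comp$elements) == 0 && abs(comp$charge) < 1e-9) {
    report$status <- "balanced"
    return(report)
  }
  # Try an H2O/H+ repair: imbalance restricted to H, O and charge, with
  # n_H2O = -imb_O, n_H = -imb_H - 2*n_H2O, requiring n_H = -imb_charge.
  other <- setdiff(names(comp$elements), c("H", "O"))
  if (length(other) == 0) {
    imb_H <- if ("H" %in% names(comp$elements)) comp$elements[["H"]] else 0
    imb_O <- if ("O" %in% names(comp$elements)) comp$elements[["O"]] else 0
    n_h2o <- -imb_O
    n_h <- -imb_H - 2 * n_h2o
    integral <- function(z) abs(z - round(z)) < 1e-9
    if (integral(n_h2o) && integral(n_h) &&
        abs(n_h - (-comp$charge)) < 1e-9) {
      comp_code <- names(sort(table(split_species_id(st$species_id)$compartment),
                              decreasing = TRUE))[1]
      terms <- data.frame(species_id = character(), coeff = numeric(),
                          stringsAsFactors = FALSE)
      if (abs(n_h2o) > 1e-9) {
        terms <- rbind(terms, data.frame(
          species_id = species_id(water_id, comp_code), coeff = n_h2o))
      }
      if (abs(n_h) > 1e-9) {
        terms <- rbind(terms, data.frame(
          species_id = species_id(proton_id, comp_code), coeff = n_h))
      }
      st2 <- rbind(st, terms)
      st2 <- stats::aggregate(coeff ~ species_id, data = st2, FUN = sum)
      st2 <- st2[abs(st2$coeff) > 1e-12, , drop = FALSE]
      report$status <- "repaired"
      report$repaired <- TRUE
      report$repair_terms <- terms
      report$stoich <- st2[order(st2$species_id), , drop = FALSE]
      return(report)
    }
  }
  report$status <- "unbalanced"
  report
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", x$reaction_id, ": ", x$status, "\n", sep = "")
  invisible(x)
}

repair_metabolite_rows <- function(proton_id, water_id) {
  data.frame(
    metabolite_id = c(proton_id, water_id),
    name = c("proton", "water"),
    formula = c("H", "H2O"),
    charge = c(1L, 0L),
    mass = c(1.008, 18.015),
    is_generic = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Balance every reaction of a network
#'
#' Runs [check_and_repair_balance()] over all reactions, applies the
#' recorded repairs, and returns the reports. Unrepairable reactions are
#' retained but flagged unless `strict = TRUE`, in which case they are
#' dropped.
#'
#' @param net a `metnet`.
#' @param strict drop unbalanced/unverifiable reactions (default FALSE).
#' @inheritParams check_and_repair_balance
#' @return list with `network` and `reports` (data.frame: `reaction_id`,
#'   `status`, `imbalance`).
#' @export
balance_network <- function(net, strict = FALSE, proton_id = "h",
                            water_id = "h2o") {
  reports <- lapply(net$reactions$reaction_id, function(id) {
    check_and_repair_balance(net, id, proton_id, water_id)
  })
  status <- vapply(reports, `[[`, character(1), "status")
  if (any(status == "repaired")) {
    need <- repair_metabolite_rows(proton_id, water_id)
    new <- !(need$metabolite_id %in% net$metabolites$metabolite_id)
    net$metabolites <- rbind(net$metabolites, need[new, , drop = FALSE])
    for (rep in reports[status == "repaired"]) {
      net$stoich <- net$stoich[net$stoich$reaction_id != rep$reaction_id, ,
                               drop = FALSE]
      net$stoich <- rbind(net$stoich, cbind(reaction_id = rep$reaction_id,
                                            rep$stoich))
    }
  }
  if (strict) {
    bad <- vapply(reports, `[[`, character(1), "reaction_id")[
      status %in% c("unbalanced", "unverifiable")]
    net <- subset_reactions(net, setdiff(net$reactions$reaction_id, bad))
  }
  net <- log_step(net, sprintf(
    "balance_network: %d balanced, %d repaired, %d unbalanced, %d unverifiable",
    sum(status == "balanced"), sum(status == "repaired"),
    sum(status == "unbalanced"), sum(status == "unverifiable")))
  summary <- data.frame(
    reaction_id = vapply(reports, `[[`, character(1), "reaction_id"),
    status = status,
    imbalance = vapply(reports, function(r) {
      if (is.null(r$element_imbalance)) return("")
      paste(c(sprintf("%s:%+g", names(r$element_imbalance), r$element_imbalance),
              if (!is.na(r$charge_imbalance) && abs(r$charge_imbalance) > 1e-9)
                sprintf("charge:%+g", r$charge_imbalance)),
            collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  list(network = net, reports = summary, details = reports)
}

#' Assign reaction directionality from the Gibbs energy
#'
#' Reactions with unknown Gibbs energy are reversible. Strongly exergonic
#' reactions (delta_g <= -threshold) become irreversible forward; strongly
#' endergonic ones (delta_g >= +threshold) are flipped (substrates and
#' products swapped, delta_g negated) and made irreversible; anything in
#' between stays reversible. Bounds follow `bound_policy` and are never
#' widened beyond it. Only metabolic reactions are touched: transport and
#' exchange reactions carry no thermodynamic annotation and keep the
#' directionality they were constructed with.
#'
#' @param net a `metnet`.
#' @param threshold irreversibility cutoff in kJ/mol (default 30).
#' @param bound_policy see [default_bound_policy()].
#' @return the network with updated reversibility, bounds and stoichiometry.
#' @export
assign_directionality <- function(net, threshold = 30,
                                  bound_policy = default_bound_policy()) {
  metab <- net$reactions$rtype == "metabolic"
  dg <- net$reactions$delta_g
  flip <- metab & !is.na(dg) & dg >= threshold
  irrev <- metab & !is.na(dg) & abs(dg) >= threshold
  if (any(flip)) {
    ids <- net$reactions$reaction_id[flip]
    sel <- net$stoich$reaction_id %in% ids
    net$stoich$coeff[sel] <- -net$stoich$coeff[sel]
    net$reactions$delta_g[flip] <- -net$reactions$delta_g[flip]
  }
  net$reactions$reversible[metab] <- !irrev[metab]
  net$reactions$lower_bound[metab] <- ifelse(irrev[metab],
                                             bound_policy$irreversible[1],
                                             bound_policy$reversible[1])
  net$reactions$upper_bound[metab] <- ifelse(irrev[metab],
                                             bound_policy$irreversible[2],
                                             bound_policy$reversible[2])
  log_step(net, sprintf(
    "assign_directionality: T=%g, %d irreversible (%d flipped), %d reversible",
    threshold, sum(irrev), sum(flip), sum(metab) - sum(irrev)))
}
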