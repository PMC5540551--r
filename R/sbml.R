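# SBML Level 3 export/import.
#
# SBML core has no slot for flux bounds, reaction type, EC numbers or Gibbs
# energies, so those ride in a package annotation namespace; metabolite
# properties (formula, charge, mass, generic flag) ride on the species
# entries. The importer reads exactly what the exporter writes, giving a
# lossless round trip.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
META_NS <- "https://metacomp.invalid/sbml-annotations"

sanitize_sid <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", out), out, paste0("x", out))
}

#' Export a network as an SBML Level 3 document
#'
#' @param net a `metnet`.
#' @param path output file path.
#' @param model_id SBML model id.
#' @return invisibly, `path`.
#' @seealso [import_sbml()]
#' @export
export_sbml <- function(net, path, model_id = "metacomp_model") {
  sp <- species(net)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:mc" = META_NS, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model_id))

  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (comp in sort(unique(sp$compartment))) {
    xml2::xml_add_child(loc, "compartment", id = comp,
                        name = unname(DRAFT_COMPARTMENTS[comp]),
                        constant = "true")
  }

  met <- net$metabolites[match(sp$metabolite_id, net$metabolites$metabolite_id), ]
  los <- xml2::xml_add_child(model, "listOfSpecies")
  sid <- make.unique(sanitize_sid(paste0("M_", sp$metabolite_id, "_", sp$compartment)))
  for (i in seq_len(nrow(sp))) {
    node <- xml2::xml_add_child(
      los, "species", id = sid[i], name = sp$metabolite_id[i],
      compartment = sp$compartment[i], constant = "false",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false"
    )
    xml2::xml_set_attr(node, "mc:displayName", met$name[i])
    xml2::xml_set_attr(node, "mc:formula", met$formula[i])
    xml2::xml_set_attr(node, "mc:charge", met$charge[i])
    if (!is.na(met$mass[i])) xml2::xml_set_attr(node, "mc:mass", met$mass[i])
    xml2::xml_set_attr(node, "mc:isGeneric", tolower(met$is_generic[i]))
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  rid <- make.unique(sanitize_sid(paste0("R_", net$reactions$reaction_id)))
  for (i in seq_len(nrow(net$reactions))) {
    rxn <- net$reactions[i, ]
    node <- xml2::xml_add_child(
      lor, "reaction", id = rid[i], name = rxn$reaction_id,
      reversible = tolower(rxn$reversible), fast = "false"
    )
    xml2::xml_set_attr(node, "mc:lowerBound", rxn$lower_bound)
    xml2::xml_set_attr(node, "mc:upperBound", rxn$upper_bound)
    xml2::xml_set_attr(node, "mc:rtype", rxn$rtype)
    if (nzchar(rxn$ec_numbers)) xml2::xml_set_attr(node, "mc:ec", rxn$ec_numbers)
    if (!is.na(rxn$delta_g)) xml2::xml_set_attr(node, "mc:deltaG", rxn$delta_g)
    st <- reaction_stoich(net, rxn$reaction_id)
    subs <- st[st$coeff < 0, , drop = FALSE]
    prods <- st[st$coeff > 0, , drop = FALSE]
    if (nrow(subs) > 0) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (k in seq_len(nrow(subs))) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sid[match(subs$species_id[k], sp$species_id)],
                            stoichiometry = format(abs(subs$coeff[k]), digits = 12),
                            constant = "true")
      }
    }
    if (nrow(prods) > 0) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (k in seq_len(nrow(prods))) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sid[match(prods$species_id[k], sp$species_id)],
                            stoichiometry = format(prods$coeff[k], digits = 12),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from an SBML Level 3 document
#'
#' Reads documents written by [export_sbml()] (SBML core plus the package
#' annotation attributes). Structural problems raise an error.
#'
#' @param path SBML file path.
#' @return a [metnet] object.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, mc = META_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("SBML validation failure: no <model>")

  spn <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (length(spn) == 0 && length(xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)) > 0) {
    stop("SBML validation failure: reactions but no species")
  }
  attr_or_na <- function(nodes, a) {
    v <- xml2::xml_attr(nodes, a)
    v
  }
  sp_sid <- xml2::xml_attr(spn, "id")
  sp_met <- xml2::xml_attr(spn, "name")
  sp_comp <- xml2::xml_attr(spn, "compartment")
  if (any(is.na(sp_sid)) || any(is.na(sp_comp))) {
    stop("SBML validation failure: species missing id/compartment")
  }
  metabolites <- data.frame(
    metabolite_id = sp_met,
    name = attr_or_na(spn, "displayName"),
    formula = attr_or_na(spn, "formula"),
    charge = suppressWarnings(as.integer(attr_or_na(spn, "charge"))),
    mass = suppressWarnings(as.numeric(attr_or_na(spn, "mass"))),
    is_generic = attr_or_na(spn, "isGeneric") == "true",
    stringsAsFactors = FALSE
  )
  metabolites <- metabolites[!duplicated(metabolites$metabolite_id), , drop = FALSE]
  species_map <- stats::setNames(species_id(sp_met, sp_comp), sp_sid)

  rxn_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rx_list <- lapply(rxn_nodes, function(node) {
    id <- xml2::xml_attr(node, "name")
    if (is.na(id)) id <- xml2::xml_attr(node, "id")
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(node, xp, ns)
      if (length(nodes) == 0) return(empty_stoich_table())
      data.frame(
        reaction_id = id,
        species_id = unname(species_map[xml2::xml_attr(nodes, "species")]),
        coeff = sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        stringsAsFactors = FALSE
      )
    }
    st <- rbind(refs("./s:listOfReactants/s:speciesReference", -1),
                refs("./s:listOfProducts/s:speciesReference", +1))
    if (any(is.na(st$species_id))) {
      stop("SBML validation failure: speciesReference to unknown species in ", id)
    }
    ec <- xml2::xml_attr(node, "ec"); if (is.na(ec)) ec <- ""
    list(
      row = data.frame(
        reaction_id = id,
        reversible = xml2::xml_attr(node, "reversible") == "true",
        lower_bound = as.numeric(xml2::xml_attr(node, "lowerBound")),
        upper_bound = as.numeric(xml2::xml_attr(node, "upperBound")),
        delta_g = suppressWarnings(as.numeric(xml2::xml_attr(node, "deltaG"))),
        ec_numbers = ec,
        rtype = xml2::xml_attr(node, "rtype"),
        stringsAsFactors = FALSE
      ),
      stoich = st
    )
  })
  reactions <- if (length(rx_list)) do.call(rbind, lapply(rx_list, `[[`, "row")) else empty_reaction_table()
  stoich <- if (length(rx_list)) do.call(rbind, lapply(rx_list, `[[`, "stoich")) else empty_stoich_table()
  metnet(metabolites, reactions, stoich, log = paste0("import_sbml:", basename(path)))
}
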