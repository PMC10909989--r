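# SBML Level 3 Version 2 core serialization of the model.
#
# The document carries 3 unit-size compartments, the 8 dynamic species, the
# two capacities as constant boundary-condition species, the two modulators
# as constant species (id `DG2` stands in for the digit-initial name "2DG"),
# the rate constants as parameters, and 7 reactions whose kinetic laws state
# the printed rate equations in MathML. Reactions 2-5 carry reversible="true".

mml <- list(
  ci = function(x) sprintf("<ci> %s </ci>", x),
  cn = function(v) sprintf("<cn> %s </cn>", format(v, digits = 17)),
  apply = function(op, ...) {
    paste0("<apply><", op, "/>", paste0(c(...), collapse = ""), "</apply>")
  }
)

sbml_kinetic_laws <- function() {
  ci <- mml$ci; cn <- mml$cn; ap <- mml$apply
  list(
    R1 = ap("times", ci("k_in"), ci("Glu_ex"),
            ap("minus", ci("Capacity_G"), ci("Glu"))),
    R2 = ap("minus",
            ap("times", ci("kf_1"), ci("Glu"),
               ap("minus",
                  ap("plus", cn(1), ap("times", ci("Oligomycin"), ci("i2"))),
                  ap("times", ci("DG2"), ci("i1")))),
            ap("times", ci("kr_1"), ci("Pyr"))),
    R3 = ap("minus", ap("times", ci("kf_2"), ci("Pyr")),
            ap("times", ci("kr_2"), ci("Lac"))),
    R4 = ap("minus", ap("times", ci("kf_3"), ci("Lac")),
            ap("times", ci("kr_3"), ci("Lac_ex"))),
    R5 = ap("minus",
            ap("times", ci("kf_4"), ci("Pyr"),
               ap("minus", ci("Capacity_M"), ci("TCA"))),
            ap("times", ci("kr_4"), ci("TCA"))),
    R6 = ap("times", ci("kf_5"), ci("TCA"),
            ap("minus", cn(1), ap("times", ci("Oligomycin"), ci("i2")))),
    R7 = ap("times", ci("kf_6"), ci("TCA"))
  )
}

sbml_topology <- function() {
  list(R1 = list(reactant = "Glu_ex", product = "Glu", reversible = FALSE,
                 modifiers = c("Capacity_G")),
       R2 = list(reactant = "Glu", product = "Pyr", reversible = TRUE,
                 modifiers = c("Oligomycin", "DG2")),
       R3 = list(reactant = "Pyr", product = "Lac", reversible = TRUE,
                 modifiers = character(0)),
       R4 = list(reactant = "Lac", product = "Lac_ex", reversible = TRUE,
                 modifiers = character(0)),
       R5 = list(reactant = "Pyr", product = "TCA", reversible = TRUE,
                 modifiers = c("Capacity_M")),
       R6 = list(reactant = "TCA", product = "OxPP", reversible = FALSE,
                 modifiers = c("Oligomycin")),
       R7 = list(reactant = "TCA", product = "CellComponents", reversible = FALSE,
                 modifiers = character(0)))
}

species_compartment <- function() {
  c(Glu_ex = "media", Lac_ex = "media", Capacity_G = "media",
    Oligomycin = "media", DG2 = "media",
    Glu = "cell", Pyr = "cell", Lac = "cell", Capacity_M = "cell",
    TCA = "mitochondria", OxPP = "mitochondria", CellComponents = "mitochondria")
}

#' Export the model as SBML
#'
#' Serializes a parameter set (and optionally a modulator dose) as an SBML
#' Level 3 Version 2 core document. The two capacities are encoded as
#' constant species flagged `boundaryCondition="true"` — they throttle flux
#' without being consumed — and the modulator concentrations as constant
#' species referenced inside the kinetic-law MathML rather than via events,
#' since doses are constant over a run.
#'
#' @param params an [eca_params()] object; validated before any writing.
#' @param dose an [eca_dose()] stored as the modulator species' initial
#'   amounts.
#' @param path optional file path; when given the document is written there.
#' @return An `xml2` document (invisibly when `path` is given).
#' @export
export_sbml <- function(params, dose = eca_dose(), path = NULL) {
  validate_params(params)
  comp <- species_compartment()
  init <- c(Glu_ex = params$glu_ex0, Glu = 0, Pyr = 0, Lac = 0, Lac_ex = 0,
            TCA = 0, OxPP = 0, CellComponents = 0,
            Capacity_G = params$Capacity_G, Capacity_M = params$Capacity_M,
            Oligomycin = dose$oligo, DG2 = dose$dg2)
  boundary <- c("Capacity_G", "Capacity_M")
  constant <- c(boundary, "Oligomycin", "DG2")
  fmt <- function(v) format(v, digits = 17)

  species_xml <- vapply(names(init), function(id) {
    sprintf(paste0('<species id="%s" name="%s" compartment="%s" ',
                   'initialAmount="%s" hasOnlySubstanceUnits="true" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            id, if (id == "DG2") "2DG" else id, comp[[id]], fmt(init[[id]]),
            tolower(id %in% boundary), tolower(id %in% constant))
  }, character(1))

  par_names <- c("k_in", "kf_1", "kr_1", "kf_2", "kr_2", "kf_3", "kr_3",
                 "kf_4", "kr_4", "kf_5", "kf_6", "i1", "i2")
  params_xml <- vapply(par_names, function(nm) {
    sprintf('<parameter id="%s" value="%s" constant="true"/>', nm, fmt(params[[nm]]))
  }, character(1))

  topo <- sbml_topology()
  laws <- sbml_kinetic_laws()
  reactions_xml <- vapply(names(topo), function(id) {
    r <- topo[[id]]
    mods <- if (length(r$modifiers)) {
      paste0("<listOfModifiers>",
             paste0(sprintf('<modifierSpeciesReference species="%s"/>',
                            r$modifiers), collapse = ""),
             "</listOfModifiers>")
    } else ""
    paste0(sprintf('<reaction id="%s" reversible="%s">', id, tolower(r$reversible)),
           sprintf(paste0('<listOfReactants><speciesReference species="%s" ',
                          'stoichiometry="1" constant="true"/></listOfReactants>'),
                   r$reactant),
           sprintf(paste0('<listOfProducts><speciesReference species="%s" ',
                          'stoichiometry="1" constant="true"/></listOfProducts>'),
                   r$product),
           mods,
           '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
           laws[[id]], "</math></kineticLaw></reaction>")
  }, character(1))

  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="eca_glucose_catabolism" name="Capacity-limited glucose catabolism">',
    "<listOfCompartments>",
    '<compartment id="media" size="1" constant="true"/>',
    '<compartment id="cell" size="1" constant="true"/>',
    '<compartment id="mitochondria" size="1" constant="true"/>',
    "</listOfCompartments>",
    "<listOfSpecies>", paste0(species_xml, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste0(params_xml, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste0(reactions_xml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")

  doc <- xml2::read_xml(doc_str)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import an SBML model
#'
#' Reads an SBML document produced by [export_sbml()] (or a structurally
#' equivalent one) and reconstructs the parameter set, modulator dose and
#' reaction network. Unknown extra elements are ignored with a warning;
#' missing species, parameters or reactions raise an error naming the
#' element.
#'
#' @param x file path or `xml2` document.
#' @return List with `params` ([eca_params()]), `dose` ([eca_dose()]) and
#'   `network` ([build_network()] of the params).
#' @export
import_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  doc <- xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  sp_amt <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  names(sp_amt) <- sp_ids
  need_sp <- c(species_names(), "Capacity_G", "Capacity_M", "Oligomycin", "DG2")
  missing_sp <- setdiff(need_sp, sp_ids)
  if (length(missing_sp)) {
    stop("SBML document is missing species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  extra_sp <- setdiff(sp_ids, need_sp)
  if (length(extra_sp)) {
    warning("ignoring unknown species: ", paste(extra_sp, collapse = ", "),
            call. = FALSE)
  }

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_val <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(par_val) <- par_ids
  need_par <- c("k_in", "kf_1", "kr_1", "kf_2", "kr_2", "kf_3", "kr_3",
                "kf_4", "kr_4", "kf_5", "kf_6", "i1", "i2")
  missing_par <- setdiff(need_par, par_ids)
  if (length(missing_par)) {
    stop("SBML document is missing parameter(s): ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  need_rx <- paste0("R", 1:7)
  missing_rx <- setdiff(need_rx, rx_ids)
  if (length(missing_rx)) {
    stop("SBML document is missing reaction(s): ",
         paste(missing_rx, collapse = ", "), call. = FALSE)
  }

  args <- as.list(par_val[need_par])
  args$Capacity_G <- unname(sp_amt[["Capacity_G"]])
  args$Capacity_M <- unname(sp_amt[["Capacity_M"]])
  args$glu_ex0 <- unname(sp_amt[["Glu_ex"]])
  params <- do.call(eca_params, args)
  dose <- eca_dose(oligo = unname(sp_amt[["Oligomycin"]]),
                   dg2 = unname(sp_amt[["DG2"]]))
  list(params = params, dose = dose, network = build_network(params))
}
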