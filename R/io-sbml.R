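#' @name sbml_io
#' @title SBML model I/O
#' @description Writes and reads the model as SBML. The default dialect is
#' Level 3 Version 1 with flux-modelling attributes (bounds as shared
#' parameters, an active maximisation objective, gene products and per-
#' reaction gene associations). A legacy Level 2 Version 1 dialect encodes
#' bounds and the objective coefficient as kinetic-law parameters
#' (`LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`), the historical
#' convention of constraint-based models. Category, subsystem, provenance
#' fields and the PMF flag travel in structured notes, so table and SBML
#' round trips are lossless.
NULL

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_L2_NS <- "http://www.sbml.org/sbml/level2/version1"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

notes_fields <- c(subsystem = "SUBSYSTEM", category = "CATEGORY",
                  transport_category = "TRANSPORT_CATEGORY",
                  directionality_evidence = "DIRECTIONALITY_EVIDENCE",
                  localisation_evidence = "LOCALISATION_EVIDENCE",
                  heart_expression = "HEART_EXPRESSION")

add_notes <- function(node, fields) {
  fields <- fields[!is.na(fields) & nzchar(fields)]
  if (!length(fields)) return(invisible(NULL))
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
  for (key in names(fields))
    xml2::xml_add_child(body, "p", paste0(key, ": ", fields[[key]]))
  invisible(NULL)
}

read_notes <- function(node) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='notes']//*[local-name()='p']")
  out <- character(0)
  for (p in ps) {
    txt <- xml2::xml_text(p)
    i <- regexpr(":", txt, fixed = TRUE)
    if (i > 0)
      out[trimws(substr(txt, 1, i - 1))] <- trimws(substr(txt, i + 1, nchar(txt)))
  }
  out
}

attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hits <- names(at) == name | endsWith(names(at), paste0(":", name))
  if (any(hits)) at[[which(hits)[1]]] else NA_character_
}

genes_split <- function(genes_str) {
  if (!nzchar(genes_str)) return(character(0))
  strsplit(genes_str, ";")[[1]]
}

#' Write a model as SBML
#'
#' @param model a `mito_model`.
#' @param path output file.
#' @param dialect `"L3V1"` (default, flux-extension attributes) or `"L2V1"`
#'   (legacy kinetic-law bound parameters).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, dialect = c("L3V1", "L2V1")) {
  dialect <- match.arg(dialect)
  if (dialect == "L3V1") write_sbml_l3(model, path) else write_sbml_l2(model, path)
}

write_sbml_l3 <- function(model, path) {
  root <- xml2::xml_new_root("sbml", xmlns = SBML_L3_NS,
                             "xmlns:fbc" = SBML_FBC_NS,
                             level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(root, "model", id = "mitoflux_model",
                             "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", name = "cytosol",
                      constant = "true")
  xml2::xml_add_child(comps, "compartment", id = "m",
                      name = "mitochondrial matrix", constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    mt <- model$mets[i, ]
    sp <- xml2::xml_add_child(sps, "species", id = paste0("M_", mt$id),
      name = mt$name,
      compartment = if (mt$compartment == "mitochondrial") "m" else "c",
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false", "fbc:charge" = as.character(mt$charge))
    if (!is.na(mt$formula) && nzchar(mt$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
    if (mt$is_pmf) add_notes(sp, c(PMF = "true"))
  }
  # shared bound parameters
  bounds <- sort(unique(c(model$rxns$lower, model$rxns$upper)))
  pid <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", fmt_num(v)))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds)
    xml2::xml_add_child(pars, "parameter", id = pid(v), value = fmt_num(v),
                        constant = "true")
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  all_genes <- character(0)
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    s <- model$stoich[[i]]
    rx <- xml2::xml_add_child(rxs, "reaction", id = paste0("R_", r$id),
      reversible = if (r$lower < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = pid(r$lower), "fbc:upperFluxBound" = pid(r$upper))
    add_notes(rx, stats::setNames(
      as.character(r[names(notes_fields)]), notes_fields))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lst <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("M_", names(reac)[k]),
                            stoichiometry = fmt_num(-reac[[k]]), constant = "true")
    }
    if (length(prod)) {
      lst <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("M_", names(prod)[k]),
                            stoichiometry = fmt_num(prod[[k]]), constant = "true")
    }
    gs <- genes_split(r$genes)
    if (length(gs)) {
      all_genes <- union(all_genes, gs)
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      holder <- if (length(gs) > 1) xml2::xml_add_child(gpa, "fbc:or") else gpa
      for (g in gs) {
        sym <- strsplit(g, "|", fixed = TRUE)[[1]][1]
        xml2::xml_add_child(holder, "fbc:geneProductRef",
                            "fbc:geneProduct" = paste0("G_", gsub("[^0-9A-Za-z_]", "_", sym)))
      }
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fol <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fol, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective_id),
                      "fbc:coefficient" = "1")
  if (length(all_genes)) {
    gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in sort(all_genes)) {
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      xml2::xml_add_child(gps, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", gsub("[^0-9A-Za-z_]", "_", parts[1])),
                          "fbc:label" = parts[1],
                          "fbc:name" = if (length(parts) > 1) parts[2] else parts[1])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

write_sbml_l2 <- function(model, path) {
  root <- xml2::xml_new_root("sbml", xmlns = SBML_L2_NS,
                             level = "2", version = "1")
  mdl <- xml2::xml_add_child(root, "model", id = "mitoflux_model")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", name = "cytosol")
  xml2::xml_add_child(comps, "compartment", id = "m", name = "mitochondrial matrix")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    mt <- model$mets[i, ]
    sp <- xml2::xml_add_child(sps, "species", id = paste0("M_", mt$id),
      name = mt$name,
      compartment = if (mt$compartment == "mitochondrial") "m" else "c",
      charge = as.character(mt$charge), boundaryCondition = "false")
    fields <- character(0)
    if (!is.na(mt$formula) && nzchar(mt$formula)) fields["FORMULA"] <- mt$formula
    if (mt$is_pmf) fields["PMF"] <- "true"
    add_notes(sp, fields)
  }
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    s <- model$stoich[[i]]
    rx <- xml2::xml_add_child(rxs, "reaction", id = paste0("R_", r$id),
      reversible = if (r$lower < 0) "true" else "false")
    fields <- stats::setNames(as.character(r[names(notes_fields)]), notes_fields)
    gs <- genes_split(r$genes)
    if (length(gs)) fields["GENE_ASSOCIATION"] <- paste(gs, collapse = ";")
    add_notes(rx, fields)
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lst <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("M_", names(reac)[k]),
                            stoichiometry = fmt_num(-reac[[k]]))
    }
    if (length(prod)) {
      lst <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(lst, "speciesReference",
                            species = paste0("M_", names(prod)[k]),
                            stoichiometry = fmt_num(prod[[k]]))
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    pl <- xml2::xml_add_child(kl, "listOfParameters")
    xml2::xml_add_child(pl, "parameter", id = "LOWER_BOUND", value = fmt_num(r$lower))
    xml2::xml_add_child(pl, "parameter", id = "UPPER_BOUND", value = fmt_num(r$upper))
    xml2::xml_add_child(pl, "parameter", id = "OBJECTIVE_COEFFICIENT",
                        value = if (r$id == model$objective_id) "1" else "0")
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Accepts both dialects written by [write_sbml()] (auto-detected from the
#' document level): Level 3 with flux attributes, or legacy Level 2 Version 1
#' with kinetic-law bound parameters.
#'
#' @param path SBML file.
#' @return a `mito_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document: ", path)
  level <- xml2::xml_attr(doc, "level")
  strip <- function(x, pre) sub(paste0("^", pre), "", x)

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp_nodes)) stop("SBML validation: no species found")
  mets <- do.call(rbind, lapply(sp_nodes, function(sp) {
    id <- strip(attr_any(sp, "id"), "M_")
    comp <- attr_any(sp, "compartment")
    charge <- attr_any(sp, "charge")
    notes <- read_notes(sp)
    formula <- attr_any(sp, "chemicalFormula")
    if (is.na(formula) && "FORMULA" %in% names(notes)) formula <- notes[["FORMULA"]]
    data.frame(id = id, name = attr_any(sp, "name"),
               compartment = if (identical(comp, "m")) "mitochondrial" else "cytosolic",
               charge = if (is.na(charge)) 0L else as.integer(charge),
               formula = if (is.na(formula)) NA_character_ else formula,
               is_pmf = identical(unname(notes["PMF"]), "true"),
               stringsAsFactors = FALSE)
  }))

  # gene products (L3)
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_map <- list()
  for (gp in gp_nodes) {
    gid <- attr_any(gp, "id")
    lab <- attr_any(gp, "label")
    nm <- attr_any(gp, "name")
    gp_map[[gid]] <- if (!is.na(nm) && nzchar(nm) && !identical(nm, lab))
      paste0(lab, "|", nm) else lab
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) stop("SBML validation: no reactions found")

  # L3 bound parameters
  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(p) as.numeric(attr_any(p, "value")), 0),
    vapply(par_nodes, function(p) attr_any(p, "id"), ""))

  objective_id <- NULL
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) objective_id <- strip(attr_any(fo, "reaction"), "R_")

  rxns <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    rx <- rx_nodes[[i]]
    rid <- strip(attr_any(rx, "id"), "R_")
    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./*[local-name()='", side,
                                            "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sid <- strip(attr_any(ref, "species"), "M_")
        if (!sid %in% mets$id)
          stop("SBML validation: reaction '", rid,
               "' references unknown species '", sid, "'")
        coef <- attr_any(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        stoich[sid] <- (if (sid %in% names(stoich)) stoich[[sid]] else 0) + sgn * coef
      }
    }
    notes <- read_notes(rx)
    lower <- upper <- NULL
    if (identical(level, "3")) {
      lower <- par_val[[attr_any(rx, "lowerFluxBound")]]
      upper <- par_val[[attr_any(rx, "upperFluxBound")]]
      gens <- character(0)
      refs <- xml2::xml_find_all(rx, ".//*[local-name()='geneProductRef']")
      for (ref in refs) {
        gid <- attr_any(ref, "geneProduct")
        gens <- c(gens, gp_map[[gid]] %||% sub("^G_", "", gid))
      }
    } else {
      kp <- xml2::xml_find_all(rx, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      for (p in kp) {
        pid <- attr_any(p, "id")
        if (identical(pid, "LOWER_BOUND")) lower <- as.numeric(attr_any(p, "value"))
        if (identical(pid, "UPPER_BOUND")) upper <- as.numeric(attr_any(p, "value"))
        if (identical(pid, "OBJECTIVE_COEFFICIENT") &&
            as.numeric(attr_any(p, "value")) != 0) objective_id <- rid
      }
      gens <- genes_split(notes["GENE_ASSOCIATION"] %||% "")
      if (length(gens) == 1 && is.na(gens)) gens <- character(0)
    }
    if (is.null(lower) || is.null(upper))
      stop("SBML validation: reaction '", rid, "' has no flux bounds")
    get_note <- function(key, default = "") {
      if (key %in% names(notes)) notes[[key]] else default
    }
    tc <- get_note("TRANSPORT_CATEGORY", NA_character_)
    rxns[[i]] <- reaction(rid, stoich, lower = lower, upper = upper,
      genes = gens,
      subsystem = get_note("SUBSYSTEM"),
      category = get_note("CATEGORY", "metabolic"),
      transport_category = if (!is.na(tc) && nzchar(tc)) tc else NA_character_,
      directionality_evidence = get_note("DIRECTIONALITY_EVIDENCE"),
      localisation_evidence = get_note("LOCALISATION_EVIDENCE"),
      heart_expression = get_note("HEART_EXPRESSION"))
  }
  ids <- vapply(rxns, `[[`, "", "id")
  if (is.null(objective_id) || !objective_id %in% ids) {
    pseudo <- vapply(rxns, function(r) r$category == "pseudo", TRUE)
    objective_id <- if (any(pseudo & grepl("ATP", ids))) ids[pseudo & grepl("ATP", ids)][1]
                    else ids[1]
  }
  model_network(mets, rxns, objective_id = objective_id,
                notes = paste0("read from ", basename(path)))
}
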