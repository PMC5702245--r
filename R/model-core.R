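#' Create a metabolite
#'
#' Metabolites are compartmentalised species: the same chemical in the cytosol
#' and in the mitochondrial matrix is two metabolites, distinguished by the
#' `_c` / `_m` id suffix. The proton-motive-force (PMF) bookkeeping species is
#' an ordinary metabolite flagged with `is_pmf`; it exists in both compartments
#' and is exempt from elemental/charge balance checks.
#'
#' @param id metabolite id; must end in `_c` (cytosolic) or `_m`
#'   (mitochondrial) unless `compartment = "boundary"`.
#' @param name human-readable name.
#' @param compartment one of `"cytosolic"`, `"mitochondrial"`, `"boundary"`.
#' @param charge signed integer elementary charge of the predominant species
#'   at pH 7.
#' @param formula optional elemental formula (e.g. `"C6H12O6"`).
#' @param is_pmf flag for the PMF pseudo-species.
#' @return a one-row `data.frame` with the metabolite fields.
#' @examples
#' metabolite("atp_c", "ATP", "cytosolic", charge = -4)
#' @export
metabolite <- function(id, name = id,
                       compartment = c("cytosolic", "mitochondrial", "boundary"),
                       charge = 0L, formula = NA_character_, is_pmf = FALSE) {
  compartment <- match.arg(compartment)
  suffix <- c(cytosolic = "_c", mitochondrial = "_m", boundary = "")[compartment]
  if (nzchar(suffix) && !endsWith(id, suffix)) {
    stop(sprintf("metabolite id '%s' must end with '%s' for compartment '%s'",
                 id, suffix, compartment))
  }
  data.frame(id = id, name = name, compartment = compartment,
             charge = as.integer(charge), formula = formula,
             is_pmf = isTRUE(is_pmf), stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' @param id reaction id. Ids of reactions that depart from their
#'   reference-database form carry the suffix `_MitoCore`.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower,upper flux bounds in umol/min/gDW. A reaction with
#'   `lower >= 0` is irreversible.
#' @param genes character vector of `"SYMBOL|ENSG..."` pairs (may be empty).
#' @param subsystem pathway label.
#' @param category one of `"metabolic"`, `"mito_transport"`,
#'   `"boundary_exchange"`, `"pseudo"`.
#' @param transport_category for `mito_transport` reactions only: one of
#'   `"CARRIER"`, `"UNIPORT_UNKNOWN"`, `"DIFFUSION"`, `"FLIPPASE"`.
#' @param directionality_evidence,localisation_evidence,heart_expression
#'   free-text provenance fields.
#' @return an object of class `mf_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower = -1000, upper = 1000,
                     genes = character(), subsystem = "",
                     category = c("metabolic", "mito_transport",
                                  "boundary_exchange", "pseudo"),
                     transport_category = NA_character_,
                     directionality_evidence = "",
                     localisation_evidence = "",
                     heart_expression = "") {
  category <- match.arg(category)
  if (lower > upper) stop(sprintf("reaction '%s': lower bound exceeds upper bound", id))
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (anyDuplicated(names(stoichiometry)))
    stop(sprintf("reaction '%s': duplicated metabolite in stoichiometry", id))
  if (category == "mito_transport") {
    if (!transport_category %in% c("CARRIER", "UNIPORT_UNKNOWN", "DIFFUSION", "FLIPPASE"))
      stop(sprintf("reaction '%s': mito_transport requires a transport category", id))
  } else if (!is.na(transport_category)) {
    stop(sprintf("reaction '%s': transport category only applies to mito_transport", id))
  }
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 genes = genes, subsystem = subsystem, category = category,
                 transport_category = transport_category,
                 directionality_evidence = directionality_evidence,
                 localisation_evidence = localisation_evidence,
                 heart_expression = heart_expression),
            class = "mf_reaction")
}

#' @export
print.mf_reaction <- function(x, ...) {
  cat(x$id, ": ", format_equation(x$stoichiometry, x$lower < 0), "\n",
      "  bounds [", x$lower, ", ", x$upper, "]  category ", x$category,
      if (!is.na(x$transport_category)) paste0("/", x$transport_category), "\n", sep = "")
  invisible(x)
}

compartment_of <- function(ids) {
  ifelse(endsWith(ids, "_c"), "cytosolic",
         ifelse(endsWith(ids, "_m"), "mitochondrial", "boundary"))
}

#' Assemble a metabolic network
#'
#' Binds metabolites and reactions into a validated model. Validation enforces
#' the structural invariants: referenced metabolites exist, ids are unique,
#' bounds are ordered, each category touches the compartments it is allowed to
#' (the PMF species is ignored when counting compartments of a `metabolic`
#' reaction, since the respiratory complexes move PMF across the membrane while
#' their chemistry is purely mitochondrial), and every `mito_transport`
#' reaction moves PMF antisymmetrically (coefficient on the cytosolic side
#' equal to minus the matrix side): transport dissipates or relocates the
#' gradient, it never creates it.
#'
#' @param metabolites a `data.frame` as produced by [metabolite()] (rows may be
#'   `rbind`ed) or a list of such.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the default objective reaction (by convention one
#'   of the four pseudo reactions).
#' @param notes free-text provenance.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `mito_model`.
#' @export
model_network <- function(metabolites, reactions, objective_id,
                          notes = "", check = TRUE) {
  if (is.list(metabolites) && !is.data.frame(metabolites))
    metabolites <- do.call(rbind, metabolites)
  if (inherits(reactions, "mf_reaction")) reactions <- list(reactions)
  rxns <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    lower = vapply(reactions, `[[`, 0, "lower"),
    upper = vapply(reactions, `[[`, 0, "upper"),
    genes = vapply(reactions, function(r) paste(r$genes, collapse = ";"), ""),
    subsystem = vapply(reactions, `[[`, "", "subsystem"),
    category = vapply(reactions, `[[`, "", "category"),
    transport_category = vapply(reactions, `[[`, NA_character_, "transport_category"),
    directionality_evidence = vapply(reactions, `[[`, "", "directionality_evidence"),
    localisation_evidence = vapply(reactions, `[[`, "", "localisation_evidence"),
    heart_expression = vapply(reactions, `[[`, "", "heart_expression"),
    stringsAsFactors = FALSE)
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxns$id
  model <- structure(list(mets = metabolites, rxns = rxns, stoich = stoich,
                          objective_id = objective_id, notes = notes),
                     class = "mito_model")
  if (check) validate_model(model)
  model
}

#' Validate a model's structural invariants
#'
#' @param model a `mito_model`.
#' @return the model, invisibly; errors describe the offending reaction.
#' @export
validate_model <- function(model) {
  mets <- model$mets
  if (anyDuplicated(mets$id))
    stop("duplicated metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(model$rxns$id))
    stop("duplicated reaction ids: ",
         paste(unique(model$rxns$id[duplicated(model$rxns$id)]), collapse = ", "))
  suffix_ok <- (mets$compartment == "cytosolic" & endsWith(mets$id, "_c")) |
    (mets$compartment == "mitochondrial" & endsWith(mets$id, "_m")) |
    mets$compartment == "boundary"
  if (!all(suffix_ok))
    stop("metabolite id/compartment suffix mismatch: ",
         paste(mets$id[!suffix_ok], collapse = ", "))
  if (!model$objective_id %in% model$rxns$id)
    stop("objective '", model$objective_id, "' is not a reaction in the model")
  pmf_ids <- mets$id[mets$is_pmf]
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    s <- model$stoich[[i]]
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(unknown, collapse = ", ")))
    if (r$lower > r$upper)
      stop(sprintf("reaction '%s': lower bound exceeds upper bound", r$id))
    comps <- unique(compartment_of(setdiff(names(s), pmf_ids)))
    comps_all <- unique(compartment_of(names(s)))
    switch(r$category,
      metabolic = if (length(comps) != 1)
        stop(sprintf("metabolic reaction '%s' touches %d compartments", r$id, length(comps))),
      mito_transport = if (!all(c("cytosolic", "mitochondrial") %in% comps_all))
        stop(sprintf("mito_transport reaction '%s' must touch both compartments", r$id)),
      boundary_exchange = if (!identical(comps_all, "cytosolic"))
        stop(sprintf("boundary_exchange reaction '%s' may only touch cytosolic species", r$id)),
      pseudo = NULL)
    if (r$category == "mito_transport" && length(pmf_ids) == 2) {
      kc <- if (pmf_ids[compartment_of(pmf_ids) == "cytosolic"] %in% names(s))
        s[[pmf_ids[compartment_of(pmf_ids) == "cytosolic"]]] else 0
      km <- if (pmf_ids[compartment_of(pmf_ids) == "mitochondrial"] %in% names(s))
        s[[pmf_ids[compartment_of(pmf_ids) == "mitochondrial"]]] else 0
      if (abs(kc + km) > 1e-12)
        stop(sprintf("transport reaction '%s' creates/destroys PMF (%.3g vs %.3g)",
                     r$id, kc, km))
    }
  }
  invisible(model)
}

#' @export
print.mito_model <- function(x, ...) {
  cat("mito_model: ", nrow(x$mets), " metabolites, ", nrow(x$rxns),
      " reactions\n", sep = "")
  cat("  objective: ", x$objective_id, "\n", sep = "")
  tab <- table(x$rxns$category)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assemble the stoichiometric matrix
#'
#' Rows are the model's (non-boundary) metabolites, columns its reactions;
#' entry (i, j) is the coefficient of metabolite i in reaction j. Boundary
#' sinks/sources appear only as the one-sided columns of `boundary_exchange`
#' reactions.
#'
#' @param model a `mito_model`.
#' @return a sparse `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
assemble_stoichiometric_matrix <- function(model) {
  mets <- model$mets$id[model$mets$compartment != "boundary"]
  n <- nrow(model$rxns)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    s <- model$stoich[[j]]
    idx <- match(names(s), mets)
    if (anyNA(idx)) {
      bad <- names(s)[is.na(idx)]
      bad <- setdiff(bad, model$mets$id)  # boundary species are legitimately absent
      if (length(bad))
        stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                     model$rxns$id[j], paste(bad, collapse = ", ")))
      keep <- !is.na(idx)
      idx <- idx[keep]; s <- s[keep]
    }
    ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx))); xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), n),
                       dimnames = list(mets, model$rxns$id))
}

parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Balance report for a reaction
#'
#' Reports the net charge delta and, where formulas are available, elemental
#' deltas of a reaction. The PMF pseudo-species and `pseudo`-category reactions
#' are exempt and flagged as such; missing formulas are reported, never raised.
#' Hydrogen is tallied separately because the network deliberately omits free
#' scalar protons (proton coupling is carried by the PMF coefficients), so an
#' apparent H/charge delta frequently corresponds to omitted protons.
#'
#' @param reaction an [reaction()] object.
#' @param metabolites metabolite table (as in a `mito_model`).
#' @return an object of class `mf_balance_report`: list with `charge_delta`,
#'   `element_deltas`, `exemptions`, `missing_formula`.
#' @export
validate_balance <- function(reaction, metabolites) {
  s <- reaction$stoichiometry
  exempt <- character(0)
  if (reaction$category == "pseudo") exempt <- c(exempt, "pseudo")
  idx <- match(names(s), metabolites$id)
  if (anyNA(idx))
    stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                 reaction$id, paste(names(s)[is.na(idx)], collapse = ", ")))
  pmf <- metabolites$is_pmf[idx]
  if (any(pmf)) exempt <- c(exempt, "pmf")
  s_bal <- s[!pmf]
  idx_bal <- idx[!pmf]
  charge_delta <- if (reaction$category == "pseudo") NA_real_ else
    sum(s_bal * metabolites$charge[idx_bal])
  missing <- names(s_bal)[is.na(metabolites$formula[idx_bal]) |
                            !nzchar(ifelse(is.na(metabolites$formula[idx_bal]), "",
                                           metabolites$formula[idx_bal]))]
  element_deltas <- numeric(0)
  if (reaction$category != "pseudo" && length(missing) == 0 && length(s_bal)) {
    tot <- list()
    for (k in seq_along(s_bal)) {
      f <- parse_formula(metabolites$formula[idx_bal[k]])
      for (el in names(f)) tot[[el]] <- (tot[[el]] %||% 0) + s_bal[[k]] * f[[el]]
    }
    element_deltas <- unlist(tot)
    element_deltas <- element_deltas[abs(element_deltas) > 1e-9]
  }
  structure(list(reaction_id = reaction$id, charge_delta = charge_delta,
                 element_deltas = element_deltas, exemptions = unique(exempt),
                 missing_formula = missing),
            class = "mf_balance_report")
}

#' @export
print.mf_balance_report <- function(x, ...) {
  cat("balance report for ", x$reaction_id, "\n", sep = "")
  if (length(x$exemptions))
    cat("  exempt: ", paste(x$exemptions, collapse = ", "), "\n", sep = "")
  if (!is.na(x$charge_delta))
    cat("  net charge delta: ", x$charge_delta, "\n", sep = "")
  if (length(x$element_deltas))
    cat("  element deltas: ",
        paste(sprintf("%s %+g", names(x$element_deltas), x$element_deltas),
              collapse = ", "), "\n", sep = "")
  if (length(x$missing_formula))
    cat("  no formula: ", paste(x$missing_formula, collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild reactions from a stoichiometric matrix
#'
#' Inverse of [assemble_stoichiometric_matrix()] for the stoichiometries:
#' returns the named coefficient vectors column by column.
#'
#' @param S a stoichiometric matrix with dimnames.
#' @return named list of named numeric vectors.
#' @keywords internal
stoich_from_matrix <- function(S) {
  out <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    col[col != 0]
  })
  names(out) <- colnames(S)
  out
}

met_index <- function(model, id) {
  i <- match(id, model$mets$id)
  if (is.na(i)) stop("unknown metabolite: ", id)
  i
}

rxn_index <- function(model, id) {
  i <- match(id, model$rxns$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  i
}

#' Set flux bounds of a reaction
#' @param model a `mito_model`.
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lower)) model$rxns$lower[i] <- lower
  if (!is.null(upper)) model$rxns$upper[i] <- upper
  if (model$rxns$lower[i] > model$rxns$upper[i])
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", id))
  model
}

#' Set the model objective
#' @param model a `mito_model`.
#' @param id reaction id to use as objective.
#' @return the modified model.
#' @export
set_objective <- function(model, id) {
  rxn_index(model, id)
  model$objective_id <- id
  model
}
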