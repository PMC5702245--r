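#' @name model_qc
#' @title Model quality control
#' @description Automated checks mirroring how a curated metabolic
#' reconstruction is tested before release: every reaction must be able to
#' carry flux when the cytosolic boundary is open, no metabolite may be a
#' dead end, and a fully closed system must be unable to generate ATP, NADH,
#' NADPH or PMF from nothing (no erroneous energy-generating cycles).
NULL

#' Open all boundary exchanges
#' @param model a `mito_model`.
#' @param bound magnitude of the opened bounds.
#' @return the modified model.
#' @export
open_boundaries <- function(model, bound = 1000) {
  ex <- model$rxns$category == "boundary_exchange"
  model$rxns$lower[ex] <- -bound
  model$rxns$upper[ex] <- bound
  model
}

#' Close all boundary exchanges
#' @param model a `mito_model`.
#' @return the modified model.
#' @export
close_boundaries <- function(model) {
  ex <- model$rxns$category == "boundary_exchange"
  model$rxns$lower[ex] <- 0
  model$rxns$upper[ex] <- 0
  model
}

#' Blocked-reaction check
#'
#' With every boundary exchange opened to permissive bounds, each reaction's
#' flux is maximised and minimised; a reaction is blocked when both optima are
#' zero.
#'
#' @param model a `mito_model`.
#' @param tol zero tolerance.
#' @return character vector of blocked reaction ids (empty when none).
#' @export
check_flux_capability <- function(model, tol = 1e-6) {
  model <- open_boundaries(model)
  p <- model_lp_parts(model)
  n <- length(p$rxn_ids)
  bat <- .simplex_fva(p$S, p$zero, seq_len(n), as.numeric(p$lb), as.numeric(p$ub))
  can_fwd <- bat$max_status == 0L & bat$max > tol
  can_bwd <- bat$min_status == 0L & bat$min < -tol
  p$rxn_ids[!(can_fwd | can_bwd)]
}

#' Energy-generating-cycle check
#'
#' Closes every boundary exchange and maximises ATP hydrolysis: any positive
#' optimum reveals a thermodynamically impossible internal loop producing ATP
#' "for free". The same closed-system test is repeated against temporary
#' currency sinks for PMF, matrix and cytosolic NADH, and matrix NADPH, since
#' an erroneous loop may launder energy through any of them.
#'
#' @param model a `mito_model`.
#' @param objective_id the ATP hydrolysis pseudo reaction (defaults to the
#'   model objective).
#' @return maximal closed-system ATP-hydrolysis flux, with attribute
#'   `details`: named vector of the per-currency closed-system optima.
#' @export
check_energy_generating_cycles <- function(model,
                                           objective_id = model$objective_id) {
  closed <- close_boundaries(model)
  run <- function(m, obj) {
    r <- fba(m, obj)
    if (r$status == "optimal") r$objective_value
    else if (r$status == "unbounded") Inf else 0
  }
  details <- c(atp = run(closed, objective_id))
  sinks <- list(
    pmf = c(pmf_c = -1, pmf_m = 1),
    nadh_m = c(nadh_m = -1, nad_m = 1),
    nadh_c = c(nadh_c = -1, nad_c = 1),
    nadph_m = c(nadph_m = -1, nadp_m = 1))
  for (nm in names(sinks)) {
    s <- sinks[[nm]]
    if (!all(names(s) %in% closed$mets$id)) next
    m2 <- closed
    m2$rxns <- rbind(m2$rxns, data.frame(
      id = paste0("DM_", nm, "_qc"), lower = 0, upper = 1000, genes = "",
      subsystem = "QC sink", category = "pseudo",
      transport_category = NA_character_, directionality_evidence = "",
      localisation_evidence = "", heart_expression = "",
      stringsAsFactors = FALSE))
    m2$stoich <- c(m2$stoich, stats::setNames(list(s), paste0("DM_", nm, "_qc")))
    details[nm] <- run(m2, paste0("DM_", nm, "_qc"))
  }
  structure(max(details["atp"]), details = details)
}

#' Dead-end metabolite check
#'
#' Lists metabolites that can only ever be produced or only ever consumed
#' across all reactions (boundary exchanges counted; reversible reactions
#' count on both sides).
#'
#' @param model a `mito_model`.
#' @return character vector of dead-end metabolite ids.
#' @export
check_dead_ends <- function(model) {
  ids <- model$mets$id
  producible <- stats::setNames(rep(FALSE, length(ids)), ids)
  consumable <- producible
  for (i in seq_len(nrow(model$rxns))) {
    s <- model$stoich[[i]]
    fwd <- model$rxns$upper[i] > 0
    bwd <- model$rxns$lower[i] < 0
    for (k in seq_along(s)) {
      met <- names(s)[k]
      if (s[[k]] > 0) {
        if (fwd) producible[met] <- TRUE
        if (bwd) consumable[met] <- TRUE
      } else {
        if (fwd) consumable[met] <- TRUE
        if (bwd) producible[met] <- TRUE
      }
    }
  }
  ids[!(producible & consumable)]
}

#' Full quality-control report
#'
#' Runs [check_flux_capability()], [check_dead_ends()] and
#' [check_energy_generating_cycles()], and collects elemental balance issues
#' from [validate_balance()] (reactions with a non-hydrogen element imbalance
#' among fully-formula-annotated species; hydrogen and charge deltas are
#' reported informationally since the network deliberately omits free scalar
#' protons). `passed` is true iff all lists are empty and the closed-system
#' energy optimum is zero.
#'
#' @param model a `mito_model`.
#' @param tol zero tolerance for the energy-cycle optimum.
#' @return an object of class `mf_qc_report`.
#' @export
qc_report <- function(model, tol = 1e-6) {
  blocked <- check_flux_capability(model)
  dead <- check_dead_ends(model)
  energy <- check_energy_generating_cycles(model)
  balance_issues <- character(0)
  for (i in seq_len(nrow(model$rxns))) {
    r <- reaction_from_model(model, i)
    if (r$category %in% c("pseudo", "boundary_exchange")) next
    rep_i <- validate_balance(r, model$mets)
    if (length(rep_i$missing_formula)) next
    el <- rep_i$element_deltas
    el <- el[setdiff(names(el), "H")]
    if (length(el) && any(abs(el) > 1e-9))
      balance_issues <- c(balance_issues, r$id)
  }
  structure(list(blocked_reactions = blocked,
                 dead_end_metabolites = dead,
                 energy_cycle_atp = as.numeric(energy),
                 energy_cycle_details = attr(energy, "details"),
                 balance_issues = balance_issues,
                 passed = length(blocked) == 0 && length(dead) == 0 &&
                   length(balance_issues) == 0 &&
                   abs(as.numeric(energy)) <= tol),
            class = "mf_qc_report")
}

reaction_from_model <- function(model, i) {
  r <- model$rxns[i, ]
  reaction(r$id, model$stoich[[i]], lower = r$lower, upper = r$upper,
           genes = if (nzchar(r$genes)) strsplit(r$genes, ";")[[1]] else character(),
           subsystem = r$subsystem, category = r$category,
           transport_category = r$transport_category,
           directionality_evidence = r$directionality_evidence,
           localisation_evidence = r$localisation_evidence,
           heart_expression = r$heart_expression)
}

#' @export
print.mf_qc_report <- function(x, ...) {
  cat("QC report: ", if (x$passed) "PASSED" else "FAILED", "\n", sep = "")
  cat("  blocked reactions:   ", length(x$blocked_reactions),
      if (length(x$blocked_reactions))
        paste0(" (", paste(x$blocked_reactions, collapse = ", "), ")"), "\n", sep = "")
  cat("  dead-end metabolites:", length(x$dead_end_metabolites),
      if (length(x$dead_end_metabolites))
        paste0(" (", paste(x$dead_end_metabolites, collapse = ", "), ")"), "\n")
  cat("  closed-system energy optimum:", format(x$energy_cycle_atp), "\n")
  cat("  balance issues:      ", length(x$balance_issues), "\n")
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param report an `mf_qc_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
qc_report_json <- function(report, path = NULL) {
  payload <- list(
    blocked_reactions = report$blocked_reactions,
    dead_end_metabolites = report$dead_end_metabolites,
    energy_cycle_atp = report$energy_cycle_atp,
    energy_cycle_details = as.list(report$energy_cycle_details),
    balance_issues = report$balance_issues,
    passed = report$passed)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
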