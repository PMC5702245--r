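#' @name table_io
#' @title Tabular model I/O
#'
#' @description Reactions are serialised one per row with a human-readable
#' equation column, e.g.
#' `"atp_m + adp_c + 0.82 pmf_c -> atp_c + adp_m + 0.82 pmf_m"`;
#' `<=>` marks reversible reactions, a one-sided equation (`"glc_c <=>"`)
#' is a boundary exchange (positive flux = efflux). Coefficients are written
#' as plain decimals and re-read exactly as written. A companion metabolite
#' table carries name, charge, formula and the PMF flag.
NULL

# parse "c1 met1 + c2 met2 -> ..." into a named coefficient vector
parse_equation <- function(eq, line = NA_integer_) {
  err <- function(msg, tok = NULL) {
    where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
    tokmsg <- if (is.null(tok)) "" else sprintf(" near '%s'", tok)
    stop(sprintf("equation parse error%s%s: %s in \"%s\"", where, tokmsg, msg, eq),
         call. = FALSE)
  }
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
           else if (grepl("->", eq, fixed = TRUE)) "->"
           else err("no '->' or '<=>' arrow")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2) err("multiple arrows")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) err("empty term")
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) err("coefficient is not a number", parts[1])
        met <- parts[2]
      } else err("too many tokens in term", tm)
      if (!grepl("^[A-Za-z0-9][A-Za-z0-9_]*$", met) || !grepl("[A-Za-z]", met))
        err("invalid metabolite token", met)
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  s <- lhs
  for (m in names(rhs))
    s[m] <- (if (m %in% names(s)) s[[m]] else 0) + rhs[[m]]
  s <- s[s != 0]
  attr(s, "reversible") <- arrow == "<=>"
  s
}

fmt_num <- function(x) {
  out <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
}

format_equation <- function(stoich, reversible) {
  side <- function(s) {
    if (!length(s)) return("")
    paste(ifelse(abs(s) == 1, names(s), paste(fmt_num(abs(s)), names(s))),
          collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(side(lhs), if (reversible) "<=>" else "->", side(rhs))
}

#' Read a model from the reaction-table dialect
#'
#' @param path path to the reaction TSV.
#' @param metabolites_path path to the companion metabolite TSV; defaults to
#'   `<path minus .tsv>_metabolites.tsv` when that file exists. Without it,
#'   metabolites are inferred from id suffixes with charge 0.
#' @param objective_id objective reaction; defaults to the first `pseudo`
#'   reaction whose id contains `"ATP"`, else the first pseudo reaction.
#' @return a `mito_model`.
#' @export
read_table <- function(path, metabolites_path = NULL, objective_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", "equation", "lower", "upper")
  if (!all(needed %in% names(tab)))
    stop("reaction table must have columns: ", paste(needed, collapse = ", "))
  opt <- function(col) {
    if (!col %in% names(tab)) return(rep("", nrow(tab)))
    out <- as.character(tab[[col]])
    ifelse(is.na(out), "", out)
  }
  rxns <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- parse_equation(tab$equation[i], line = i + 1L)
    tc <- opt("transport_category")[i]
    rxns[[i]] <- reaction(
      id = tab$id[i], stoichiometry = unclass(c(s)),
      lower = tab$lower[i], upper = tab$upper[i],
      genes = if (nzchar(opt("genes")[i])) strsplit(opt("genes")[i], ";")[[1]] else character(),
      subsystem = opt("subsystem")[i],
      category = if (nzchar(opt("category")[i])) opt("category")[i] else "metabolic",
      transport_category = if (nzchar(tc) && !is.na(tc)) tc else NA_character_,
      directionality_evidence = opt("directionality_evidence")[i],
      localisation_evidence = opt("localisation_evidence")[i],
      heart_expression = opt("heart_expression")[i])
  }
  if (is.null(metabolites_path)) {
    cand <- sub("\\.tsv$", "_metabolites.tsv", path)
    if (file.exists(cand)) metabolites_path <- cand
  }
  met_ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))))
  if (!is.null(metabolites_path)) {
    mt <- utils::read.delim(metabolites_path, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE)
    missing <- setdiff(met_ids, mt$id)
    if (length(missing))
      stop("metabolite table lacks entries for: ", paste(missing, collapse = ", "))
    mets <- data.frame(id = mt$id, name = mt$name, compartment = mt$compartment,
                       charge = as.integer(mt$charge),
                       formula = ifelse(is.na(mt$formula) | !nzchar(mt$formula),
                                        NA_character_, mt$formula),
                       is_pmf = as.logical(mt$is_pmf), stringsAsFactors = FALSE)
  } else {
    comp <- compartment_of(met_ids)
    if (any(comp == "boundary"))
      stop("unknown metabolite suffix (expect _c or _m): ",
           paste(met_ids[comp == "boundary"], collapse = ", "))
    mets <- data.frame(id = met_ids, name = met_ids, compartment = comp,
                       charge = 0L, formula = NA_character_,
                       is_pmf = grepl("^pmf_", met_ids), stringsAsFactors = FALSE)
  }
  if (is.null(objective_id)) {
    pseudo <- vapply(rxns, function(r) r$category == "pseudo", TRUE)
    ids <- vapply(rxns, `[[`, "", "id")
    objective_id <- if (any(pseudo & grepl("ATP", ids))) ids[pseudo & grepl("ATP", ids)][1]
                    else if (any(pseudo)) ids[pseudo][1] else ids[1]
  }
  model_network(mets, rxns, objective_id = objective_id,
                notes = paste0("read from ", basename(path)))
}

#' Write a model in the reaction-table dialect
#'
#' @param model a `mito_model`.
#' @param path reaction TSV path.
#' @param metabolites_path companion metabolite TSV path (default derived from
#'   `path`).
#' @return `path`, invisibly.
#' @export
write_table <- function(model, path,
                        metabolites_path = sub("\\.tsv$", "_metabolites.tsv", path)) {
  eqs <- vapply(seq_len(nrow(model$rxns)), function(i)
    format_equation(model$stoich[[i]], model$rxns$lower[i] < 0), "")
  tab <- data.frame(id = model$rxns$id, equation = eqs,
                    lower = fmt_num(model$rxns$lower),
                    upper = fmt_num(model$rxns$upper),
                    genes = model$rxns$genes,
                    subsystem = model$rxns$subsystem,
                    category = model$rxns$category,
                    transport_category = ifelse(is.na(model$rxns$transport_category),
                                                "", model$rxns$transport_category),
                    directionality_evidence = model$rxns$directionality_evidence,
                    localisation_evidence = model$rxns$localisation_evidence,
                    heart_expression = model$rxns$heart_expression,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- model$mets
  mt$formula[is.na(mt$formula)] <- ""
  utils::write.table(mt, metabolites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a flux solution as TSV
#'
#' Writes one row per reaction: id, flux and, when an FVA result is supplied,
#' the min/max range.
#'
#' @param result a flux result from [fba()] or [geometric_fba()].
#' @param path output path.
#' @param fva optional [fva()] result supplying ranges.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(result, path, fva = NULL) {
  tab <- data.frame(id = names(result$fluxes), flux = unname(result$fluxes))
  if (!is.null(fva)) {
    tab$min <- fva$ranges[tab$id, "min"]
    tab$max <- fva$ranges[tab$id, "max"]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
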