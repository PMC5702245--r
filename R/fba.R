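#' @name fba_engine
#' @title Flux balance analysis engine
#' @description Linear-programming analysis of a `mito_model`: FBA, FVA,
#' geometric FBA, gene/reaction knockouts and bound scans. All solves share
#' the package's bounded-variable simplex; solver settings are deterministic,
#' so repeated runs return identical results.
NULL

model_lp_parts <- function(model) {
  S <- as.matrix(assemble_stoichiometric_matrix(model))
  list(S = S, lb = model$rxns$lower, ub = model$rxns$upper,
       rxn_ids = model$rxns$id, zero = rep(0, nrow(S)))
}

objective_vector <- function(model, objective_id) {
  i <- rxn_index(model, objective_id)
  cc <- rep(0, nrow(model$rxns))
  cc[i] <- 1
  if (all(cc == 0)) stop("degenerate all-zero objective")
  cc
}

flux_result <- function(status, objective_value, fluxes, ids) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = stats::setNames(fluxes, ids)),
            class = "mf_flux_result")
}

#' @export
print.mf_flux_result <- function(x, ...) {
  cat("flux result: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective_value, digits = 8), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves `optimise c'v  s.t.  S v = 0, lb <= v <= ub` where `c` selects the
#' objective reaction. The steady-state constraint covers every non-boundary
#' metabolite; exchanges are the only sources and sinks.
#'
#' @param model a `mito_model`.
#' @param objective_id objective reaction id (default: the model objective).
#' @param sense `"max"` or `"min"`.
#' @return an `mf_flux_result` with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value` and the flux vector.
#' @export
fba <- function(model, objective_id = model$objective_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- model_lp_parts(model)
  cc <- objective_vector(model, objective_id)
  r <- lp_solve(cc, p$S, p$zero, p$zero, p$lb, p$ub, maximise = sense == "max")
  if (r$status == "iteration_limit")
    stop("solver failed to converge (iteration limit)")
  flux_result(r$status,
              if (r$status == "optimal") r$objective else NA_real_,
              if (r$status == "optimal") r$x else rep(NA_real_, length(p$lb)),
              p$rxn_ids)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with attaining
#' at least `fraction` of the optimal objective. At `fraction = 1` the ranges
#' bracket every optimal flux vector; relaxing to 0.98 reveals the flexibility
#' available within 98% of the optimum.
#'
#' @param model a `mito_model`.
#' @param objective_id objective reaction id.
#' @param fraction required fraction of the optimum, in (0, 1].
#' @param reactions reaction ids to analyse (default: all).
#' @return an `mf_fva_result`: list with `fraction`, `optimum` and a `ranges`
#'   matrix (rows = reactions, columns `min`/`max`; `NA` rows flag reactions
#'   whose sub-problem failed).
#' @export
fva <- function(model, objective_id = model$objective_id, fraction = 1.0,
                reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  base <- fba(model, objective_id)
  if (base$status != "optimal")
    stop("FVA requires an optimal base solution; FBA status: ", base$status)
  opt <- base$objective_value
  # encode c'v >= fraction*opt on the objective reaction's own bounds
  model2 <- model
  i <- rxn_index(model, objective_id)
  floor_v <- if (opt >= 0) fraction * opt else opt / fraction
  model2$rxns$lower[i] <- max(model2$rxns$lower[i], floor_v)
  p <- model_lp_parts(model2)
  if (is.null(reactions)) reactions <- p$rxn_ids
  ranges <- matrix(NA_real_, length(reactions), 2,
                   dimnames = list(reactions, c("min", "max")))
  js <- match(reactions, p$rxn_ids)
  bat <- .simplex_fva(p$S, rep(0, nrow(p$S)), as.integer(js),
                      as.numeric(p$lb), as.numeric(p$ub))
  ok_min <- bat$min_status == 0L
  ok_max <- bat$max_status == 0L
  ranges[reactions[ok_min], "min"] <- bat$min[ok_min]
  ranges[reactions[ok_max], "max"] <- bat$max[ok_max]
  structure(list(fraction = fraction, optimum = opt, ranges = ranges),
            class = "mf_fva_result")
}

#' @export
print.mf_fva_result <- function(x, ...) {
  wid <- x$ranges[, "max"] - x$ranges[, "min"]
  cat("FVA at fraction ", x$fraction, " (optimum ",
      format(x$optimum, digits = 8), "): ", nrow(x$ranges), " reactions, ",
      sum(wid > 1e-6, na.rm = TRUE), " with non-point ranges\n", sep = "")
  invisible(x)
}

#' Geometric FBA settings
#'
#' @param epsilon convergence tolerance on the width of the flux bounding box.
#' @param flex_rel relative flexibility on the optimum: the objective is
#'   constrained to at least `(1 - flex_rel) * optimum`.
#' @param max_iter iteration cap.
#' @return a `geometric_settings` list.
#' @export
geometric_settings <- function(epsilon = 1e-4, flex_rel = 0, max_iter = 60) {
  stopifnot(epsilon > 0, flex_rel >= 0, flex_rel < 1, max_iter >= 1)
  structure(list(epsilon = epsilon, flex_rel = flex_rel, max_iter = max_iter),
            class = "geometric_settings")
}

#' Geometric flux balance analysis
#'
#' Returns a single well-centred optimal flux vector, deterministically:
#' among all flux distributions attaining the optimum, alternate optima
#' (isoenzyme splits, parallel transport routes) are resolved by iteratively
#' computing the FVA bounding box at the optimum and moving to the point
#' minimising the maximum deviation from the box midpoints, shrinking the box
#' until its width falls below `epsilon`.
#'
#' @param model a `mito_model`.
#' @param objective_id objective reaction id.
#' @param settings a [geometric_settings()] object.
#' @return an `mf_flux_result`; `objective_value` is the flux through the
#'   objective reaction at the returned point.
#' @export
geometric_fba <- function(model, objective_id = model$objective_id,
                          settings = geometric_settings()) {
  base <- fba(model, objective_id)
  if (base$status != "optimal")
    return(base)
  opt <- base$objective_value
  i_obj <- rxn_index(model, objective_id)
  work <- model
  floor_v <- if (opt >= 0) (1 - settings$flex_rel) * opt else opt / (1 - settings$flex_rel)
  work$rxns$lower[i_obj] <- max(work$rxns$lower[i_obj], floor_v)
  n <- nrow(work$rxns)
  lo <- work$rxns$lower
  hi <- work$rxns$upper
  p <- model_lp_parts(work)
  m <- nrow(p$S)
  wide <- seq_len(n)
  v <- base$fluxes
  pad <- 1e-9  # keep the shrinking box strictly feasible under rounding
  for (iter in seq_len(settings$max_iter)) {
    # FVA over the current box, batch-updated after the sweep
    lo2 <- lo; hi2 <- hi
    bat <- .simplex_fva(p$S, p$zero, as.integer(wide),
                        as.numeric(lo), as.numeric(hi))
    okm <- bat$min_status == 0L; okM <- bat$max_status == 0L
    lo2[wide[okm]] <- pmax(lo[wide[okm]], bat$min[okm] - pad)
    hi2[wide[okM]] <- pmin(hi[wide[okM]], bat$max[okM] + pad)
    lo <- lo2; hi <- pmax(hi2, lo2)  # guard against FVA rounding crossing
    wide <- which(hi - lo > settings$epsilon)
    if (!length(wide)) break
    mid <- (lo + hi) / 2
    # minimax LP: minimise t subject to |v_j - mid_j| <= t on the wide set
    k <- length(wide)
    A <- cbind(rbind(p$S, matrix(0, 2 * k, n)), c(rep(0, m), rep(0, 2 * k)))
    A[m + seq_len(k), n + 1] <- -1
    A[m + k + seq_len(k), n + 1] <- 1
    for (ii in seq_len(k)) {
      A[m + ii, wide[ii]] <- 1
      A[m + k + ii, wide[ii]] <- 1
    }
    rowlb <- c(p$zero, rep(-Inf, k), mid[wide])
    rowub <- c(p$zero, mid[wide], rep(Inf, k))
    cc <- c(rep(0, n), 1)
    r <- lp_solve(cc, A, rowlb, rowub, c(lo, 0), c(hi, Inf), maximise = FALSE)
    if (r$status != "optimal") {
      cond <- structure(
        class = c("mf_geometric_error", "error", "condition"),
        list(message = paste0("geometric FBA sub-problem ", r$status),
             call = sys.call(-1), iterate = flux_result("optimal", v[i_obj], v, p$rxn_ids)))
      stop(cond)
    }
    t_star <- max(r$objective, 0) + pad
    v <- stats::setNames(r$x[seq_len(n)], p$rxn_ids)
    lo[wide] <- pmax(lo[wide], mid[wide] - t_star)
    hi[wide] <- pmin(hi[wide], mid[wide] + t_star)
    if (iter == settings$max_iter && length(which(hi - lo > settings$epsilon))) {
      cond <- structure(
        class = c("mf_geometric_error", "error", "condition"),
        list(message = sprintf("geometric FBA did not converge in %d iterations",
                               settings$max_iter),
             call = sys.call(-1),
             iterate = flux_result("optimal", v[i_obj], v, p$rxn_ids)))
      stop(cond)
    }
  }
  # final consistent point inside the converged box
  cc <- objective_vector(work, objective_id)
  r <- lp_solve_eq(cc, p$S, lo, hi, maximise = TRUE)
  if (r$status != "optimal") stop("geometric FBA: final solve ", r$status)
  flux_result("optimal", r$x[i_obj], r$x, p$rxn_ids)
}

#' Match knockout targets to reactions
#'
#' Targets may be reaction ids, gene symbols or stable gene identifiers.
#' Protein complexes are single reactions, so knocking out any subunit gene
#' disables the whole catalytic step.
#'
#' @param model a `mito_model`.
#' @param targets character vector.
#' @return integer vector of reaction indices.
#' @keywords internal
match_knockout_targets <- function(model, targets) {
  gene_lists <- strsplit(model$rxns$genes, ";")
  hit <- rep(FALSE, nrow(model$rxns))
  for (tg in targets) {
    if (tg %in% model$rxns$id) {
      hit[model$rxns$id == tg] <- TRUE
      next
    }
    matched <- vapply(gene_lists, function(gl) {
      any(vapply(strsplit(gl, "|", fixed = TRUE),
                 function(parts) tg %in% parts, TRUE))
    }, TRUE)
    if (!any(matched)) {
      known <- sort(unique(unlist(lapply(gene_lists, function(gl)
        vapply(strsplit(gl, "|", fixed = TRUE), `[`, "", 1)))))
      known <- known[nzchar(known)]
      stop("unknown knockout target '", tg, "'; known genes: ",
           paste(known, collapse = ", "))
    }
    hit <- hit | matched
  }
  which(hit)
}

#' Apply a knockout to a model
#' @param model a `mito_model`.
#' @param targets gene symbols, gene ids or reaction ids.
#' @return the model with all associated reactions constrained to zero flux.
#' @export
apply_knockout <- function(model, targets) {
  idx <- match_knockout_targets(model, targets)
  model$rxns$lower[idx] <- 0
  model$rxns$upper[idx] <- 0
  model
}

#' Simulate a knockout
#'
#' Constrains every reaction associated with any target to zero flux, then
#' runs FBA.
#'
#' @inheritParams apply_knockout
#' @param objective_id objective reaction id.
#' @param method `"fba"` or `"geometric"`.
#' @return an `mf_flux_result`.
#' @export
knockout <- function(model, targets, objective_id = model$objective_id,
                     method = c("fba", "geometric")) {
  method <- match.arg(method)
  model <- apply_knockout(model, targets)
  if (method == "geometric") geometric_fba(model, objective_id)
  else fba(model, objective_id)
}

#' Scan one bound of a reaction over a series of values
#'
#' Re-solves the model once per value; infeasible points are reported in the
#' result, and the scan continues.
#'
#' @param model a `mito_model`.
#' @param reaction_id reaction whose bound is scanned.
#' @param bound_side `"lower"` or `"upper"`.
#' @param values numeric vector of bound values (sorted).
#' @param objective_id objective reaction id.
#' @param method `"fba"` or `"geometric"`.
#' @return list of `mf_flux_result`, one per value, in input order.
#' @export
scan_bound <- function(model, reaction_id, bound_side = c("lower", "upper"),
                       values, objective_id = model$objective_id,
                       method = c("fba", "geometric")) {
  bound_side <- match.arg(bound_side)
  method <- match.arg(method)
  if (is.unsorted(values)) stop("scan values must be sorted")
  lapply(values, function(v) {
    m <- if (bound_side == "lower") set_bounds(model, reaction_id, lower = v)
         else set_bounds(model, reaction_id, upper = v)
    if (method == "geometric") {
      base <- fba(m, objective_id)
      if (base$status != "optimal") return(base)
      geometric_fba(m, objective_id)
    } else fba(m, objective_id)
  })
}
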