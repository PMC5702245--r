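#' @name simulations
#' @title Simulation protocols
#' @description Reproducible recipes over the bundled model: maximal ATP
#' yield per fuel, fumarase-deficiency knockout, and the UCP2 proton-leak
#' scan, plus attribution of acetyl-CoA production to fuel pathways.
NULL

#' ATP-yield protocol settings
#'
#' The yield protocol isolates one fuel: every boundary uptake of a
#' metabolite that can be degraded to produce ATP is closed, oxygen is opened
#' to 50 umol/min/gDW (so oxygen is never limiting), the fuel of interest is
#' admitted at 1 umol/min/gDW, and ATP hydrolysis is maximised with geometric
#' FBA. At unit uptake the objective equals mol ATP per mol fuel.
#'
#' @param fuel_id boundary exchange id (or bare fuel name, e.g. `"glc"`).
#' @param fuel_uptake fuel uptake bound.
#' @param o2_uptake oxygen uptake bound.
#' @param objective objective reaction id.
#' @param method `"geometric"` (default) or `"fba"`.
#' @return a `yield_protocol` list.
#' @export
yield_protocol <- function(fuel_id, fuel_uptake = 1, o2_uptake = 50,
                           objective = "OF_ATP_MitoCore",
                           method = c("geometric", "fba")) {
  structure(list(fuel_id = fuel_id, fuel_uptake = fuel_uptake,
                 o2_uptake = o2_uptake, objective = objective,
                 method = match.arg(method)),
            class = "yield_protocol")
}

#' Exchange reactions of degradable fuels
#' @param model a `mito_model`.
#' @return character vector of exchange reaction ids.
#' @export
degradable_fuels <- function(model) {
  model$rxns$id[model$rxns$subsystem == "Exchange/fuel" &
                  model$rxns$category == "boundary_exchange"]
}

resolve_exchange <- function(model, fuel_id) {
  if (fuel_id %in% model$rxns$id) return(fuel_id)
  cand <- paste0("EX_", fuel_id)
  if (cand %in% model$rxns$id) return(cand)
  stop("no boundary exchange for fuel '", fuel_id, "'")
}

#' Maximal ATP yield of a single fuel
#'
#' Applies the yield protocol and returns the maximal ATP-hydrolysis flux.
#' Oxygen must be non-binding at the optimum; this is asserted. A fuel with
#' no degradation route yields 0 with a warning.
#'
#' @param model a `mito_model`.
#' @param protocol a [yield_protocol()]; alternatively pass `fuel` to use
#'   protocol defaults.
#' @param fuel shorthand: fuel id used to construct a default protocol.
#' @return the yield (umol ATP/min/gDW; mol ATP per mol fuel at unit uptake),
#'   with the full flux result in attribute `result`.
#' @export
atp_yield <- function(model, protocol = NULL, fuel = NULL) {
  if (is.null(protocol)) {
    if (is.null(fuel)) stop("supply a protocol or a fuel id")
    protocol <- yield_protocol(fuel)
  }
  ex <- resolve_exchange(model, protocol$fuel_id)
  for (f in degradable_fuels(model)) model <- set_bounds(model, f, lower = 0)
  model <- set_bounds(model, "EX_o2", lower = -protocol$o2_uptake)
  model <- set_bounds(model, ex, lower = -protocol$fuel_uptake)
  res <- if (protocol$method == "geometric")
    geometric_fba(model, protocol$objective)
  else fba(model, protocol$objective)
  if (res$status != "optimal")
    stop("yield protocol solve failed: ", res$status)
  yld <- res$objective_value
  if (yld <= 1e-9 && protocol$fuel_uptake > 0)
    warning("fuel '", protocol$fuel_id, "' has no ATP-producing degradation route")
  o2_used <- -res$fluxes[["EX_o2"]]
  if (o2_used > protocol$o2_uptake - 1e-6)
    stop("oxygen is binding at the optimum; raise o2_uptake")
  structure(yld, result = res)
}

#' ATP yields for a set of fuels
#'
#' @param model a `mito_model`.
#' @param fuels exchange ids or bare fuel names; default: all degradable
#'   fuels in the model.
#' @param ... passed to [yield_protocol()].
#' @return data.frame with columns `fuel` and `atp_yield` (rounded to one
#'   decimal in the printed column `atp_yield_1dp`, matching the convention
#'   for reporting yields).
#' @export
atp_yield_table <- function(model, fuels = degradable_fuels(model), ...) {
  ylds <- vapply(fuels, function(f)
    as.numeric(atp_yield(model, yield_protocol(f, ...))), 0)
  data.frame(fuel = sub("^EX_", "", fuels), atp_yield = unname(ylds),
             atp_yield_1dp = round(unname(ylds), 1))
}

#' Simulate fumarase deficiency
#'
#' Fumarate hydratase is encoded by a single gene with cytosolic and
#' mitochondrial isoforms; the knockout therefore disables both compartmental
#' reactions at once. Uptake bounds are left at their configured (default
#' cardiomyocyte) values. Reports the wild-type and knockout solutions, the
#' percent reduction in maximal ATP production and the fumarate boundary
#' efflux in the knockout.
#'
#' @param model a `mito_model` with uptake config applied.
#' @param gene the fumarate hydratase gene symbol.
#' @param objective_id objective reaction id.
#' @param method `"geometric"` (default) or `"fba"`.
#' @return list with `wild_type`, `knockout` (both `mf_flux_result`),
#'   `percent_atp_reduction`, `fumarate_efflux`.
#' @export
simulate_fumarase_deficiency <- function(model, gene = "FH",
                                         objective_id = model$objective_id,
                                         method = c("geometric", "fba")) {
  method <- match.arg(method)
  solve1 <- function(m) {
    if (method == "geometric") {
      base <- fba(m, objective_id)
      if (base$status != "optimal") return(base)
      geometric_fba(m, objective_id)
    } else fba(m, objective_id)
  }
  wt <- solve1(model)
  ko_model <- apply_knockout(model, gene)
  ko <- solve1(ko_model)
  reduction <- if (wt$status == "optimal" && ko$status == "optimal" &&
                   wt$objective_value > 0)
    100 * (1 - ko$objective_value / wt$objective_value) else NA_real_
  efflux <- if (ko$status == "optimal" && "EX_fum" %in% names(ko$fluxes))
    ko$fluxes[["EX_fum"]] else NA_real_
  list(wild_type = wt, knockout = ko,
       percent_atp_reduction = reduction, fumarate_efflux = efflux)
}

#' Proton-leak scan through the uncoupling-protein step
#'
#' Forces a minimum flux (the leak) through `HtmB_MitoCore` -- vectorial
#' protons re-entering the matrix and dissipating one PMF each -- over a
#' series of values, and tracks maximal ATP production together with the
#' fluxes through the ATP synthase, the ATP/ADP carrier and the phosphate
#' carrier. Infeasible points (leak beyond what the chain plus reversed ATP
#' machinery can sustain) truncate the series with a message.
#'
#' @param model a `mito_model` with uptake config applied.
#' @param leak_values increasing leak fluxes (umol/min/gDW).
#' @param leak_id leak reaction id.
#' @param objective_id objective reaction id.
#' @param method `"geometric"` (default) or `"fba"`.
#' @return data.frame with columns `leak`, `max_atp`, `atp_synthase`,
#'   `ant`, `pi_carrier`.
#' @export
proton_leak_scan <- function(model, leak_values = seq(0, 400, by = 25),
                             leak_id = "HtmB_MitoCore",
                             objective_id = model$objective_id,
                             method = c("geometric", "fba")) {
  method <- match.arg(method)
  rxn_index(model, leak_id)
  results <- scan_bound(model, leak_id, "lower", leak_values,
                        objective_id = objective_id, method = method)
  rows <- list()
  for (i in seq_along(leak_values)) {
    r <- results[[i]]
    if (r$status != "optimal") {
      message("leak ", leak_values[i], " ", r$status,
              "; truncating scan at ", length(rows), " points")
      break
    }
    rows[[i]] <- data.frame(
      leak = leak_values[i], max_atp = r$objective_value,
      atp_synthase = r$fluxes[["ATPS_MitoCore"]],
      ant = r$fluxes[["ATPADPtm_MitoCore"]],
      # net phosphate import: forward minus backward member of the split pair
      pi_carrier = r$fluxes[["PItm_F_MitoCore"]] - r$fluxes[["PItm_B_MitoCore"]])
  }
  do.call(rbind, rows)
}

#' Attribute acetyl-CoA production to fuel pathways
#'
#' Partitions the total matrix acetyl-CoA-producing flux of an optimal
#' solution by upstream fuel: beta-oxidation (fatty acid), ketolysis
#' (ketone bodies), and pyruvate dehydrogenase flux split over the sources of
#' the pyruvate it consumed. FBA carries no tracer information, so shared
#' pools (phosphoenolpyruvate, cytosolic and matrix pyruvate) are resolved by
#' proportional mixing: each pool passes its inflow source fractions on
#' pro rata, which is solved as a small linear system over the pool network
#' (glycolytic triose phosphates can carry both glucose- and glycerol-derived
#' carbon; matrix pyruvate mixes imported pyruvate with alanine- and
#' malic-enzyme-derived pyruvate, the latter attributed to amino acid
#' degradation).
#'
#' @param flux_result an optimal `mf_flux_result`.
#' @param model the model the result was computed on.
#' @return an `acetyl_coa_attribution`: named fractions over
#'   `fatty_acid`, `glucose`, `lactate`, `ketone`, `amino_acid`, `glycerol`
#'   (summing to 1 when total production is positive) with attribute
#'   `total_flux`.
#' @export
attribute_acetyl_coa <- function(flux_result, model) {
  if (flux_result$status != "optimal")
    stop("attribution requires an optimal flux result")
  v <- flux_result$fluxes
  sources <- c("fatty_acid", "glucose", "lactate", "ketone", "amino_acid", "glycerol")
  unit <- function(nm) stats::setNames(as.numeric(sources == nm), sources)
  pools <- c("dhap_c", "g3p_c", "pep_c", "pyr_c", "pyr_m")
  # inflows per pool: list of (weight, source tag or upstream pool)
  inflow <- function(rid, coef = 1) {
    w <- if (rid %in% names(v)) v[[rid]] * coef else 0
    max(w, 0)
  }
  flows <- list(
    dhap_c = list(list(w = inflow("FBA"), from = "glucose"),
                  list(w = inflow("G3PQOm_MitoCore"), from = "glycerol"),
                  list(w = inflow("TPI", -1), from = "g3p_c")),
    g3p_c = list(list(w = inflow("FBA"), from = "glucose"),
                 list(w = inflow("TPI"), from = "dhap_c")),
    pep_c = list(list(w = inflow("ENO"), from = "g3p_c"),
                 list(w = inflow("PEPtm_MitoCore"), from = "amino_acid")),
    pyr_c = list(list(w = inflow("PYK"), from = "pep_c"),
                 list(w = inflow("LDH_L", -1), from = "lactate"),
                 list(w = inflow("PYRt2m_B_MitoCore"), from = "pyr_m"),
                 list(w = inflow("EX_pyr", -1), from = "lactate")),
    pyr_m = list(list(w = inflow("PYRt2m_F_MitoCore"), from = "pyr_c"),
                 list(w = inflow("ALATA_m"), from = "amino_acid"),
                 list(w = inflow("ME2m"), from = "amino_acid")))
  # fractions f[pool,] = sum_i w_i * f(from_i) / sum_i w_i; linear in f
  np <- length(pools)
  A <- diag(np)
  B <- matrix(0, np, length(sources), dimnames = list(pools, sources))
  for (pi in seq_len(np)) {
    fl <- flows[[pools[pi]]]
    tot <- sum(vapply(fl, `[[`, 0, "w"))
    if (tot <= 1e-12) next
    for (f in fl) {
      if (f$w <= 0) next
      if (f$from %in% pools) A[pi, match(f$from, pools)] <-
          A[pi, match(f$from, pools)] - f$w / tot
      else B[pi, ] <- B[pi, ] + (f$w / tot) * unit(f$from)
    }
  }
  fr <- tryCatch(solve(A, B), error = function(e) {
    # a pure exchange cycle (e.g. pyruvate shuttled in and straight back out)
    # makes the mixing system singular; break it by dropping the backflow
    flows$pyr_c[[3]]$w <- 0
    A2 <- diag(np)
    B2 <- B * 0
    for (pi in seq_len(np)) {
      fl <- flows[[pools[pi]]]
      tot <- sum(vapply(fl, `[[`, 0, "w"))
      if (tot <= 1e-12) next
      for (f in fl) {
        if (f$w <= 0) next
        if (f$from %in% pools) A2[pi, match(f$from, pools)] <-
            A2[pi, match(f$from, pools)] - f$w / tot
        else B2[pi, ] <- B2[pi, ] + (f$w / tot) * unit(f$from)
      }
    }
    solve(A2, B2)
  })
  rownames(fr) <- pools
  producers <- list(
    list(rid = "FAOXC160_MitoCore", coef = 8, src = unit("fatty_acid")),
    list(rid = "ACATm", coef = 2, src = unit("ketone")),
    list(rid = "PDHm", coef = 1, src = fr["pyr_m", ]))
  total <- 0
  acc <- stats::setNames(rep(0, length(sources)), sources)
  for (p in producers) {
    w <- inflow(p$rid, 1) * p$coef
    if (w <= 0) next
    total <- total + w
    acc <- acc + w * p$src
  }
  fractions <- if (total > 1e-12) acc / total else acc * 0
  structure(fractions, total_flux = total, class = "acetyl_coa_attribution")
}

#' @export
print.acetyl_coa_attribution <- function(x, ...) {
  tot <- attr(x, "total_flux")
  cat("acetyl-CoA production: ", format(tot, digits = 6), " umol/min/gDW\n", sep = "")
  if (tot > 0) {
    f <- sort(unclass(x), decreasing = TRUE)
    for (nm in names(f)) cat(sprintf("  %-11s %5.1f%%\n", nm, 100 * f[[nm]]))
  }
  invisible(x)
}
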