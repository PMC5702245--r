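#' Bioenergetic parameters of the proton-motive-force bookkeeping
#'
#' The PMF is represented as a pseudo-metabolite. Its two physical components
#' are weighted by their relative contribution to the total gradient: a
#' transport step that moves net charge across the inner membrane (affecting
#' the membrane potential) carries 0.82 PMF per elementary charge, a step that
#' moves a proton electroneutrally (affecting only the pH gradient) carries
#' 0.18 PMF per proton; a pumped (vectorial) proton affects both and carries
#' 1.0. The respiratory complexes pump 10 PMF per matrix NADH and 6 per
#' ubiquinol, split 4/2/4 over complexes I/III/IV by default (an alternative
#' 4/4/2 split can be selected; only the totals affect ATP yields). The ATP
#' synthase consumes 2.7 PMF per ATP, and a fraction 1e-5 of complex-I flux
#' (0.001%) is diverted to superoxide.
#'
#' @param delta_psi_fraction,delta_ph_fraction relative contributions of the
#'   membrane potential and the pH gradient; must sum to 1.
#' @param protons_per_atp protons (PMF) consumed per ATP at the synthase.
#' @param ros_fraction superoxide produced per unit complex-I flux.
#' @param pmf_per_nadh,pmf_per_qh2 total PMF translocated per 2 electrons
#'   entering at complex I / at the quinone pool.
#' @param complex_split named vector `c(CI=, CIII=, CIV=)`; `CI+CIII+CIV` must
#'   equal `pmf_per_nadh` and `CIII+CIV` must equal `pmf_per_qh2`.
#' @return an object of class `pmf_parameters`.
#' @export
pmf_parameters <- function(delta_psi_fraction = 0.82, delta_ph_fraction = 0.18,
                           protons_per_atp = 2.7, ros_fraction = 1e-5,
                           pmf_per_nadh = 10, pmf_per_qh2 = 6,
                           complex_split = c(CI = 4, CIII = 2, CIV = 4)) {
  if (abs(delta_psi_fraction + delta_ph_fraction - 1) > 1e-12)
    stop("delta_psi_fraction + delta_ph_fraction must equal 1")
  if (!all(c("CI", "CIII", "CIV") %in% names(complex_split)))
    stop("complex_split needs entries CI, CIII, CIV")
  if (abs(sum(complex_split[c("CI", "CIII", "CIV")]) - pmf_per_nadh) > 1e-12)
    stop("complex_split CI+CIII+CIV must equal pmf_per_nadh")
  if (abs(sum(complex_split[c("CIII", "CIV")]) - pmf_per_qh2) > 1e-12)
    stop("complex_split CIII+CIV must equal pmf_per_qh2")
  if (ros_fraction < 0 || ros_fraction >= 1) stop("ros_fraction must be in [0, 1)")
  if (protons_per_atp <= 0) stop("protons_per_atp must be positive")
  structure(list(delta_psi_fraction = delta_psi_fraction,
                 delta_ph_fraction = delta_ph_fraction,
                 protons_per_atp = protons_per_atp,
                 ros_fraction = ros_fraction,
                 pmf_per_nadh = pmf_per_nadh, pmf_per_qh2 = pmf_per_qh2,
                 complex_split = complex_split),
            class = "pmf_parameters")
}

#' PMF stoichiometric coefficient of a transport step
#'
#' `0.82 * |net charge| + 0.18 * electroneutral protons` per transport cycle.
#' A full vectorial proton (charge 1 and one pH unit) gives 1.0.
#'
#' @param net_charge_translocated net elementary charges moved into the matrix
#'   per cycle.
#' @param electroneutral_protons electroneutrally co-moved protons per cycle
#'   (non-negative).
#' @param params a [pmf_parameters()] object.
#' @return the PMF coefficient (non-negative real).
#' @examples
#' pmf_coefficient(1, 0)  # ATP4-/ADP3- exchange: 0.82
#' pmf_coefficient(0, 1)  # electroneutral phosphate/H+ symport: 0.18
#' pmf_coefficient(1, 1)  # pumped proton: 1.0
#' @export
pmf_coefficient <- function(net_charge_translocated, electroneutral_protons,
                            params = pmf_parameters()) {
  if (electroneutral_protons < 0)
    stop("electroneutral_protons must be non-negative")
  params$delta_psi_fraction * abs(net_charge_translocated) +
    params$delta_ph_fraction * electroneutral_protons
}

#' Construct a mitochondrial transport step
#'
#' Builds the reaction(s) for one of the four transport categories:
#' \describe{
#'   \item{CARRIER}{characterised transporter; counter-exchange and proton
#'     coupling modelled explicitly.}
#'   \item{UNIPORT_UNKNOWN}{transporter unidentified; uniport. A charged
#'     species moving inward co-transports PMF for the charge it moves.}
#'   \item{DIFFUSION}{free reversible uniport (O2, CO2, H2O, ...); no PMF.}
#'   \item{FLIPPASE}{ATP-hydrolysis-coupled lipid insertion into the inner
#'     membrane.}
#' }
#' The PMF coefficient is computed with [pmf_coefficient()] from the declared
#' net charge moved into the matrix and electroneutral proton count, and is
#' attached antisymmetrically (`-k pmf_c`, `+k pmf_m`): transport dissipates
#' the gradient in the written direction, it never creates it (a negative
#' `net_charge` -- uncompensated anion entry -- would have to create PMF and is
#' rejected; such carriers are modelled proton-compensated instead). With
#' `split_pair = TRUE` a proton-coupled carrier is emitted as two irreversible
#' reactions, with the proton/PMF cost only on the written (downhill)
#' direction, so the pair cannot pump PMF when run in reverse.
#'
#' @param id reaction id (pair ids get `_F`/`_B` inserted before any
#'   `_MitoCore` suffix).
#' @param category transport category.
#' @param import,export base metabolite names (no compartment suffix) moved
#'   cytosol to matrix / matrix to cytosol; named numeric vectors give
#'   non-unit coefficients.
#' @param net_charge net elementary charge moved into the matrix per cycle.
#' @param protons electroneutral protons co-moved into the matrix per cycle.
#' @param reversible default: reversible iff no PMF is moved.
#' @param split_pair emit forward/backward irreversible pair (PMF-coupled
#'   carriers only).
#' @param couple_atp hydrolyse one cytosolic ATP per cycle (mandatory for
#'   FLIPPASE).
#' @param genes,subsystem,... passed to [reaction()].
#' @param params a [pmf_parameters()] object.
#' @return an `mf_reaction`, or a list of two for `split_pair = TRUE`.
#' @export
make_transport_step <- function(id,
                                category = c("CARRIER", "UNIPORT_UNKNOWN",
                                             "DIFFUSION", "FLIPPASE"),
                                import = character(), export = character(),
                                net_charge = 0, protons = 0,
                                reversible = NULL, split_pair = FALSE,
                                couple_atp = FALSE,
                                genes = character(), subsystem = "Mitochondrial transport",
                                params = pmf_parameters(), ...) {
  category <- match.arg(category)
  as_coef <- function(x) {
    if (is.null(names(x))) stats::setNames(rep(1, length(x)), x) else x
  }
  import <- as_coef(import); export <- as_coef(export)
  if (net_charge < 0)
    stop(sprintf("transport step '%s': net anion entry would create PMF; %s",
                 id, "model it proton-compensated (net_charge 0, protons > 0)"))
  k <- pmf_coefficient(net_charge, protons, params)
  if (category == "DIFFUSION" && k != 0)
    stop(sprintf("transport step '%s': DIFFUSION steps cannot move PMF", id))
  if (category == "FLIPPASE" && !couple_atp)
    stop(sprintf("transport step '%s': a flippase must hydrolyse ATP", id))
  if (is.null(reversible)) reversible <- k == 0 && !couple_atp
  stoich_of <- function(imp, exp, pmf) {
    s <- numeric(0)
    add <- function(s, ids, sfx, val) {
      for (i in seq_along(ids)) {
        key <- paste0(names(ids)[i], sfx)
        s[key] <- (if (key %in% names(s)) s[[key]] else 0) + val * ids[[i]]
      }
      s
    }
    s <- add(s, imp, "_c", -1)
    s <- add(s, imp, "_m", +1)
    s <- add(s, exp, "_m", -1)
    s <- add(s, exp, "_c", +1)
    if (pmf > 0) {
      s["pmf_c"] <- (if ("pmf_c" %in% names(s)) s[["pmf_c"]] else 0) - pmf
      s["pmf_m"] <- (if ("pmf_m" %in% names(s)) s[["pmf_m"]] else 0) + pmf
    }
    if (couple_atp) {
      s["atp_c"] <-(if ("atp_c" %in% names(s)) s[["atp_c"]] else 0) - 1
      s["h2o_c"] <- (if ("h2o_c" %in% names(s)) s[["h2o_c"]] else 0) - 1
      s["adp_c"] <- (if ("adp_c" %in% names(s)) s[["adp_c"]] else 0) + 1
      s["pi_c"] <- (if ("pi_c" %in% names(s)) s[["pi_c"]] else 0) + 1
    }
    s
  }
  mk <- function(rid, s, lo, hi) {
    reaction(rid, s, lower = lo, upper = hi, genes = genes,
             subsystem = subsystem, category = "mito_transport",
             transport_category = category, ...)
  }
  if (split_pair) {
    if (k <= 0)
      stop(sprintf("transport step '%s': split_pair is for PMF-coupled carriers", id))
    pair_id <- function(tag) {
      if (grepl("_MitoCore$", id)) sub("_MitoCore$", paste0(tag, "_MitoCore"), id)
      else paste0(id, tag)
    }
    fwd <- mk(pair_id("_F"), stoich_of(import, export, k), 0, 1000)
    bwd <- mk(pair_id("_B"), stoich_of(export, import, 0), 0, 1000)
    return(list(forward = fwd, backward = bwd))
  }
  mk(id, stoich_of(import, export, k), if (reversible) -1000 else 0, 1000)
}

#' Construct the respiratory chain and ROS-handling reactions
#'
#' Complex I oxidises matrix NADH, reduces ubiquinone and pumps
#' `complex_split["CI"]` PMF per unit flux, with a fraction `ros_fraction` of
#' its flux diverted to superoxide (which proportionally reduces quinone
#' reduction and proton pumping). Complex II and the ETF:ubiquinone
#' oxidoreductase reduce the quinone pool directly -- the flavin prosthetic
#' groups of these enzymes are bound cofactors, so no free FAD/FADH species
#' exists anywhere in the model and their flux equals the quinone reduction
#' they drive. Complexes III/IV transfer electrons via cytochrome c to oxygen,
#' pumping `complex_split["CIII"]`/`complex_split["CIV"]` PMF. The ATP synthase
#' consumes `protons_per_atp` PMF per matrix ATP (reversible: under extreme
#' proton leak it runs backwards, hydrolysing matrix ATP to restore the
#' gradient). Superoxide is dismuted and the peroxide reduced at the expense
#' of matrix NADPH.
#'
#' @param params a [pmf_parameters()] object.
#' @return named list of `mf_reaction`s.
#' @export
make_respiratory_chain <- function(params = pmf_parameters()) {
  ros <- params$ros_fraction
  sp <- params$complex_split
  oxphos <- "Oxidative phosphorylation"
  list(
    complex_I = reaction("CPLX1_MitoCore",
      c(nadh_m = -1, q10_m = -(1 - ros), o2_m = -ros, pmf_m = -sp[["CI"]] * (1 - ros),
        nad_m = 1, q10h2_m = 1 - ros, o2s_m = ros, pmf_c = sp[["CI"]] * (1 - ros)),
      lower = 0, genes = c("NDUFS1|ENSG00000023228", "NDUFV1|ENSG00000167792"),
      subsystem = oxphos,
      directionality_evidence = "irreversible; proton pumping against the gradient"),
    complex_II = reaction("CPLX2",
      c(succ_m = -1, q10_m = -1, fum_m = 1, q10h2_m = 1),
      lower = 0, genes = c("SDHA|ENSG00000073578", "SDHB|ENSG00000117118"),
      subsystem = oxphos,
      directionality_evidence = "prosthetic FAD bound; quinone reduced directly"),
    etf_qo = reaction("ETFQO_MitoCore",
      c(etfrd_m = -1, q10_m = -1, etfox_m = 1, q10h2_m = 1),
      lower = 0, genes = c("ETFDH|ENSG00000171503"), subsystem = oxphos,
      directionality_evidence = "prosthetic FAD bound; quinone reduced directly"),
    complex_III = reaction("CPLX3_MitoCore",
      c(q10h2_m = -1, ficytc_m = -2, pmf_m = -sp[["CIII"]],
        q10_m = 1, focytc_m = 2, pmf_c = sp[["CIII"]]),
      lower = 0, genes = c("UQCRC1|ENSG00000010256"), subsystem = oxphos),
    complex_IV = reaction("CPLX4_MitoCore",
      c(focytc_m = -2, o2_m = -0.5, pmf_m = -sp[["CIV"]],
        ficytc_m = 2, h2o_m = 1, pmf_c = sp[["CIV"]]),
      lower = 0, genes = c("MT-CO1|ENSG00000198804"), subsystem = oxphos),
    atp_synthase = reaction("ATPS_MitoCore",
      c(adp_m = -1, pi_m = -1, pmf_c = -params$protons_per_atp,
        atp_m = 1, h2o_m = 1, pmf_m = params$protons_per_atp),
      lower = -1000, genes = c("ATP5F1A|ENSG00000152234"), subsystem = oxphos,
      directionality_evidence = "reversible: hydrolyses ATP to sustain PMF under leak"),
    sod = reaction("SOD2m",
      c(o2s_m = -2, o2_m = 1, h2o2_m = 1),
      lower = 0, genes = c("SOD2|ENSG00000112096"), subsystem = "ROS detoxification"),
    peroxidase = reaction("GPXm_MitoCore",
      c(h2o2_m = -1, nadph_m = -1, nadp_m = 1, h2o_m = 2),
      lower = 0, genes = c("GPX1|ENSG00000233276"), subsystem = "ROS detoxification",
      directionality_evidence = "lumped glutathione peroxidase + reductase")
  )
}

#' Construct the four pseudo objective reactions
#'
#' Sink-style summaries of cellular demand usable as FBA objectives: ATP
#' hydrolysis (cellular ATP demand), heme biosynthesis (succinyl-CoA +
#' glycine via 5-aminolevulinate), inner-membrane lipid provision, and amino
#' acid biosynthesis (reductive amination of 2-oxoglutarate). Pseudo reactions
#' are exempt from balance checks.
#'
#' @return named list of four `mf_reaction`s.
#' @export
make_pseudo_reactions <- function() {
  list(
    atp_hydrolysis = reaction("OF_ATP_MitoCore",
      c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
      lower = 0, category = "pseudo", subsystem = "Objective",
      directionality_evidence = "cellular ATP demand"),
    heme = reaction("OF_HEME_MitoCore",
      c(succoa_m = -8, gly_m = -8, coa_m = 8),
      lower = 0, category = "pseudo", subsystem = "Objective"),
    lipid = reaction("OF_LIPID_MitoCore",
      c(hdca_m = -2, glyc3p_c = -1),
      lower = 0, category = "pseudo", subsystem = "Objective",
      directionality_evidence = "phosphatidate-style membrane lipid sink"),
    amino_acid = reaction("OF_AA_MitoCore",
      c(akg_m = -1, nh3_m = -1, nadph_m = -1, nadp_m = 1),
      lower = 0, category = "pseudo", subsystem = "Objective",
      directionality_evidence = "reductive amination of 2-oxoglutarate")
  )
}

# metabolite catalogue for the bundled reduced model -------------------------

reduced_metabolites <- function() {
  # base id | name | charge | formula (NA where a clean elemental balance is
  # not expressible without free protons) | compartments
  def <- list(
    list("glc",    "D-glucose",              0, "C6H12O6", "c"),
    list("g6p",    "glucose 6-phosphate",   -2, NA, "c"),
    list("f6p",    "fructose 6-phosphate",  -2, NA, "c"),
    list("fdp",    "fructose 1,6-bisphosphate", -4, NA, "c"),
    list("dhap",   "dihydroxyacetone phosphate", -2, NA, "c"),
    list("g3p",    "glyceraldehyde 3-phosphate", -2, NA, "c"),
    list("13dpg",  "1,3-bisphosphoglycerate", -4, NA, "c"),
    list("3pg",    "3-phosphoglycerate",    -3, NA, "c"),
    list("2pg",    "2-phosphoglycerate",    -3, NA, "c"),
    list("pep",    "phosphoenolpyruvate",   -3, NA, "cm"),
    list("pyr",    "pyruvate",              -1, "C3H3O3", "cm"),
    list("lac",    "(S)-lactate",           -1, "C3H5O3", "c"),
    list("glyc",   "glycerol",               0, "C3H8O3", "c"),
    list("glyc3p", "glycerol 3-phosphate",  -2, NA, "c"),
    list("cit",    "citrate",               -3, "C6H5O7", "m"),
    list("icit",   "isocitrate",            -3, "C6H5O7", "m"),
    list("akg",    "2-oxoglutarate",        -2, "C5H4O5", "cm"),
    list("succoa", "succinyl-CoA",          -5, NA, "m"),
    list("succ",   "succinate",             -2, "C4H4O4", "m"),
    list("fum",    "fumarate",              -2, "C4H2O4", "cm"),
    list("mal",    "(S)-malate",            -2, "C4H4O5", "cm"),
    list("oaa",    "oxaloacetate",          -2, "C4H2O5", "cm"),
    list("accoa",  "acetyl-CoA",            -4, NA, "m"),
    list("aacoa",  "acetoacetyl-CoA",       -4, NA, "m"),
    list("coa",    "coenzyme A",            -4, NA, "cm"),
    list("bhb",    "(R)-3-hydroxybutanoate", -1, "C4H7O3", "cm"),
    list("acac",   "acetoacetate",          -1, "C4H5O3", "cm"),
    list("hdca",   "hexadecanoate",         -1, "C16H31O2", "cm"),
    list("pmtcoa", "palmitoyl-CoA",         -4, NA, "cm"),
    list("crn",    "L-carnitine",            0, NA, "cm"),
    list("pmtcrn", "palmitoyl-carnitine",    0, NA, "cm"),
    list("ala",    "L-alanine",              0, "C3H7NO2", "cm"),
    list("asp",    "L-aspartate",           -1, "C4H6NO4", "cm"),
    list("glu",    "L-glutamate",           -1, "C5H8NO4", "cm"),
    list("gln",    "L-glutamine",            0, "C5H10N2O3", "cm"),
    list("gly",    "glycine",                0, "C2H5NO2", "cm"),
    list("nh3",    "ammonia",                0, "H3N", "cm"),
    list("nad",    "NAD+",                  -1, NA, "cm"),
    list("nadh",   "NADH",                  -2, NA, "cm"),
    list("nadp",   "NADP+",                 -3, NA, "m"),
    list("nadph",  "NADPH",                 -4, NA, "m"),
    list("atp",    "ATP",                   -4, NA, "cm"),
    list("adp",    "ADP",                   -3, NA, "cm"),
    list("amp",    "AMP",                   -2, NA, "c"),
    list("gtp",    "GTP",                   -4, NA, "m"),
    list("gdp",    "GDP",                   -3, NA, "m"),
    list("pi",     "orthophosphate",        -2, NA, "cm"),
    list("ppi",    "pyrophosphate",         -3, NA, "c"),
    list("q10",    "ubiquinone",             0, NA, "m"),
    list("q10h2",  "ubiquinol",              0, NA, "m"),
    list("etfox",  "ETF (oxidised)",         0, NA, "m"),
    list("etfrd",  "ETF (reduced)",          0, NA, "m"),
    list("ficytc", "ferricytochrome c",      3, NA, "m"),
    list("focytc", "ferrocytochrome c",      2, NA, "m"),
    list("o2s",    "superoxide",            -1, NA, "m"),
    list("h2o2",   "hydrogen peroxide",      0, "H2O2", "m"),
    list("o2",     "oxygen",                 0, "O2", "cm"),
    list("co2",    "carbon dioxide",         0, "CO2", "cm"),
    list("h2o",    "water",                  0, "H2O", "cm"),
    list("pmf",    "proton motive force",    0, NA, "cm")
  )
  rows <- list()
  for (d in def) {
    for (cm in strsplit(d[[5]], "")[[1]]) {
      comp <- if (cm == "c") "cytosolic" else "mitochondrial"
      rows[[length(rows) + 1L]] <-
        metabolite(paste0(d[[1]], "_", cm), d[[2]], comp, charge = d[[3]],
                   formula = d[[4]], is_pmf = d[[1]] == "pmf")
    }
  }
  do.call(rbind, rows)
}

# static (non-transport, non-chain) reactions of the bundled model
reduced_core_reactions <- function() {
  rev <- function(id, eq, genes = "", sub = "", dir = "")
    list(id = id, eq = eq, lo = -1000, hi = 1000, genes = genes, sub = sub, dir = dir)
  irr <- function(id, eq, genes = "", sub = "", dir = "")
    list(id = id, eq = eq, lo = 0, hi = 1000, genes = genes, sub = sub, dir = dir)
  gly <- "Glycolysis"; tca <- "TCA cycle"; aam <- "Amino acid metabolism"
  ket <- "Ketone body degradation"; fao <- "Fatty acid oxidation"
  rows <- list(
    irr("HEX1",  "glc_c + atp_c -> g6p_c + adp_c", "HK1|ENSG00000156515", gly,
        "large negative delta G; irreversible"),
    rev("PGI",   "g6p_c <=> f6p_c", "GPI|ENSG00000105220", gly),
    irr("PFK",   "f6p_c + atp_c -> fdp_c + adp_c", "PFKM|ENSG00000152556", gly,
        "large negative delta G; irreversible"),
    rev("FBA",   "fdp_c <=> dhap_c + g3p_c", "ALDOA|ENSG00000149925", gly),
    rev("TPI",   "dhap_c <=> g3p_c", "TPI1|ENSG00000111669", gly),
    rev("GAPD",  "g3p_c + nad_c + pi_c <=> 13dpg_c + nadh_c",
        "GAPDH|ENSG00000111640", gly),
    rev("PGK",   "13dpg_c + adp_c <=> 3pg_c + atp_c", "PGK1|ENSG00000102144", gly),
    rev("PGM",   "3pg_c <=> 2pg_c", "PGAM2|ENSG00000164708", gly),
    rev("ENO",   "2pg_c <=> pep_c + h2o_c", "ENO3|ENSG00000108515", gly),
    irr("PYK",   "pep_c + adp_c -> pyr_c + atp_c", "PKM|ENSG00000067225", gly,
        "large negative delta G; irreversible"),
    rev("LDH_L", "pyr_c + nadh_c <=> lac_c + nad_c", "LDHA|ENSG00000134333",
        "Lactate metabolism"),
    irr("GLYK",  "glyc_c + atp_c -> glyc3p_c + adp_c", "GK|ENSG00000198814",
        "Glycerol metabolism"),
    rev("MDH1",  "oaa_c + nadh_c <=> mal_c + nad_c", "MDH1|ENSG00000014641",
        "Malate-aspartate shuttle"),
    rev("GOT1",  "asp_c + akg_c <=> oaa_c + glu_c", "GOT1|ENSG00000120053",
        "Malate-aspartate shuttle"),
    rev("FUM_C", "fum_c + h2o_c <=> mal_c", "FH|ENSG00000091483",
        "TCA cycle (cytosolic isoform)"),
    irr("FACOAL160", "hdca_c + atp_c + coa_c -> pmtcoa_c + amp_c + ppi_c",
        "ACSL1|ENSG00000151726", fao, "pyrophosphate hydrolysis pulls activation"),
    irr("PPA",   "ppi_c + h2o_c -> 2 pi_c", "PPA1|ENSG00000180817", fao),
    rev("AK1",   "amp_c + atp_c <=> 2 adp_c", "AK1|ENSG00000106263",
        "Nucleotide interconversion"),
    irr("CPT1",  "pmtcoa_c + crn_c -> pmtcrn_c + coa_c", "CPT1B|ENSG00000205560",
        "Carnitine shuttle"),
    irr("CPT2",  "pmtcrn_m + coa_m -> pmtcoa_m + crn_m", "CPT2|ENSG00000157184",
        "Carnitine shuttle"),
    irr("FAOXC160_MitoCore",
        "pmtcoa_m + 7 coa_m + 7 nad_m + 7 etfox_m + 7 h2o_m -> 8 accoa_m + 7 nadh_m + 7 etfrd_m",
        "ACADVL|ENSG00000072778;HADHA|ENSG00000084754", fao,
        "lumped beta-oxidation spiral; electrons to ETF, not free FAD"),
    irr("PDHm",  "pyr_m + coa_m + nad_m -> accoa_m + co2_m + nadh_m",
        "PDHA1|ENSG00000131828;DLAT|ENSG00000150768", tca,
        "complex modelled as one reaction"),
    irr("CSm",   "accoa_m + oaa_m + h2o_m -> cit_m + coa_m",
        "CS|ENSG00000062485", tca, "large negative delta G"),
    rev("ACONTm", "cit_m <=> icit_m", "ACO2|ENSG00000100412", tca),
    irr("ICDHxm", "icit_m + nad_m -> akg_m + co2_m + nadh_m",
        "IDH3A|ENSG00000166411", tca),
    irr("ICDHym_MitoCore", "icit_m + nadp_m -> akg_m + co2_m + nadph_m",
        "IDH2|ENSG00000182054", tca,
        "kept irreversible to prevent NADH/NADPH interconversion"),
    irr("AKGDm", "akg_m + coa_m + nad_m -> succoa_m + co2_m + nadh_m",
        "OGDH|ENSG00000105953;DLST|ENSG00000119689", tca,
        "complex modelled as one reaction"),
    rev("SUCOAS1m", "succoa_m + gdp_m + pi_m <=> succ_m + gtp_m + coa_m",
        "SUCLG1|ENSG00000163541", tca),
    rev("NDPK6m", "gtp_m + adp_m <=> gdp_m + atp_m", "NME4|ENSG00000103024",
        "Nucleotide interconversion"),
    rev("FUMm",  "fum_m + h2o_m <=> mal_m", "FH|ENSG00000091483", tca),
    rev("MDHm",  "mal_m + nad_m <=> oaa_m + nadh_m", "MDH2|ENSG00000146701", tca),
    rev("GOT2m", "asp_m + akg_m <=> oaa_m + glu_m", "GOT2|ENSG00000125166",
        "Malate-aspartate shuttle"),
    irr("PCm",   "pyr_m + co2_m + atp_m + h2o_m -> oaa_m + adp_m + pi_m",
        "PC|ENSG00000173599", "Anaplerosis"),
    irr("PEPCKm", "oaa_m + gtp_m -> pep_m + co2_m + gdp_m",
        "PCK2|ENSG00000100889", "Anaplerosis/cataplerosis"),
    irr("ME2m",  "mal_m + nad_m -> pyr_m + co2_m + nadh_m",
        "ME2|ENSG00000082212", "Anaplerosis/cataplerosis"),
    irr("GDHm",  "glu_m + nad_m + h2o_m -> akg_m + nh3_m + nadh_m",
        "GLUD1|ENSG00000148672", aam,
        "deamination direction; ammonia effluxed"),
    irr("GLSm",  "gln_m + h2o_m -> glu_m + nh3_m", "GLS|ENSG00000115419", aam),
    rev("ALATA_m", "ala_m + akg_m <=> pyr_m + glu_m", "GPT2|ENSG00000166123", aam),
    rev("BDHm",  "bhb_m + nad_m <=> acac_m + nadh_m", "BDH1|ENSG00000161267", ket),
    irr("SCOTm", "acac_m + succoa_m -> aacoa_m + succ_m", "OXCT1|ENSG00000083720",
        ket, "succinyl-CoA transfer; forfeits one substrate-level GTP"),
    irr("ACATm", "aacoa_m + coa_m -> 2 accoa_m", "ACAT1|ENSG00000075239", ket)
  )
  lapply(rows, function(r) {
    s <- parse_equation(r$eq)
    reaction(r$id, unclass(c(s)), lower = r$lo, upper = r$hi,
             genes = if (nzchar(r$genes)) strsplit(r$genes, ";")[[1]] else character(),
             subsystem = r$sub, category = "metabolic",
             directionality_evidence = r$dir,
             heart_expression = "expressed in heart (curated set)")
  })
}

reduced_transport_reactions <- function(params) {
  steps <- list()
  add <- function(x) {
    if (inherits(x, "mf_reaction")) steps[[length(steps) + 1L]] <<- x
    else for (r in x) steps[[length(steps) + 1L]] <<- r
  }
  # pyruvate carrier: H+ symport split into irreversible forward/backward
  add(make_transport_step("PYRt2m_MitoCore", "CARRIER", import = "pyr",
        net_charge = 0, protons = 1, split_pair = TRUE,
        genes = c("MPC1|ENSG00000060762"), params = params))
  # adenine nucleotide translocase: electrogenic, reversible
  add(make_transport_step("ATPADPtm_MitoCore", "CARRIER",
        import = "adp", export = "atp", net_charge = 1, protons = 0,
        reversible = TRUE, genes = c("SLC25A4|ENSG00000151729"), params = params))
  # phosphate carrier: electroneutral H+ symport, split so the reverse
  # direction (phosphate efflux) cannot pump protons from the Pi gradient
  add(make_transport_step("PItm_MitoCore", "CARRIER", import = "pi",
        net_charge = 0, protons = 1, split_pair = TRUE,
        genes = c("SLC25A3|ENSG00000075415"), params = params))
  # aspartate/glutamate carrier: glutamate enters with a proton, aspartate
  # leaves; net +1 charge into the matrix and one proton moved, so the full
  # 1.0 PMF is dissipated per cycle and the carrier is irreversible
  add(make_transport_step("ASPGLUm_MitoCore", "CARRIER",
        import = "glu", export = "asp", net_charge = 1, protons = 1,
        genes = c("SLC25A12|ENSG00000115840"), params = params))
  # oxoglutarate/malate and dicarboxylate carriers: electroneutral antiports
  add(make_transport_step("AKGMALtm", "CARRIER", import = "mal", export = "akg",
        genes = c("SLC25A11|ENSG00000108528"), params = params))
  add(make_transport_step("DICtm", "CARRIER", import = "pi", export = "mal",
        genes = c("SLC25A10|ENSG00000183048"), params = params))
  add(make_transport_step("FUMtm_MitoCore", "CARRIER", import = "pi", export = "fum",
        genes = c("SLC25A10|ENSG00000183048"), params = params))
  # glutamate carrier: H+ symport, inward only
  add(make_transport_step("GLUt2m_MitoCore", "CARRIER", import = "glu",
        net_charge = 0, protons = 1,
        genes = c("SLC25A22|ENSG00000177542"), params = params))
  # aspartate entry: proton-compensated carrier, inward only
  add(make_transport_step("ASPt2m_MitoCore", "CARRIER", import = "asp",
        net_charge = 0, protons = 1, params = params))
  # phosphoenolpyruvate export (citrate-carrier mediated, proton-compensated)
  add(make_transport_step("PEPtm_MitoCore", "CARRIER", import = "pi", export = "pep",
        reversible = FALSE, genes = c("SLC25A1|ENSG00000100075"), params = params))
  # carnitine/acylcarnitine translocase
  add(make_transport_step("CACT", "CARRIER", import = "pmtcrn", export = "crn",
        genes = c("SLC25A20|ENSG00000178537"), params = params))
  # neutral species with unidentified transporters: uniport
  add(make_transport_step("ALAtm", "UNIPORT_UNKNOWN", import = "ala", params = params))
  add(make_transport_step("GLNtm", "UNIPORT_UNKNOWN", import = "gln", params = params))
  add(make_transport_step("GLYtm", "UNIPORT_UNKNOWN", import = "gly", params = params))
  # diffusion: gases, water, ammonia, ketone bodies (as neutral acids)
  add(make_transport_step("O2tm", "DIFFUSION", import = "o2", params = params))
  add(make_transport_step("CO2tm", "DIFFUSION", import = "co2", params = params))
  add(make_transport_step("H2Otm", "DIFFUSION", import = "h2o", params = params))
  add(make_transport_step("NH3tm", "DIFFUSION", import = "nh3", params = params))
  add(make_transport_step("BHBtm_MitoCore", "DIFFUSION", import = "bhb", params = params))
  add(make_transport_step("ACACtm_MitoCore", "DIFFUSION", import = "acac", params = params))
  # inner-membrane lipid insertion via flippase
  add(make_transport_step("HDCAFLIPm_MitoCore", "FLIPPASE", import = "hdca",
        couple_atp = TRUE, params = params))
  # UCP2 proton leak: one vectorial proton re-enters the matrix
  add(make_transport_step("HtmB_MitoCore", "CARRIER",
        net_charge = 1, protons = 1, reversible = FALSE,
        genes = c("UCP2|ENSG00000175567"),
        subsystem = "Proton leak", params = params))
  steps
}

# the glycerol-phosphate shuttle is membrane-bound and spans compartments
g3p_shuttle_reaction <- function() {
  reaction("G3PQOm_MitoCore",
           c(glyc3p_c = -1, q10_m = -1, dhap_c = 1, q10h2_m = 1),
           lower = 0, genes = c("GPD2|ENSG00000115159"),
           subsystem = "Glycerophosphate shuttle", category = "mito_transport",
           transport_category = "CARRIER",
           directionality_evidence = "membrane-bound dehydrogenase faces the cytosol")
}

reduced_exchange_reactions <- function() {
  fuel <- c("glc", "lac", "pyr", "hdca", "bhb", "acac", "ala", "glu",
            "gln", "asp", "glyc", "fum")
  other <- c("gly", "o2", "co2", "h2o", "nh3", "pi")
  mk <- function(base, is_fuel) {
    reaction(paste0("EX_", base),
             stats::setNames(-1, paste0(base, "_c")),
             lower = 0, upper = 1000, category = "boundary_exchange",
             subsystem = if (is_fuel) "Exchange/fuel" else "Exchange",
             directionality_evidence = "uptake closed by default; set via config")
  }
  c(lapply(fuel, mk, is_fuel = TRUE), lapply(other, mk, is_fuel = FALSE))
}

#' Default cardiomyocyte uptake configuration
#'
#' Uptake bounds (umol/min/gDW, positive = maximal uptake) for the bundled
#' reduced model, emulating a well-perfused heart: a fatty-acid-dominant fuel
#' mix supplied in slight excess so that oxygen availability limits overall
#' flux. These values are approximate editable defaults chosen to reproduce
#' the physiological regime (most acetyl-CoA from beta-oxidation, the rest
#' from glucose, lactate, ketone bodies and amino acids); replace them with
#' measured uptakes for quantitative case studies.
#'
#' @return a named list with `uptakes` (named vector, by exchange reaction)
#'   and `o2` (maximal oxygen uptake).
#' @export
default_uptake_config <- function() {
  list(uptakes = c(EX_glc = 0.6, EX_lac = 0.4, EX_pyr = 0.1, EX_hdca = 0.45,
                   EX_bhb = 0.15, EX_acac = 0.05, EX_ala = 0.15, EX_glu = 0.1,
                   EX_gln = 0.1, EX_asp = 0.05, EX_glyc = 0.05, EX_gly = 0.05,
                   EX_fum = 0),
       o2 = 16)
}

#' Apply an uptake configuration to a model
#'
#' Sets the lower bound of each exchange to `-uptake` (exchanges are written
#' export-positive) and frees water, phosphate and carbon dioxide.
#'
#' @param model a `mito_model`.
#' @param config as from [default_uptake_config()].
#' @return the modified model.
#' @export
apply_uptake_config <- function(model, config = default_uptake_config()) {
  for (ex in names(config$uptakes))
    model <- set_bounds(model, ex, lower = -config$uptakes[[ex]])
  model <- set_bounds(model, "EX_o2", lower = -config$o2)
  for (ex in c("EX_h2o", "EX_pi", "EX_co2"))
    model <- set_bounds(model, ex, lower = -1000)
  model
}

#' Build the bundled reduced cardiomyocyte model
#'
#' Assembles the two-compartment network: glycolysis, pyruvate dehydrogenase,
#' TCA cycle, malate-aspartate and glycerophosphate shuttles, carnitine
#' shuttle with beta-oxidation of hexadecanoate, ketone-body degradation,
#' lactate oxidation, degradation routes for alanine, aspartate, glutamate and
#' glutamine (transaminases, glutamate dehydrogenase and the mitochondrial
#' PEPCK / NAD-malic-enzyme routes for four-carbon exit), the full respiratory
#' chain with ROS branch, the UCP2 proton leak (`HtmB_MitoCore`), boundary
#' exchanges, and the four pseudo objective reactions. All PMF coefficients
#' derive from [pmf_coefficient()] under `params`.
#'
#' @param params a [pmf_parameters()] object.
#' @param config uptake configuration applied to the returned model.
#' @param qc run the quality-control suite and fail on any finding.
#' @return a validated `mito_model` with objective `OF_ATP_MitoCore`.
#' @export
build_reduced_model <- function(params = pmf_parameters(),
                                config = default_uptake_config(), qc = FALSE) {
  rxns <- c(reduced_core_reactions(),
            reduced_transport_reactions(params),
            list(g3p_shuttle_reaction()),
            unname(make_respiratory_chain(params)),
            unname(make_pseudo_reactions()),
            reduced_exchange_reactions())
  free_fad <- grep("^fad", unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))),
                   value = TRUE)
  if (length(free_fad))
    stop("free FAD/FADH species are not allowed in the model: ",
         paste(free_fad, collapse = ", "))
  model <- model_network(reduced_metabolites(), rxns,
                         objective_id = "OF_ATP_MitoCore",
                         notes = "bundled reduced cardiomyocyte network")
  model <- apply_uptake_config(model, config)
  if (qc) {
    rep <- qc_report(model)
    if (!rep$passed) {
      stop("model failed quality control: ",
           paste(c(if (length(rep$blocked_reactions))
                     paste("blocked:", paste(rep$blocked_reactions, collapse = ",")),
                   if (length(rep$dead_end_metabolites))
                     paste("dead ends:", paste(rep$dead_end_metabolites, collapse = ",")),
                   if (rep$energy_cycle_atp > 1e-6)
                     sprintf("energy cycle ATP %.3g", rep$energy_cycle_atp)),
                 collapse = "; "))
    }
  }
  model
}
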