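test_that("pmf_coefficient weights charge and pH contributions", {
  expect_equal(pmf_coefficient(1, 0), 0.82)   # ATP4-/ADP3- exchange
  expect_equal(pmf_coefficient(0, 1), 0.18)   # electroneutral Pi/H+ symport
  expect_equal(pmf_coefficient(1, 1), 1.00)   # pumped vectorial proton
  expect_equal(pmf_coefficient(2, 0), 1.64)
  expect_error(pmf_coefficient(1, -1), "non-negative")
})

test_that("pmf_parameters enforces its internal consistency", {
  p <- pmf_parameters()
  expect_equal(p$delta_psi_fraction + p$delta_ph_fraction, 1)
  expect_equal(sum(p$complex_split), p$pmf_per_nadh)
  expect_equal(sum(p$complex_split[c("CIII", "CIV")]), p$pmf_per_qh2)
  expect_error(pmf_parameters(delta_psi_fraction = 0.8), "equal 1")
  expect_error(pmf_parameters(complex_split = c(CI = 5, CIII = 2, CIV = 4)),
               "pmf_per_nadh")
  # the alternative 4/4/2 split keeps both totals and is selectable
  expect_error(pmf_parameters(complex_split = c(CI = 4, CIII = 4, CIV = 2)), NA)
  # a split violating the quinol total is rejected
  expect_error(pmf_parameters(complex_split = c(CI = 3, CIII = 4, CIV = 3)),
               "pmf_per_qh2")
})

test_that("transport steps are built per category with correct PMF", {
  # CARRIER: the ATP/ADP exchange reproduces the electrogenic equation
  ant <- make_transport_step("ANT", "CARRIER", import = "adp", export = "atp",
                             net_charge = 1, protons = 0, reversible = TRUE)
  expect_equal(ant$stoichiometry[["atp_m"]], -1)
  expect_equal(ant$stoichiometry[["adp_c"]], -1)
  expect_equal(ant$stoichiometry[["pmf_c"]], -0.82)
  expect_equal(ant$stoichiometry[["atp_c"]], 1)
  expect_equal(ant$stoichiometry[["adp_m"]], 1)
  expect_equal(ant$stoichiometry[["pmf_m"]], 0.82)

  # DIFFUSION: reversible uniport, no PMF
  o2 <- make_transport_step("O2t", "DIFFUSION", import = "o2")
  expect_equal(sort(names(o2$stoichiometry)), c("o2_c", "o2_m"))
  expect_lt(o2$lower, 0)
  expect_error(make_transport_step("bad", "DIFFUSION", import = "x",
                                   net_charge = 1), "PMF")

  # UNIPORT_UNKNOWN, charged cation inward: 0.82 PMF co-transported
  k <- make_transport_step("Kt", "UNIPORT_UNKNOWN", import = "k",
                           net_charge = 1)
  expect_equal(k$stoichiometry[["pmf_c"]], -0.82)

  # uncompensated anion entry would create PMF and is rejected
  expect_error(make_transport_step("bad", "UNIPORT_UNKNOWN", import = "cl",
                                   net_charge = -1), "create PMF")

  # FLIPPASE requires ATP hydrolysis
  fl <- make_transport_step("FLIP", "FLIPPASE", import = "lipid",
                            couple_atp = TRUE)
  expect_equal(fl$stoichiometry[["atp_c"]], -1)
  expect_error(make_transport_step("FLIP2", "FLIPPASE", import = "lipid"),
               "ATP")
})

test_that("split proton-coupled pairs cannot pump PMF in reverse", {
  pair <- make_transport_step("XT", "CARRIER", import = "x", net_charge = 0,
                              protons = 1, split_pair = TRUE)
  fwd <- pair$forward
  bwd <- pair$backward
  expect_gte(fwd$lower, 0)
  expect_gte(bwd$lower, 0)
  expect_equal(fwd$stoichiometry[["pmf_c"]], -0.18)
  expect_false("pmf_c" %in% names(bwd$stoichiometry))
  expect_equal(bwd$stoichiometry[["x_m"]], -1)
  expect_equal(bwd$stoichiometry[["x_c"]], 1)
})

test_that("respiratory chain obeys the pumping stoichiometry and ROS branch", {
  p <- pmf_parameters()
  chain <- make_respiratory_chain(p)
  ros <- p$ros_fraction
  c1 <- chain$complex_I$stoichiometry
  expect_equal(c1[["pmf_c"]], 4 * (1 - ros))
  expect_equal(c1[["o2s_m"]], ros)
  expect_equal(c1[["q10h2_m"]], 1 - ros)
  expect_equal(chain$complex_III$stoichiometry[["pmf_c"]], 2)
  expect_equal(chain$complex_IV$stoichiometry[["pmf_c"]], 4)
  expect_equal(chain$atp_synthase$stoichiometry[["pmf_c"]], -2.7)
  # superoxide removal runs at the expense of NADPH
  expect_equal(chain$peroxidase$stoichiometry[["nadph_m"]], -1)
  # complex II is a single reaction coupling succinate to quinone directly
  c2 <- chain$complex_II$stoichiometry
  expect_equal(c2[["succ_m"]], -1)
  expect_equal(c2[["q10h2_m"]], 1)
  # no free FAD/FADH species anywhere
  all_species <- unlist(lapply(chain, function(r) names(r$stoichiometry)))
  expect_length(grep("^fad", all_species), 0)
})

test_that("four pseudo reactions exist and serve as objectives", {
  ps <- make_pseudo_reactions()
  expect_length(ps, 4)
  expect_true(all(vapply(ps, function(r) r$category == "pseudo", TRUE)))
  expect_equal(ps$atp_hydrolysis$stoichiometry,
               c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1))
  m <- bundled_for_tests()
  expect_equal(sum(m$rxns$category == "pseudo"), 4)
  # maximising ATP hydrolysis maximises cytosolic ATP regeneration demand
  r <- fba(m, "OF_ATP_MitoCore")
  expect_equal(r$status, "optimal")
  expect_gt(r$objective_value, 0)
})

test_that("oxphos micro-model exports 10(1-ros)/3.7 ATP per matrix NADH", {
  micro <- oxphos_micro_model(nadh_limit = 1)
  r <- fba(micro, "OF_ATP")
  expect_equal(r$status, "optimal")
  # hand arithmetic: the chain delivers 10*(1-ros) PMF per NADH (ROS removal
  # is free here, NADPH has its own source) and each exported ATP costs 3.7
  expected <- 10 * (1 - 1e-5) / 3.7
  expect_equal(r$objective_value, expected, tolerance = 1e-6 / expected)
})

test_that("bundled model embodies the builder conventions", {
  m <- bundled_for_tests()
  # no free FAD/FADH anywhere in the built model
  expect_length(grep("^fad", m$mets$id), 0)
  # the UCP2 proton leak step is present under its fixed id
  i <- match("HtmB_MitoCore", m$rxns$id)
  expect_false(is.na(i))
  expect_equal(m$stoich[[i]], c(pmf_c = -1, pmf_m = 1))
  # every PMF-moving transport coefficient is reproduced by pmf_coefficient
  # from mechanism counts (charge, protons)
  mech <- list(ATPADPtm_MitoCore = c(1, 0), ASPGLUm_MitoCore = c(1, 1),
               PItm_F_MitoCore = c(0, 1), PYRt2m_F_MitoCore = c(0, 1),
               GLUt2m_MitoCore = c(0, 1), ASPt2m_MitoCore = c(0, 1),
               HtmB_MitoCore = c(1, 1))
  for (id in names(mech)) {
    s <- m$stoich[[match(id, m$rxns$id)]]
    expect_equal(-s[["pmf_c"]], pmf_coefficient(mech[[id]][1], mech[[id]][2]),
                 label = id)
  }
  # transport categories are exclusive to mito_transport and all four occur
  tc <- m$rxns$transport_category
  expect_true(all(is.na(tc[m$rxns$category != "mito_transport"])))
  expect_setequal(unique(tc[m$rxns$category == "mito_transport"]),
                  c("CARRIER", "UNIPORT_UNKNOWN", "DIFFUSION", "FLIPPASE"))
})

test_that("builder runs its QC gate cleanly under default parameters", {
  expect_error(build_reduced_model(qc = TRUE), NA)
})
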