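test_that("stoichiometric matrix transcribes toy and empty models", {
  mets <- rbind(metabolite("a_c", "A", "cytosolic"),
                metabolite("b_c", "B", "cytosolic"))
  rxns <- list(reaction("R1", c(a_c = -1, b_c = 1), lower = 0),
               reaction("R2", c(b_c = -1), lower = 0,
                        category = "boundary_exchange"))
  m <- model_network(mets, rxns, objective_id = "R2")
  S <- as.matrix(assemble_stoichiometric_matrix(m))
  expect_identical(dim(S), c(2L, 2L))
  expect_equal(S["a_c", "R1"], -1)
  expect_equal(S["b_c", "R1"], 1)
  expect_equal(S["b_c", "R2"], -1)
  expect_equal(S["a_c", "R2"], 0)

  empty <- model_network(metabolite("x_c", "x", "cytosolic")[0, ],
                         list(), objective_id = "none", check = FALSE)
  S0 <- assemble_stoichiometric_matrix(empty)
  expect_identical(dim(S0), c(0L, 0L))
})

test_that("ATP/ADP carrier column carries the 0.82 PMF coefficients", {
  m <- bundled_for_tests()
  S <- assemble_stoichiometric_matrix(m)
  col <- S[, "ATPADPtm_MitoCore"]
  expect_equal(col[["atp_m"]], -1)
  expect_equal(col[["adp_c"]], -1)
  expect_equal(col[["pmf_c"]], -0.82)
  expect_equal(col[["atp_c"]], 1)
  expect_equal(col[["adp_m"]], 1)
  expect_equal(col[["pmf_m"]], 0.82)
})

test_that("matrix assembly is a bijection on the bundled model", {
  m <- bundled_for_tests()
  S <- assemble_stoichiometric_matrix(m)
  rebuilt <- mitoflux:::stoich_from_matrix(S)
  for (id in m$rxns$id) {
    orig <- m$stoich[[match(id, m$rxns$id)]]
    back <- rebuilt[[id]]
    expect_identical(sort(names(orig)), sort(names(back)), label = id)
    expect_identical(unname(orig[sort(names(orig))]),
                     unname(back[sort(names(back))]), label = id)
  }
})

test_that("unknown metabolite in a reaction is a structural error naming it", {
  mets <- metabolite("a_c", "A", "cytosolic")
  rxns <- list(reaction("BAD", c(a_c = -1, ghost_c = 1), lower = 0))
  expect_error(model_network(mets, rxns, objective_id = "BAD"),
               "BAD.*ghost_c")
})

test_that("model invariants reject malformed structures", {
  mets <- rbind(metabolite("a_c", "A", "cytosolic"),
                metabolite("b_m", "B", "mitochondrial"))
  # metabolic reaction spanning compartments
  expect_error(model_network(mets,
    list(reaction("X", c(a_c = -1, b_m = 1), lower = 0)),
    objective_id = "X"), "compartments")
  # boundary exchange touching matrix species
  expect_error(model_network(mets,
    list(reaction("EX", c(b_m = -1), lower = 0, category = "boundary_exchange")),
    objective_id = "EX"), "cytosolic")
  # id/suffix mismatch
  expect_error(metabolite("a_m", "A", "cytosolic"), "suffix|must end")
  # bounds out of order
  expect_error(reaction("R", c(a_c = -1), lower = 5, upper = 1), "bound")
})

test_that("transport reactions move PMF antisymmetrically across the bundle", {
  m <- bundled_for_tests()
  transports <- which(m$rxns$category == "mito_transport")
  expect_gt(length(transports), 15)
  for (i in transports) {
    s <- m$stoich[[i]]
    kc <- if ("pmf_c" %in% names(s)) s[["pmf_c"]] else 0
    km <- if ("pmf_m" %in% names(s)) s[["pmf_m"]] else 0
    expect_equal(kc + km, 0, label = m$rxns$id[i])
    # transport dissipates: pmf_c is consumed, never produced, in the
    # written direction
    expect_lte(kc, 0, label = m$rxns$id[i])
  }
})

test_that("balance reports exempt PMF and pseudo reactions and tally charge", {
  mets <- rbind(
    metabolite("h_c", "proton", "cytosolic", charge = 1, formula = "H"),
    metabolite("h_m", "proton", "mitochondrial", charge = 1, formula = "H"),
    metabolite("pi_c", "phosphate", "cytosolic", charge = -2),
    metabolite("pi_m", "phosphate", "mitochondrial", charge = -2),
    metabolite("pmf_c", "PMF", "cytosolic", is_pmf = TRUE),
    metabolite("pmf_m", "PMF", "mitochondrial", is_pmf = TRUE),
    metabolite("a_c", "A", "cytosolic", charge = -1),
    metabolite("b_c", "B", "cytosolic", charge = 0))
  # electroneutral phosphate/proton symport with explicit protons: balanced,
  # PMF coefficients excluded from the tally
  pic <- reaction("PIC", c(h_c = -1, pi_c = -1, pmf_c = -0.18,
                           h_m = 1, pi_m = 1, pmf_m = 0.18),
                  lower = 0, category = "mito_transport",
                  transport_category = "CARRIER")
  rep1 <- validate_balance(pic, mets)
  expect_equal(rep1$charge_delta, 0)
  expect_true("pmf" %in% rep1$exemptions)

  # A(-1) -> B(0): charge delta +1 reported
  rep2 <- validate_balance(reaction("AB", c(a_c = -1, b_c = 1), lower = 0), mets)
  expect_equal(rep2$charge_delta, 1)

  # pseudo reactions are exempt
  rep3 <- validate_balance(
    reaction("OF", c(a_c = -1), lower = 0, category = "pseudo"), mets)
  expect_true("pseudo" %in% rep3$exemptions)
  expect_true(is.na(rep3$charge_delta))

  # missing formulas are reported, never raised
  expect_named(rep2$element_deltas, NULL)
  expect_true(all(c("a_c", "b_c") %in% rep2$missing_formula))
})

test_that("elemental deltas are computed when formulas are complete", {
  mets <- rbind(
    metabolite("fum_c", "fumarate", "cytosolic", charge = -2, formula = "C4H2O4"),
    metabolite("h2o_c", "water", "cytosolic", charge = 0, formula = "H2O"),
    metabolite("mal_c", "malate", "cytosolic", charge = -2, formula = "C4H4O5"))
  ok <- validate_balance(
    reaction("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1)), mets)
  expect_length(ok$element_deltas, 0)
  bad <- validate_balance(
    reaction("BAD", c(fum_c = -1, mal_c = 1)), mets)
  expect_true("O" %in% names(bad$element_deltas))
})
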