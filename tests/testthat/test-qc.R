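test_that("bundled model passes the full QC suite", {
  m <- bundled_for_tests()
  rep <- qc_report(m)
  expect_true(rep$passed)
  expect_length(rep$blocked_reactions, 0)
  expect_length(rep$dead_end_metabolites, 0)
  expect_length(rep$balance_issues, 0)
  expect_equal(rep$energy_cycle_atp, 0, tolerance = 1e-6)
  # currency screening extends to PMF/NADH/NADPH sinks
  expect_true(all(abs(rep$energy_cycle_details) < 1e-6))
  js <- qc_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_true(parsed$passed)
})

test_that("an orphan reaction is flagged as blocked", {
  m <- bundled_for_tests()
  broken <- m
  broken$mets <- rbind(broken$mets,
                       metabolite("orphan_c", "orphan", "cytosolic"))
  broken$rxns <- rbind(broken$rxns, data.frame(
    id = "ORPHAN", lower = 0, upper = 1000, genes = "", subsystem = "",
    category = "metabolic", transport_category = NA_character_,
    directionality_evidence = "", localisation_evidence = "",
    heart_expression = "", stringsAsFactors = FALSE))
  broken$stoich <- c(broken$stoich,
                     list(ORPHAN = c(pyr_c = -1, orphan_c = 1)))
  blocked <- check_flux_capability(broken)
  expect_true("ORPHAN" %in% blocked)
  expect_false(qc_report(broken)$passed)
})

test_that("reversible loop members with no net requirement are not blocked", {
  # A <-> B via two reversible routes: flux can circulate through either
  mets <- rbind(metabolite("a_c", "A", "cytosolic"),
                metabolite("b_c", "B", "cytosolic"))
  m <- model_network(mets, list(
    reaction("EX_a", c(a_c = -1), lower = 0, upper = 0,
             category = "boundary_exchange"),
    reaction("R1", c(a_c = -1, b_c = 1)),
    reaction("R2", c(a_c = -1, b_c = 1))), objective_id = "R1")
  blocked <- check_flux_capability(m)
  expect_false("R1" %in% blocked)
  expect_false("R2" %in% blocked)
})

test_that("stripping PMF from the ANT plus a reversible leak creates a cycle", {
  m <- bundled_for_tests()
  broken <- m
  i <- match("ATPADPtm_MitoCore", broken$rxns$id)
  s <- broken$stoich[[i]]
  broken$stoich[[i]] <- s[setdiff(names(s), c("pmf_c", "pmf_m"))]
  # the historical artefact: a proton-coupled step runnable in reverse
  broken <- set_bounds(broken, "HtmB_MitoCore", lower = -1000)
  e <- check_energy_generating_cycles(broken)
  expect_gt(as.numeric(e), 1e-3)
  expect_false(qc_report(broken)$passed)
  # the intact model detects nothing
  expect_equal(as.numeric(check_energy_generating_cycles(m)), 0,
               tolerance = 1e-6)
})

test_that("closed-system PMF sink optimum is exactly zero on the bundle", {
  m <- bundled_for_tests()
  e <- check_energy_generating_cycles(m)
  expect_equal(unname(attr(e, "details")["pmf"]), 0, tolerance = 1e-6)
})

test_that("dead-end detection distinguishes produced-only species", {
  m <- bundled_for_tests()
  expect_length(check_dead_ends(m), 0)
  broken <- m
  broken$mets <- rbind(broken$mets, metabolite("x_c", "X", "cytosolic"))
  broken$rxns <- rbind(broken$rxns, data.frame(
    id = "MAKES_X", lower = 0, upper = 1000, genes = "", subsystem = "",
    category = "metabolic", transport_category = NA_character_,
    directionality_evidence = "", localisation_evidence = "",
    heart_expression = "", stringsAsFactors = FALSE))
  broken$stoich <- c(broken$stoich, list(MAKES_X = c(pyr_c = -1, x_c = 1)))
  expect_true("x_c" %in% check_dead_ends(broken))
  expect_false(qc_report(broken)$passed)
  # boundary-exchanged metabolites are not dead ends
  expect_false("glc_c" %in% check_dead_ends(m))
})
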