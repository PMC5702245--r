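printed_yields <- c(glc = 33.0, hdca = 111.8, lac = 15.5, bhb = 23.1,
                    acac = 20.2, ala = 16.0, glu = 23.8, asp = 16.0)

test_that("yield protocol reproduces the reference yields within 0.3", {
  m <- bundled_for_tests()
  for (f in names(printed_yields)) {
    y <- as.numeric(atp_yield(m, yield_protocol(f)))
    expect_lte(abs(y - printed_yields[[f]]), 0.3, label = f)
  }
})

test_that("yields agree with the independent proton-accounting oracle", {
  m <- bundled_for_tests()
  # pathway tallies per mole of fuel, counted by hand from the catalogue
  oracle <- c(
    # glucose: 2 ATP + 2 cytosolic NADH (glycolysis), 2 pyruvate imported
    # (0.18 each), each pyruvate worth 4 matrix NADH + 1 QH2 + 1 matrix GTP
    glc = yield_oracle(nadh_m = 8, nadh_c = 2, qh2 = 2, slp_matrix = 2,
                       atp_c = 2, transport_pmf = 2 * 0.18),
    # lactate: cytosolic oxidation to pyruvate, then as above
    lac = yield_oracle(nadh_m = 4, nadh_c = 1, qh2 = 1, slp_matrix = 1,
                       transport_pmf = 0.18),
    # hexadecanoate: activation costs 2 ATP; 7 beta-oxidation cycles give
    # 7 NADH + 7 QH2 (via ETF); 8 acetyl-CoA each 3 NADH + 1 QH2 + 1 GTP
    hdca = yield_oracle(nadh_m = 31, qh2 = 15, slp_matrix = 8, atp_c = -2),
    # 3-hydroxybutanoate: BDH NADH + 2 acetyl-CoA, one GTP forfeited to SCOT
    bhb = yield_oracle(nadh_m = 7, qh2 = 2, slp_matrix = 1),
    acac = yield_oracle(nadh_m = 6, qh2 = 2, slp_matrix = 1),
    # alanine: matrix transamination + GDH, pyruvate fully oxidised
    ala = yield_oracle(nadh_m = 5, qh2 = 1, slp_matrix = 1),
    # glutamate: GDH + 2-oxoglutarate -> malate -> oxaloacetate -> PEP ->
    # pyruvate -> full oxidation; PEP export is electroneutral, PEPCK
    # spends one of the two matrix GTPs, pyruvate kinase repays in cytosol
    glu = yield_oracle(nadh_m = 7, qh2 = 2, slp_matrix = 1, atp_c = 1,
                       transport_pmf = 2 * 0.18),
    asp = yield_oracle(nadh_m = 5, qh2 = 1, slp_matrix = 0, atp_c = 1,
                       transport_pmf = 2 * 0.18))
  for (f in names(oracle)) {
    y <- as.numeric(atp_yield(m, yield_protocol(f, method = "fba")))
    expect_equal(y, unname(oracle[f]), tolerance = 1e-6, label = f)
  }
})

test_that("each fuel's yield protocol completes within its time budget", {
  m <- bundled_for_tests()
  for (f in c("glc", "hdca")) {
    dt <- system.time(atp_yield(m, yield_protocol(f)))["elapsed"]
    expect_lt(dt, 1.0)
  }
})

test_that("yields are linear in uptake while oxygen is in excess", {
  m <- bundled_for_tests()
  y1 <- as.numeric(atp_yield(m, yield_protocol("glc", fuel_uptake = 1)))
  y2 <- as.numeric(atp_yield(m, yield_protocol("glc", fuel_uptake = 2)))
  expect_equal(y2, 2 * y1, tolerance = 1e-6)
  y0 <- suppressWarnings(
    as.numeric(atp_yield(m, yield_protocol("glc", fuel_uptake = 0))))
  expect_equal(y0, 0, tolerance = 1e-6)
})

test_that("fuel ordering follows the energy content of the substrates", {
  m <- bundled_for_tests()
  y <- vapply(c("hdca", "glc", "lac"), function(f)
    as.numeric(atp_yield(m, yield_protocol(f, method = "fba"))), 0)
  expect_gt(y[["hdca"]], y[["glc"]])
  expect_gt(y[["glc"]], y[["lac"]])
})

test_that("a fuel with no degradation route yields zero with a warning", {
  m <- bundled_for_tests()
  expect_warning(y <- atp_yield(m, yield_protocol("gly", method = "fba")),
                 "no ATP-producing")
  expect_equal(as.numeric(y), 0, tolerance = 1e-9)
})

test_that("fumarase deficiency collapses ATP production and effluxes fumarate", {
  m <- bundled_for_tests()
  fd <- simulate_fumarase_deficiency(m)
  expect_equal(fd$wild_type$status, "optimal")
  expect_equal(fd$knockout$status, "optimal")
  # knockout can never increase the objective
  expect_lte(fd$knockout$objective_value, fd$wild_type$objective_value)
  # qualitative disease signature: deep ATP loss, fumarate in the effluent
  expect_gt(fd$percent_atp_reduction, 50)
  expect_gt(fd$fumarate_efflux, 0)
  # compensation: pyruvate carboxylase replenishes oxaloacetate and the
  # malate-aspartate carrier keeps running
  expect_gt(fd$knockout$fluxes[["PCm"]], 1e-6)
  expect_gt(fd$knockout$fluxes[["ASPGLUm_MitoCore"]], 1e-6)
  # both compartmental fumarases are dead in the knockout
  expect_equal(unname(abs(fd$knockout$fluxes[c("FUM_C", "FUMm")])), c(0, 0))
})

test_that("proton leak scan shows synthase and carrier reversal", {
  m <- bundled_for_tests()
  sc <- suppressMessages(
    proton_leak_scan(m, leak_values = seq(0, 500, by = 50)))
  expect_gt(nrow(sc), 3)
  # maximal ATP strictly non-increasing, strictly decreasing once leak binds
  expect_true(all(diff(sc$max_atp) <= 1e-8))
  expect_lt(sc$max_atp[nrow(sc)], sc$max_atp[1])
  # synthase flux monotonically decreasing and negative at the highest leak
  expect_true(all(diff(sc$atp_synthase) <= 1e-8))
  expect_lt(sc$atp_synthase[nrow(sc)], 0)
  # ATP/ADP and phosphate carriers reversed relative to baseline
  expect_gt(sc$ant[1], 0)
  expect_gt(sc$pi_carrier[1], 0)
  expect_lt(sc$ant[nrow(sc)], 0)
  expect_lt(sc$pi_carrier[nrow(sc)], 0)
})

test_that("acetyl-CoA attribution sums to one and isolates single fuels", {
  m <- bundled_for_tests()
  # single-fuel glucose run: everything from glucose
  m1 <- m
  for (f in degradable_fuels(m1)) m1 <- set_bounds(m1, f, lower = 0)
  m1 <- set_bounds(m1, "EX_glc", lower = -1)
  m1 <- set_bounds(m1, "EX_o2", lower = -50)
  r1 <- geometric_fba(m1)
  a1 <- attribute_acetyl_coa(r1, m1)
  expect_equal(unname(a1[["glucose"]]), 1, tolerance = 1e-6)
  # mixed default run: fractions sum to 1, beta-oxidation dominates
  r <- geometric_fba(m)
  a <- attribute_acetyl_coa(r, m)
  expect_equal(sum(a), 1, tolerance = 1e-9)
  expect_gt(attr(a, "total_flux"), 0)
  expect_gt(a[["fatty_acid"]], max(a[setdiff(names(a), "fatty_acid")]))
  # zero acetyl-CoA flux: empty attribution
  closed <- close_boundaries(m)
  r0 <- fba(closed)
  a0 <- attribute_acetyl_coa(r0, closed)
  expect_equal(attr(a0, "total_flux"), 0)
  expect_true(all(a0 == 0))
})
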