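test_that("FBA solves the linear chain and honours the uptake cap", {
  m <- toy_chain_model(cap = 5)
  r <- fba(m, "EX_b")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 5)
  expect_equal(unname(r$fluxes[c("EX_a", "A2B", "EX_b")]), c(-5, 5, 5))
})

test_that("FBA matches the brute-force vertex oracle on toy networks", {
  for (seed in 1:12) {
    m <- random_toy_model(n_mets = 3, n_rxns = 6, seed = seed)
    S <- as.matrix(assemble_stoichiometric_matrix(m))
    r <- fba(m, "EX_out")
    cc <- as.numeric(m$rxns$id == "EX_out")
    o <- brute_lp(cc, S, rep(0, nrow(S)), m$rxns$lower, m$rxns$upper)
    if (o$feasible) {
      expect_equal(r$status, "optimal", label = paste("seed", seed))
      expect_equal(r$objective_value, o$objective, tolerance = 1e-8,
                   label = paste("seed", seed))
    } else {
      expect_false(r$status == "optimal", label = paste("seed", seed))
    }
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- bundled_for_tests()
  r <- fba(m)
  S <- as.matrix(assemble_stoichiometric_matrix(m))
  resid <- max(abs(S %*% r$fluxes))
  expect_lte(resid, 1e-9 * max(1, max(abs(r$fluxes))))
  expect_true(all(r$fluxes >= m$rxns$lower - 1e-9))
  expect_true(all(r$fluxes <= m$rxns$upper + 1e-9))
})

test_that("solver failure modes are reported, never silent", {
  mets <- metabolite("a_c", "A", "cytosolic")
  # infeasible: a forced exchange with no counterpart
  m1 <- model_network(mets, list(
    reaction("EX1", c(a_c = -1), lower = 2, upper = 5,
             category = "boundary_exchange")), objective_id = "EX1")
  expect_equal(fba(m1)$status, "infeasible")
  # unbounded: unlimited antiparallel exchanges
  m2 <- model_network(mets, list(
    reaction("EX1", c(a_c = -1), lower = -Inf, upper = Inf,
             category = "boundary_exchange"),
    reaction("EX2", c(a_c = 1), lower = -Inf, upper = Inf,
             category = "boundary_exchange")), objective_id = "EX1")
  expect_equal(fba(m2)$status, "unbounded")
  # degenerate objective
  expect_error(fba(m1, "nope"), "unknown reaction")
})

test_that("FVA ranges are points on a single path and nest with fraction", {
  m <- toy_chain_model(cap = 5)
  fv <- fva(m, "EX_b", fraction = 1.0)
  expect_true(all(abs(fv$ranges[, "max"] - fv$ranges[, "min"]) < 1e-8))
  fv98 <- fva(m, "EX_b", fraction = 0.98)
  expect_true(all(fv98$ranges[, "min"] <= fv$ranges[, "min"] + 1e-8))
  expect_true(all(fv98$ranges[, "max"] >= fv$ranges[, "max"] - 1e-8))
})

test_that("duplicate isoenzymes have wide individual ranges but a fixed sum", {
  m <- toy_parallel_model()
  fv <- fva(m, "EX_b")
  expect_equal(unname(fv$ranges["P1", ]), c(0, 10))
  expect_equal(unname(fv$ranges["P2", ]), c(0, 10))
  expect_equal(unname(fv$ranges["EX_b", ]), c(10, 10))
})

test_that("FVA at the optimum brackets both FBA and geometric FBA vectors", {
  m <- bundled_for_tests()
  fv <- fva(m)
  r1 <- fba(m)
  r2 <- geometric_fba(m)
  for (id in m$rxns$id) {
    expect_gte(r1$fluxes[[id]], fv$ranges[id, "min"] - 1e-6)
    expect_lte(r1$fluxes[[id]], fv$ranges[id, "max"] + 1e-6)
    expect_gte(r2$fluxes[[id]], fv$ranges[id, "min"] - 1e-6)
    expect_lte(r2$fluxes[[id]], fv$ranges[id, "max"] + 1e-6)
  }
})

test_that("geometric FBA equals FBA on a single path and splits parallel paths", {
  m <- toy_chain_model(cap = 5)
  g <- geometric_fba(m, "EX_b")
  r <- fba(m, "EX_b")
  expect_equal(g$fluxes, r$fluxes, tolerance = 1e-6)
  # two identical parallel paths of joint capacity 10: each carries 5
  # (verified independently: the minimax-deviation point of the segment
  # {P1 + P2 = 10, P1, P2 >= 0} is its midpoint)
  mp <- toy_parallel_model()
  g2 <- geometric_fba(mp, "EX_b")
  expect_equal(g2$fluxes[["P1"]], 5, tolerance = 1e-3)
  expect_equal(g2$fluxes[["P2"]], 5, tolerance = 1e-3)
  expect_equal(g2$objective_value, 10, tolerance = 1e-6)
})

test_that("geometric FBA is deterministic and idempotent", {
  m <- bundled_for_tests()
  g1 <- geometric_fba(m)
  g2 <- geometric_fba(m)
  expect_identical(g1$fluxes, g2$fluxes)
  # idempotence: clamping the model to the returned vector and re-running
  # returns the same vector
  m2 <- m
  m2$rxns$lower <- pmax(m2$rxns$lower, g1$fluxes - 1e-6)
  m2$rxns$upper <- pmin(m2$rxns$upper, g1$fluxes + 1e-6)
  g3 <- geometric_fba(m2)
  expect_equal(g3$fluxes, g1$fluxes, tolerance = 1e-4)
})

test_that("knockouts zero associated reactions and never help the objective", {
  m <- bundled_for_tests()
  wt <- fba(m)
  # a complex is one reaction: one subunit gene disables the whole step
  ko_model <- apply_knockout(m, "NDUFS1")
  i <- match("CPLX1_MitoCore", ko_model$rxns$id)
  expect_equal(ko_model$rxns$lower[i], 0)
  expect_equal(ko_model$rxns$upper[i], 0)
  ko <- knockout(m, "NDUFS1")
  expect_lte(ko$objective_value, wt$objective_value + 1e-9)
  # the FH gene maps to both compartmental fumarases
  idx <- mitoflux:::match_knockout_targets(m, "FH")
  expect_setequal(m$rxns$id[idx], c("FUM_C", "FUMm"))
  # knocking out a reaction off any active path changes nothing
  ko2 <- knockout(m, "OF_HEME_MitoCore")
  expect_equal(ko2$objective_value, wt$objective_value, tolerance = 1e-9)
  expect_error(knockout(m, "NOT_A_GENE"), "known genes")
})

test_that("bound scans report infeasible points and keep input order", {
  m <- toy_chain_model(cap = 5)
  res <- scan_bound(m, "A2B", "lower", c(0, 3, 8), objective_id = "EX_b")
  expect_length(res, 3)
  expect_equal(res[[1]]$objective_value, 5)
  expect_equal(res[[2]]$objective_value, 5)
  expect_equal(res[[3]]$status, "infeasible")
  expect_error(scan_bound(m, "A2B", "lower", c(3, 0)), "sorted")
})
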