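# Shared fixtures and independent oracles.

# Brute-force LP oracle: enumerate all basic solutions of
# {A x = b, l <= x <= u} (choose a basis, pin the rest at bounds) and take the
# best feasible one. Exponential, for <= 8-variable toys only; independent of
# the package's simplex.
brute_lp <- function(cc, A, b, l, u) {
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(n <= 10, m <= n)
  best <- -Inf
  feas <- FALSE
  argbest <- NULL
  for (B in utils::combn(n, m, simplify = FALSE)) {
    Nn <- setdiff(seq_len(n), B)
    combos <- if (length(Nn)) expand.grid(rep(list(c(1, 2)), length(Nn)))
              else data.frame(row.names = 1)
    for (ci in seq_len(nrow(combos))) {
      xn <- ifelse(unlist(combos[ci, ]) == 1, l[Nn], u[Nn])
      if (any(!is.finite(xn))) next
      AB <- A[, B, drop = FALSE]
      if (abs(det(AB)) < 1e-10) next
      rhs <- b - if (length(Nn)) A[, Nn, drop = FALSE] %*% xn else 0
      xb <- solve(AB, rhs)
      x <- numeric(n)
      x[B] <- xb
      if (length(Nn)) x[Nn] <- xn
      if (any(x < l - 1e-7) || any(x > u + 1e-7)) next
      feas <- TRUE
      val <- sum(cc * x)
      if (val > best) {
        best <- val
        argbest <- x
      }
    }
  }
  list(feasible = feas, objective = best, x = argbest)
}

# independent proton-accounting oracle for ATP yields: given pathway tallies
# for one mole of fuel, return mol ATP at the cytosolic demand reaction.
# A matrix NADH pumps 10*(1-ros) PMF along the chain, but each unit of
# complex-I flux makes ros superoxide whose removal consumes ros/2 NADPH,
# diverting ros/2 NADH-equivalents from NAD- to NADP-isocitrate
# dehydrogenase; solving w = 10(1-ros) - (ros/2) w gives the effective worth
# of a matrix NADH. A cytosolic NADH pays 1 PMF to the malate-aspartate
# shuttle on top. Quinol is worth 6. Each exported matrix substrate-level ATP
# costs 1 PMF (0.82 ANT + 0.18 Pi carrier); each cytosolic ATP made by the
# synthase costs 3.7 PMF (2.7 synthase + 1 export).
yield_oracle <- function(nadh_m = 0, nadh_c = 0, qh2 = 0, slp_matrix = 0,
                         atp_c = 0, transport_pmf = 0, ros = 1e-5) {
  w <- 10 * (1 - ros) / (1 + ros / 2)
  pmf <- nadh_m * w + nadh_c * (w - 1) + qh2 * 6 -
    slp_matrix * 1 - transport_pmf
  atp_c + slp_matrix + pmf / 3.7
}

# linear chain: A_in -> A -> B -> B_out with a capacity on the uptake
toy_chain_model <- function(cap = 5) {
  mets <- rbind(metabolite("a_c", "A", "cytosolic"),
                metabolite("b_c", "B", "cytosolic"))
  rxns <- list(
    reaction("EX_a", c(a_c = -1), lower = -cap, upper = 0,
             category = "boundary_exchange"),
    reaction("A2B", c(a_c = -1, b_c = 1), lower = 0),
    reaction("EX_b", c(b_c = -1), lower = 0, upper = 1000,
             category = "boundary_exchange"))
  model_network(mets, rxns, objective_id = "EX_b")
}

# two identical parallel paths A -> B of joint capacity 10
toy_parallel_model <- function() {
  mets <- rbind(metabolite("a_c", "A", "cytosolic"),
                metabolite("b_c", "B", "cytosolic"))
  rxns <- list(
    reaction("EX_a", c(a_c = -1), lower = -10, upper = 0,
             category = "boundary_exchange"),
    reaction("P1", c(a_c = -1, b_c = 1), lower = 0),
    reaction("P2", c(a_c = -1, b_c = 1), lower = 0),
    reaction("EX_b", c(b_c = -1), lower = 0, upper = 1000,
             category = "boundary_exchange"))
  model_network(mets, rxns, objective_id = "EX_b")
}

# random small mass-balanced networks for property tests
random_toy_model <- function(n_mets = 3, n_rxns = 6, seed = 1) {
  set.seed(seed)
  ids <- paste0(letters[seq_len(n_mets)], "_c")
  mets <- do.call(rbind, lapply(ids, function(i) metabolite(i, i, "cytosolic")))
  rxns <- list()
  # one uptake, one efflux, internal conversions
  rxns[[1]] <- reaction("EX_in", stats::setNames(-1, ids[1]),
                        lower = -round(runif(1, 1, 8), 1), upper = 0,
                        category = "boundary_exchange")
  rxns[[2]] <- reaction("EX_out", stats::setNames(-1, ids[n_mets]),
                        lower = 0, upper = 1000, category = "boundary_exchange")
  for (k in seq_len(n_rxns - 2)) {
    pair <- sample(n_mets, 2)
    s <- stats::setNames(c(-1, 1), ids[pair])
    rev <- runif(1) < 0.5
    rxns[[k + 2]] <- reaction(paste0("R", k), s,
                              lower = if (rev) -10 else 0, upper = 10)
  }
  model_network(mets, rxns, objective_id = "EX_out")
}

# micro-model of oxidative phosphorylation: respiratory chain fed by a matrix
# NADH source, ATP exported and hydrolysed in the cytosol
oxphos_micro_model <- function(params = pmf_parameters(), nadh_limit = 1) {
  base <- c("pmf", "nad", "nadh", "nadp", "nadph", "q10", "q10h2", "etfox",
            "etfrd", "ficytc", "focytc", "o2s", "o2", "h2o", "h2o2",
            "atp", "adp", "pi", "succ", "fum")
  mets <- list()
  for (b in base) {
    comp <- c("m")
    if (b %in% c("pmf", "o2", "h2o", "atp", "adp", "pi")) comp <- c("c", "m")
    for (cm in comp)
      mets[[length(mets) + 1]] <- metabolite(
        paste0(b, "_", cm), b,
        ifelse(cm == "c", "cytosolic", "mitochondrial"),
        is_pmf = b == "pmf")
  }
  chain <- make_respiratory_chain(params)
  rxns <- c(unname(chain), list(
    reaction("DM_nadh", c(nad_m = -1, nadh_m = 1), lower = 0, upper = nadh_limit,
             category = "pseudo"),
    reaction("DM_nadph", c(nadp_m = -1, nadph_m = 1), lower = 0,
             category = "pseudo"),
    make_transport_step("ANT", "CARRIER", import = "adp", export = "atp",
                        net_charge = 1, protons = 0, reversible = TRUE,
                        params = params),
    make_transport_step("PIC", "CARRIER", import = "pi", net_charge = 0,
                        protons = 1, reversible = FALSE, params = params),
    make_transport_step("O2t", "DIFFUSION", import = "o2", params = params),
    make_transport_step("H2Ot", "DIFFUSION", import = "h2o", params = params),
    reaction("OF_ATP", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
             lower = 0, category = "pseudo"),
    reaction("EX_o2", c(o2_c = -1), lower = -1000, upper = 1000,
             category = "boundary_exchange"),
    reaction("EX_h2o", c(h2o_c = -1), lower = -1000, upper = 1000,
             category = "boundary_exchange")))
  # complex II / ETF inputs are unused here; pin their substrates
  rxns <- c(rxns, list(
    reaction("DM_succ", c(succ_m = 1, fum_m = -1), lower = 0, upper = 0,
             category = "pseudo"),
    reaction("DM_etf", c(etfox_m = -1, etfrd_m = 1), lower = 0, upper = 0,
             category = "pseudo")))
  model_network(do.call(rbind, mets), rxns, objective_id = "OF_ATP")
}

expect_model_equal <- function(a, b) {
  ma <- a$mets[order(a$mets$id), ]
  mb <- b$mets[order(b$mets$id), ]
  rownames(ma) <- rownames(mb) <- NULL
  expect_equal(ma, mb)
  ra <- a$rxns[order(a$rxns$id), ]
  rb <- b$rxns[order(b$rxns$id), ]
  rownames(ra) <- rownames(rb) <- NULL
  expect_equal(ra, rb)
  for (id in a$rxns$id) {
    sa <- a$stoich[[match(id, a$rxns$id)]]
    sb <- b$stoich[[match(id, b$rxns$id)]]
    expect_identical(sort(names(sa)), sort(names(sb)), label = id)
    expect_equal(sa[sort(names(sa))], sb[sort(names(sb))], label = id)
  }
  expect_identical(a$objective_id, b$objective_id)
}

# the eight-fuel reference protocol shared by simulation and acceptance tests
bundled_for_tests <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reduced_model()
    cache
  }
})
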