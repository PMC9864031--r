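# FBA, MOMA, energy accounting and the scenario runner.

test_that("FBA solves a bound-limited chain exactly", {
  sol <- fba(chain_model(ub_in = 10))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes), c(10, 10, 10))
})

test_that("FBA agrees with vertex enumeration on random small networks", {
  for (seed in 1:25) {
    net <- random_network(seed)
    oracle <- vertex_enum_lp(net$S, net$lb, net$ub, net$cc)
    mine <- mbgem:::simplex_lp(net$S, rep(0, nrow(net$S)), net$cc,
                               net$lb, net$ub)
    expect_identical(mine$status, oracle$status, info = seed)
    if (oracle$status == "optimal") {
      expect_equal(mine$obj, oracle$obj, tolerance = 1e-8,
                   info = paste("seed", seed))
    }
  }
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  for (m in list(tm$healthy, tm$mb)) {
    sol <- suppressMessages(fba(m, config = cfg))
    S <- as.matrix(build_stoichiometric_matrix(m))
    b <- suppressMessages(mbgem:::model_bounds(m, cfg))
    expect_lt(max(abs(S %*% sol$fluxes)),
              1e-8 * max(1, max(abs(sol$fluxes))))
    expect_true(all(sol$fluxes >= b$lb - 1e-8))
    expect_true(all(sol$fluxes <= b$ub + 1e-8))
  }
})

test_that("the FBA optimum is invariant under reaction permutation and
           reversible splitting", {
  m <- branch_model()
  base <- fba(m)$objective_value
  set.seed(5)
  pc <- sample(nrow(m$reactions))
  m2 <- metabolic_model(m$metabolites, m$reactions[pc, ],
                        m$stoich[m$reactions$id[pc]], m$genes, m$biomass_id)
  expect_equal(fba(m2)$objective_value, base, tolerance = 1e-9)

  # make RB reversible, then split it into two irreversibles
  m3 <- m
  m3$reactions$lower_bound[m3$reactions$id == "RB"] <- -5
  v3 <- fba(m3)$objective_value
  rx <- m3$reactions
  rx$lower_bound[rx$id == "RB"] <- 0
  rx <- rbind(rx, data.frame(id = "RB_rev", name = "b to a",
                             lower_bound = 0, upper_bound = 5, gpr = "",
                             pathway = "unassigned", is_exchange = FALSE,
                             atp_yield = 0L, paper_id = NA))
  sto <- m3$stoich
  sto$RB_rev <- c(aC = 1, bC = -1)
  m4 <- metabolic_model(m3$metabolites, rx, sto, biomass_id = "EX_b")
  expect_equal(fba(m4)$objective_value, v3, tolerance = 1e-9)
})

test_that("tightening a bound never increases the optimum", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  base <- suppressMessages(fba(tm$healthy, config = cfg))$objective_value
  for (nutrient in c("glucose", "tyrosine", "oxygen")) {
    cfg2 <- cfg
    cfg2$uptake_bounds[nutrient] <- cfg$uptake_bounds[[nutrient]] / 2
    v <- suppressMessages(fba(tm$healthy, config = cfg2))$objective_value
    expect_lte(v, base + 1e-9)
  }
})

test_that("MOMA identities and the Euclidean projection example hold", {
  m <- chain_model()
  ref <- fba(m)
  # empty perturbation: m = h, D = 0
  adj <- moma(m, ref)
  expect_equal(adj$objective_value, 0, tolerance = 1e-5)
  expect_equal(unname(adj$fluxes), unname(ref$fluxes), tolerance = 1e-5)

  # h = (1,2,3) on three independent routes, route 3 forced to 0, the
  # others free in [0,3]: projection is (1,2,0) at distance 3
  mets <- data.frame(id = c("aC", "bC", "cC"), name = c("a", "b", "c"))
  rxns <- data.frame(id = c("in_a", "out_a", "in_b", "out_b", "in_c",
                            "out_c"),
                     name = "r", lower_bound = 0, upper_bound = 3,
                     is_exchange = TRUE)
  sto <- list(in_a = c(aC = 1), out_a = c(aC = -1), in_b = c(bC = 1),
              out_b = c(bC = -1), in_c = c(cC = 1), out_c = c(cC = -1))
  m2 <- metabolic_model(mets, rxns, sto, biomass_id = "out_a")
  h <- c(out_a = 1, out_b = 2, out_c = 3)
  adj2 <- moma(m2, h, bound_overrides = list(out_c = c(0, 0),
                                             in_c = c(0, 0)))
  expect_identical(adj2$status, "optimal")
  expect_equal(unname(adj2$fluxes[c("out_a", "out_b", "out_c")]),
               c(1, 2, 0), tolerance = 1e-5)
  expect_equal(adj2$objective_value, 3, tolerance = 1e-5)

  # infeasible perturbation reports a status flag
  m3 <- chain_model()
  adj3 <- moma(m3, ref, bound_overrides = list(EX_a = c(5, 10),
                                               R1 = c(0, 1)))
  expect_identical(adj3$status, "infeasible")
})

test_that("MOMA matches a grid-search oracle on a 2-D polytope", {
  # branch model: free fluxes (RB, RC) in [0,10]^2 with RB + RC <= 10;
  # knock the reference off-polytope and compare with dense grid search
  m <- branch_model()
  h <- c(EX_a = 9, RB = 6, RC = 3, EX_b = 6, EX_c = 3)
  adj <- moma(m, h, bound_overrides = list(RB = c(0, 2)))
  grid <- seq(0, 10, by = 0.005)
  best <- Inf
  for (rb in grid[grid <= 2]) for (rc in grid) {
    if (rb + rc > 10) next
    v <- c(rb + rc, rb, rc, rb, rc)
    d2 <- sum((v - h)^2)
    if (d2 < best) best <- d2
  }
  expect_equal(adj$objective_value, sqrt(best), tolerance = 1e-4)
})

test_that("energy accounting attributes ATP by pathway", {
  # single ATP-producing reaction at flux 5, yield 1 -> share 1
  m <- metabolic_model(
    data.frame(id = c("aC", "atpC"), name = c("a", "atp")),
    data.frame(id = c("EX_a", "SYN", "ATPM"),
               name = c("in", "synthase", "burn"),
               lower_bound = c(5, 0, 0), upper_bound = c(5, 10, 10),
               pathway = c("exchange", "OXPHOS", "maintenance"),
               is_exchange = c(TRUE, FALSE, FALSE),
               atp_yield = c(0L, 1L, -1L)),
    list(EX_a = c(aC = 1), SYN = c(aC = -1, atpC = 1), ATPM = c(atpC = -1)),
    biomass_id = "SYN")
  acct <- energy_accounting(m, fba(m))
  expect_equal(acct$atp_total, 5)
  expect_equal(acct$atp_share_by_pathway$OXPHOS, 1.0)

  # toy baseline: recompute shares by independent summation
  tm <- toy_fixture()
  sol <- suppressMessages(fba(tm$mb, config = scenario_config()))
  acct2 <- energy_accounting(tm$mb, sol)
  rx <- tm$mb$reactions
  hand <- tapply(pmax(0, rx$atp_yield * sol$fluxes[rx$id]), rx$pathway, sum)
  hand <- hand[hand > 0]
  for (pw in names(hand)) {
    expect_equal(acct2$atp_by_pathway[[pw]], unname(hand[pw]),
                 tolerance = 1e-9)
  }
  expect_equal(sum(unlist(acct2$atp_share_by_pathway)), 1, tolerance = 1e-9)
  # LacR/OCR arithmetic on hand inputs
  v <- sol$fluxes
  lac <- sum(v[c("EX_lac_C")])
  o2 <- sum(v[c("EX_o2_N", "EX_o2_A")])
  expect_equal(acct2$lacr_over_ocr, lac / o2, tolerance = 1e-12)
})

test_that("deprivation scenarios reproduce the designed phenotypes", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  runs <- suppressMessages(lapply(
    c("baseline", "no_glucose", "no_glutamine", "no_both"),
    function(sc) scenario_run(tm$mb, cfg, sc)))
  names(runs) <- c("baseline", "no_glucose", "no_glutamine", "no_both")
  expect_gt(runs$baseline$biomass, 0)
  expect_equal(runs$no_glucose$biomass, 0, tolerance = 1e-8)
  expect_equal(runs$no_glutamine$biomass, runs$baseline$biomass,
               tolerance = 1e-6)
  expect_lt(runs$no_both$accounting$atp_total,
            runs$baseline$accounting$atp_total - 1e-6)
})

test_that("uptake bounds split 97/3 between neuron and astrocyte", {
  tm <- toy_fixture()
  b <- suppressMessages(mbgem:::model_bounds(tm$healthy, scenario_config()))
  expect_equal(unname(b$ub["EX_glc_N"]), 0.852 * 0.97)
  expect_equal(unname(b$ub["EX_glc_A"]), 0.852 * 0.03)
  expect_equal(unname(b$ub["EX_leu_N"]), 0.034 * 0.97)
})
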