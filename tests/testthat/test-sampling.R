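# ACHR sampling and differential-flux testing.

test_that("a single free flux on [0,1] samples uniformly", {
  m <- metabolic_model(
    data.frame(id = "xC", name = "x"),
    data.frame(id = c("EX_in", "EX_out"), name = c("in", "out"),
               lower_bound = 0, upper_bound = 1,
               is_exchange = c(TRUE, TRUE)),
    list(EX_in = c(xC = 1), EX_out = c(xC = -1)),
    biomass_id = "EX_out")
  s <- achr_sample(m, n_samples = 5000, seed = 3)
  mu <- mean(s$samples["EX_in", ])
  se <- stats::sd(s$samples["EX_in", ]) / sqrt(5000)
  expect_lt(abs(mu - 0.5), 3 * se + 0.01)
})

test_that("identical seeds give bitwise-identical sample matrices", {
  tm <- toy_fixture()
  a <- suppressMessages(achr_sample(tm$mb, scenario_config(),
                                    n_samples = 200, seed = 7))
  b <- suppressMessages(achr_sample(tm$mb, scenario_config(),
                                    n_samples = 200, seed = 7))
  expect_identical(a$samples, b$samples)
  c <- suppressMessages(achr_sample(tm$mb, scenario_config(),
                                    n_samples = 200, seed = 8))
  expect_false(identical(a$samples, c$samples))
})

test_that("every sampled profile satisfies bounds and mass balance", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  s <- suppressMessages(achr_sample(tm$mb, cfg, n_samples = 1000, seed = 5))
  S <- as.matrix(build_stoichiometric_matrix(tm$mb))
  b <- suppressMessages(mbgem:::model_bounds(tm$mb, cfg))
  expect_lt(max(abs(S %*% s$samples)), 1e-6)
  expect_true(all(s$samples >= b$lb - 1e-9))
  expect_true(all(s$samples <= b$ub + 1e-9))
})

test_that("a fully determined flux is sampled at exactly its value", {
  # forced chain: every reaction pinned to the uptake rate
  m <- chain_model()
  m$reactions$lower_bound[1] <- 10   # EX_a fixed at 10
  s <- achr_sample(m, n_samples = 100, seed = 1)
  expect_equal(unname(s$samples["R1", ]), rep(10, 100), tolerance = 1e-9)
  expect_equal(unname(s$samples["BIO", ]), rep(10, 100), tolerance = 1e-9)
})

test_that("infeasible models refuse to sample", {
  m <- chain_model()
  # a knockout that blocks the chain still leaves the zero flux state
  expect_error(achr_sample(m, knockout_reactions = "R1",
                           n_samples = 10, seed = 1), NA)
  m$reactions$lower_bound[m$reactions$id == "BIO"] <- 50
  expect_error(achr_sample(m, n_samples = 10, seed = 1), "infeasible")
})

test_that("Welch statistics match the hand-computed example", {
  # x = (1,2,3) vs y = (4,5,6): t = -3.674, df = 4, p ~ 0.021
  a <- structure(list(samples = matrix(c(1, 2, 3), 1, 3,
                                       dimnames = list("R", NULL))),
                 class = "sampling_result")
  b <- structure(list(samples = matrix(c(4, 5, 6), 1, 3,
                                       dimnames = list("R", NULL))),
                 class = "sampling_result")
  dt <- differential_flux_test(a, b)
  expect_equal(dt$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(dt$df, 4, tolerance = 1e-9)
  expect_equal(dt$p, 0.02131, tolerance = 1e-4)
  # cross-check against the stats implementation
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(dt$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(dt$p, tt$p.value, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg step-up arithmetic and invariants hold", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  # identical samplings: all t = 0, p = 1, nothing significant
  tm <- toy_fixture()
  s <- suppressMessages(achr_sample(tm$mb, scenario_config(),
                                    n_samples = 200, seed = 9))
  dt <- differential_flux_test(s, s)
  expect_true(all(dt$t_stat == 0))
  expect_true(all(dt$p == 1))
  expect_false(any(dt$significant))
  expect_true(all(dt$p_adj >= dt$p))
  # BH never rejects more than unadjusted testing
  s2 <- suppressMessages(achr_sample(tm$healthy, scenario_config(),
                                     n_samples = 200, seed = 9))
  dt2 <- differential_flux_test(s2, s)
  expect_lte(sum(dt2$p_adj < 0.05), sum(dt2$p < 0.05))
  # tested set is the intersection of reaction sets
  expect_setequal(dt2$reaction,
                  intersect(rownames(s2$samples), rownames(s$samples)))
})

test_that("disease and healthy samplings separate strongly on the fixture", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  sh <- suppressMessages(achr_sample(tm$healthy, cfg, n_samples = 1000,
                                     seed = 31))
  sm <- suppressMessages(achr_sample(tm$mb, cfg, n_samples = 1000,
                                     seed = 32))
  dt <- differential_flux_test(sh, sm)
  # forced Warburg rewiring: lactate export must shift detectably
  expect_true(dt$significant[dt$reaction == "EX_lac_C"])
  expect_gt(dt$mean_b[dt$reaction == "EX_lac_C"],
            dt$mean_a[dt$reaction == "EX_lac_C"])
})
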