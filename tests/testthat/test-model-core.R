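# Model structures, GPR logic and the stoichiometric matrix.

test_that("GPR parsing and evaluation follow boolean semantics", {
  cases <- list(
    list(rule = "(g1 and g2)", ko = "g1", active = FALSE),
    list(rule = "(g1 and g2) or g3", ko = "g1", active = TRUE),
    list(rule = "(g1 and g2) or g3", ko = c("g1", "g3"), active = FALSE),
    list(rule = "g1 or g2", ko = c("g1", "g2"), active = FALSE),
    list(rule = "", ko = c("g1", "g2"), active = TRUE),     # constitutive
    list(rule = "g1 AND (g2 OR g3)", ko = "g3", active = TRUE)
  )
  for (cs in cases) {
    expect_identical(evaluate_gpr(cs$rule, cs$ko), cs$active,
                     info = cs$rule)
  }
  expect_setequal(gpr_genes("(HK1 or HK2) and GAPDH"),
                  c("HK1", "HK2", "GAPDH"))
  expect_error(parse_gpr("g1 and (g2"), "missing")
  expect_error(parse_gpr("g1 or or g2"), "unexpected")
})

test_that("unknown knockout ids warn and are ignored", {
  expect_warning(res <- evaluate_gpr("g1", "gX", genes = "g1"), "unknown")
  expect_true(res)
})

test_that("GPR evaluation is monotone in the knockout set", {
  set.seed(1)
  genes <- paste0("g", 1:5)
  for (k in 1:30) {
    leaves <- sample(genes, sample(2:4, 1))
    ops <- sample(c(" and ", " or "), length(leaves) - 1, replace = TRUE)
    rule <- leaves[1]
    for (i in seq_along(ops)) rule <- paste0("(", rule, ops[i],
                                             leaves[i + 1], ")")
    small <- sample(genes, sample(0:3, 1))
    large <- union(small, sample(genes, sample(0:3, 1)))
    if (!evaluate_gpr(rule, small)) {
      expect_false(evaluate_gpr(rule, large), info = rule)
    }
  }
})

test_that("validation enforces the structural invariants", {
  mets <- data.frame(id = c("aC", "bC"), name = c("a", "b"))
  rxns <- data.frame(id = c("EX_a", "R1"), name = c("in", "conv"),
                     lower_bound = c(0, 0), upper_bound = c(10, 10),
                     is_exchange = c(TRUE, FALSE))
  sto <- list(EX_a = c(aC = 1), R1 = c(aC = -1, bC = 1))

  expect_silent(metabolic_model(mets, rxns, sto, biomass_id = "R1"))
  # reversed bounds
  bad <- rxns; bad$lower_bound[2] <- 20
  expect_error(metabolic_model(mets, bad, sto, biomass_id = "R1"),
               "lower_bound > upper_bound")
  # missing biomass
  expect_error(metabolic_model(mets, rxns, sto, biomass_id = "nope"),
               "biomass")
  # orphan metabolite
  mets2 <- rbind(mets, data.frame(id = "zC", name = "z"))
  expect_error(metabolic_model(mets2, rxns, sto, biomass_id = "R1"),
               "no reaction")
  # exchange with two metabolites
  sto2 <- sto; sto2$EX_a <- c(aC = 1, bC = 1)
  expect_error(metabolic_model(mets, rxns, sto2, biomass_id = "R1"),
               "exactly one")
})

test_that("metabolite tags follow the trailing-letter convention", {
  expect_identical(metabolite_tag(c("glcN", "glcA", "lacC", "foo")),
                   c("N", "A", "C", NA))
})

test_that("the stoichiometric matrix reproduces signed coefficients", {
  m <- branch_model()
  S <- build_stoichiometric_matrix(m)
  expect_identical(dim(S), c(3L, 5L))
  expect_equal(S["aC", "RB"], -1)
  expect_equal(S["bC", "RB"], 1)
  # exchange column: single entry
  expect_equal(sum(S[, "EX_b"] != 0), 1)
  expect_equal(S["bC", "EX_b"], -1)
  # S v = 0 holds at any FBA solution
  v <- fba(m)$fluxes
  expect_lt(max(abs(as.matrix(S) %*% v)), 1e-9 * max(1, max(abs(v))))
})

test_that("S sparsity is permutation-equivariant", {
  m <- toy_fixture()$healthy
  S <- as.matrix(build_stoichiometric_matrix(m))
  set.seed(3)
  pr <- sample(nrow(m$metabolites))
  pc <- sample(nrow(m$reactions))
  m2 <- metabolic_model(m$metabolites[pr, ], m$reactions[pc, ],
                        m$stoich[m$reactions$id[pc]], m$genes,
                        m$biomass_id)
  S2 <- as.matrix(build_stoichiometric_matrix(m2))
  expect_equal(S2[rownames(S), colnames(S)], S)
})

test_that("gene knockouts disable exactly the GPR-inactive reactions", {
  tm <- toy_fixture()
  off <- reactions_disabled_by(tm$mb, "GAPDH")
  expect_setequal(off, c("GLYC_N", "GLYC_A"))
  expect_length(reactions_disabled_by(tm$mb, "HK1"), 0)   # isoenzyme
  expect_setequal(reactions_disabled_by(tm$mb, c("HK1", "HK2")),
                  c("GLYC_N", "GLYC_A"))
  expect_setequal(reactions_disabled_by(tm$mb, "LAT1"),
                  c("EX_leu_N", "EX_trp_N", "EX_tyr_N",
                    "EX_leu_A", "EX_trp_A", "EX_tyr_A"))
})
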