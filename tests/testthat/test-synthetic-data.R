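# Synthetic model and expression generators.

test_that("the generated models validate and carry the documented
           structure", {
  tm <- toy_fixture()
  for (m in list(tm$healthy, tm$mb)) {
    expect_silent(validate_model(m))
    expect_gte(nrow(m$reactions), 60)
    expect_lte(nrow(m$reactions), 120)
    expect_gte(length(unique(m$reactions$pathway)), 8)
    expect_identical(m$biomass_id, "BIOMASS")
  }
  expect_identical(tm$healthy$reactions$id, tm$mb$reactions$id)
  # neuron glucose exchange bound = 0.852 x 0.97
  i <- match("EX_glc_N", tm$healthy$reactions$id)
  expect_equal(tm$healthy$reactions$upper_bound[i], 0.82644)
})

test_that("healthy and MB variants differ only in the designed bounds", {
  tm <- toy_fixture()
  h <- tm$healthy$reactions
  m <- tm$mb$reactions
  expect_identical(h$gpr, m$gpr)
  expect_identical(tm$healthy$stoich, tm$mb$stoich)
  delta <- h$id[h$lower_bound != m$lower_bound |
                  h$upper_bound != m$upper_bound]
  expect_setequal(delta, tm$ground_truth$designed$bound_delta_reactions)
})

test_that("the generators reproduce the designed disease phenotype", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  fh <- suppressMessages(fba(tm$healthy, config = cfg))
  fm <- suppressMessages(fba(tm$mb, config = cfg))
  expect_gt(fh$objective_value, 0)
  expect_gt(fm$objective_value, 0)
  glc <- sum(fm$fluxes[c("EX_glc_N", "EX_glc_A")])
  lac <- sum(fm$fluxes["EX_lac_C"])
  expect_gte(lac / glc,
             tm$ground_truth$designed$lactate_glucose_ratio_min)
  # Warburg contrast: glycolytic ATP dominates in MB, OXPHOS in healthy
  am <- energy_accounting(tm$mb, fm)
  ah <- energy_accounting(tm$healthy, fh)
  expect_gt(am$atpg_over_atpop, 1)
  expect_lt(ah$atpg_over_atpop, 1)
  expect_gt(am$lacr_over_ocr, ah$lacr_over_ocr)
})

test_that("inconsistent pathway toggles are rejected", {
  expect_error(toy_model_spec(fatty_acid = FALSE), "cannot be disabled")
  expect_error(toy_model_spec(cholesterol = FALSE), "cannot be disabled")
  # optional branches may be dropped; ground truth adapts
  tm2 <- suppressMessages(generate_toy_models(toy_model_spec(
    gaba = FALSE, taurine = FALSE)))
  expect_false(any(grepl("^GAD_|^TAUS_", tm2$mb$reactions$id)))
  expect_setequal(tm2$ground_truth$gimme_absent_genes, "GYS1")
})

test_that("expression generation is seed-reproducible with calibrated
           planted folds", {
  tm <- toy_fixture()
  spec <- expression_spec(genes = tm$mb$genes,
                          planted_up = tm$ground_truth$planted_up_genes,
                          planted_down =
                            tm$ground_truth$gimme_absent_genes)
  a <- generate_expression_series(spec, seed = 11)
  b <- generate_expression_series(spec, seed = 11)
  expect_identical(a$expr$values, b$expr$values)
  c <- generate_expression_series(spec, seed = 12)
  expect_false(identical(a$expr$values, c$expr$values))

  # empirical fold of planted 4x genes within +/-25% at n = 10
  mb <- a$expr$samples$condition == "MB"
  for (g in tm$ground_truth$planted_up_genes) {
    fold <- mean(a$expr$values[g, mb]) / mean(a$expr$values[g, !mb])
    expect_gt(fold, 3); expect_lt(fold, 5)
  }
  expect_error(expression_spec(genes = "g1", planted_up = "gZ"),
               "unknown gene")
  expect_error(expression_spec(genes = c("g1", "g2"),
                               planted_up = c(g1 = 2),
                               planted_down = c(g1 = 0.1)),
               "disjoint")
})

test_that("binarization recovers the planted states in at least 95% of
           seeds", {
  tm <- toy_fixture()
  ok <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    ex <- generate_expression_series(expression_spec(
      genes = tm$mb$genes,
      planted_up = tm$ground_truth$planted_up_genes,
      planted_down = tm$ground_truth$gimme_absent_genes), seed = seed)
    st <- binarize_expression(ex$expr, "MB",
                              gimme_threshold_presets[["GSE37418"]])
    states <- st$states[tm$mb$genes]
    want_absent <- tm$ground_truth$gimme_absent_genes
    ok <- ok + (all(states[want_absent] == "A") &&
                  all(states[setdiff(tm$mb$genes, want_absent)] == "P"))
  }
  expect_gte(ok / n_seeds, 0.95)
})

test_that("the ground-truth report predicts every screen outcome", {
  # the integration/essentiality/antimetabolite tests assert each piece;
  # here the report itself is checked for internal consistency
  tm <- toy_fixture()
  gt <- tm$ground_truth
  expect_true(all(gt$pan_essential_healthy_safe %in%
                    gt$essential_genes_biomass))
  expect_false(any(unlist(gt$synthetic_lethal_pairs) %in%
                     gt$essential_genes_biomass))
  expect_true(all(gt$gimme_absent_genes %in% tm$mb$genes))
  expect_true(all(gt$gimme_removed_reactions %in% tm$mb$reactions$id))
})
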