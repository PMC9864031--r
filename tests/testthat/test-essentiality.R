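# Deletion screens: essential genes, synthetic lethality, healthy safety.

test_that("single deletions recover exactly the planted essential set", {
  tm <- toy_fixture()
  ess <- suppressMessages(single_deletion(tm$mb,
                                          config = scenario_config()))
  expect_setequal(ess$target[ess$essential],
                  tm$ground_truth$essential_genes_biomass)
  # transporter knockout: biomass zero, essential
  glut <- ess[ess$target == "SLC2A1", ]
  expect_equal(glut$ko_value, 0, tolerance = 1e-8)
  expect_true(glut$essential)
  # isoenzyme knockout: growth unchanged, not essential
  iso <- ess[ess$target == "HK1", ]
  expect_equal(iso$reduction_fraction, 0, tolerance = 1e-8)
  expect_false(iso$essential)
})

test_that("a reduction of exactly 40% is not essential (strict rule)", {
  m <- chain_model(ub_in = 10)
  # two parallel routes: blocking one caps growth at 6/10
  rx <- m$reactions
  rx$upper_bound[rx$id == "R1"] <- 6
  rx <- rbind(rx, data.frame(id = "R1b", name = "alt", lower_bound = 0,
                             upper_bound = 100, gpr = "gAlt",
                             pathway = "unassigned", is_exchange = FALSE,
                             atp_yield = 0L, paper_id = NA))
  sto <- m$stoich
  sto$R1b <- c(aC = -1, bC = 1)
  m2 <- metabolic_model(m$metabolites, rx, sto, biomass_id = "BIO")
  res <- single_deletion(m2, "gAlt", "gene")
  expect_equal(res$reduction_fraction, 0.40, tolerance = 1e-9)
  expect_false(res$essential)          # "more than 40%" is strict
  res2 <- single_deletion(m2, "gAlt", "gene", cutoff = 0.39)
  expect_true(res2$essential)
})

test_that("reaction- and gene-level deletion agree on single-gene
           single-reaction pathways", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  g <- suppressMessages(single_deletion(tm$mb, "G6PD", "gene",
                                        config = cfg))
  r <- suppressMessages(single_deletion(tm$mb, c("PPP_N", "PPP_A"),
                                        "reaction", config = cfg))
  # deleting the gene equals deleting both catalyzed reactions jointly;
  # each single reaction already abolishes growth here
  expect_true(g$essential)
  expect_true(all(r$essential))
  expect_equal(g$ko_value, 0, tolerance = 1e-8)
})

test_that("double deletions find exactly the planted isoenzyme pairs", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  singles <- suppressMessages(single_deletion(tm$mb, config = cfg))
  sl <- suppressMessages(double_deletion_synthetic_lethals(
    tm$mb, config = cfg, singles = singles))
  found <- sl[sl$synthetic_lethal, c("gene1", "gene2")]
  want <- do.call(rbind, lapply(tm$ground_truth$synthetic_lethal_pairs,
                                function(p) sort(p)))
  expect_equal(nrow(found), nrow(want))
  for (k in seq_len(nrow(want))) {
    hit <- any(found$gene1 == want[k, 1] & found$gene2 == want[k, 2])
    expect_true(hit, info = paste(want[k, ], collapse = "+"))
  }
  # single-essential genes are excluded from the candidate pairs
  expect_false(any(unlist(found) %in%
                     singles$target[singles$essential]))
})

test_that("adding an isoenzyme can only shrink the essential set", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  m2 <- tm$mb
  # give GAPDH an isoenzyme on both glycolysis copies
  i <- m2$reactions$id %in% c("GLYC_N", "GLYC_A")
  m2$reactions$gpr[i] <- "(HK1 or HK2) and (GAPDH or GAPDH2)"
  m2$genes <- c(m2$genes, "GAPDH2")
  e1 <- suppressMessages(single_deletion(tm$mb, config = cfg))
  e2 <- suppressMessages(single_deletion(m2, tm$mb$genes, config = cfg))
  set1 <- e1$target[e1$essential]
  set2 <- e2$target[e2$essential]
  expect_true(all(set2 %in% set1))
  expect_false("GAPDH" %in% set2)
})

test_that("the common-essential screen intersects objectives and applies
           the healthy-safety filter", {
  tm <- toy_fixture()
  scr <- suppressMessages(common_essential_screen(tm$mb, tm$healthy,
                                                  scenario_config()))
  # biomass-essential but not ATP-essential genes are excluded
  g6 <- scr[scr$gene == "G6PD", ]
  expect_true(g6$essential_biomass)
  expect_false(g6$essential_atp)
  expect_false(g6$common_essential)
  # a gene whose healthy knockout halts healthy growth is filtered
  glut <- scr[scr$gene == "SLC2A1", ]
  expect_true(glut$common_essential)
  expect_false(glut$healthy_safe)
  expect_false(glut$candidate)
  # exactly the planted glutamine-addiction genes survive
  expect_setequal(scr$gene[scr$candidate],
                  tm$ground_truth$pan_essential_healthy_safe)
})

test_that("deletion screens are deterministic", {
  tm <- toy_fixture()
  cfg <- scenario_config()
  a <- suppressMessages(single_deletion(tm$mb,
                                        c("GLS", "HK1", "CS", "FASN"),
                                        config = cfg))
  b <- suppressMessages(single_deletion(tm$mb,
                                        c("GLS", "HK1", "CS", "FASN"),
                                        config = cfg))
  expect_identical(a, b)
})
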