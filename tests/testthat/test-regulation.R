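# ZF/ZG scoring and TR/NTR classification.

fake_sampling <- function(mat) {
  structure(list(samples = mat), class = "sampling_result")
}

test_that("ZF and summed ZG follow their definitions", {
  set.seed(2)
  tm <- toy_fixture()
  ex <- toy_expression()$expr
  rid <- c("GLYC_N", "LDH_N")
  a <- fake_sampling(matrix(stats::rnorm(200, 1, 0.5), 2, 100,
                            dimnames = list(rid, NULL)))
  b <- fake_sampling(matrix(stats::rnorm(200, 3, 0.5), 2, 100,
                            dimnames = list(rid, NULL)))
  z <- suppressMessages(compute_z_scores(a, b, ex, "healthy", "MB", tm$mb))
  # ZF definition recomputed by hand
  for (i in 1:2) {
    zf_hand <- (mean(b$samples[i, ]) - mean(a$samples[i, ])) /
      sqrt(stats::var(a$samples[i, ]) + stats::var(b$samples[i, ]))
    expect_equal(z$ZF[z$reaction == rid[i]], zf_hand, tolerance = 1e-12)
  }
  # equal sampled distributions: ZF = 0
  z0 <- suppressMessages(compute_z_scores(a, a, ex, "healthy", "MB", tm$mb))
  expect_true(all(z0$ZF == 0))
  # multi-gene ZG is the sum over GPR genes
  zg <- mbgem:::gene_z_scores(ex, "healthy", "MB")
  glyc_genes <- gpr_genes("(HK1 or HK2) and GAPDH")
  expect_equal(z$ZG_total[z$reaction == "GLYC_N"],
               sum(zg[glyc_genes]), tolerance = 1e-12)
  # the mean-normalized variant divides by the gene count
  zm <- suppressMessages(compute_z_scores(a, b, ex, "healthy", "MB", tm$mb,
                                          zg_aggregate = "mean"))
  expect_equal(zm$ZG_total[zm$reaction == "GLYC_N"],
               mean(zg[glyc_genes]), tolerance = 1e-12)
})

test_that("two genes scoring 1.2 and 1.0 sum to ZG_total 2.2", {
  vals <- rbind(ga = c(1, 3, 6, 8), gb = c(2, 2, 5, 5))
  colnames(vals) <- paste0("s", 1:4)
  zg <- mbgem:::gene_z_scores(
    expression_matrix(vals, conditions = c("A", "A", "B", "B")), "A", "B")
  # sanity: the helper reproduces hand Welch arithmetic
  hand <- (mean(c(6, 8)) - mean(c(1, 3))) /
    sqrt(stats::var(c(1, 3)) / 2 + stats::var(c(6, 8)) / 2)
  expect_equal(unname(zg["ga"]), hand, tolerance = 1e-12)
  # and summation over a 2-gene rule is plain addition
  rec <- data.frame(reaction = "R", ZF = 2.5,
                    ZG_total = 1.2 + 1.0, genes = "ga;gb", n_genes = 2L,
                    sign_concordant = TRUE)
  out <- classify_regulation(rec)
  expect_equal(out$ZG_total, 2.2)
  expect_identical(out$class, "TR")
})

test_that("classification thresholds and classes follow the 1.96 rule", {
  rec <- data.frame(
    reaction = c("r1", "r2", "r3", "r4", "r5"),
    ZF = c(2.5, 2.5, 1.0, -2.5, -0.5),
    ZG_total = c(2.3, 0.1, 5.0, -2.2, 0.0),
    genes = "", n_genes = 0L, sign_concordant = TRUE)
  out <- classify_regulation(rec, z_crit = 1.96)
  expect_identical(out$class, c("TR", "NTR", "none", "TR", "none"))
  # the critical value is the two-sided 5% normal quantile
  expect_equal(round(stats::qnorm(0.975), 2), 1.96)
  expect_error(classify_regulation(rec, z_crit = -1), "z_crit")
})

test_that("classification is symmetric under condition swap and the
           TR/NTR partition is exact", {
  set.seed(4)
  tm <- toy_fixture()
  ex <- toy_expression()$expr
  rid <- tm$mb$reactions$id[1:20]
  a <- fake_sampling(matrix(stats::rnorm(20 * 50, 0, 1), 20, 50,
                            dimnames = list(rid, NULL)))
  b <- fake_sampling(matrix(stats::rnorm(20 * 50, 2, 1), 20, 50,
                            dimnames = list(rid, NULL)))
  zab <- suppressMessages(compute_z_scores(a, b, ex, "healthy", "MB",
                                           tm$mb))
  zba <- suppressMessages(compute_z_scores(b, a, ex, "MB", "healthy",
                                           tm$mb))
  expect_equal(zab$ZF, -zba$ZF, tolerance = 1e-12)
  expect_equal(zab$ZG_total, -zba$ZG_total, tolerance = 1e-12)
  cab <- classify_regulation(zab)
  cba <- classify_regulation(zba)
  expect_identical(cab$class, cba$class)
  # partition: TR and NTR disjoint, union = flux-altered set
  flux_alt <- abs(cab$ZF) > 1.96
  expect_identical(cab$class %in% c("TR", "NTR"), flux_alt)
})

test_that("planted up-regulated genes score ZG above the critical value
           across seeds", {
  tm <- toy_fixture()
  up <- tm$ground_truth$planted_up_genes
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    ex <- generate_expression_series(expression_spec(
      genes = tm$mb$genes, planted_up = up,
      planted_down = tm$ground_truth$gimme_absent_genes), seed = seed)
    zg <- mbgem:::gene_z_scores(ex$expr, "healthy", "MB")
    hits <- hits + all(zg[up] > 1.96)
  }
  expect_gte(hits / n_seeds, 0.95)
})
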