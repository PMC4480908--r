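test_that("the same seed reproduces a dataset exactly", {
  cfg <- simulation_config(n_genes = 1000, n_responsive = 80, seed = 5)
  expect_identical(simulate_experiment(cfg), simulate_experiment(cfg))
  cfg2 <- simulation_config(n_genes = 1000, n_responsive = 80, seed = 6)
  expect_false(identical(simulate_experiment(cfg)$truth,
                         simulate_experiment(cfg2)$truth))
})

test_that("odds of 1 is the null and infeasible targets are rejected", {
  expect_equal(odds_for_rf(1, 500, 300, 5000), 1, tolerance = 1e-12)
  expect_gt(odds_for_rf(2, 500, 300, 5000), 1)
  expect_lt(odds_for_rf(0.5, 500, 300, 5000), 1)
  expect_error(odds_for_rf(10, 500, 3000, 5000), "infeasible")
  cfg_null <- simulation_config(n_genes = 2000, n_responsive = 100,
                                target_rf = 1, seed = 1)
  expect_equal(cfg_null$enrichment_odds, 1, tolerance = 1e-12)
})

test_that("PCGT component sets respect the all/any lattice", {
  cfg <- simulation_config(n_genes = 4000, n_responsive = 200, seed = 9)
  ds <- simulate_experiment(cfg, layers = "pcgt")
  s <- ds$pcgt_sets
  for (comp in c("suz12", "eed", "phc1", "rnf2")) {
    expect_true(all(s$all %in% s[[comp]]))
    expect_true(all(s[[comp]] %in% s$any))
  }
  expect_equal(length(s$any), round(cfg$n_genes * cfg$pcgt_fraction))
  expect_setequal(s$any, combine_gene_sets(s[1:4], "at_least_one"))
  expect_setequal(s$all, combine_gene_sets(s[1:4], "all"))
})

test_that("realised PCGT bias converges to the planted RF across sizes", {
  for (n_genes in c(5000, 10000, 20000)) {
    rfs <- vapply(1:20, function(s) {
      cfg <- simulation_config(n_genes = n_genes,
                               n_responsive = round(n_genes * 0.08),
                               target_rf = 1.5, seed = s)
      ds <- simulate_experiment(cfg, layers = c("pcgt", "truth"))
      truth_pos <- ds$truth$gene_id[ds$truth$class == "positive"]
      gene_set_enrichment(truth_pos, ds$pcgt_sets$any,
                          ds$truth$gene_id)$rf
    }, 0)
    expect_equal(mean(rfs), 1.5, tolerance = 0.08)
  }
})

test_that("generated library totals respect the configured library size", {
  cfg <- simulation_config(n_genes = 3000, n_responsive = 200,
                           library_size = 5e5, seed = 12)
  ds <- simulate_experiment(cfg)
  totals <- colSums(ds$seq_counts$counts)
  # NB sums concentrate around the nominal library size
  expect_true(all(abs(totals - cfg$library_size) / cfg$library_size < 0.05))
  expect_true(all(ds$seq_counts$counts >= 0))
})

test_that("truth classes are disjoint with the configured sizes", {
  cfg <- simulation_config(n_genes = 3000, n_responsive = 150, seed = 3)
  ds <- simulate_experiment(cfg, layers = c("pcgt", "truth"))
  expect_equal(sum(ds$truth$class == "positive"), 150)
  expect_equal(sum(ds$truth$class == "negative"), 150)
  expect_equal(sum(ds$truth$class == "none"), 2700)
})

test_that("knockdown and overexpression shift methylation in mirror", {
  cfg <- simulation_config(n_genes = 2000, n_responsive = 150, seed = 8)
  ds <- simulate_experiment(cfg, layers = c("pcgt", "truth", "counts"))
  m <- ds$methylation
  pos <- ds$truth$class == "positive"
  neg <- ds$truth$class == "negative"
  none <- ds$truth$class == "none"
  expect_true(all(m[pos, "kd_si1"] < m[pos, "kd_control"]))
  expect_true(all(m[pos, "oe"] > m[pos, "oe_control"]))
  expect_true(all(m[neg, "kd_si1"] > m[neg, "kd_control"]))
  expect_true(all(m[neg, "oe"] < m[neg, "oe_control"]))
  expect_equal(m[none, "kd_si1"], m[none, "kd_control"])
  expect_true(all(m > 0 & m < 1))
})

test_that("array scores separate present from absent genes", {
  cfg <- simulation_config(n_genes = 2000, n_responsive = 150, seed = 4)
  ds <- simulate_experiment(cfg, layers = c("pcgt", "truth", "array"))
  s <- ds$array_scores$kd_control
  present <- ds$methylation[, "kd_control"] > cfg$presence_threshold
  expect_gt(mean(s[present, ]), mean(s[!present, ]) + 1)
  expect_equal(ncol(s), cfg$replicate_count)
})

test_that("end-to-end recovery finds the planted structure on a small run", {
  # library size scaled with gene count to keep per-gene depth at the
  # default ~100 fragments
  cfg <- simulation_config(n_genes = 4000, n_responsive = 320,
                           library_size = 4e5, seed = 21)
  rep <- end_to_end_recovery(cfg)
  expect_gt(rep$metrics$seq$sensitivity, 0.8)
  expect_gt(rep$metrics$array$sensitivity, 0.5)
  expect_gt(rep$metrics$seq$specificity, 0.8)
  # recovered lists are enriched for the planted PCGT bias
  any_rows <- rep$table1[rep$table1$target == "any", ]
  expect_true(all(any_rows$rf > 1.2))
  # the two arms share far more genes than chance
  expect_gt(rep$cross_line$positive$observed,
            rep$cross_line$positive$expected)
  expect_lt(rep$cross_line$positive$p_chi2, 1e-6)
})
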