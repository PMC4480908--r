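ct_records <- function(treated_target = 25, control_target = 24,
                       refs = c(GAPDH = 20, TOP1 = 22)) {
  rbind(
    data.frame(sample_id = "treated", target = "GENE", ct = treated_target),
    data.frame(sample_id = "treated", target = names(refs), ct = unname(refs)),
    data.frame(sample_id = "control", target = "GENE", ct = control_target),
    data.frame(sample_id = "control", target = names(refs), ct = unname(refs))
  )
}

test_that("delta-delta-Ct reproduces the hand-worked example", {
  res <- delta_delta_ct(ct_records(), c("GAPDH", "TOP1"), "treated", "control")
  expect_equal(res$delta_delta_ct, 1.0)
  expect_equal(res$fold, 0.5)
})

test_that("identical measurements give fold 1 and lowering Ct doubles fold", {
  same <- delta_delta_ct(ct_records(24, 24), c("GAPDH", "TOP1"),
                         "treated", "control")
  expect_equal(same$fold, 1)
  base <- delta_delta_ct(ct_records(25, 24), c("GAPDH", "TOP1"),
                         "treated", "control")
  minus1 <- delta_delta_ct(ct_records(24, 24), c("GAPDH", "TOP1"),
                           "treated", "control")
  expect_equal(minus1$fold, 2 * base$fold)
})

test_that("delta-delta-Ct is antisymmetric in treated/control", {
  fwd <- delta_delta_ct(ct_records(), c("GAPDH", "TOP1"), "treated", "control")
  rev <- delta_delta_ct(ct_records(), c("GAPDH", "TOP1"), "control", "treated")
  expect_equal(fwd$fold * rev$fold, 1)
  expect_equal(fwd$delta_delta_ct, -rev$delta_delta_ct)
})

test_that("replicate Cts are averaged and missing references are errors", {
  rec <- rbind(ct_records(), data.frame(sample_id = "treated",
                                        target = "GENE", ct = 27))
  res <- delta_delta_ct(rec, c("GAPDH", "TOP1"), "treated", "control")
  expect_equal(res$delta_delta_ct, 2.0)  # mean(25, 27) - refs vs control
  rec2 <- ct_records()
  rec2 <- rec2[!(rec2$sample_id == "control" & rec2$target == "TOP1"), ]
  expect_error(delta_delta_ct(rec2, c("GAPDH", "TOP1"), "treated", "control"),
               "control.*TOP1")
})

test_that("spike-in fold enrichment follows the four-Ct arithmetic", {
  # hand evaluation: 2^7 / 2^0.5
  expect_equal(spikein_fold_enrichment(25, 18, 25, 24.5),
               128 / sqrt(2), tolerance = 1e-12)
  expect_equal(spikein_fold_enrichment(25, 20, 25, 20), 1)
  # invariant under adding a constant to all four Cts
  expect_equal(spikein_fold_enrichment(25, 18, 25, 24.5),
               spikein_fold_enrichment(30, 23, 30, 29.5))
})

test_that("spike-in estimate recovers a true 1000-fold preference", {
  cfg <- simulation_config(n_genes = 200, n_responsive = 10, seed = 19)
  ds <- simulate_experiment(cfg, layers = "qpcr")
  ct <- ds$ct_tables$spike
  m <- function(target, fraction) {
    mean(ct$ct[ct$target == target & ct$fraction == fraction])
  }
  est <- spikein_fold_enrichment(m("lambda_meth", "input"),
                                 m("lambda_meth", "enriched"),
                                 m("lambda_unmeth", "input"),
                                 m("lambda_unmeth", "enriched"))
  # Ct noise sd 0.15 over 3 replicates: a ~2 sd log2 band around 1000
  expect_gt(est, 1000 * 2^-0.5)
  expect_lt(est, 1000 * 2^0.5)
})

test_that("flat groups give ANOVA p near 1; degenerate variance errors", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- anova_dunnett(g, n_mc = 2000, seed = 2)
  expect_equal(res$p_anova, 1)
  expect_true(all(res$comparisons$p_adjusted > 0.99))
  expect_error(anova_dunnett(list(c(1, 1), c(2, 2)), n_mc = 100),
               "zero within-group variance")
})

test_that("Dunnett adjustment dominates the unadjusted t comparison", {
  set.seed(14)
  for (i in 1:10) {
    g <- list(rnorm(5), rnorm(5, 0.8), rnorm(5, -0.3), rnorm(5))
    res <- anova_dunnett(g, n_mc = 4000, seed = i)
    expect_true(all(res$comparisons$p_adjusted >=
                      res$comparisons$p_unadjusted - 0.01))
  }
})

test_that("Monte Carlo Dunnett agrees with the multcomp implementation", {
  skip_if_not_installed("multcomp")
  set.seed(3)
  y <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 0.3))
  grp <- factor(rep(c("ctrl", "t1", "t2"), each = 6))
  fit <- stats::aov(y ~ grp)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  ours <- anova_dunnett(split(y, grp), control_index = 1,
                        n_mc = 2e5, seed = 7)
  expect_equal(ours$comparisons$p_adjusted,
               as.numeric(mc$test$pvalues), tolerance = 0.01)
})

test_that("Monte Carlo Dunnett p stabilises as n_mc grows", {
  set.seed(3)
  y <- c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 0.3))
  grp <- factor(rep(c("ctrl", "t1", "t2"), each = 6))
  a <- anova_dunnett(split(y, grp), 1, n_mc = 1e5, seed = 11)
  b <- anova_dunnett(split(y, grp), 1, n_mc = 2e5, seed = 12)
  expect_true(all(abs(a$comparisons$p_adjusted -
                        b$comparisons$p_adjusted) < 0.005))
})
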