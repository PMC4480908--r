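test_that("Yates chi-square matches hand evaluations of the closed formula", {
  # exact independence: correction floors the statistic at zero
  flat <- yates_chi_square(contingency_table(10, 10, 10, 10))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  # hand evaluation: n=50, |ad-bc|-n/2 = 350, denominator 25^4
  strong <- yates_chi_square(contingency_table(20, 5, 5, 20))
  expect_equal(strong$chi2, 15.68, tolerance = 1e-9)
  expect_equal(strong$p, pchisq(15.68, 1, lower.tail = FALSE))
  # cross-line overlap margins embedded in a 40000-gene universe
  fig2 <- yates_chi_square(contingency_table(139, 1415, 1706, 36740))
  expect_gt(fig2$chi2, 60)
  expect_lt(fig2$p, 1e-15)
})

test_that("zero margins are rejected with advice to use the exact test", {
  expect_error(yates_chi_square(contingency_table(0, 0, 5, 5)), "exact")
})

test_that("low expected cells trigger a warning in the result", {
  res <- yates_chi_square(contingency_table(2, 3, 3, 40))
  expect_match(res$warnings, "expected cell")
})

test_that("the exact overlap p agrees with an independent oracle", {
  # independent oracle: Fisher's exact test on the same tables
  for (cells in list(c(10, 10, 20, 60), c(3, 7, 12, 50), c(25, 5, 8, 30))) {
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    oracle <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(exact_overlap_p(t), oracle, tolerance = 1e-9)
  }
  # a table at exact independence has p = 1
  expect_equal(exact_overlap_p(contingency_table(10, 10, 10, 10)), 1)
})

test_that("representation factor arithmetic and guards", {
  rf <- representation_factor(10, 20, 30, 100)
  expect_equal(rf$expected, 6)
  expect_equal(rf$rf, 10 / 6)
  # overlap equal to expectation gives rf = 1
  expect_equal(representation_factor(6, 20, 30, 100)$rf, 1)
  # margins from the cross-line comparison under an assumed universe
  fig2 <- representation_factor(139, 1554, 1845, 40000)
  expect_equal(fig2$expected, 1554 * 1845 / 40000)
  expect_equal(fig2$rf, 1.94, tolerance = 0.005)
  expect_error(representation_factor(25, 20, 30, 100), "exceeds")
  expect_error(representation_factor(1, 60, 70, 100), "impossible")
})

test_that("rf times expected reproduces the observed count exactly", {
  set.seed(5)
  for (i in 1:200) {
    N <- sample(50:5000, 1)
    sa <- sample(1:(N - 1), 1)
    sb <- sample(1:(N - 1), 1)
    obs <- sample(max(0, sa + sb - N):min(sa, sb), 1)
    rf <- representation_factor(obs, sa, sb, N)
    expect_equal(rf$rf * rf$expected, obs)
    expect_equal(rf$rf > 1, obs > rf$expected)
  }
})

test_that("Yates correction never exceeds the uncorrected statistic", {
  tables <- random_tables(100, seed = 19)
  for (t in tables) {
    y <- yates_chi_square(t)
    m <- matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE)
    un <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_lte(y$chi2, un$statistic + 1e-9)
    expect_gte(y$p, un$p.value - 1e-9)
    # transposition and simultaneous row/column swap leave chi2 unchanged
    tr <- yates_chi_square(contingency_table(t$a, t$c, t$b, t$d))
    sw <- yates_chi_square(contingency_table(t$d, t$c, t$b, t$a))
    expect_equal(tr$chi2, y$chi2, tolerance = 1e-12)
    expect_equal(sw$chi2, y$chi2, tolerance = 1e-12)
  }
})

test_that("gene_set_enrichment builds the table from id sets", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:20]
  target <- universe[11:40]
  er <- gene_set_enrichment(query, target, universe)
  expect_equal(er$observed, 10)
  expect_equal(er$rf, 10 / 6)
  expect_equal(er$chi2, 3.646, tolerance = 5e-4)
  expect_equal(er$p_chi2, 0.056, tolerance = 0.01)
  expect_equal(er$universe_size, 100)
  # target ids outside the universe are ignored
  er2 <- gene_set_enrichment(query, c(target, "nope"), universe)
  expect_equal(er2$observed, er$observed)
  expect_error(gene_set_enrichment(character(), target, universe), "empty query")
  expect_error(gene_set_enrichment(query, target, character()), "empty universe")
  expect_error(gene_set_enrichment("alien", target, universe), "outside")
})

test_that("perfect overlap maximises rf; random queries are null on average", {
  universe <- sprintf("u%03d", 1:200)
  target <- universe[1:40]
  er <- gene_set_enrichment(target, target, universe)
  expect_equal(er$rf, length(universe) / length(target))
  expect_lt(er$p_exact, 1e-12)
  set.seed(29)
  rfs <- replicate(1000, {
    gene_set_enrichment(sample(universe, 50), target, universe)$rf
  })
  expect_equal(mean(rfs), 1.0, tolerance = 0.03)
})

test_that("gene-set combinators respect the intersection/union lattice", {
  expect_equal(combine_gene_sets(list(c("g1", "g2"), c("g2", "g3")), "all"),
               "g2")
  expect_setequal(
    combine_gene_sets(list(c("g1", "g2"), c("g2", "g3")), "at_least_one"),
    c("g1", "g2", "g3"))
  set.seed(4)
  pool <- sprintf("g%03d", 1:150)
  comps <- replicate(4, sample(pool, 60), simplify = FALSE)
  all_t <- combine_gene_sets(comps, "all")
  any_t <- combine_gene_sets(comps, "at_least_one")
  expect_lte(length(all_t), min(lengths(comps)))
  expect_gte(length(any_t), max(lengths(comps)))
  expect_true(all(all_t %in% any_t))
})

test_that("cross-list overlap reproduces the printed-margin arithmetic", {
  pos <- cross_list_overlap(sprintf("a%04d", 1:1554),
                            c(sprintf("a%04d", 1:139), sprintf("b%04d", 1:1706)),
                            universe_size = 40000)
  expect_equal(pos$observed, 139)
  expect_equal(pos$rf, 1.94, tolerance = 0.005)
  expect_lt(pos$p_chi2, 1e-15)
  neg <- overlap_enrichment(49, 1475, 873, 39000)
  expect_gt(neg$p_chi2, 0.004)
  expect_lt(neg$p_chi2, 0.007)
  # overlap equal to expectation: rf 1, p near 1
  nul <- overlap_enrichment(6, 20, 30, 100)
  expect_equal(nul$rf, 1)
  expect_gt(nul$p_chi2, 0.9)
})

test_that("GMT and plain gene lists round-trip", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1", "justname"), bad)
  expect_error(read_gmt(bad), "line 2")
  lst <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "g1", "g2", "", "g1"), lst)
  expect_equal(read_gene_list(lst), c("g1", "g2"))
})
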