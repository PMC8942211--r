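# Exact-test core and the 25-class enrichment scan.

test_that("fisher_exact matches the enumeration oracle on derived tables", {
  # symmetric table
  r <- fisher_exact(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  # enumerated by brute force over margins (4,4,4,4): p = 34/70
  r2 <- fisher_exact(3, 1, 1, 3)
  expect_equal(r2$p, fisher_p_oracle(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(r2$p, 0.485714285714286, tolerance = 1e-10)
  # agrees with the independent stats::fisher.test p-value
  for (tb in list(c(10, 3, 2, 15), c(1, 9, 11, 3), c(12, 2, 380, 92314))) {
    expect_equal(fisher_exact(tb[1], tb[2], tb[3], tb[4])$p,
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(0, 0, 0, 0), "degenerate")
})

test_that("fisher p is exact for random tables and invariant to swaps", {
  set.seed(7)
  for (i in 1:200) {
    tb <- as.integer(stats::rmultinom(1, sample(2:40, 1), rep(0.25, 4)))
    if (sum(tb) == 0) next
    p <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p
    expect_equal(p, fisher_p_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    # simultaneous row and column swap leaves p unchanged
    expect_equal(fisher_exact(tb[4], tb[3], tb[2], tb[1])$p, p,
                 tolerance = 1e-12)
    if (all(tb > 0)) {
      or1 <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$odds_ratio
      or2 <- fisher_exact(tb[2], tb[1], tb[4], tb[3])$odds_ratio
      expect_equal(or1 * or2, 1, tolerance = 1e-12)
    }
  }
})

test_that("woolf_ci evaluates the closed form and contains the OR", {
  ci <- woolf_ci(10, 10, 5, 20)
  se <- sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 20)
  expect_equal(ci$ci_low, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(ci$ci_high, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-12)
  # symmetric about 1 on the log scale for the symmetric table
  ci2 <- woolf_ci(5, 5, 5, 5)
  expect_equal(log(ci2$ci_low), -log(ci2$ci_high), tolerance = 1e-12)
  # containment, including zero-cell (Haldane-Anscombe) tables
  set.seed(3)
  for (i in 1:50) {
    tb <- sample(0:30, 4, replace = TRUE)
    if (sum(tb) == 0) next
    est <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$odds_ratio
    ci <- woolf_ci(tb[1], tb[2], tb[3], tb[4])
    expect_true(ci$ci_low <= est && est <= ci$ci_high)
  }
})

test_that("bonferroni caps at 1 and floors reported q at 1e-100", {
  expect_equal(bonferroni(0.001, 25)$q, 0.025)
  expect_equal(bonferroni(0.2, 25)$q, 1)
  b <- bonferroni(1e-120, 25)
  expect_equal(b$q, 1e-100)
  expect_true(b$q_floored)
  expect_true(all(bonferroni(c(0.5, 1e-3))$q >= c(0.5, 1e-3)))
})

test_that("classify_association applies the OR/q rule", {
  expect_equal(classify_association(3.2, 1e-100), "class_a_enriched")
  expect_equal(classify_association(0.05, 1.8e-05), "class_b_enriched")
  expect_equal(classify_association(1.4, 0.2), "none")
  expect_equal(classify_association(0.5, 0.049), "class_b_enriched")
})

test_that("contingency_for_feature counts covered residues once per class", {
  p <- make_proteins(10, "P1")
  part <- build_partition(p, make_regions("P1", 3L, 5L))
  f <- make_features("P1", "motif", 4L, 8L)
  ct <- contingency_for_feature(part, f, "motif")
  expect_equal(unlist(ct[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 1L, 3L, 4L))
  # duplicated annotation of the same class does not double-count
  ct2 <- contingency_for_feature(part, dplyr::bind_rows(f, f), "motif")
  expect_equal(ct2$a, 2L)
  # absent class: a = c = 0 with full margins
  ct3 <- contingency_for_feature(part, f, "domain")
  expect_equal(unlist(ct3[, c("a", "b", "c", "d")], use.names = FALSE),
               c(0L, 3L, 0L, 7L))
})

test_that("enrichment_scan returns 25 rows and survives absent features", {
  p <- make_proteins(60, "P1")
  part <- build_partition(p, make_regions("P1", 1L, 20L))
  f <- make_features("P1", "motif", c(2L, 30L), c(6L, 35L))
  e <- enrichment_scan(part, f)
  expect_equal(nrow(e), 25)
  expect_equal(sum(!e$degenerate), 1)
  expect_true(all(e$call[e$degenerate] == "none"))
  expect_true(all(is.na(e$p[e$degenerate])))
  # empty class errors
  empty_part <- build_partition(p, make_regions("P1", integer(), integer()))
  expect_error(enrichment_scan(empty_part, f), "non-empty")
})

test_that("enrichment_scan recovers a planted odds ratio", {
  # one protein: 10k DR + 40k NR residues; single class planted at OR 3 over
  # a 2% background; remaining classes left unannotated
  spec <- tibble::tibble(feature_class = "motif", baseline_rate = 0.02,
                         target_or = 3, interval_length = 1L)
  p <- make_proteins(50000, "P1")
  part <- build_partition(p, make_regions("P1", 1L, 10000L))
  hits <- 0
  for (s in 1:20) {
    f <- plant_features(p, part, spec, seed = 1000 + s)
    e <- enrichment_scan(part, f, classes = "motif", m = 25)
    if (e$call == "class_a_enriched" && e$odds_ratio > 2.4 &&
          e$odds_ratio < 3.7) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("null partitions stay at the nominal per-test call rate", {
  # identical 2% feature rate in both classes; over 60 replicate scans of
  # 25 tests each, the fraction of q < 0.05 calls must stay at or below
  # alpha (Bonferroni makes it far smaller)
  set.seed(99)
  n_a <- 5000
  n_b <- 25000
  calls <- 0
  for (rep in 1:60) {
    for (j in 1:25) {
      a <- rbinom(1, n_a, 0.02)
      c_ <- rbinom(1, n_b, 0.02)
      ft <- fisher_exact(a, n_a - a, c_, n_b - c_)
      if (bonferroni(ft$p, 25)$q < 0.05) calls <- calls + 1
    }
  }
  expect_lte(calls / (60 * 25), 0.05)
})

test_that("median_feature_content computes per-cell medians over regions", {
  p <- make_proteins(c(10, 10, 10), c("A", "B", "C"))
  reg <- dplyr::bind_rows(
    make_regions("A", 1L, 10L), # fully covered: content 1.0
    make_regions("B", 1L, 10L), # motif 2-3: content 0.2
    make_regions("C", 1L, 10L)  # motif 1-5: content 0.5
  )
  reg$function_category <- c("inhibitor", "inhibitor", "inhibitor")
  f <- dplyr::bind_rows(
    make_features("A", "region_of_interest", 1L, 10L),
    make_features("B", "motif", 2L, 3L),
    make_features("C", "motif", 1L, 5L)
  )
  mc <- median_feature_content(reg, f, p, "function")
  roi <- mc[mc$feature_class == "region_of_interest", ]
  expect_equal(roi$median_content, 1.0)
  expect_equal(roi$n_regions, 1L)
  motif <- mc[mc$feature_class == "motif", ]
  expect_equal(motif$median_content, 0.35) # even count: mean of 0.2, 0.5
  expect_equal(motif$n_regions, 2L)

  # odd-count median and multi-label categories
  reg2 <- make_regions("A", c(1L, 1L, 6L), c(4L, 8L, 10L),
                       region_id = c("r1", "r2", "r3"))
  reg2$partner_category <- c("protein binding",
                             "protein binding;ion binding",
                             "protein binding")
  f2 <- make_features("A", "motif", 1L, 4L) # contents 1, 0.5, 0
  mc2 <- median_feature_content(reg2, f2, p, "partner")
  pb <- mc2[mc2$category == "protein binding", ]
  expect_equal(pb$n_regions, 2L) # r3 has zero covered residues: excluded
  expect_equal(pb$median_content, 0.75)
  expect_equal(mc2$n_regions[mc2$category == "ion binding"], 1L)
})
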