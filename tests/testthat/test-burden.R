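# Variant-to-region assignment, ratios, strata, association, fractions.

test_that("length_stratum uses the <=30 / <=100 boundaries", {
  expect_equal(as.character(length_stratum(c(1, 30, 31, 100, 101))),
               c("short", "short", "medium", "medium", "long"))
})

test_that("variants are assigned by anchor residue to every covering region", {
  p <- make_proteins(400, "MECP2")
  reg <- make_regions("MECP2", c(207L, 261L), c(310L, 330L),
                      region_id = c("rA", "rB"))
  # frameshift at 250: inside rA only (250 < 261)
  v1 <- make_variants("MECP2", 250L, "frameshift", source = "pathogenic_db",
                      allele_count = NA, significance = "pathogenic")
  b1 <- region_variant_counts(reg, v1, p)
  expect_equal(b1$n_path_frameshift, c(1L, 0L))
  # missense at 270: nested in both regions -> both increment
  v2 <- make_variants("MECP2", 270L, "missense")
  b2 <- region_variant_counts(reg, v2, p)
  expect_equal(b2$n_pop_missense, c(1L, 1L))
  expect_equal(b2$n_mis, b2$n_pop_missense)
  # contribution conservation: total region increments = covering regions
  expect_equal(sum(b2$n_pop_missense),
               sum(reg$start <= 270 & reg$end >= 270))
  expect_error(region_variant_counts(reg, make_variants("MECP2", 500L,
                                                        "missense"), p),
               "beyond protein length")
})

test_that("pathogenic counts exclude VUS/benign but fractions keep them", {
  p <- make_proteins(100, "P1")
  reg <- make_regions("P1", 10L, 60L, region_id = "r1")
  part <- build_partition(p, reg)
  v <- dplyr::bind_rows(
    make_variants("P1", c(20L, 25L), "missense", source = "pathogenic_db",
                  allele_count = NA, significance = "vus"),
    make_variants("P1", 30L, "missense", source = "pathogenic_db",
                  allele_count = NA, significance = "pathogenic"),
    make_variants("P1", 35L, "missense", source = "pathogenic_db",
                  allele_count = NA, significance = "benign"),
    make_variants("P1", 40L, "missense", source = "population")
  )
  b <- region_variant_counts(reg, v, p)
  expect_equal(b$n_path_missense, 1L) # the single pathogenic record
  expect_equal(b$n_pop_missense, 1L)
  fr <- clinical_class_fractions(part, v)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$significance == "vus"], 0.5)
  expect_equal(fr$n[fr$significance == "vus"], 2L)
})

test_that("clinical fractions hand-tally on a mixed fixture and DR scope", {
  p <- make_proteins(200, "P1")
  part <- build_partition(p, make_regions("P1", 1L, 100L))
  sig <- c(rep("pathogenic", 10), "vus", "benign")
  v <- make_variants("P1", c(1:10, 50L, 60L) * 1L,
                     c(rep("nonsense", 10), "missense", "missense"),
                     source = "pathogenic_db", allele_count = NA,
                     significance = sig)
  # plus one pathogenic missense OUTSIDE the disordered region: excluded
  v <- dplyr::bind_rows(v, make_variants("P1", 150L, "missense",
                                         source = "pathogenic_db",
                                         allele_count = NA,
                                         significance = "pathogenic"))
  fr <- clinical_class_fractions(part, v)
  expect_equal(fr$fraction[fr$vtype == "nonsense"], 1) # unanimity
  mis <- fr[fr$vtype == "missense", ]
  expect_equal(sort(mis$fraction), c(0.5, 0.5)) # 1 vus + 1 benign, DR only
})

test_that("mis_syn_ratio guards division and burden_summary excludes NA", {
  expect_equal(mis_syn_ratio(10, 5), 2)
  expect_equal(mis_syn_ratio(0, 4), 0)
  expect_true(is.na(mis_syn_ratio(3, 0)))

  counts <- tibble::tibble(
    region_id = c("a", "b", "c"),
    length = c(10L, 50L, 120L),
    n_mis = c(10L, 3L, 8L), n_syn = c(5L, 0L, 4L),
    mis_syn_ratio = mis_syn_ratio(c(10, 3, 8), c(5, 0, 4)),
    stratum = length_stratum(c(10, 50, 120))
  )
  s <- burden_summary(counts)
  expect_equal(s$n_regions[s$stratum == "all"], 3L)
  expect_equal(s$n_defined[s$stratum == "all"], 2L)
  expect_equal(s$mean[s$stratum == "all"], 2)
  expect_equal(s$max[s$stratum == "all"], 2)
  expect_true(is.na(s$mean[s$stratum == "medium"])) # only the n_syn=0 region
  expect_equal(sum(s$n_regions[s$stratum != "all"]),
               s$n_regions[s$stratum == "all"])
})

test_that("partition totals split variants by residue class without loss", {
  p <- make_proteins(100, "P1")
  part <- build_partition(p, make_regions("P1", 1L, 40L))
  v <- dplyr::bind_rows(
    make_variants("P1", c(10L, 20L, 80L), "missense"),
    make_variants("P1", c(30L, 90L), "synonymous")
  )
  tot <- partition_variant_totals(part, v)
  mis <- tot[tot$vtype == "missense", ]
  expect_equal(c(mis$n_class_a, mis$n_class_b), c(2L, 1L))
  expect_equal(sum(tot$n_class_a) + sum(tot$n_class_b), nrow(v))
})

test_that("population_association reproduces the published 2x2 and strata", {
  r <- association_from_counts(41691, 20282, 176888, 92314)
  expect_equal(round(r$odds_ratio, 1), 1.1)
  expect_equal(r$p, 1.12e-13, tolerance = 0.01)
  expect_equal(r$call, "class_a_enriched")

  # equal rates -> OR ~ 1, no call; AC strata filter correctly
  p <- make_proteins(1000, "P1")
  part <- build_partition(p, make_regions("P1", 1L, 500L))
  set.seed(5)
  v <- dplyr::bind_rows(
    make_variants("P1", sample(1000, 400, TRUE), "missense",
                  allele_count = rep(c(1L, 3L), 200)),
    make_variants("P1", sample(1000, 400, TRUE), "synonymous",
                  allele_count = rep(c(1L, 3L), 200))
  )
  ra <- population_association(part, v)
  expect_equal(ra$call, "none")
  rs <- population_association(part, v, "singleton")
  expect_equal(rs$a + rs$b + rs$c + rs$d, 400)
  rm_ <- population_association(part, v, "multiton")
  expect_equal(rm_$a + rm_$b + rm_$c + rm_$d, 400)
})

test_that("a planted 10% DR missense excess is recovered within the CI", {
  # Poisson counts at the scale of the real cohort (300k residues), planted
  # odds ratio 1.1; the Woolf CI should cover 1.1 in ~95% of replicates
  set.seed(21)
  hits <- 0
  for (rep in 1:100) {
    a <- rpois(1, 50000 * 0.15 * 1.1) # DR missense
    b <- rpois(1, 50000 * 0.15)       # DR synonymous
    c_ <- rpois(1, 250000 * 0.15)     # NR missense
    d <- rpois(1, 250000 * 0.15)      # NR synonymous
    r <- association_from_counts(a, b, c_, d)
    if (r$ci_low <= 1.1 && 1.1 <= r$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("mean defined ratio converges to the planted rate ratio", {
  # uniform per-residue rates: missense rho*lambda vs synonymous lambda
  set.seed(13)
  lambda <- 40
  rho <- 2.3
  n_mis <- rpois(300, rho * lambda)
  n_syn <- rpois(300, lambda)
  r <- mis_syn_ratio(n_mis, n_syn)
  expect_equal(mean(r, na.rm = TRUE), rho, tolerance = 0.05)
})
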