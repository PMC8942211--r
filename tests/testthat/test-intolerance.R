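# The three-condition median-threshold intolerance rule.

paper_path <- list(missense = 2, nonsense = 2, frameshift = 2, inframe = 2)

test_that("compute_thresholds takes per-type medians over all regions", {
  counts <- make_counts(
    c("a", "b", "c"),
    path = list(missense = c(0L, 2L, 9L), nonsense = c(0L, 0L, 0L),
                frameshift = c(0L, 2L, 9L), inframe = c(1L, 1L, 1L)),
    pop = list(missense = c(10L, 22L, 40L), nonsense = c(0L, 1L, 2L),
               frameshift = c(0L, 0L, 0L), inframe = c(2L, 2L, 2L))
  )
  th <- compute_thresholds(counts)
  expect_equal(th$median_pathogenic[th$vtype == "frameshift"], 2)
  expect_equal(th$median_population[th$vtype == "missense"], 22)
  # even-count median: mean of central order statistics
  counts4 <- make_counts(
    letters[1:4],
    path = list(missense = c(0L, 1L, 3L, 9L), nonsense = rep(0L, 4),
                frameshift = rep(0L, 4), inframe = rep(0L, 4)),
    pop = list(missense = rep(0L, 4), nonsense = rep(0L, 4),
               frameshift = rep(0L, 4), inframe = rep(0L, 4))
  )
  expect_equal(compute_thresholds(counts4)$median_pathogenic[1], 2)
  expect_error(compute_thresholds(counts[0, ]), "zero regions")
})

test_that("the worked missense example is not called intolerant", {
  # 30 pathogenic vs 28 population missense: conditions (i) and (ii) hold
  # but the population count exceeds the cohort median of 22
  counts <- make_counts("r1",
                        path = list(missense = 30L, nonsense = 0L,
                                    frameshift = 0L, inframe = 0L),
                        pop = list(missense = 28L, nonsense = 0L,
                                   frameshift = 0L, inframe = 0L))
  calls <- classify_regions(counts, reference_thresholds())
  expect_equal(calls$missense, "neither")
})

test_that("published catalogue rows classify per their starred types", {
  th <- reference_thresholds()
  # MECP2 207-310: frameshift 77/0, nonsense 13/0, missense 14/60, inframe 4/0
  mecp2 <- make_counts("MECP2:207-310",
                       path = list(missense = 14L, nonsense = 13L,
                                   frameshift = 77L, inframe = 4L),
                       pop = list(missense = 60L, nonsense = 0L,
                                  frameshift = 0L, inframe = 0L))
  c1 <- classify_regions(mecp2, th)
  expect_equal(c1$frameshift, "intolerant")
  expect_equal(c1$nonsense, "intolerant")
  expect_equal(c1$inframe, "intolerant")
  expect_equal(c1$missense, "neither") # 60 population > median 22
  expect_equal(c1$overall, "intolerant")
  # BMPR1A 24-54 under the default non-strict mode: frameshift and inframe
  # qualify with pathogenic counts equal to the median
  bmpr1a <- make_counts("BMPR1A:24-54",
                        path = list(missense = 0L, nonsense = 1L,
                                    frameshift = 5L, inframe = 2L),
                        pop = list(missense = 12L, nonsense = 0L,
                                   frameshift = 0L, inframe = 0L))
  c2 <- classify_regions(bmpr1a, th)
  expect_equal(c2$frameshift, "intolerant")
  expect_equal(c2$inframe, "intolerant")
  expect_equal(c2$nonsense, "neither") # 1 < median 2
  expect_equal(c2$missense, "neither")
  # strict mode demotes the equal-to-median inframe count
  c3 <- classify_regions(bmpr1a, th, mode = "strict")
  expect_equal(c3$inframe, "neither")
  expect_equal(c3$frameshift, "intolerant")
  # all-zero region: neither everywhere
  zero <- make_counts("z", path = list(missense = 0L, nonsense = 0L,
                                       frameshift = 0L, inframe = 0L),
                      pop = list(missense = 0L, nonsense = 0L,
                                 frameshift = 0L, inframe = 0L))
  vts <- c("missense", "nonsense", "frameshift", "inframe")
  expect_equal(unlist(classify_regions(zero, th)[1, vts], use.names = FALSE),
               rep("neither", 4))
})

test_that("intolerant and tolerant verdicts never co-occur, calls are
           order-invariant, and intolerance is monotone in N_path", {
  set.seed(31)
  counts <- make_counts(
    sprintf("r%03d", 1:200),
    path = list(missense = rpois(200, 2), nonsense = rpois(200, 1),
                frameshift = rpois(200, 1), inframe = rpois(200, 1)),
    pop = list(missense = rpois(200, 20), nonsense = rpois(200, 2),
               frameshift = rpois(200, 2), inframe = rpois(200, 2))
  )
  th <- compute_thresholds(counts)
  calls <- classify_regions(counts, th)
  for (vt in c("missense", "nonsense", "frameshift", "inframe")) {
    expect_true(all(calls[[vt]] %in% c("intolerant", "tolerant", "neither")))
  }
  # permutation invariance
  perm <- sample(nrow(counts))
  calls_p <- classify_regions(counts[perm, ], th)
  expect_equal(calls_p[order(calls_p$region_id), ],
               calls[order(calls$region_id), ], ignore_attr = TRUE)
  # monotonicity: raising N_path never turns intolerant into not-intolerant
  bump <- counts
  bump$n_path_frameshift <- bump$n_path_frameshift + 5L
  was <- classify_regions(counts, th)$frameshift == "intolerant"
  now <- classify_regions(bump, th)$frameshift == "intolerant"
  expect_true(all(now[was]))
})

test_that("summarize_calls counts verdicts and orders region ids", {
  counts <- make_counts(
    c("b", "a", "c"),
    path = list(missense = c(0L, 30L, 0L), nonsense = c(0L, 0L, 0L),
                frameshift = c(5L, 0L, 0L), inframe = c(0L, 0L, 0L)),
    pop = list(missense = c(0L, 2L, 40L), nonsense = c(0L, 0L, 0L),
               frameshift = c(0L, 0L, 0L), inframe = c(0L, 0L, 0L))
  )
  s <- summarize_calls(classify_regions(counts, reference_thresholds()))
  expect_equal(s$n_intolerant, 2L)
  expect_equal(s$intolerant_ids, c("a", "b")) # sorted
  expect_equal(s$n_by_vtype$n_intolerant[
    s$n_by_vtype$vtype == "missense"], 1L)
  expect_equal(s$n_by_vtype$n_intolerant[
    s$n_by_vtype$vtype == "frameshift"], 1L)
  expect_equal(s$tolerant_ids, "c") # 40 population missense, 0 pathogenic
})

test_that("planted intolerant regions are recovered with high sensitivity", {
  # pathogenic rate 6 per type in planted regions, full population
  # suppression; thresholds recomputed from each replicate cohort
  cfg <- synthetic_config(
    n_proteins = 25,
    pathogenic_rates = c(missense = 6, nonsense = 6, frameshift = 6,
                         inframe = 6),
    population_suppression = 0, n_intolerant_planted = 8)
  sens <- double(20)
  false_pos <- 0
  for (s in seq_len(20)) {
    d <- simulate_idr_dataset(cfg, seed = 5000 + s)
    b <- region_variant_counts(d$regions, d$variants, d$proteins)
    calls <- classify_regions(b, compute_thresholds(b))
    got <- summarize_calls(calls)$intolerant_ids
    planted <- d$truth$planted_intolerant_ids
    sens[s] <- mean(planted %in% got)
    # non-planted regions called intolerant only when they overlap a
    # planted region (shared pathogenic variants)
    planted_cov <- residue_coverage(
      d$proteins, d$regions[d$regions$region_id %in% planted, ])
    extra <- setdiff(got, planted)
    for (id in extra) {
      rr <- d$regions[d$regions$region_id == id, ]
      overlaps <- any(planted_cov[[rr$accession]][rr$start:rr$end])
      if (!overlaps) false_pos <- false_pos + 1
    }
  }
  expect_gte(mean(sens), 0.9)
  expect_equal(false_pos, 0)
})
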