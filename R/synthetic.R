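# Seeded synthetic proteome generator. Emulates the statistical structure of
# the real inputs -- region placement on proteins, per-residue feature
# annotation with a controllable disordered-vs-ordered odds ratio, and
# per-region variant counts with planted pathogenic enrichment and population
# suppression -- with known ground truth, so every pipeline stage is testable
# without any database access. Per-residue Bernoulli (features) and Poisson
# (variants) models are deliberately the simplest structure sufficient to
# exercise every statistic computed downstream; amino-acid composition and
# mutational opportunity are not modelled.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a cohort sized like the real one in miniature: 300
#' proteins of mean length 600 with one to three disordered regions each
#' (roughly 600 regions), region lengths drawn from the short/medium/long
#' mixture observed in the human IDR cohort (48/32/20%), all 25 feature
#' classes at a 2% per-residue background rate with no planted enrichment,
#' population synonymous rate 0.05 per residue with a 2.3 missense-to-
#' synonymous rate ratio, and 20 planted mutation-intolerant regions.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length_range Uniform range of protein lengths (residues).
#' @param regions_per_protein_range Uniform integer range of regions per
#'   protein.
#' @param region_length_mixture Named weights over `short`/`medium`/`long`.
#' @param region_length_ranges Named list of `c(min, max)` lengths per
#'   stratum.
#' @param p_nested Probability that a region is placed nested inside an
#'   earlier region of the same protein (overlap also arises freely from
#'   uniform placement).
#' @param feature_spec Tibble `feature_class`, `baseline_rate` (per-residue
#'   Bernoulli rate in NR), `target_or` (disordered-vs-ordered odds ratio),
#'   `interval_length` (annotation record length; 1 = point sites). Defaults
#'   to all 25 classes at rate 0.02, OR 1, length 1.
#' @param lambda_syn Population synonymous per-residue Poisson rate.
#' @param rho_mis Missense-to-synonymous rate ratio (population missense rate
#'   is `rho_mis * lambda_syn`).
#' @param rho_other Named rate ratios (vs `lambda_syn`) for population
#'   nonsense/frameshift/inframe variants.
#' @param pathogenic_rates Named per-region Poisson means of pathogenic
#'   variants per mutation type inside planted-intolerant regions (zero
#'   elsewhere).
#' @param population_suppression Multiplier on population rates inside
#'   planted-intolerant regions (0 = fully depleted).
#' @param n_intolerant_planted Number of regions planted as
#'   mutation-intolerant.
#' @return An `idr_sim_config` list.
#' @export
synthetic_config <- function(
    n_proteins = 300,
    protein_length_range = c(300, 900),
    regions_per_protein_range = c(1, 3),
    region_length_mixture = c(short = 0.48, medium = 0.32, long = 0.20),
    region_length_ranges = list(short = c(10, 30), medium = c(31, 100),
                                long = c(101, 250)),
    p_nested = 0.1,
    feature_spec = NULL,
    lambda_syn = 0.05,
    rho_mis = 2.3,
    rho_other = c(nonsense = 0.05, frameshift = 0.05, inframe = 0.1),
    pathogenic_rates = c(missense = 3, nonsense = 4, frameshift = 6,
                         inframe = 3),
    population_suppression = 0.1,
    n_intolerant_planted = 20) {
  if (is.null(feature_spec)) {
    feature_spec <- tibble(feature_class = idr_feature_classes(),
                           baseline_rate = 0.02, target_or = 1,
                           interval_length = 1L)
  }
  stopifnot(
    n_proteins >= 0,
    protein_length_range[1] >= 1,
    protein_length_range[1] <= protein_length_range[2],
    all(feature_spec$baseline_rate >= 0),
    all(feature_spec$baseline_rate < 1),
    all(feature_spec$target_or > 0),
    lambda_syn >= 0, rho_mis >= 0,
    population_suppression >= 0, population_suppression <= 1,
    n_intolerant_planted >= 0,
    abs(sum(region_length_mixture) - 1) < 1e-8
  )
  max_region <- max(vapply(region_length_ranges, max, double(1)))
  if (max_region > protein_length_range[1]) {
    abort("region length range exceeds the minimum protein length")
  }
  structure(
    list(n_proteins = n_proteins,
         protein_length_range = protein_length_range,
         regions_per_protein_range = regions_per_protein_range,
         region_length_mixture = region_length_mixture,
         region_length_ranges = region_length_ranges,
         p_nested = p_nested,
         feature_spec = feature_spec,
         lambda_syn = lambda_syn, rho_mis = rho_mis, rho_other = rho_other,
         pathogenic_rates = pathogenic_rates,
         population_suppression = population_suppression,
         n_intolerant_planted = n_intolerant_planted),
    class = "idr_sim_config"
  )
}

#' Simulate proteins and disordered regions
#'
#' Protein lengths are uniform in the configured range; each region draws a
#' length stratum from the mixture, a length uniform within the stratum, and
#' a start uniform among positions that keep it inside the protein. With
#' probability `p_nested` a region is instead placed inside an earlier region
#' of the same protein, so overlapping and nested rows occur as in real
#' annotation.
#'
#' @param config An `idr_sim_config`.
#' @param seed Integer seed.
#' @return List with `proteins` and `regions` tibbles.
#' @export
simulate_proteome <- function(config, seed = 1) {
  set.seed(seed)
  n <- config$n_proteins
  if (n == 0) {
    return(list(proteins = tibble(accession = character(),
                                  gene = character(), length = integer()),
                regions = tibble(region_id = character(),
                                 accession = character(), gene = character(),
                                 start = integer(), end = integer(),
                                 length = integer())))
  }
  proteins <- tibble(
    accession = sprintf("SYNP%04d", seq_len(n)),
    gene = sprintf("GENE%04d", seq_len(n)),
    length = sample(config$protein_length_range[1]:
                      config$protein_length_range[2], n, replace = TRUE)
  )
  rr <- config$regions_per_protein_range
  strata <- names(config$region_length_mixture)
  regions <- purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(rr[1]:rr[2], 1)
    if (k == 0) return(NULL)
    plen <- proteins$length[i]
    rows <- vector("list", k)
    for (j in seq_len(k)) {
      s <- sample(strata, 1, prob = config$region_length_mixture)
      rng <- config$region_length_ranges[[s]]
      rlen <- sample(rng[1]:min(rng[2], plen), 1)
      prev <- if (j > 1) rows[[j - 1]] else NULL
      if (!is.null(prev) && runif(1) < config$p_nested &&
            (prev$end - prev$start + 1) > rlen) {
        start <- sample(prev$start:(prev$end - rlen + 1), 1)
      } else {
        start <- sample(seq_len(plen - rlen + 1), 1)
      }
      rows[[j]] <- tibble(accession = proteins$accession[i],
                          gene = proteins$gene[i],
                          start = as.integer(start),
                          end = as.integer(start + rlen - 1))
    }
    bind_rows(rows)
  })
  regions <- mutate(regions,
                    region_id = sprintf("SYNR%05d", row_number()),
                    length = .data$end - .data$start + 1L,
                    function_category = NA_character_,
                    partner_category = NA_character_,
                    transition_category = NA_character_,
                    state_category = NA_character_)
  list(proteins = proteins, regions = regions[, .REGION_COLS])
}

#' Plant feature annotations with a target disordered-vs-ordered odds ratio
#'
#' Per class, residues are annotated by independent Bernoulli draws with NR
#' rate `r` and DR rate `r'` chosen so that `odds(r') = target_or * odds(r)`.
#' Maximal runs of annotated residues are merged into interval records (so a
#' planted class with `interval_length = 1` yields point sites and short
#' runs). For classes with `interval_length = L > 1`, seed positions are
#' drawn at rate/L and extended to length-L records clipped at the protein
#' end; the odds-ratio contrast then applies to seed placement rather than
#' exact per-residue coverage.
#'
#' @param proteins Protein tibble.
#' @param partition The DR/NR `idr_partition` of those proteins.
#' @param feature_spec Feature specification (see [synthetic_config()]).
#' @param seed Integer seed.
#' @return Feature tibble in the [read_features()] layout.
#' @export
plant_features <- function(proteins, partition, feature_spec, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(feature_spec)), function(i) {
    r <- feature_spec$baseline_rate[i]
    or <- feature_spec$target_or[i]
    il <- feature_spec$interval_length[i]
    cl <- feature_spec$feature_class[i]
    if (r == 0) return(NULL)
    odds_dr <- or * r / (1 - r)
    r_dr <- odds_dr / (1 + odds_dr)
    if (r >= 0.99 || r_dr >= 0.99) {
      abort(paste0("rate saturation for feature class ", cl))
    }
    purrr::map_dfr(proteins$accession, function(acc) {
      len <- proteins$length[proteins$accession == acc]
      rate <- ifelse(partition$mask[[acc]], r_dr, r) / il
      hit <- runif(len) < rate
      if (!any(hit)) return(NULL)
      if (il > 1) {
        starts <- which(hit)
        tibble(accession = acc, feature_class = cl,
               start = as.integer(starts),
               end = as.integer(pmin(starts + il - 1L, len)),
               description = NA_character_)
      } else {
        runs <- rle(hit)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        keep <- runs$values
        tibble(accession = acc, feature_class = cl,
               start = as.integer(starts[keep]),
               end = as.integer(ends[keep]),
               description = NA_character_)
      }
    })
  })
}

#' Simulate population and pathogenic variants
#'
#' Population variants are per-residue Poisson: synonymous at `lambda_syn`,
#' missense at `rho_mis * lambda_syn`, nonsense/frameshift/inframe at
#' `rho_other * lambda_syn`, all multiplied by `population_suppression` on
#' residues covered by a planted-intolerant region. Allele counts are
#' geometric (so singleton/multiton strata are non-degenerate). Pathogenic
#' variants are Poisson per planted region and mutation type at
#' `pathogenic_rates`, uniform within the region, and zero elsewhere.
#'
#' @param proteins,regions Proteome tibbles ([simulate_proteome()]).
#' @param partition The DR/NR partition of `proteins`/`regions`.
#' @param config An `idr_sim_config`.
#' @param planted_ids Region ids planted as intolerant.
#' @param seed Integer seed.
#' @return Variant tibble in the [read_variants()] layout.
#' @export
simulate_variants <- function(proteins, regions, partition, config,
                              planted_ids, seed = 1) {
  set.seed(seed)
  planted_cov <- residue_coverage(
    proteins, regions[regions$region_id %in% planted_ids, , drop = FALSE])
  pop_rates <- c(synonymous = 1, missense = config$rho_mis,
                 config$rho_other[c("nonsense", "frameshift", "inframe")])
  names(pop_rates) <- c("synonymous", "missense", "nonsense", "frameshift",
                        "inframe")
  pop <- purrr::map_dfr(proteins$accession, function(acc) {
    len <- proteins$length[proteins$accession == acc]
    supp <- ifelse(planted_cov[[acc]], config$population_suppression, 1)
    purrr::map_dfr(names(pop_rates), function(vt) {
      rate <- config$lambda_syn * pop_rates[[vt]] * supp
      total <- sum(rate)
      if (total == 0) return(NULL)
      k <- rpois(1, total)
      if (k == 0) return(NULL)
      pos <- sample.int(len, k, replace = TRUE, prob = rate)
      tibble(accession = acc, position = as.integer(pos), vtype = vt,
             source = "population",
             allele_count = rgeom(k, prob = 0.5) + 1L,
             significance = "none", phenotype = NA_character_)
    })
  })
  planted <- regions[regions$region_id %in% planted_ids, , drop = FALSE]
  path <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
    purrr::map_dfr(names(config$pathogenic_rates), function(vt) {
      k <- rpois(1, config$pathogenic_rates[[vt]])
      if (k == 0) return(NULL)
      pos <- sample(planted$start[i]:planted$end[i], k, replace = TRUE)
      tibble(accession = planted$accession[i], position = as.integer(pos),
             vtype = vt, source = "pathogenic_db",
             allele_count = NA_integer_, significance = "pathogenic",
             phenotype = NA_character_)
    })
  })
  bind_rows(pop, path)
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Runs [simulate_proteome()], [build_partition()], [plant_features()] and
#' [simulate_variants()] under a single seed. Identical config + seed yields
#' an identical dataset at every stage.
#'
#' @param config An `idr_sim_config` ([synthetic_config()]).
#' @param seed Integer seed.
#' @return List `proteins`, `regions`, `features`, `variants`, `partition`,
#'   and `truth` (planted per-class log odds ratios, planted-intolerant
#'   region ids, the config and seed).
#' @export
#' @examples
#' d <- simulate_idr_dataset(synthetic_config(n_proteins = 10), seed = 7)
#' glance(d$partition)
simulate_idr_dataset <- function(config = synthetic_config(), seed = 1) {
  prot <- simulate_proteome(config, seed = seed)
  if (nrow(prot$proteins) == 0) {
    return(list(proteins = prot$proteins, regions = prot$regions,
                features = NULL, variants = NULL, partition = NULL,
                truth = list(planted_log_or = setNames(
                  log(config$feature_spec$target_or),
                  config$feature_spec$feature_class),
                  planted_intolerant_ids = character(), seed = seed,
                  config = config)))
  }
  partition <- build_partition(prot$proteins, prot$regions)
  features <- plant_features(prot$proteins, partition, config$feature_spec,
                             seed = seed + 1L)
  set.seed(seed + 2L)
  n_plant <- min(config$n_intolerant_planted, nrow(prot$regions))
  planted_ids <- sort(sample(prot$regions$region_id, n_plant))
  variants <- simulate_variants(prot$proteins, prot$regions, partition,
                                config, planted_ids, seed = seed + 3L)
  list(proteins = prot$proteins, regions = prot$regions,
       features = features, variants = variants, partition = partition,
       truth = list(planted_log_or = setNames(
         log(config$feature_spec$target_or),
         config$feature_spec$feature_class),
         planted_intolerant_ids = planted_ids, seed = seed, config = config))
}

#' Write a synthetic dataset as TSV tables
#'
#' The written tables round-trip losslessly through [read_proteins()],
#' [read_regions()], [read_features()] and [read_variants()].
#'
#' @param data Dataset list from [simulate_idr_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_idr_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteins(data$proteins, file.path(dir, "proteins.tsv"))
  write_regions(data$regions, file.path(dir, "regions.tsv"))
  write_features(data$features, file.path(dir, "features.tsv"))
  write_variants(data$variants, file.path(dir, "variants.tsv"))
  truth <- data$truth
  truth$config <- unclass(truth$config)
  truth$config$feature_spec <- as.data.frame(truth$config$feature_spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
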