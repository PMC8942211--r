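# End-to-end orchestration and packaged reference fixtures.

#' Run the full IDR characterization pipeline
#'
#' Executes, in order: DR/NR partition construction, the 25-class feature
#' enrichment scan on DR vs NR residues, per-region variant burden (with the
#' missense/synonymous association and clinical-class fractions), the
#' median-threshold intolerance classification, the same enrichment scan on
#' intolerant- vs tolerant-IDR residues, and permutation feature importance
#' of the intolerant-vs-tolerant classifier. One TSV is written per stage,
#' plus a JSON summary of the headline statistics and a MANIFEST. The run is
#' fully deterministic given the inputs and `seed`. A failing stage aborts
#' with the stage name; TSVs of completed stages are retained and the
#' MANIFEST records the incompleteness.
#'
#' @param proteins,regions,features,variants Input tibbles (see the
#'   `read_*()` readers or [simulate_idr_dataset()]).
#' @param out_dir Output directory.
#' @param alpha Significance level.
#' @param m Bonferroni multiplier for the feature scans.
#' @param thresholds `"recompute"` (cohort medians), `"reference"`
#'   ([reference_thresholds()]), or a threshold tibble.
#' @param mode Intolerance rule mode, `"non_strict"` or `"strict"`.
#' @param seed Integer seed (classifier and importance).
#' @param repeats Permutation repeats for importance.
#' @return Invisibly, a list with every stage result and `summary`.
#' @export
run_full <- function(proteins, regions, features, variants, out_dir,
                     alpha = 0.05, m = 25,
                     thresholds = c("recompute", "reference"),
                     mode = c("non_strict", "strict"), seed = 1,
                     repeats = 10) {
  if (is.character(thresholds)) thresholds <- match.arg(thresholds)
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  res <- list()
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(df), path, na = "")
    written <<- c(written, basename(path))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(written,
                   paste0("INCOMPLETE: stage '", name, "' failed: ",
                          conditionMessage(e))),
                 file.path(out_dir, "MANIFEST"))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  res$partition <- stage("partition", {
    p <- build_partition(proteins, regions)
    emit("partition", tidy(p))
    p
  })
  res$enrichment_dr_nr <- stage("enrichment_dr_nr", {
    e <- enrichment_scan(res$partition, features, alpha = alpha, m = m)
    emit("enrichment_dr_nr", e)
    e
  })
  res$burden <- stage("burden", {
    b <- region_variant_counts(regions, variants, proteins)
    emit("burden", b)
    b
  })
  res$burden_summary <- stage("burden", burden_summary(res$burden))
  res$population_association <- stage(
    "burden", population_association(res$partition, variants))
  res$clinical_fractions <- stage(
    "burden", clinical_class_fractions(res$partition, variants))
  res$intolerance <- stage("intolerance", {
    th <- if (identical(thresholds, "recompute")) {
      compute_thresholds(res$burden)
    } else if (identical(thresholds, "reference")) {
      reference_thresholds()
    } else {
      thresholds
    }
    calls <- classify_regions(res$burden, th, mode = mode)
    emit("intolerance", calls)
    calls
  })
  res$calls_summary <- stage("intolerance", summarize_calls(res$intolerance))

  cs <- res$calls_summary
  res$enrichment_intol_tol <- stage("enrichment_intolerant_tolerant", {
    if (cs$n_intolerant == 0 || cs$n_tolerant == 0) {
      NULL
    } else {
      p2 <- region_class_partition(proteins, regions, cs$intolerant_ids,
                                   cs$tolerant_ids)
      e <- enrichment_scan(p2, features, alpha = alpha, m = m)
      emit("enrichment_intolerant_tolerant", e)
      e
    }
  })
  imp_stage <- stage("importance", {
    labelled <- res$intolerance[res$intolerance$overall != "neither", ]
    if (length(unique(labelled$overall)) < 2) {
      NULL
    } else {
      reg <- regions[match(labelled$region_id, regions$region_id), ]
      fc <- region_feature_counts(reg, features)
      fit <- fit_intolerance_classifier(fc, labelled$overall, seed = seed)
      imp <- permutation_importance(fit, repeats = repeats, seed = seed + 1L)
      emit("importance", imp)
      list(fit = fit, importance = imp)
    }
  })
  res$classifier <- imp_stage$fit
  res$importance <- imp_stage$importance

  res$summary <- list(
    n_proteins = nrow(proteins),
    n_regions = nrow(regions),
    n_dr = res$partition$n_a,
    n_nr = res$partition$n_b,
    n_dr_features = sum(res$enrichment_dr_nr$call == "class_a_enriched"),
    n_nr_features = sum(res$enrichment_dr_nr$call == "class_b_enriched"),
    mis_syn = as.list(res$burden_summary[res$burden_summary$stratum == "all",
                                         c("mean", "median", "max")]),
    missense_or = res$population_association$odds_ratio,
    missense_p = res$population_association$p,
    n_intolerant = cs$n_intolerant,
    n_tolerant = cs$n_tolerant,
    n_intolerant_by_vtype = setNames(as.list(cs$n_by_vtype$n_intolerant),
                                     cs$n_by_vtype$vtype),
    baseline_ap = if (!is.null(res$classifier)) res$classifier$baseline_ap
                  else NULL,
    top_features = if (!is.null(res$importance)) {
      head(res$importance$feature_class, 5)
    } else NULL,
    alpha = alpha, m = m, mode = mode, seed = seed, repeats = repeats
  )
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  written <- c(written, "summary.json")
  writeLines(c(written, "COMPLETE"), file.path(out_dir, "MANIFEST"))
  invisible(res)
}

#' Packaged catalogue of mutation-intolerant IDR variant counts
#'
#' The published catalogue of 34 mutation-intolerant disordered regions in 20
#' human proteins, with the per-region pathogenic (ClinVar) and population
#' (gnomAD) counts of frameshift, nonsense, missense and inframe variants,
#' plus Disorder Ontology labels where available. Intolerance verdicts are
#' never shipped: they are always recomputed from these counts with
#' [classify_regions()] (use [reference_thresholds()] to judge the catalogue
#' against the full-cohort medians).
#'
#' @return An `idr_burden`-layout tibble of 34 rows (without population
#'   synonymous counts, which the catalogue does not include).
#' @export
#' @examples
#' counts <- load_intolerant_idr_counts()
#' calls <- classify_regions(counts, reference_thresholds())
#' summarize_calls(calls)$n_intolerant # 34
load_intolerant_idr_counts <- function() {
  path <- system.file("extdata", "intolerant_idr_counts.tsv",
                      package = "idrconstraint", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", start = "i", end = "i",
    function_category = "c", partner_category = "c",
    transition_category = "c", .default = "i"), progress = FALSE)
  if (nrow(df) != 34) {
    abort("packaged intolerant-IDR catalogue is corrupted (expected 34 rows)")
  }
  df <- mutate(df,
               region_id = sprintf("%s:%d-%d", .data$gene, .data$start,
                                   .data$end),
               length = .data$end - .data$start + 1L,
               stratum = length_stratum(.data$length))
  count_cols <- c(paste0("n_path_", .PROTEIN_VTYPES),
                  paste0("n_pop_", .PROTEIN_VTYPES))
  if (any(is.na(as.matrix(df[, count_cols]))) ||
        any(as.matrix(df[, count_cols]) < 0)) {
    abort("packaged intolerant-IDR catalogue is corrupted (bad counts)")
  }
  df[, c("region_id", "gene", "start", "end", "length", "stratum",
         "function_category", "partner_category", "transition_category",
         count_cols)]
}

#' Packaged published 2x2 contingency tables
#'
#' Two residue-level contingency tables from the human IDP cohort: the
#' population missense-vs-synonymous table over DR/NR residues, and the
#' peptide-feature table (derived from the printed totals: 541 peptide
#' residues of 345,106, 53% of them disordered, 58,993 DR and 286,113 NR
#' residues).
#'
#' @return Tibble `name`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' t <- load_reference_contingency()
#' with(t[t$name == "missense_synonymous", ],
#'      fisher_exact(a, b, c, d)$odds_ratio) # ~1.07
load_reference_contingency <- function() {
  path <- system.file("extdata", "reference_2x2.tsv",
                      package = "idrconstraint", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(name = "c", .default = "d"),
                  progress = FALSE)
}
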