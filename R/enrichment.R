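# Feature-enrichment scan over a binary residue partition: per feature class,
# a 2x2 table of (class-A / class-B) x (with / without feature), two-sided
# Fisher's exact test, Woolf CI, Bonferroni x25, and an association call.

#' Contingency table for one feature class over a residue partition
#'
#' A residue "has" the feature iff it is covered by at least one annotation
#' record of that class; multiplicity within a class never double-counts a
#' residue.
#'
#' @param partition An `idr_partition` (see [build_partition()]).
#' @param features Feature tibble ([read_features()]); records on proteins
#'   outside the partition are ignored.
#' @param feature_class One of [idr_feature_classes()].
#' @return Tibble with one row: `feature_class`, `a`, `b`, `c`, `d` (`a` =
#'   class-A residues with the feature, `b` = class-A without, `c`/`d`
#'   likewise for class B).
#' @export
contingency_for_feature <- function(partition, features, feature_class) {
  if (!feature_class %in% .FEATURE_CLASSES) {
    abort(paste0("unknown feature class: ", feature_class))
  }
  rows <- features[features$feature_class == feature_class &
                     features$accession %in% partition$proteins$accession, ,
                   drop = FALSE]
  cov <- residue_coverage(partition$proteins, rows)
  acc <- partition$proteins$accession
  a <- sum(vapply(acc, function(x)
    sum(cov[[x]] & partition$mask[[x]] & partition$universe[[x]]),
    integer(1)))
  c_ <- sum(vapply(acc, function(x)
    sum(cov[[x]] & !partition$mask[[x]] & partition$universe[[x]]),
    integer(1)))
  tibble(feature_class = feature_class,
         a = a, b = partition$n_a - a, c = c_, d = partition$n_b - c_)
}

#' Enrichment scan of all 25 feature classes over a residue partition
#'
#' Runs [contingency_for_feature()], [fisher_exact()], [woolf_ci()] and
#' [bonferroni()] for every feature class. Works unchanged for the DR-vs-NR
#' partition and for the intolerant-vs-tolerant IDR-residue partition
#' ([region_class_partition()]). Classes entirely absent from both residue
#' classes are kept as degenerate rows (`degenerate = TRUE`, statistics `NA`,
#' call `"none"`) rather than erroring, so a scan never crashes on sparse
#' annotation.
#'
#' @inheritParams contingency_for_feature
#' @param alpha Significance level for the call, default 0.05.
#' @param m Bonferroni multiplier, default 25.
#' @param classes Feature classes to scan; default all 25.
#' @return An `idr_enrichment` tibble: `feature_class`, `a`--`d`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `q`, `q_floored`, `call`
#'   (`class_a_enriched` / `class_b_enriched` / `none`), `degenerate`.
#' @export
enrichment_scan <- function(partition, features, alpha = 0.05, m = 25,
                            classes = idr_feature_classes()) {
  if (partition$n_a == 0 || partition$n_b == 0) {
    abort("both partition classes must be non-empty")
  }
  rows <- purrr::map_dfr(classes, function(cl) {
    ct <- contingency_for_feature(partition, features, cl)
    if (ct$a + ct$c == 0) { # feature absent everywhere
      return(mutate(ct, odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, q = NA_real_,
                    q_floored = FALSE, call = "none", degenerate = TRUE))
    }
    ft <- fisher_exact(ct$a, ct$b, ct$c, ct$d)
    ci <- woolf_ci(ct$a, ct$b, ct$c, ct$d)
    bq <- bonferroni(ft$p, m)
    mutate(ct, odds_ratio = ft$odds_ratio, ci_low = ci$ci_low,
           ci_high = ci$ci_high, p = ft$p, q = bq$q,
           q_floored = bq$q_floored,
           call = classify_association(ft$odds_ratio, bq$q, alpha),
           degenerate = FALSE)
  })
  structure(rows, class = c("idr_enrichment", class(rows)),
            labels = partition$labels, alpha = alpha)
}

#' Median feature content of IDRs by Disorder Ontology category
#'
#' For each (feature class, category) cell: the content of a region is the
#' fraction of its residues covered by annotations of that class; the median
#' is taken over regions in the category that have at least one covered
#' residue, and `n_regions` counts those regions. Regions without a label on
#' the chosen axis are excluded; semicolon-separated multi-labels contribute
#' to every listed category.
#'
#' @param regions Region tibble carrying the `*_category` columns.
#' @param features Feature tibble.
#' @param proteins Protein tibble (needed for coverage bounds).
#' @param category_axis One of `"function"`, `"partner"`, `"transition"`,
#'   `"state"`.
#' @return Tibble `feature_class`, `category`, `n_regions`, `median_content`.
#'   Empty cells are absent (no row).
#' @export
median_feature_content <- function(regions, features, proteins,
                                   category_axis = c("function", "partner",
                                                     "transition", "state")) {
  category_axis <- match.arg(category_axis)
  col <- paste0(category_axis, "_category")
  reg <- regions[!is.na(regions[[col]]), , drop = FALSE]
  if (nrow(reg) == 0) {
    return(tibble(feature_class = character(), category = character(),
                  n_regions = integer(), median_content = double()))
  }
  reg <- tidyr::separate_longer_delim(
    mutate(reg, category = .data[[col]]), "category", delim = ";")
  reg$category <- trimws(reg$category)

  content <- region_feature_content(reg, features, proteins)
  content %>%
    left_join(select(reg, "region_id", "category"), by = "region_id",
              relationship = "many-to-many") %>%
    filter(.data$content > 0) %>%
    group_by(.data$feature_class, .data$category) %>%
    summarise(n_regions = dplyr::n_distinct(.data$region_id),
              median_content = median(.data$content), .groups = "drop")
}

# Per-region, per-class fraction of residues covered by the class. Long
# tibble region_id x feature_class -> content (only classes present on the
# region's protein are evaluated; absent combinations have content 0 and are
# omitted).
region_feature_content <- function(regions, features, proteins) {
  feats <- features[features$accession %in% unique(regions$accession), ,
                    drop = FALSE]
  purrr::map_dfr(unique(feats$feature_class), function(cl) {
    cov <- residue_coverage(proteins, feats[feats$feature_class == cl, ,
                                            drop = FALSE])
    reg <- regions[!duplicated(regions$region_id), , drop = FALSE]
    covered <- vapply(seq_len(nrow(reg)), function(i) {
      sum(cov[[reg$accession[i]]][reg$start[i]:reg$end[i]])
    }, integer(1))
    tibble(region_id = reg$region_id, feature_class = cl,
           content = covered / reg$length)
  })
}
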