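# Variant burden: map variants onto regions and onto the DR/NR partition,
# missense/synonymous ratios with length strata, the DR-vs-NR missense
# association, and clinical-significance fractions by mutation type.

#' Length stratum of a disordered region
#'
#' @param length Region length(s) in residues.
#' @return Factor with levels `short` (<= 30), `medium` (30 < length <= 100),
#'   `long` (> 100).
#' @export
#' @examples
#' length_stratum(c(30, 100, 101)) # short, medium, long
length_stratum <- function(length) {
  cut(length, breaks = c(0, 30, 100, Inf),
      labels = c("short", "medium", "long"))
}

#' Per-region variant counts
#'
#' Counts, for every region, pathogenic and population variants of each
#' protein-changing type plus population synonymous variants. A variant
#' contributes to every region containing its anchor residue, so overlapping
#' regions each count it (region rows are deliberately not additive).
#' Clinically classified records count as pathogenic only when their
#' significance is pathogenic/likely-pathogenic; benign and VUS records never
#' do.
#'
#' @param regions Region tibble ([read_regions()]).
#' @param variants Variant tibble ([read_variants()]).
#' @param proteins Optional protein table; variant positions beyond a protein
#'   length are then errors.
#' @return An `idr_burden` tibble: one row per region with `n_path_<vtype>`
#'   and `n_pop_<vtype>` for missense/nonsense/frameshift/inframe, `n_syn`
#'   (population synonymous), `n_mis` (= `n_pop_missense`), `mis_syn_ratio`
#'   (`NA` when `n_syn == 0`; see [mis_syn_ratio()]) and `stratum`.
#' @export
region_variant_counts <- function(regions, variants, proteins = NULL) {
  if (!is.null(proteins)) {
    len <- setNames(proteins$length, proteins$accession)
    over <- variants$accession %in% proteins$accession &
      variants$position > len[variants$accession]
    if (any(over)) {
      abort(paste0("variant position beyond protein length in row(s): ",
                   paste(head(which(over), 10), collapse = ", ")))
    }
  }
  if (!"length" %in% names(regions)) {
    regions <- mutate(regions, length = .data$end - .data$start + 1L)
  }
  counts <- matrix(0L, nrow = nrow(regions), ncol = 9,
                   dimnames = list(NULL, c(
                     paste0("n_path_", .PROTEIN_VTYPES),
                     paste0("n_pop_", .PROTEIN_VTYPES), "n_syn")))
  v <- variants
  v$is_path <- v$source == "pathogenic_db" & v$significance == "pathogenic"
  v$is_pop <- v$source == "population"
  for (i in seq_len(nrow(regions))) {
    hit <- v$accession == regions$accession[i] &
      v$position >= regions$start[i] & v$position <= regions$end[i]
    if (!any(hit)) next
    vh <- v[hit, , drop = FALSE]
    for (vt in .PROTEIN_VTYPES) {
      counts[i, paste0("n_path_", vt)] <- sum(vh$is_path & vh$vtype == vt)
      counts[i, paste0("n_pop_", vt)] <- sum(vh$is_pop & vh$vtype == vt)
    }
    counts[i, "n_syn"] <- sum(vh$is_pop & vh$vtype == "synonymous")
  }
  out <- dplyr::bind_cols(
    select(regions, dplyr::any_of(c("region_id", "accession", "gene",
                                    "start", "end", "length"))),
    as_tibble(counts)
  )
  out <- mutate(out,
                n_mis = .data$n_pop_missense,
                mis_syn_ratio = mis_syn_ratio(.data$n_mis, .data$n_syn),
                stratum = length_stratum(.data$length))
  structure(out, class = c("idr_burden", class(out)))
}

#' Region-wise missense-to-synonymous ratio
#'
#' `n_mis / n_syn` of population variants; undefined (`NA`) when the region
#' carries no synonymous variant, and such regions are excluded from summary
#' means/medians rather than contributing unbounded values.
#'
#' @param n_mis,n_syn Population missense and synonymous counts.
#' @return Numeric vector, `NA` where `n_syn == 0`.
#' @export
mis_syn_ratio <- function(n_mis, n_syn) {
  ifelse(n_syn >= 1, n_mis / n_syn, NA_real_)
}

#' Summaries of the missense/synonymous ratio by length stratum
#'
#' @param counts An `idr_burden` tibble ([region_variant_counts()]).
#' @return Tibble with one row per stratum (`all`, `short`, `medium`,
#'   `long`): `n_regions`, `n_defined` (regions with a defined ratio), and
#'   `mean`, `median`, `max` over the defined ratios.
#' @export
burden_summary <- function(counts) {
  one <- function(df, label) {
    r <- df$mis_syn_ratio[!is.na(df$mis_syn_ratio)]
    tibble(stratum = label, n_regions = nrow(df), n_defined = length(r),
           mean = if (length(r)) mean(r) else NA_real_,
           median = if (length(r)) median(r) else NA_real_,
           max = if (length(r)) max(r) else NA_real_)
  }
  bind_rows(
    one(counts, "all"),
    purrr::map_dfr(c("short", "medium", "long"),
                   function(s) one(counts[counts$stratum == s, ], s))
  )
}

#' Partition-level variant totals
#'
#' Totals of mapped variants per type and source, split by the residue class
#' (DR/NR) of the anchor residue. Variants on proteins outside the partition,
#' or outside its universe, are dropped.
#'
#' @param partition An `idr_partition`.
#' @param variants Variant tibble.
#' @return Tibble `vtype`, `source`, `n_class_a`, `n_class_b`.
#' @export
partition_variant_totals <- function(partition, variants) {
  v <- variants[variants$accession %in% partition$proteins$accession, ,
                drop = FALSE]
  v$in_a <- partition_lookup(partition, v$accession, v$position)
  v <- v[!is.na(v$in_a), , drop = FALSE]
  v %>%
    group_by(.data$vtype, .data$source) %>%
    summarise(n_class_a = sum(.data$in_a), n_class_b = sum(!.data$in_a),
              .groups = "drop")
}

#' DR-vs-NR association of missense versus synonymous population variants
#'
#' Fisher's exact test on the 2x2 table (DR missense, DR synonymous, NR
#' missense, NR synonymous) of population variants, optionally restricted to
#' singletons (allele count = 1) or multitons (allele count > 1). A single
#' test: no multiplicity correction (`q = p`).
#'
#' @param partition The DR/NR `idr_partition`.
#' @param variants Variant tibble.
#' @param ac_stratum `"all"`, `"singleton"` or `"multiton"`.
#' @param alpha Significance level for the call.
#' @return One-row tibble in the [enrichment_scan()] layout (`a` = DR
#'   missense, `b` = DR synonymous, `c` = NR missense, `d` = NR synonymous).
#' @export
population_association <- function(partition, variants,
                                   ac_stratum = c("all", "singleton",
                                                  "multiton"),
                                   alpha = 0.05) {
  ac_stratum <- match.arg(ac_stratum)
  v <- variants[variants$source == "population" &
                  variants$vtype %in% c("missense", "synonymous"), ,
                drop = FALSE]
  if (ac_stratum == "singleton") v <- v[v$allele_count == 1, , drop = FALSE]
  if (ac_stratum == "multiton") v <- v[v$allele_count > 1, , drop = FALSE]
  tot <- partition_variant_totals(partition, v)
  cell <- function(vt, col) {
    x <- tot[[col]][tot$vtype == vt]
    if (length(x) == 0) 0L else x
  }
  a <- cell("missense", "n_class_a"); b <- cell("synonymous", "n_class_a")
  c_ <- cell("missense", "n_class_b"); d <- cell("synonymous", "n_class_b")
  association_from_counts(a, b, c_, d, alpha = alpha,
                          stratum = ac_stratum)
}

#' Fisher association from explicit 2x2 counts
#'
#' The count-level entry point behind [population_association()]; useful for
#' published contingency tables. Single test (`m = 1`).
#'
#' @inheritParams fisher_exact
#' @param alpha Significance level.
#' @param stratum Optional label carried into the output.
#' @return One-row tibble: counts, `odds_ratio`, `ci_low`, `ci_high`, `p`,
#'   `q`, `call`.
#' @export
#' @examples
#' association_from_counts(41691, 20282, 176888, 92314)
association_from_counts <- function(a, b, c, d, alpha = 0.05,
                                    stratum = "all") {
  ft <- fisher_exact(a, b, c, d)
  ci <- woolf_ci(a, b, c, d)
  bq <- bonferroni(ft$p, m = 1)
  tibble(stratum = stratum, a = a, b = b, c = c, d = d,
         odds_ratio = ft$odds_ratio, ci_low = ci$ci_low,
         ci_high = ci$ci_high, p = ft$p, q = bq$q,
         call = classify_association(ft$odds_ratio, bq$q, alpha))
}

#' Clinical-significance fractions of IDR-hitting variants by mutation type
#'
#' Among clinically classified (pathogenic-database) variants whose anchor
#' residue is disordered, the fraction of benign, VUS and pathogenic records
#' per mutation type. Records with no assigned significance are excluded;
#' fractions sum to 1 over the classified records of a type.
#'
#' @param partition The DR/NR `idr_partition`.
#' @param variants Variant tibble.
#' @return Tibble `vtype`, `significance`, `n`, `fraction`.
#' @export
clinical_class_fractions <- function(partition, variants) {
  v <- variants[variants$source == "pathogenic_db" &
                  variants$significance %in% c("pathogenic", "benign", "vus") &
                  variants$accession %in% partition$proteins$accession, ,
                drop = FALSE]
  v$in_a <- partition_lookup(partition, v$accession, v$position)
  v <- v[!is.na(v$in_a) & v$in_a, , drop = FALSE]
  v %>%
    count(.data$vtype, .data$significance, name = "n") %>%
    group_by(.data$vtype) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
}
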