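# Median-threshold intolerance rule. Per mutation type, an IDR is
# mutation-intolerant when (i) it carries more pathogenic than population
# variants of the type, (ii) its pathogenic count reaches the cohort median
# pathogenic count, and (iii) its population count is at or below the cohort
# median population count. Tolerant is the mirror image; condition (i) makes
# the two verdicts mutually exclusive.

#' Median variant-count thresholds over a region cohort
#'
#' Medians, per mutation type, of the pathogenic and population counts over
#' all supplied regions (zero-count regions included). Medians over an even
#' number of regions are the mean of the two central order statistics.
#'
#' @param counts An `idr_burden` tibble ([region_variant_counts()]).
#' @return Tibble `vtype`, `median_pathogenic`, `median_population`.
#' @export
compute_thresholds <- function(counts) {
  if (nrow(counts) == 0) abort("cannot compute thresholds from zero regions")
  purrr::map_dfr(.PROTEIN_VTYPES, function(vt) {
    tibble(vtype = vt,
           median_pathogenic = median(counts[[paste0("n_path_", vt)]]),
           median_population = median(counts[[paste0("n_pop_", vt)]]))
  })
}

#' Reference thresholds from the human IDP cohort
#'
#' The median pathogenic (ClinVar) and population (gnomAD) variant counts
#' per mutation type observed over the full DisProt 2020_06 human IDR
#' cohort: pathogenic medians 2/2/2/2 and population medians 22 (missense)
#' and 2 (nonsense, frameshift, inframe). Pin these when classifying a
#' region subset that should be judged against the full-cohort expectation
#' rather than its own medians.
#'
#' @return Tibble in the [compute_thresholds()] layout.
#' @export
#' @examples
#' reference_thresholds()
reference_thresholds <- function() {
  tibble(vtype = .PROTEIN_VTYPES,
         median_pathogenic = 2,
         median_population = c(22, 2, 2, 2))
}

#' Call each region intolerant, tolerant, or neither, per mutation type
#'
#' Applies the three-condition rule per type. In the default `non_strict`
#' mode condition (ii) admits counts equal to the median (`>=`); `strict`
#' requires a strict excess (`>`). Condition (iii) is `<=` in both modes.
#' The overall label is `intolerant` when any type is intolerant, else
#' `tolerant` when any type is tolerant, else `neither`.
#'
#' @param counts An `idr_burden` tibble.
#' @param thresholds Threshold tibble; defaults to medians recomputed from
#'   `counts` ([compute_thresholds()]); pass [reference_thresholds()] to pin
#'   the full-cohort values.
#' @param mode `"non_strict"` (default) or `"strict"`.
#' @return An `idr_intolerance` tibble: `region_id`, one verdict column per
#'   mutation type (`intolerant`/`tolerant`/`neither`), and `overall`.
#' @export
#' @examples
#' # 30 pathogenic vs 28 population missense: above-median population
#' # count, so NOT missense-intolerant
#' counts <- tibble::tibble(region_id = "r1",
#'   n_path_missense = 30, n_pop_missense = 28,
#'   n_path_nonsense = 0, n_pop_nonsense = 0,
#'   n_path_frameshift = 0, n_pop_frameshift = 0,
#'   n_path_inframe = 0, n_pop_inframe = 0)
#' classify_regions(counts, reference_thresholds())$missense
classify_regions <- function(counts, thresholds = compute_thresholds(counts),
                             mode = c("non_strict", "strict")) {
  mode <- match.arg(mode)
  ge <- if (mode == "non_strict") `>=` else `>`
  out <- tibble(region_id = counts$region_id)
  for (vt in .PROTEIN_VTYPES) {
    n_path <- counts[[paste0("n_path_", vt)]]
    n_pop <- counts[[paste0("n_pop_", vt)]]
    med_path <- thresholds$median_pathogenic[thresholds$vtype == vt]
    med_pop <- thresholds$median_population[thresholds$vtype == vt]
    intol <- n_path > n_pop & ge(n_path, med_path) & n_pop <= med_pop
    tol <- n_pop > n_path & ge(n_pop, med_pop) & n_path <= med_path
    out[[vt]] <- dplyr::case_when(intol ~ "intolerant",
                                  tol ~ "tolerant",
                                  .default = "neither")
  }
  verdicts <- as.matrix(out[, .PROTEIN_VTYPES])
  out$overall <- dplyr::case_when(
    rowSums(verdicts == "intolerant") > 0 ~ "intolerant",
    rowSums(verdicts == "tolerant") > 0 ~ "tolerant",
    .default = "neither"
  )
  structure(out, class = c("idr_intolerance", class(out)),
            thresholds = thresholds, mode = mode)
}

#' Summarize intolerance calls
#'
#' @param calls An `idr_intolerance` tibble ([classify_regions()]).
#' @return List with `n_by_vtype` (tibble of intolerant and tolerant region
#'   counts per mutation type), `intolerant_ids` and `tolerant_ids` (overall
#'   labels, sorted by region id), and scalar `n_intolerant`, `n_tolerant`.
#' @export
summarize_calls <- function(calls) {
  n_by_vtype <- purrr::map_dfr(.PROTEIN_VTYPES, function(vt) {
    tibble(vtype = vt,
           n_intolerant = sum(calls[[vt]] == "intolerant"),
           n_tolerant = sum(calls[[vt]] == "tolerant"))
  })
  intolerant_ids <- sort(calls$region_id[calls$overall == "intolerant"])
  tolerant_ids <- sort(calls$region_id[calls$overall == "tolerant"])
  list(n_by_vtype = n_by_vtype,
       intolerant_ids = intolerant_ids,
       tolerant_ids = tolerant_ids,
       n_intolerant = length(intolerant_ids),
       n_tolerant = length(tolerant_ids))
}
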