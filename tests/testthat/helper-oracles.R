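# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, probabilities from log-binomial coefficients.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k)
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

# Average precision by naive threshold sweep over distinct scores.
ap_oracle <- function(labels, scores) {
  labels <- as.logical(labels)
  ap <- 0
  prev_recall <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    precision <- sum(labels[sel]) / sum(sel)
    recall <- sum(labels[sel]) / sum(labels)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Residue-by-residue interval union.
union_size_oracle <- function(len, starts, ends) {
  v <- logical(len)
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
  sum(v)
}

make_proteins <- function(lengths, accessions = sprintf("P%02d",
                                                        seq_along(lengths))) {
  tibble::tibble(accession = accessions,
                 gene = paste0("G_", accessions),
                 length = as.integer(lengths))
}

make_regions <- function(accession, start, end, region_id = NULL, ...) {
  n <- length(start)
  tibble::tibble(
    region_id = region_id %||%
      sprintf("%s:%d-%d", rep_len(accession, n), start, end),
    accession = rep_len(accession, n),
    gene = paste0("G_", rep_len(accession, n)),
    start = as.integer(start), end = as.integer(end),
    length = as.integer(end - start + 1L),
    function_category = NA_character_, partner_category = NA_character_,
    transition_category = NA_character_, state_category = NA_character_,
    ...
  )
}

make_features <- function(accession, feature_class, start, end) {
  tibble::tibble(accession = accession, feature_class = feature_class,
                 start = as.integer(start), end = as.integer(end),
                 description = NA_character_)
}

make_variants <- function(accession, position, vtype,
                          source = "population", allele_count = 1L,
                          significance = "none") {
  n <- length(position)
  tibble::tibble(accession = rep_len(accession, n),
                 position = as.integer(position),
                 vtype = rep_len(vtype, n),
                 source = rep_len(source, n),
                 allele_count = rep_len(as.integer(allele_count), n),
                 significance = rep_len(significance, n),
                 phenotype = NA_character_)
}

# Burden-layout count table from per-vtype pathogenic/population pairs.
make_counts <- function(region_id, path, pop) {
  out <- tibble::tibble(region_id = region_id)
  for (vt in c("missense", "nonsense", "frameshift", "inframe")) {
    out[[paste0("n_path_", vt)]] <- path[[vt]]
    out[[paste0("n_pop_", vt)]] <- pop[[vt]]
  }
  out
}
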