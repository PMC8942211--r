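# Residue-level binary partitions. The primary one labels every residue of
# every studied protein as disordered (DR: covered by >= 1 annotated region)
# or non-annotated (NR: everything else). The same container also carries the
# intolerant-vs-tolerant IDR-residue contrast, where the universe is
# restricted to residues inside classified regions.

# Per-protein logical coverage vectors for a set of 1-based inclusive
# intervals. Interval union is delegated to IRanges::coverage.
residue_coverage <- function(proteins, intervals) {
  masks <- lapply(setNames(proteins$length, proteins$accession),
                  function(len) logical(len))
  if (nrow(intervals) > 0) {
    for (acc in unique(intervals$accession)) {
      rows <- intervals[intervals$accession == acc, , drop = FALSE]
      cov <- IRanges::coverage(IRanges::IRanges(rows$start, rows$end),
                               width = proteins$length[proteins$accession == acc])
      masks[[acc]] <- as.vector(cov) > 0
    }
  }
  masks
}

new_partition <- function(proteins, mask, universe, labels) {
  structure(
    list(proteins = proteins, mask = mask, universe = universe,
         labels = labels,
         n_a = sum(vapply(proteins$accession,
                          function(a) sum(mask[[a]] & universe[[a]]),
                          integer(1))),
         n_b = sum(vapply(proteins$accession,
                          function(a) sum(!mask[[a]] & universe[[a]]),
                          integer(1)))),
    class = "idr_partition"
  )
}

#' Build the disordered / non-annotated residue partition
#'
#' Labels each residue of each protein as DR if it is covered by at least one
#' disordered region of that protein, NR otherwise. Overlapping and
#' duplicated regions union away: the partition is idempotent in the region
#' rows, and `n_dr + n_nr` always equals the summed protein lengths.
#'
#' @param proteins Protein tibble (`accession`, `length`); every region's
#'   accession must appear here (missing proteins are an error, lengths are
#'   never inferred).
#' @param regions Region tibble as from [read_regions()].
#' @return An `idr_partition` object; see [tidy.idr_partition()] for the
#'   per-protein view and `glance()` for the `n_dr` / `n_nr` totals.
#' @export
#' @examples
#' p <- tibble::tibble(accession = "P1", gene = "G1", length = 10L)
#' r <- tibble::tibble(region_id = "r1", accession = "P1",
#'                     start = 3L, end = 5L)
#' glance(build_partition(p, r))
build_partition <- function(proteins, regions) {
  validate_regions(regions, proteins)
  mask <- residue_coverage(proteins, regions)
  universe <- lapply(setNames(proteins$length, proteins$accession),
                     function(len) rep(TRUE, len))
  new_partition(proteins, mask, universe, labels = c("DR", "NR"))
}

#' Build the intolerant- vs tolerant-IDR residue partition
#'
#' Restricts the residue universe to residues covered by a classified region
#' (intolerant or tolerant) and labels as class A those covered by at least
#' one intolerant region. Feeding this partition to [enrichment_scan()]
#' contrasts feature content of mutation-intolerant against mutation-tolerant
#' disordered residues with the identical machinery used for DR vs NR.
#'
#' @param proteins Protein tibble.
#' @param regions Region tibble.
#' @param intolerant_ids,tolerant_ids Character vectors of `region_id`s.
#' @return An `idr_partition` with labels `c("intolerant", "tolerant")`.
#' @export
region_class_partition <- function(proteins, regions, intolerant_ids,
                                   tolerant_ids) {
  validate_regions(regions, proteins)
  r_int <- regions[regions$region_id %in% intolerant_ids, , drop = FALSE]
  r_tol <- regions[regions$region_id %in% tolerant_ids, , drop = FALSE]
  mask <- residue_coverage(proteins, r_int)
  tol_cov <- residue_coverage(proteins, r_tol)
  universe <- lapply(setNames(proteins$accession, proteins$accession),
                     function(a) mask[[a]] | tol_cov[[a]])
  new_partition(proteins, mask, universe,
                labels = c("intolerant", "tolerant"))
}

#' @export
print.idr_partition <- function(x, ...) {
  cat("<idr_partition> ", nrow(x$proteins), " protein(s); ",
      x$labels[1], " residues: ", x$n_a, ", ", x$labels[2], " residues: ",
      x$n_b, "\n", sep = "")
  invisible(x)
}

#' Per-protein residue counts of a partition
#'
#' @param x An `idr_partition`.
#' @param ... Unused.
#' @return Tibble `accession`, `length`, `n_class_a`, `n_class_b` (for the
#'   DR/NR partition: disordered and non-annotated residue counts).
#' @export
#' @method tidy idr_partition
tidy.idr_partition <- function(x, ...) {
  tibble(
    accession = x$proteins$accession,
    length = x$proteins$length,
    n_class_a = vapply(x$proteins$accession,
                       function(a) sum(x$mask[[a]] & x$universe[[a]]),
                       integer(1)),
    n_class_b = vapply(x$proteins$accession,
                       function(a) sum(!x$mask[[a]] & x$universe[[a]]),
                       integer(1))
  )
}

#' One-row summary of a partition
#'
#' @param x An `idr_partition`.
#' @param ... Unused.
#' @return Tibble with `n_proteins`, `class_a`, `class_b`, `n_class_a`,
#'   `n_class_b`.
#' @export
#' @method glance idr_partition
glance.idr_partition <- function(x, ...) {
  tibble(n_proteins = nrow(x$proteins),
         class_a = x$labels[1], class_b = x$labels[2],
         n_class_a = x$n_a, n_class_b = x$n_b)
}

# DR/NR status of single residues: TRUE if the anchor residue is class A and
# inside the universe; NA if outside the universe or on an unknown protein.
partition_lookup <- function(partition, accession, position) {
  vapply(seq_along(accession), function(i) {
    m <- partition$mask[[accession[i]]]
    u <- partition$universe[[accession[i]]]
    if (is.null(m) || position[i] > length(m)) return(NA)
    if (!u[position[i]]) return(NA)
    m[position[i]]
  }, logical(1))
}
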