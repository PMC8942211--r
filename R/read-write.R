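# Readers and writers for the three tabular interfaces: disorder-region
# tables, sequence-feature tables, and protein-coordinate variant tables.
# All coordinates are 1-based inclusive throughout (UniProt/DisProt
# convention); `start == end` marks a point site.

.REGION_COLS <- c(
  "region_id", "accession", "gene", "start", "end", "length",
  "function_category", "partner_category", "transition_category",
  "state_category"
)

.CATEGORY_COLS <- c(
  "function_category", "partner_category", "transition_category",
  "state_category"
)

#' Read a disorder-region table
#'
#' Reads experimentally annotated disordered regions (one row per region) with
#' optional Disorder Ontology category labels. Regions of one protein may
#' overlap or nest; both are preserved as distinct rows.
#'
#' @param source Path to a TSV or JSON file, or a data frame already holding
#'   the columns of the TSV interface.
#' @param dialect `"tsv"` (columns `accession`, `start`, `end`, optionally
#'   `region_id`, `gene` and the four `*_category` columns) or `"json"` (an
#'   array of objects with the same fields).
#' @param proteins Optional protein table (`accession`, `length`). When given,
#'   every region must lie on a listed protein and within its bounds;
#'   violations are errors naming the offending region.
#' @param validate_categories Warn (once, collapsed) about category labels
#'   outside the known Disorder Ontology vocabulary. Labels are always kept
#'   verbatim.
#' @return A tibble with columns `region_id`, `accession`, `gene`, `start`,
#'   `end`, `length`, `function_category`, `partner_category`,
#'   `transition_category`, `state_category`. Input row order is preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\tstart\tend", "P1\t3\t5"), tf)
#' read_regions(tf)
read_regions <- function(source, dialect = c("tsv", "json"), proteins = NULL,
                         validate_categories = TRUE) {
  dialect <- match.arg(dialect)
  df <- if (is.data.frame(source)) {
    as_tibble(source)
  } else if (dialect == "json") {
    as_tibble(jsonlite::fromJSON(source))
  } else {
    readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  required <- c("accession", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("region table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 |
                 df$end < df$start)
  if (length(bad) > 0) {
    abort(paste0("malformed region coordinates (start > end, non-positive, ",
                 "or non-numeric) in row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  if (!"region_id" %in% names(df) || all(is.na(df$region_id))) {
    df$region_id <- sprintf("%s:%d-%d", df$accession, df$start, df$end)
    df$region_id <- make.unique(df$region_id, sep = "#")
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  for (col in .CATEGORY_COLS) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][!is.na(df[[col]]) & trimws(df[[col]]) == ""] <- NA_character_
  }
  df$length <- df$end - df$start + 1L
  if (validate_categories) {
    unknown <- character(0)
    for (col in .CATEGORY_COLS) {
      labels <- unlist(strsplit(stats::na.omit(df[[col]]), ";", fixed = TRUE))
      bad_lab <- setdiff(unique(tolower(trimws(labels))),
                         .KNOWN_CATEGORIES[[col]])
      if (length(bad_lab) > 0) {
        unknown <- c(unknown, paste0(col, ": ", bad_lab))
      }
    }
    if (length(unknown) > 0) {
      warn(paste0("unrecognized Disorder Ontology label(s) kept verbatim: ",
                  paste(unique(unknown), collapse = "; ")))
    }
  }
  out <- df[, .REGION_COLS]
  if (!is.null(proteins)) validate_regions(out, proteins)
  out
}

#' Write a disorder-region table
#'
#' Inverse of [read_regions()] for the TSV dialect; `read_regions()` on the
#' written file reproduces the input tibble.
#'
#' @param regions Region tibble as returned by [read_regions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  readr::write_tsv(regions[, .REGION_COLS], path, na = "")
  invisible(path)
}

validate_regions <- function(regions, proteins) {
  missing_acc <- setdiff(regions$accession, proteins$accession)
  if (length(missing_acc) > 0) {
    abort(paste0("region(s) reference accession(s) absent from the protein ",
                 "table: ", paste(head(missing_acc, 10), collapse = ", ")))
  }
  len <- setNames(proteins$length, proteins$accession)
  over <- regions$end > len[regions$accession]
  if (any(over)) {
    abort(paste0("region(s) extend past the protein end: ",
                 paste(head(regions$region_id[over], 10), collapse = ", ")))
  }
  invisible(regions)
}

#' Read a sequence-feature table
#'
#' Reads residue-level feature annotations and normalizes the class labels
#' onto the canonical 25-class vocabulary ([idr_feature_classes()]). Records
#' whose class falls outside the vocabulary (e.g. `chain`) are dropped; the
#' number dropped is attached as attribute `n_dropped` and reported in a
#' warning.
#'
#' @param source Path to a TSV (`accession`, `feature_class`, `start`, `end`,
#'   `description`) or a UniProt-style protein GFF file, or a data frame.
#' @param dialect `"tsv"` or `"uniprot_gff"` (column 1 = accession, column 3
#'   mapped onto the vocabulary via the shipped alias table).
#' @param proteins Optional protein table; out-of-bounds coordinates are then
#'   record-level errors.
#' @return Tibble `accession`, `feature_class`, `start`, `end`, `description`;
#'   point sites have `start == end` (a missing `end` is normalized to
#'   `start`).
#' @export
read_features <- function(source, dialect = c("tsv", "uniprot_gff"),
                          proteins = NULL) {
  dialect <- match.arg(dialect)
  if (is.data.frame(source)) {
    df <- as_tibble(source)
  } else if (dialect == "uniprot_gff") {
    gff <- rtracklayer::readGFF(source)
    df <- tibble(
      accession = as.character(gff$seqid),
      feature_class = as.character(gff$type),
      start = as.integer(gff$start),
      end = as.integer(gff$end),
      description = if ("Note" %in% names(gff)) {
        vapply(gff$Note, function(x) {
          if (length(x) == 0) NA_character_ else paste(x, collapse = "; ")
        }, character(1))
      } else {
        NA_character_
      }
    )
  } else {
    df <- readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  }
  required <- c("accession", "feature_class", "start")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"end" %in% names(df)) df$end <- NA_integer_
  if (!"description" %in% names(df)) df$description <- NA_character_
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$end[is.na(df$end)] <- df$start[is.na(df$end)] # point sites
  bad <- which(is.na(df$start) | df$start < 1 | df$end < df$start)
  if (length(bad) > 0) {
    abort(paste0("malformed feature coordinates in row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  mapped <- normalize_feature_class(df$feature_class)
  n_dropped <- sum(is.na(mapped))
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " feature record(s) with class outside the ",
                "25-class vocabulary dropped (e.g. ",
                paste(head(unique(df$feature_class[is.na(mapped)]), 3),
                      collapse = ", "), ")"))
  }
  df$feature_class <- mapped
  out <- df[!is.na(mapped),
            c("accession", "feature_class", "start", "end", "description")]
  if (!is.null(proteins)) {
    len <- setNames(proteins$length, proteins$accession)
    known <- out$accession %in% proteins$accession
    over <- known & out$end > len[out$accession]
    if (any(over)) {
      abort(paste0("feature record(s) extend past the protein end in row(s): ",
                   paste(head(which(over), 10), collapse = ", ")))
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a sequence-feature table
#' @param features Feature tibble as returned by [read_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("accession", "feature_class", "start", "end", "description")
  readr::write_tsv(features[, cols], path, na = "")
  invisible(path)
}

#' Read a protein-coordinate variant table
#'
#' Reads population (gnomAD-style) and clinically classified (ClinVar-style)
#' variants already mapped to protein coordinates. Indels are anchored at
#' their first affected residue. Variant types, sources and clinical
#' significance are normalized to fixed vocabularies (`likely pathogenic` ->
#' `pathogenic`, `likely benign` -> `benign`, `uncertain significance` ->
#' `vus`). Records with a type outside
#' missense/synonymous/nonsense/frameshift/inframe (e.g. splice) are rejected
#' with a warning naming their rows.
#'
#' @param source Path to a TSV with columns `accession`, `position`, `vtype`,
#'   `source`, `allele_count`, `significance`, `phenotype`, or a data frame.
#' @param proteins Optional protein table; positions beyond the protein
#'   length are errors.
#' @return Tibble with the normalized columns above; `allele_count` is
#'   integer (population records), `significance` one of
#'   pathogenic/benign/vus/none.
#' @export
read_variants <- function(source, proteins = NULL) {
  df <- if (is.data.frame(source)) {
    as_tibble(source)
  } else {
    readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  required <- c("accession", "position", "vtype", "source")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"allele_count" %in% names(df)) df$allele_count <- NA_integer_
  if (!"significance" %in% names(df)) df$significance <- NA_character_
  if (!"phenotype" %in% names(df)) df$phenotype <- NA_character_
  df$position <- as.integer(df$position)
  bad <- which(is.na(df$position) | df$position < 1)
  if (length(bad) > 0) {
    abort(paste0("malformed variant position in row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  src <- tolower(trimws(as.character(df$source)))
  bad_src <- which(!src %in% .SOURCES)
  if (length(bad_src) > 0) {
    abort(paste0("unknown variant source (expected population/pathogenic_db) ",
                 "in row(s): ", paste(head(bad_src, 10), collapse = ", ")))
  }
  df$source <- src
  vt <- normalize_vtype(df$vtype)
  rejected <- which(is.na(vt))
  if (length(rejected) > 0) {
    warn(paste0(length(rejected), " variant record(s) with unsupported type ",
                "rejected, row(s): ",
                paste(head(rejected, 10), collapse = ", ")))
  }
  df$vtype <- vt
  df$allele_count <- as.integer(df$allele_count)
  df$significance <- normalize_significance(df$significance)
  df$significance[df$source == "population"] <- "none"
  no_ac <- df$source == "population" & is.na(df$allele_count)
  if (any(no_ac & !is.na(vt))) {
    abort(paste0("population variant record(s) lack allele_count in row(s): ",
                 paste(head(which(no_ac & !is.na(vt)), 10), collapse = ", ")))
  }
  out <- df[!is.na(vt), c("accession", "position", "vtype", "source",
                          "allele_count", "significance", "phenotype")]
  if (!is.null(proteins)) {
    len <- setNames(proteins$length, proteins$accession)
    known <- out$accession %in% proteins$accession
    over <- known & out$position > len[out$accession]
    if (any(over)) {
      abort(paste0("variant position beyond protein length in row(s): ",
                   paste(head(which(over), 10), collapse = ", ")))
    }
  }
  out
}

#' Write a variant table
#' @param variants Variant tibble as returned by [read_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  cols <- c("accession", "position", "vtype", "source", "allele_count",
            "significance", "phenotype")
  readr::write_tsv(variants[, cols], path, na = "")
  invisible(path)
}

#' Read a protein table
#'
#' @param source Path to a TSV with columns `accession`, `gene`, `length`, or
#'   a data frame.
#' @return Tibble `accession`, `gene`, `length` with unique accessions and
#'   lengths >= 1.
#' @export
read_proteins <- function(source) {
  df <- if (is.data.frame(source)) {
    as_tibble(source)
  } else {
    readr::read_tsv(source, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  missing_cols <- setdiff(c("accession", "length"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("protein table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  df$length <- as.integer(df$length)
  if (any(is.na(df$length) | df$length < 1)) {
    abort("protein lengths must be integers >= 1")
  }
  if (anyDuplicated(df$accession)) {
    abort("protein accessions must be unique")
  }
  df[, c("accession", "gene", "length")]
}

#' Write a protein table
#' @param proteins Protein tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  readr::write_tsv(proteins[, c("accession", "gene", "length")], path, na = "")
  invisible(path)
}
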