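# Canonical vocabulary for the 25 sequence-feature classes and for variant
# types / sources / clinical significance. All readers normalize onto these
# tokens; everything downstream assumes them.

.FEATURE_CLASSES <- c(
  "active_site", "metal_binding_site", "binding_site", "site",
  "dna_binding_region", "np_binding_region", "zinc_finger",
  "ca_binding_region", "region_of_interest", "repeat", "coiled_coil",
  "motif", "domain", "topological_domain", "transmembrane", "intramembrane",
  "peptide", "propeptide", "transit_peptide", "signal_peptide",
  "modified_residue", "lipidation", "glycosylation", "disulfide_bond",
  "cross_link"
)

.VTYPES <- c("missense", "synonymous", "nonsense", "frameshift", "inframe")
.PROTEIN_VTYPES <- c("missense", "nonsense", "frameshift", "inframe")
.SOURCES <- c("population", "pathogenic_db")
.SIGNIFICANCE <- c("pathogenic", "benign", "vus", "none")

#' Canonical sequence-feature classes
#'
#' The 25 residue-level annotation classes recorded in UniProt-style feature
#' tables (sites of biological interest: active sites, binding regions,
#' motifs, domains, post-translational-modification sites, ...). All
#' enrichment and importance results are indexed by this vocabulary, in this
#' fixed order.
#'
#' @return Character vector of length 25, snake_case class tokens.
#' @export
#' @examples
#' idr_feature_classes()
idr_feature_classes <- function() .FEATURE_CLASSES

# Normalize a raw feature-class label (TSV free text or GFF column 3) onto the
# canonical token; returns NA for classes outside the vocabulary.
normalize_feature_class <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[ /-]+", "_", key)
  key <- sub("s$", "", key) # tolerate plural forms ("cross-links", "motifs")
  alias <- c(
    active_site = "active_site",
    metal_binding_site = "metal_binding_site",
    metal_binding = "metal_binding_site",
    binding_site = "binding_site",
    site = "site",
    dna_binding_region = "dna_binding_region",
    dna_binding = "dna_binding_region",
    np_binding_region = "np_binding_region",
    nucleotide_phosphate_binding_region = "np_binding_region",
    np_binding = "np_binding_region",
    nucleotide_binding = "np_binding_region",
    zinc_finger = "zinc_finger",
    zinc_finger_region = "zinc_finger",
    ca_binding_region = "ca_binding_region",
    calcium_binding_region = "ca_binding_region",
    calcium_binding = "ca_binding_region",
    region_of_interest = "region_of_interest",
    region = "region_of_interest",
    repeat_ = "repeat",
    coiled_coil = "coiled_coil",
    coiled_coil_region = "coiled_coil",
    motif = "motif",
    short_sequence_motif = "motif",
    domain = "domain",
    topological_domain = "topological_domain",
    transmembrane = "transmembrane",
    transmembrane_region = "transmembrane",
    intramembrane = "intramembrane",
    intramembrane_region = "intramembrane",
    peptide = "peptide",
    propeptide = "propeptide",
    transit_peptide = "transit_peptide",
    signal_peptide = "signal_peptide",
    signal = "signal_peptide",
    modified_residue = "modified_residue",
    lipidation = "lipidation",
    lipid_moiety_binding_region = "lipidation",
    glycosylation = "glycosylation",
    glycosylation_site = "glycosylation",
    disulfide_bond = "disulfide_bond",
    cross_link = "cross_link",
    crosslink = "cross_link"
  )
  # "repeat" is a reserved word; the plural-stripping above maps "repeats" ->
  # "repeat" which survives as its own key.
  key[key == "repeat"] <- "repeat_"
  out <- unname(alias[key])
  out
}

normalize_vtype <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[ -]+", "_", key)
  alias <- c(
    missense = "missense", missense_variant = "missense",
    synonymous = "synonymous", synonymous_variant = "synonymous",
    silent = "synonymous",
    nonsense = "nonsense", stop_gained = "nonsense",
    frameshift = "frameshift", frameshift_variant = "frameshift",
    inframe = "inframe", inframe_indel = "inframe",
    inframe_deletion = "inframe", inframe_insertion = "inframe"
  )
  unname(alias[key])
}

normalize_significance <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[ _-]+", "_", key)
  key[key %in% c("", "na", ".")] <- "none"
  alias <- c(
    pathogenic = "pathogenic", likely_pathogenic = "pathogenic",
    pathogenic_likely_pathogenic = "pathogenic",
    benign = "benign", likely_benign = "benign",
    benign_likely_benign = "benign",
    vus = "vus", uncertain_significance = "vus", uncertain = "vus",
    none = "none"
  )
  out <- unname(alias[key])
  out[is.na(x)] <- "none"
  out
}

# Known second-level Disorder Ontology category labels, used only to warn on
# unrecognized labels (which are kept verbatim).
.KNOWN_CATEGORIES <- list(
  function_category = c(
    "molecular recognition effector", "effector", "inhibitor", "activator",
    "molecular recognition assembler", "assembler",
    "molecular recognition display site", "display site",
    "molecular recognition scavenger", "scavenger", "chaperone",
    "entropic chain", "flexible linker/spacer", "tethering",
    "biological condensation", "prion", "self-inhibition"
  ),
  partner_category = c(
    "protein binding", "nucleic acid binding", "lipid binding", "ion binding",
    "small molecule binding"
  ),
  transition_category = c("disorder to order", "order to disorder"),
  state_category = c("order", "disorder")
)
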