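# idrconstraint

Mutational constraint and functional feature enrichment in intrinsically
disordered protein regions (IDRs).

Most experimentally verified disordered regions of human proteins carry no
functional annotation, yet they harbour a substantial share of clinically
observed germline variants. `idrconstraint` characterizes IDRs from two
angles that need no structural information:

1. **Functional feature enrichment.** Given per-residue sequence-feature
   annotations (25 UniProt-style classes: active sites, motifs, modified
   residues, domains, ...), every residue of every studied protein is
   labelled disordered (DR, covered by ≥ 1 annotated region) or
   non-annotated (NR). For each feature class a 2×2 table of
   (DR/NR) × (with/without feature) is tested with the two-sided Fisher's
   exact test. The reported odds ratio is the cross-product estimate
   OR = (a·d)/(b·c) with a Haldane–Anscombe +0.5 correction when any cell is
   zero, the CI is the Woolf log-normal interval, and p-values are
   Bonferroni-corrected across the 25 classes (q = min(1, 25·p), reported
   with a 1e-100 floor). OR > 1 with q < 0.05 marks a DR feature; OR < 1
   with q < 0.05 an NR feature.

2. **Regional mutational constraint.** Population (gnomAD-style) and
   clinically classified (ClinVar-style) variants, already mapped to protein
   coordinates, are assigned to every region containing their anchor
   residue. Per mutation type *t* ∈ {missense, nonsense, frameshift,
   inframe}, a region with pathogenic count N^path_t and population count
   N^pop_t is called **mutation-intolerant** when

   (i) N^path_t > N^pop_t, (ii) N^path_t ≥ median^path_t, (iii) N^pop_t ≤ median^pop_t,

   where the medians are taken over all regions of the cohort
   (mutation-tolerant is the mirror image; condition (i) makes the two
   mutually exclusive). Region-wise missense/synonymous ratios
   (n_mis/n_syn), allele-count strata, and clinical-significance fractions
   complete the burden picture. Finally, per-region feature-count vectors
   feed a 100-tree Gini random forest whose permutation feature importance
   — the drop in average precision after shuffling one feature column —
   ranks which functional features distinguish intolerant from tolerant
   IDRs.

A seeded synthetic-proteome generator (`simulate_idr_dataset()`) with
planted feature odds ratios and planted intolerant regions makes every
stage testable end to end without touching any database.

## Worked example

The package ships a published catalogue of 34 mutation-intolerant human
IDRs with their raw per-type variant counts, plus the full-cohort median
thresholds (pathogenic medians 2/2/2/2; population medians 22/2/2/2):

```r
library(idrconstraint)

counts <- load_intolerant_idr_counts()
calls  <- classify_regions(counts, reference_thresholds())
summarize_calls(calls)$n_by_vtype
#> # A tibble: 4 × 3
#>   vtype      n_intolerant n_tolerant
#>   <chr>             <int>      <int>
#> 1 missense              4         15
#> 2 nonsense             25          1
#> 3 frameshift           25          1
#> 4 inframe               7          4

dplyr::filter(calls, missense == "intolerant")
#> # A tibble: 4 × 6
#>   region_id    missense   nonsense   frameshift inframe    overall
#>   <chr>        <chr>      <chr>      <chr>      <chr>      <chr>
#> 1 DDX3X:1-167  intolerant intolerant intolerant neither    intolerant
#> 2 KIT:544-565  intolerant intolerant neither    intolerant intolerant
#> 3 LDLR:163-175 intolerant intolerant intolerant neither    intolerant
#> 4 RAF1:233-259 intolerant neither    neither    neither    intolerant
```

All 34 catalogued regions are intolerant to at least one mutation type;
exactly 4 are missense-intolerant and 7 inframe-intolerant. The DDX3X
N-terminal IDR, for instance, carries 7 frameshift, 6 nonsense and 5
missense pathogenic variants against **zero** population variants of those
types — the signature of strong purifying selection on a disordered region.

The residue-level missense association over the full cohort's printed
counts (41,691 / 20,282 DR missense/synonymous vs 176,888 / 92,314 NR):

```r
t <- load_reference_contingency()
ms <- t[t$name == "missense_synonymous", ]
association_from_counts(ms$a, ms$b, ms$c, ms$d)
#>   odds_ratio   ci_low  ci_high            p             call
#> 1   1.072755 1.053017 1.092863 1.118963e-13 class_a_enriched
```

i.e. the odds of a missense over a synonymous variant rise by about 7–9%
(prints as OR 1.1) when the residue is disordered.

For a from-scratch run on synthetic data:

```r
d <- simulate_idr_dataset(synthetic_config(), seed = 7)
res <- run_full(d$proteins, d$regions, d$features, d$variants,
                out_dir = "out", seed = 7)
```

which writes one TSV per stage (partition, DR/NR enrichment, burden,
intolerance calls, intolerant-vs-tolerant enrichment, importance), a JSON
summary, and a MANIFEST. `autoplot()` methods draw the enrichment forest
plot and the importance ranking; `plot_intolerance_scatter()` shows the
median-threshold geometry.

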