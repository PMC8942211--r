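---
title: "Methods: mutational constraint and feature enrichment in disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational constraint and feature enrichment in disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrconstraint)
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments that are
biologically active without adopting a stable tertiary structure. Most
experimentally verified human IDRs carry no functional annotation, yet
disordered regions both evolve quickly in the general population and
harbour a large share of clinically observed pathogenic variants. This
package quantifies two complementary, annotation-only signals over a cohort
of proteins with experimentally annotated disorder:

* which of 25 residue-level sequence-feature classes (UniProt-style "sites
  of biological interest") are statistically enriched in disordered versus
  non-annotated residues, and
* which individual IDRs are *mutation-intolerant*: depleted of
  protein-changing variants in population data while enriched for
  pathogenic variants in clinical data.

All coordinates are 1-based inclusive (the UniProt/DisProt convention);
`start == end` marks a point site.

## The residue partition

`build_partition()` labels every residue of every studied protein:
disordered (DR) if covered by at least one annotated region, non-annotated
(NR) otherwise. NR deliberately means "not annotated as disordered", not
"ordered": no disorder prediction is attempted, mirroring how the
experimental annotation is produced. The partition is a union over region
intervals (via `IRanges::coverage()`), so duplicated or nested region rows
never change it, and `n_dr + n_nr` always equals the summed protein
lengths. Proteins referenced by a region but missing from the protein table
are an error — lengths are never inferred.

## Enrichment statistics

For each feature class, a residue "has" the feature iff it is covered by at
least one record of that class; multiplicity within a class never
double-counts (tests are per-class and independent across classes). The
2×2 table (DR/NR) × (with/without) is tested with the two-sided Fisher's
exact test, computed in log-space from `stats::dhyper()` as the sum of
hypergeometric probabilities not exceeding that of the observed table
(with the customary `1 + 1e-7` tie tolerance). The suite verifies this
p-value against an exhaustive enumeration oracle over all tables with total
at most 40, at tolerance 1e-12.

Three numerical choices deserve note:

* **The odds ratio is the sample (cross-product) estimate** (a·d)/(b·c),
  not the conditional-MLE estimate printed by `stats::fisher.test()`. The
  published residue-level tables reproduce their printed ORs (1.1 for
  missense/synonymous, 5.5 for the peptide feature) only under the
  cross-product definition, so that is the package's estimator;
  `fisher.test()` serves as an independent cross-check of the p-value in
  the tests.
* **The CI is the Woolf log-normal interval**
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)). The published analyses do not
  state their CI method, so CI bars are treated as method-dependent and are
  not an acceptance surface; Woolf is the conventional companion of the
  cross-product OR. With any zero cell, the Haldane–Anscombe +0.5
  correction is applied to all four cells for both OR and CI (never to the
  exact p), which keeps the point estimate inside its interval by
  construction.
* **Bonferroni with a reporting floor.** q = min(1, 25·p). Reported q
  values are floored at 1e-100 — the conventional "maximum significance"
  display cap — with a `q_floored` flag; the exact value is retained
  internally. Display clipping of ORs to [0.05, 10] exists only inside
  `autoplot()`.

A feature class absent from both residue classes yields a degenerate row
(`NA` statistics, call `"none"`) rather than an error, so a 25-class scan
never crashes on sparse annotation; a genuinely all-zero 2×2 table is an
error. `median_feature_content()` summarizes per-region coverage fractions
by Disorder Ontology category; medians are taken over regions with at least
one covered residue, an even count averages the two central order
statistics, and semicolon-separated multi-labels contribute to each listed
category.

## Variant burden

Variants arrive in protein coordinates; indels are anchored at their first
affected residue, and a variant belongs to a region iff its anchor residue
lies inside it — the simplest rule consistent with 1-based inclusive
coordinates, chosen because boundary-straddling indels have no published
assignment rule. Overlapping regions each receive the variant (published
per-region tallies of overlapping regions each carry their own counts), so
region rows are not additive; the suite asserts the conservation law that a
variant's total contribution equals the number of regions covering it.

The region-wise missense/synonymous ratio n_mis/n_syn is undefined when
n_syn = 0 and such regions are excluded from summary means/medians/maxima:
the published summaries report a finite maximum (12.0), so unbounded ratios
were evidently not included. Note the mean of per-region ratios carries an
upward Jensen bias of order 1/λ relative to the rate ratio; the generator
consistency test therefore checks convergence on long regions at high
rates. Length strata follow the fixed boundaries short ≤ 30 < medium ≤ 100
< long. Allele-count strata split population variants into singletons
(AC = 1) and multitons (AC > 1). Clinical-significance fractions are
computed over IDR-anchored, classified records only (pathogenic/benign/VUS
after merging the "likely" grades).

## The intolerance rule

Per mutation type, with cohort medians as the expected frequencies:
intolerant iff (i) N_path > N_pop, (ii) N_path ≥ median_path, (iii)
N_pop ≤ median_pop; tolerant is the mirror image. Two readings were
genuinely open and are resolved as follows:

* **Condition (ii) defaults to ≥ (`non_strict`).** Under the strict reading
  several catalogued intolerant regions whose only qualifying counts equal
  the median exactly would be excluded, and the published per-type totals
  for missense (4) and inframe (7) are reproduced only by the non-strict
  reading; `mode = "strict"` is exposed for sensitivity analysis.
* **Condition (iii) uses ≤**, as the rule's prose statement gives it, even
  though a scatter-plot description of the same rule suggests a strict
  inequality; the prose is taken as normative.

Thresholds default to recomputation from the supplied cohort;
`reference_thresholds()` pins the full-cohort values (pathogenic medians
2/2/2/2, population medians 22/2/2/2) for judging a region subset — the
packaged catalogue of 34 intolerant regions is always re-classified from
its raw counts this way, never shipped with verdicts. The published
frameshift (24) and nonsense (21) intolerant totals are not reproducible
from the catalogued counts under any single consistent reading of the rule
(several unstarred rows satisfy it, e.g. a nonsense count of 13 pathogenic
vs 2 population); those two totals are therefore documented here but not
asserted anywhere. Whether the full-cohort medians were computed over all
981 regions or the 945 with variant data is likewise unstated; both cohorts
are supported by passing the corresponding count table to
`compute_thresholds()`.

The overall label gives intolerant precedence: a region intolerant for any
type is never listed as tolerant overall. Condition (i) makes the per-type
verdicts mutually exclusive; the suite also asserts order-invariance and
monotonicity in N_path.

## Feature importance

Per-region feature-count vectors (records overlapping the region by ≥ 1
residue, per class) are fed to a 100-tree random forest with Gini splits —
the stock bagged-tree configuration — and features are ranked by
permutation importance: the drop in average precision after shuffling one
feature column, averaged over 10 repeats. Average precision (AP) is used
because intolerant regions are heavily outnumbered by tolerant ones;
accuracy would be dominated by the majority class. AP groups tied scores
into one threshold (precision evaluated after the whole group), and the
implementation is verified against a naive threshold-sweep oracle
exhaustively on short inputs. Drops are reported in percentage points,
negative drops retained, and a mean drop ≥ 5 points flags a feature as
important. Importance is evaluated on the training cohort by default
(resubstitution), mirroring the published protocol, which does not describe
a held-out split; an evaluation set can be supplied for out-of-sample
importance. Fully redundant informative features mask each other under
permutation — an inherent property of the method, exercised in the tests by
planting complementary rather than redundant signals.

## The synthetic generator

`simulate_idr_dataset()` emulates the statistical structure the pipeline
consumes: uniform protein lengths; regions drawn from a short/medium/long
length mixture with uniform placement (nesting with probability
`p_nested`); per-residue Bernoulli feature annotation with NR rate r and DR
rate r′ satisfying odds(r′) = OR·odds(r), runs merged into interval
records; population variants as per-residue Poisson (synonymous λ,
missense ρ·λ, other types at small multiples of λ) with geometric allele
counts; and pathogenic variants as per-region Poisson inside planted
intolerant regions, whose population rates are multiplied by a suppression
factor. Defaults are fixed once: 300 proteins of length 300–900 (mean 600,
≈ 600 regions), length mixture 48/32/20% matching the real cohort's
short/medium/long proportions, 2% feature background, λ_syn = 0.05 and
ρ = 2.3 (the real cohort's mean ratio), pathogenic rates 3–6 per planted
region with suppression 0.1, 20 planted regions. Everything is
deterministic under a seed, and generated tables round-trip losslessly
through the readers.

What it does **not** emulate: amino-acid composition, codon-level
mutational opportunity, annotation errors, correlated features, or isoform
ambiguity. Passing tests on synthetic data therefore demonstrate the
statistical machinery (calibration, coverage, recovery of planted effects),
not biological fidelity of any particular rate.

## Problem sizes and budgets

The suite runs the exhaustive Fisher oracle on all ~135k tables of total
≤ 40; null calibration over 500 replicate 25-test scans at 30k residues;
CI coverage over 500 planted-OR replicates at 50k residues; intolerance
recovery over 100 replicate cohorts of 15 proteins; and byte-determinism of
the full pipeline on 20-protein cohorts. These sizes were chosen to make
the statistical assertions sharp at interactive runtimes; all thresholds in
the tests (e.g. coverage in [0.92, 0.98] for a nominal 95% interval at 500
replicates) are three-binomial-SD bands around the nominal value.

## Known limitations

* NR residues are a mixture of ordered and unannotated-disordered residues;
  enrichment contrasts inherit that ambiguity.
* Raw variant counts are not normalized for mutational opportunity or gene
  length; the intolerance rule is a deterministic threshold rule, not a
  probabilistic constraint model, and inherits the discreteness of medians.
* Median-threshold calls on overlapping regions share variants, so a region
  nested inside a truly intolerant one can be called intolerant without
  independent evidence.
* Resubstitution importance overstates absolute AP; the ranking, not the
  magnitude, is the supported readout.
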