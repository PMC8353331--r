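---
title: "Composite biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combimark)
```

## The problem

Early clinical studies of a new drug often have a binary readout per
patient (responder / non-responder) and, nowadays, somatic variant calls
from whole-exome sequencing of tumor or cell-free DNA. With cohorts of a
dozen or two patients, the natural analysis is not model fitting but exact
contingency testing: for each gene-level event, does its frequency differ
between the response groups, and how well does the event — or a small panel
of events combined by an OR rule — separate the groups? `combimark`
implements that analysis end to end, from call files to ranked marker
panels, for a design of nine drug-sensitive and seven drug-resistant
prostate-cancer patients, with every parameter exposed.

This vignette records the models, the tunable parameters, and the design
decisions taken where the analysis had genuine freedom, so that a
maintainer can tell deliberate choices from accidents.

## Group assignment and bookkeeping

Clinical response uses the four RECIST-style labels: complete response
(CR), partial response (PR), stable disease (SD), progressive disease (PD).
The derived grouping is fixed: CR/PR are "sensitive", SD/PD "resistant",
and the two groups partition the cohort. `read_sample_sheet()` refuses
unknown labels and duplicate patient identifiers outright rather than
guessing.

## Marker definitions

A marker is `(gene, event class)`. The event classes and thresholds:

| parameter | default | meaning |
|---|---|---|
| mutation effect filter | effect ≠ synonymous | which SNV/indel annotations make a gene "mutated" |
| amplification threshold | CN ≥ 2 × ploidy | per-segment copy-number ratio |
| deletion threshold | CN ≤ 0.5 × ploidy | per-segment copy-number ratio |
| ploidy | per-patient column, fallback 2.0 | average ploidy of the sample |

Three of these deserve comment. First, which mutation classes define a
"mutated" gene is genuinely ambiguous in practice; we default to *anything
not annotated synonymous* (so frameshifts, stop gains and unclassified
coding changes count) and expose it as `mutation_effects`. TMB, by
contrast, always counts strictly non-synonymous records. Second, gene-level
CNV status is positive when *any* overlapping segment crosses a threshold;
we deliberately avoid fractional-overlap rules, which demand choices the
segment data cannot justify. Third, average ploidy is an input, not an
estimate: callers such as CNVnator report it, and re-deriving it from
segments would silently couple the marker definition to segment coverage.

Coordinates: all intervals (segments, exons, microsatellite tracts) are
0-based half-open; SNV positions are 1-based points, as in VCF. The
conversion happens once, at the I/O boundary.

One per-gene choice is worth flagging: where a study reports a gene's CNV
event without direction, the marker defaults to `cnv_any`; `GAGE2C` is the
one gene whose reported event is specifically a loss, so its composite
marker defaults to `cnv_del` (see `run_config()`'s
`cnv_class_overrides`). We flag rather than guess the direction for the
other CNV genes.

## The two statistical tests

Both tests are implemented in the package rather than delegated, because
their exact definitions are the analysis: printed p-values can only be
reproduced under one specific two-sided convention.

**Fisher exact (probability-mass two-sided).** For a 2×2 table with fixed
margins, p is the sum of hypergeometric probabilities of every table whose
probability does not exceed the observed table's, with a relative tolerance
of 1e-7 absorbing floating-point ties. This is the convention of base R's
`fisher.test` and of the clinical literature; the alternative ("doubling
the one-sided tail") gives different third decimals. The kernel
(`hypergeom_pmf()`) works in log space via `lchoose`, so tables with large
margins are stable. The test suite checks equivalence against a brute-force
enumeration oracle on every table with n ≤ 25 and against `fisher.test` on
random tables.

**Mann–Whitney U (two-sided).** U is computed from midranks. With combined
sample size ≤ 20 and no ties, the p-value is exact: the proportion of all
rank assignments whose U is at least as far from its null mean as observed.
Otherwise a normal approximation with tie correction and a 0.5 continuity
correction is used, clipped to [0, 1]. Identical samples give p = 1 in both
regimes. The exact path is checked against `wilcox.test(exact = TRUE)`.

No multiple-testing correction is applied by default anywhere — the
screening step reports raw Fisher p-values, mirroring how such small-cohort
analyses are reported; users who want Benjamini–Hochberg can apply
`p.adjust` to the `p_value` column themselves.

## Genomic metrics

**TMB** is a count of non-synonymous mutations divided by the captured
target size in Mb. The target size is a parameter (default 50 Mb, the
common whole-exome convention) because capture kits differ; this means
cross-study TMB values are comparable only up to that denominator.

**Microsatellite scanner.** Tandem repeats with motif length 1–5 bp and at
least 5 complete units are detected by run-length scanning of the
period-*m* match vector. Three conventions pin the output down uniquely:
(1) motifs are *primitive* — a poly-A run is motif `A`, never `AA`; (2) one
tract per periodic run, anchored at the leftmost position where the
periodicity starts, trimmed to whole units; (3) a tract of a longer motif
wholly contained in a shorter-motif tract is suppressed, and runs
containing `N` are broken. A brute-force oracle that tests every
(start, motif-length) pair enforces exactly these rules in the tests. The
uniform "≥ 5 repeats for all motif lengths" floor is taken at face value;
per-motif minimums (as some MISA configurations use) would be a one-line
change to `min_repeats`.

**MSI score.** The score is (# unstable sites) / (# valid sites). What
makes a site "unstable" is not standardised, so we chose the simplest
defensible statistic: a site is *valid* when both tumor and normal
repeat-length read histograms have ≥ `min_depth` (default 20) reads, and
*unstable* when the total-variation distance between the depth-normalised
histograms exceeds `shift_threshold` (default 0.3). Total variation is
symmetric in tumor/normal, bounded in [0, 1], and a 2-unit shift of a
concentrated length distribution drives it near 1 while multinomial
sampling noise at depth 50 keeps it well below 0.3 — which is why the
simulated unstable fraction is recovered within ±0.03 in the tests. Zero
valid sites yield score 0 with a warning, never an error.

**CNV burden.** The amplified/deleted fraction of exons assigns each exon
to the segment containing its midpoint (first covering segment in sorted
order when segments overlap) and applies the same thresholds as the
markers. Midpoint membership avoids fractional-overlap bookkeeping; with
non-overlapping segments the two burden fractions cannot sum above 1.

## Mutational signatures

Spectra use the standard 96 channels — six pyrimidine-reference
substitutions × 16 trinucleotide contexts, substitution-major, 5' then 3'
base in A, C, G, T order. Purine-reference calls are reverse-complemented;
indels and flankless (contig-edge) records are skipped and counted on the
returned object.

Exposure fitting is refitting against a known catalog, not de novo
extraction: non-negative least squares of the normalised spectrum on the
signature matrix, exposures renormalised to sum to 1, residual reported as
the pre-normalisation Euclidean error. NNLS is the standard refitting
choice; any solver that reproduces the parameter-recovery property (mean
absolute exposure error < 0.05 for mixtures of ≤ 4 signatures at 50,000
mutations, 20 seeded replicates — checked in the acceptance suite) could be
substituted. Fits on catalogs below 20 substitutions are returned but
flagged `low_confidence`, because NNLS on tiny catalogs is noise-dominated.

The packaged signature matrix is **synthetic**: 30 row-stochastic profiles
in the COSMIC v2 layout, each concentrating 75% of its mass on six
signature-specific peak channels over a uniform background, generated under
a fixed internal seed (`synthetic_signature_reference()`). We ship a
generator rather than the empirical COSMIC v2 catalog so the package is
self-contained and redistribution-clean; the construction is deliberately
well-conditioned (smallest singular value ≈ 0.13), and every signature
property we validate is a recovery property that holds for any such
matrix. Analyses of real cohorts should load the empirical catalog with
`read_signature_reference()` — the rest of the pipeline is unchanged.

## Classifier evaluation and combination search

How multiple markers combine is the central modelling decision. We adopt
the **any-positive (OR) rule**: a patient is test-positive when at least
one panel marker is present. The decisive argument is arithmetic: published
panel confusion counts behave as set unions of the single-marker positives
(TP of a pair equals the union of component TPs, FP never exceeds the sum
of component FPs), which only the OR rule produces. An `all_positive` (AND)
rule is provided for exploration but is not used anywhere in reproduction.
Under the OR rule, adding a marker can only keep or raise TP and keep or
lower TN — sensitivity is monotone non-decreasing and specificity
non-increasing in the panel, a property the test suite asserts on random
matrices.

The search enumerates every subset of the candidate markers up to
`max_size` (default 3 — beyond three genes, an OR panel on 16 patients is
guaranteed to overfit) and returns the complete ranking. Because no total
order is canonical, we fix a deterministic one: sensitivity ↓, specificity
↓, p ↑, panel size ↑, then lexicographic marker names. A guard (default
10⁶ subsets) forces pre-screening instead of letting the enumeration
explode.

## The synthetic-data generators and the packaged fixture

`generate_cohort()` draws binary marker matrices with *exact* per-group
column sums under a seed, and `write_cohort_files()` realises any matrix as
sample sheet + per-patient VCF/SEG files that round-trip through the
readers — so every I/O and screening test runs against files, not in-memory
shortcuts. Each emitted patient also carries 15 deterministic passenger
SNVs (unannotated for genes, 1 in 5 synonymous) so TMB and spectra are
non-degenerate for marker-negative patients.

The patient-level event matrix behind the published classifier tables was
never released; only its marginals were (per-marker positives per group,
and union counts for selected panels). `build_fixture_cohort()` therefore
ships *one* binary completion satisfying all of those constraints
simultaneously, found by constraint propagation and re-derivable by the
backtracking search in `scripts/fixture_search.R`. Two printed rows are
excluded from the constraint set as internally inconsistent (a pair whose
printed FP is impossible given its components' FPs under the OR rule, and
a single-marker row whose printed TP/FN don't fit the positive-class size
although its printed p-value fits the corrected counts); both are
documented at the constraint table, and neither affects any other row. Any
consistent completion yields identical single-marker and union confusion
tables, which is exactly what reproduction requires — the fixture is *not*
a reconstruction of which actual patient carried which mutation.

What the generators do **not** emulate: sequencing noise and depth
variation, tumor purity and subclonality, correlated co-mutation structure
beyond the imposed marginals, realistic genome context composition (catalog
references are i.i.d. uniform bases), and linkage between CNV segments.
Passing tests therefore demonstrate correctness of the computations and
exact reproduction of the published tables' arithmetic on a consistent
cohort — not robustness of the biological findings to resampling, which a
16-patient in-sample analysis cannot provide.

## Numerical choices and degenerate inputs

- Fisher tie tolerance 1e-7 (relative) when comparing table probabilities;
  p clipped to 1.
- Mann–Whitney continuity correction 0.5; variance with tie correction; a
  zero variance (all values tied) yields p = 1.
- Sensitivity/specificity with a zero denominator are `NA`, never 0/0
  artifacts; empty marker panels and empty groups are hard errors.
- Report formatting rounds half *up* (9/16 → "56.3%"), matching clinical
  reporting conventions rather than IEEE round-half-even; percentages print
  to 1 decimal, p-values to 3.
- All generators are deterministic under a seed, and
  `synthetic_signature_reference()` restores the caller's RNG state.

## Validation problem sizes

The shipped suites validate at sizes chosen to make the oracles exhaustive
yet quick: all 2×2 tables with n ≤ 25 for the Fisher oracle; tie-free
samples up to 9 + 9 for the exact Mann–Whitney comparison; 2 kb
repeat-enriched sequences for the scanner oracle; 50,000-mutation catalogs
and 20 seeded replicates for signature recovery; 500 simulated
microsatellite loci at depth 50 for MSI score recovery.

## Known limitations

- Performance estimates are apparent (in-sample); with 231 candidate
  panels on 16 patients, perfect separation is an optimistic estimate by
  construction. No cross-validation is attempted — with n = 16 it would be
  theater.
- The MSI instability criterion is one reasonable choice among several
  (alternatives: Kolmogorov–Smirnov distance, allele-count models); scores
  are comparable only within a fixed criterion.
- TMB depends on the assumed captured-target size.
- The synthetic signature reference supports methodology validation, not
  etiology statements about real signatures.
- `cnv_any` markers emitted by the cohort generator are written as
  deletions (copy number 0.8), so a re-read matrix sets both `cnv_del` and
  `cnv_any` for those genes; downstream analyses use one class per gene to
  avoid duplicated markers.
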