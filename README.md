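# combimark

Composite genomic biomarker discovery from somatic variant calls.

`combimark` is an R package for the small-cohort biomarker problem that
arises in early clinical studies of a drug: given per-patient somatic
SNV/indel and copy-number calls (typically from whole-exome sequencing of
tumor or cell-free DNA) and a binary clinical response label per patient,
find gene-level events — alone or in small OR-rule panels — that separate
drug-resistant from drug-sensitive patients. The package was built around a
16-patient prostate-cancer cohort design (9 treatment-sensitive, 7
treatment-resistant) but every stage is parameterised and reusable.

## What it computes

**Marker matrix.** Each marker is a gene paired with an event class. For
patient *i* and gene *g*:

- `mutation` = 1 if *g* carries ≥ 1 somatic SNV/indel whose annotated effect
  is not synonymous;
- `cnv_amp` = 1 if some segment listing *g* has copy number ≥ 2 × ploidy;
- `cnv_del` = 1 if some segment has copy number ≤ 0.5 × ploidy;
- `cnv_any` = `cnv_amp` OR `cnv_del`.

**Per-sample metrics.** TMB (non-synonymous mutations per Mb of captured
target, default 50 Mb), MSI score (unstable / valid microsatellite sites,
with a built-in MISA-style tandem-repeat scanner and a total-variation test
on tumor vs normal repeat-length read histograms), and exome
amplification/deletion fractions by exon midpoint.

**Mutational signatures.** 96-channel trinucleotide spectra in the
pyrimidine convention, and per-sample exposure refitting against a 30 × 96
row-stochastic signature matrix (COSMIC v2 layout) by non-negative least
squares: minimise ‖Sᵀe − m‖₂ subject to e ≥ 0, then renormalise e to sum
to 1, where S is the signature matrix and m the normalised spectrum.

**Statistics.** Self-contained implementations of the two tests used
throughout: the probability-mass two-sided Fisher exact test on 2×2 tables
(p = Σ of hypergeometric probabilities of all tables with the observed
margins no more probable than the observed one) and the two-sided
Mann–Whitney U test (exact permutation enumeration for small tie-free
samples, normal approximation with tie and continuity corrections
otherwise). Both are oracle-checked against exhaustive enumeration in the
test suite.

**Classifier evaluation and panel search.** A panel of markers classifies a
patient as positive when any member is present (OR rule). Against the
clinical grouping this gives TP/FN/FP/TN, sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP), and a Fisher exact p-value. `search_combinations()`
enumerates every panel up to a configurable size (default 3) and ranks by
sensitivity, then specificity, then p, then panel size.

## Worked example

The package ships a deterministic 16-patient fixture cohort whose marker
matrix is consistent with the published single-marker and panel confusion
tables (see `?build_fixture_cohort`):

```r
library(combimark)
library(dplyr)

fx <- build_fixture_cohort()
screened <- screen_markers(fx$matrix, fx$cohort, alpha = 0.05)
head(screened, 5)
#>   marker            gene     event_class count_resistant count_sensitive p_value direction
#> 1 CTAGE4|cnv_any    CTAGE4   cnv_any                   5               0 0.00481 higher_in_resistant
#> 2 FRG1|mutation     FRG1     mutation                  4               0 0.0192  higher_in_resistant
#> 3 GAGE2C|cnv_del    GAGE2C   cnv_del                   4               0 0.0192  higher_in_resistant
#> 4 GAGE2E|cnv_any    GAGE2E   cnv_any                   4               0 0.0192  higher_in_resistant
#> 5 HNRNPCL1|mutation HNRNPCL1 mutation                  4               0 0.0192  higher_in_resistant
```

Seventeen markers pass at α = 0.05 (7 mutation markers and 4 CNV markers
higher in the resistant group; 6 CNV markers higher in the sensitive
group). Searching all panels of up to three resistance markers:

```r
cand <- screened$marker[screened$direction == "higher_in_resistant"]
res <- search_combinations(fx$matrix, cand, fx$cohort,
                           positive_class = "resistant", max_size = 3)
res |>
  mutate(sensitivity = format_percent(sensitivity),
         specificity = format_percent(specificity),
         p = format_pvalue(p_value)) |>
  select(rank, markers, tp, fn, fp, tn, sensitivity, specificity, p) |>
  head(3)
#>   rank markers                                          tp fn fp tn sensitivity specificity p
#> 1    1 CTAGE4|cnv_any+GAGE2C|cnv_del+GAGE2E|cnv_any      7  0  0  9 100.0%      100.0%      0.000
#> 2    2 CTAGE4|cnv_any+GAGE2C|cnv_del+HNRNPCL1|mutation   7  0  0  9 100.0%      100.0%      0.000
#> 3    3 CTAGE4|cnv_any+GAGE2C|cnv_del+SP8|mutation        7  0  0  9 100.0%      100.0%      0.000
```

Eight of the 231 enumerated panels classify all 16 patients perfectly,
among them SP8/HNRNPCL1 mutation plus GAGE2C loss and SP8/FRG1 mutation
plus GAGE2C loss. Single markers top out at 85.7% sensitivity — the OR rule
is what buys perfect separation, at the price of in-sample optimism on a
cohort this small (the vignette discusses this limitation).

The same analysis runs from files on disk via the report layer:
`run_config()` plus `cmd_metrics()`, `cmd_signatures()`, `cmd_screen()` and
`cmd_combos()`, each of which writes TSV reports and a JSON run manifest.
Synthetic inputs for all of them come from `generate_cohort()`,
`generate_snv_catalog()` and `generate_msi_evidence()`.

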