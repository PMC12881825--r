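---
title: "Finding MSP biomarker regions from per-CpG methylation calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding MSP biomarker regions from per-CpG methylation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(methmsp)
library(dplyr)
```

## The screening problem

Methylation-specific PCR (MSP) detects disease-associated hypermethylation
by amplifying bisulfite-converted DNA with primers that only anneal to the
methylated (unconverted) template. A usable MSP target is therefore much
more constrained than a generic differentially methylated region:

* every CpG the primer interrogates must be close to 0% methylated in all
  control samples — a single methylated control destroys specificity;
* the disease group must be clearly hypermethylated at those CpGs, robustly
  across samples, not just on average;
* the discriminating CpGs must cluster within a primer's footprint
  (18–24 nt), and two such footprints must bracket a PCR product of
  practical size (60–400 nt including the primers).

`methmsp` encodes these constraints as a filter cascade over a merged
multi-sample table of per-cytosine calls (coverage + percent methylation,
the bedmethyl convention), followed by a coverage-aware score and an
exhaustive pairing step. No p-values are computed anywhere: the screen is a
deterministic geometric/threshold procedure, which keeps it transparent and
reproducible at clinical sequencing depths where formal testing per CpG is
underpowered anyway.

## The model, step by step

### Control gate (Filter 1)

At each position (chromosome, position, strand — strands are independent
measurements by default), control samples with coverage below `min_ctrl_cov`
(default 3 reads) are *unassessable*: they contribute no methylation
evidence, for or against. The position survives iff

* assessable controls number at least `ceiling(min_ctrls_frac * n_controls)`
  (default half, rounded up — "minimum number" semantics), and
* no assessable control has methylation strictly above `max_ctrl_meth`
  (default 10%). The comparison is strict: exactly 10% passes.

The choice that an unassessable control cannot veto deserves a note: a
methylation percentage supported by one or two reads is close to
meaningless, so treating it as a veto would let sequencing dropouts mask
genuinely clean targets. The coverage fraction requirement is what protects
against calling a position "clean" on no evidence.

### Boxplot statistics and Filter 2

Per position and group the non-missing methylation values are summarised by
a five-number boxplot statistic. The quartiles use linear interpolation
between order statistics (type 7 — the default of both R's `quantile` and
numpy's `nanpercentile`, so results are comparable across ecosystems). The
"0th" and "100th" percentiles are the whisker ends: the smallest value at or
above `p25 − 1.5·IQR` and the largest value at or below `p75 + 1.5·IQR`.
Values beyond the fences are outliers and cannot stretch the whiskers; with
a single observation all five numbers collapse onto it.

A position is a *differentiating CpG* iff the disease median is strictly
above the control upper whisker and at least one disease observation exists.
Using the median against the whisker makes the rule robust on both sides: a
single hypermethylated disease sample cannot rescue a position, and a single
outlying control cannot kill one — that is Filter 1's job, and only for
assessable controls.

### Primer windows (Filter 3)

For every differentiating CpG `p` and every window length
`L ∈ [min_primer_len, max_primer_len]`, the window `[p, p + L)` is a
candidate iff it fully contains at least `min_cpgs` differentiating CpG
*dinucleotides* — a CpG at `s` counts only when `s + 2 ≤ p + L`, because a
primer must physically span both the C and the G it discriminates on.
Windows are anchored at differentiating CpGs: a window starting earlier
contains the same or fewer differentiating sites than the one anchored at
its first contained site, so anchoring enumerates every maximal window
content while keeping the search bounded and deterministic. The test suite
checks the enumeration against an exhaustive scan over *all* starts.

### Scoring

With `Cov_ij` and `Meth_ij` (percent) the disease observations and `Norm_i`
a per-sample normaliser,

$$\mathrm{score} = \sum_{i=1}^{N}\sum_{j=1}^{M} \frac{Cov_{ij}}{Norm_i}\,Meth_{ij}.$$

`Norm_i` is computed over all differentiating sites where sample `i` has
data. The default is their **mean** coverage, which makes `Cov/Norm` a
relative coverage: deeply and shallowly sequenced disease samples then
contribute on the same scale, and rescaling one sample's coverage leaves its
contribution unchanged — with three disease samples and three CpGs at full
methylation and typical coverage, scores land in the hundreds to thousands.
With the plain **sum** (`norm_mode = "sum"`), available as a switch, each
sample's total contribution is bounded by `100 · M / K` and genome-wide `K`
drives scores toward zero; the mean is therefore the default. Missing
observations contribute zero — the score never imputes data.

### Amplicon pairing

All ordered primer pairs (A, B) on a chromosome with `A.end ≤ B.start` and
span `B.end − A.start` within the amplicon bounds become MSP regions, scored
exactly `score(A) + score(B)`. Primers within a pair may not overlap — they
must bind disjoint stretches of the amplicon — but *different* pairs may
overlap freely, and deliberately so: the downstream assay designer picks
among alternatives by annealing temperature and other chemistry constraints
this package does not model. All pairs are reported; one global best
(highest score, ties to the smallest start, then the smallest length) is
flagged rather than filtered, since "best per locus" depends on a locus
definition the user may want to impose themselves.

Each region also reports the mean disease coverage over its differentiating
CpGs and the mean methylation contrast (disease − control) over the same
CpGs. The screen only ever emits hypermethylation candidates, so this
contrast is positive on any realistic input; the suite fuzzes this over
simulated cohorts. It is not a mathematical theorem, though: a pathological
control sample that is unassessable at every CpG of a region yet heavily
methylated could, in principle, inflate the control mean without tripping
Filter 1 — on real data such a sample would indicate a coverage problem
worth investigating, not a scoring defect.

### Gene context

With an Ensembl-style GTF/GFF3, each region is classified against gene
bodies: `gene` on ≥1 nt overlap with any gene, else `upstream500` when
overlapping the 500 nt upstream of a transcription start (strand-aware,
clipped at the chromosome start), else `intergenic`. The partition is
exhaustive and mutually exclusive by construction.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `max_ctrl_meth` | 10 | % | strict veto threshold for assessable controls |
| `min_ctrl_cov` | 3 | reads | assessability gate for controls |
| `min_ctrls_frac` | 0.5 | — | fraction of controls that must be assessable (ceil) |
| `min_primer_len`–`max_primer_len` | 18–24 | nt | primer window lengths |
| `min_cpgs` | 3 | — | differentiating CpGs per primer window |
| `min_amplicon_len`–`max_amplicon_len` | 60–400 | nt | MSP region span incl. primers |
| `norm_mode` | `"mean"` | — | coverage normaliser (`"sum"` = literal total) |

Lowering `max_ctrl_meth` increases specificity monotonically (never adds a
position); raising `min_ctrl_cov` similarly only removes positions. Both
monotonicities are property-tested.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (BED convention of the
  input), including all TSV outputs; GTF/GFF coordinates are converted on
  read.
* Chromosomes sort naturally (`chr2 < chr10 < chrX`), making every output
  byte-deterministic for a given input.
* Strand `.` is rejected at parse time — the whole cascade is strand-aware.
  Opt-in pooling of the two strands of a CpG (`collapse_strands()`,
  `--collapse-strands`) sums coverages and coverage-weights the methylation.
* Coverage-0 rows parse fine but count as missing observations everywhere.
* A disease sample with no data at any differentiating site gets a missing
  normaliser, contributes zero to all scores, and warns.
* Zero surviving regions is a warning plus empty (header-only) outputs and
  exit 0 from the CLI — an honest negative, not an error.
* Percentages and scores render with two decimals in the TSVs; identical
  inputs give byte-identical outputs (checksummed in the tests).

## What the simulator does and does not emulate

`simulate_methylome()` generates: plus-strand CpG positions with geometric
background gaps (mean `cpg_spacing`, default 100 nt, minimum 2); per-sample,
per-site Poisson coverage (default mean 20×, with 7× used in tests as the
clinical regime); uniform background methylation noise in controls (default
≤5%, safely under the 10% gate); and planted cluster pairs whose geometry
(3 CpGs spaced 8 nt, pairs 150 nt apart, well separated between pairs)
guarantees discoverability under default parameters. Cohort sizes default to
3 + 3 samples, a realistic pilot-cohort size.

It does **not** emulate: read-level error or basecaller bias, CpG-island
spatial correlation of methylation, allele-specific methylation,
copy-number-driven coverage structure, or minus-strand data (hand-built
fixtures cover strand handling in the unit tests). Passing the recovery
tests therefore demonstrates the pipeline's correctness and its behaviour
under sampling noise at clinical depth — not performance on the full
messiness of real nanopore cohorts.

Problem sizes in the test suite and acceptance script — a 13 kb chromosome,
~140 CpGs, 6 samples, 20 replicate seeds per regime — were chosen as the
smallest instances on which every geometric case (multiple overlapping
primers, multiple amplicon alternatives, isolated noise CpGs, coverage
dropouts) still occurs.

## A complete run

```{r pipeline}
sim <- simulate_methylome(sim_config(seed = 1))
res <- find_msp_regions(sim$calls)
res
glance(res)
tidy(res) |>
  filter(is_best) |>
  select(chrom, start, end, length, score, mean_coverage, mean_meth_diff)
evaluate_recovery(sim$truth, tidy(res))
```

```{r plots, fig.width=7, fig.height=3}
plot_site_methylation(res$stats, chrom = "chrSim", start = 1950, end = 2200)
autoplot(res)
```

## Known limitations

* Primer thermodynamics (melting temperature, hairpins, dimers) and
  bisulfite-converted primer sequences are out of scope — outputs are
  *regions* for a primer-design tool to refine.
* The score has no significance calibration; it ranks candidates within a
  run and is comparable across runs only under similar cohort sizes.
* `Norm_i` uses genome-wide differentiating sites; in cohorts where disease
  samples differ wildly in which chromosomes are covered, a per-region
  normaliser could rank differently.
* The "best" flag is global; per-locus selection is left to the user.
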