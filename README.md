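# methmsp

Discovery of candidate biomarker regions for **methylation-specific PCR
(MSP)** from multi-sample, per-cytosine DNA methylation calls (bedmethyl
files, e.g. from nanopore sequencing).

MSP amplifies bisulfite-converted DNA with primers that anneal only to the
methylated template, so a clinically useful MSP target must combine two
properties that generic DMR callers do not optimise for: the region has to be
**essentially unmethylated in every control sample** (otherwise the assay
loses specificity) and **strongly hypermethylated in the disease group**, and
the discriminating CpGs have to be **dense enough to sit inside an 18–24 nt
primer**, with two such primers spanning a 60–400 nt PCR product. `methmsp`
screens a genome-wide methylation table for exactly this geometry and emits
scored primer candidates and primer-pair (amplicon) regions, with optional
sequence, GC content and gene context.

## Method

Per sample and cytosine the input provides a read coverage and a percent
methylation. The pipeline applies three filters and a score:

1. **Control gate (Filter 1).** A position is kept iff at least
   `ceil(minCtrls × n_controls)` control samples are assessable there
   (coverage ≥ `minCtrCov`, default 3×, default fraction 50%) and no
   assessable control shows methylation above the threshold (default 10%).
   Unassessable controls contribute no evidence in either direction.
2. **Boxplot statistics & Filter 2.** For each remaining position and group,
   the 25th/50th/75th percentiles are computed by linear interpolation
   (type-7); the 0th/100th "percentiles" are the whisker ends — the most
   extreme values within 1.5·IQR of the quartiles, so outliers do not move
   them. A position is a *differentiating CpG* iff the disease median lies
   strictly above the control 100th percentile.
3. **Primer scan (Filter 3).** Windows of length `L ∈ [18, 24]` nt anchored
   at differentiating CpGs are candidates when they fully contain at least
   `minCpGs = 3` differentiating CpG dinucleotides.
4. **Score.** With `Cov_ij`, `Meth_ij` the coverage and percent methylation
   of disease sample *i* at CpG *j*, and `Norm_i` the per-sample coverage
   normaliser over that sample's differentiating sites (mean by default, the
   plain sum via `norm_mode = "sum"`),

   `scorePrimer = Σ_i Σ_j (Cov_ij / Norm_i) · Meth_ij`

5. **Amplicon pairing.** All ordered, non-overlapping primer pairs whose
   span (left primer start → right primer end) is 60–400 nt become MSP
   regions; a region's score is exactly the sum of its two primer scores,
   and the highest-scoring region is flagged.

## Worked example

The package ships a seeded methylome simulator that plants pairs of
hypermethylated CpG clusters in primer/amplicon geometry on an otherwise
unmethylated background (3 control + 3 disease samples, ~20× Poisson
coverage):

```r
library(methmsp)
sim <- simulate_methylome(sim_config(seed = 1))
res <- find_msp_regions(sim$calls)
res
#> <msp_result>
#>   positions:             141
#>   pass Filter 1:         141
#>   differentiating CpGs:  45
#>   candidate primers:     42
#>   MSP regions:           147
#>   best region:           chrSim:2000-2168 (length 168, score 1533.38)
evaluate_recovery(sim$truth, tidy(res))
#> # A tibble: 1 × 5
#>   n_truth n_recovered recall n_predictions false_positives
#> 1       3           3      1           147               0
```

All 141 simulated positions pass the control gate (controls carry only ≤5%
noise), 45 CpGs differentiate the groups (the 18 planted cluster CpGs plus
isolated noise positions), and only the planted clusters are dense enough to
host primers: 42 candidate windows (7 lengths × 6 clusters) pairing into 147
overlapping amplicon alternatives that recover all 3 planted truth regions
with no false positive. `tidy(res)` returns the region table
(`mean_meth_diff` is the disease-minus-control methylation contrast over the
region's CpGs — positive by design of the screen), `glance(res)` the one-row
run summary, and `autoplot(res)` a score track.

The same run from a shell, writing `boxplotData.tsv`, `interestingCpGs.tsv`,
`primerData.tsv`, `pcrProduct.tsv` (plus `mspRegions.fa` with
`--reference`):

```sh
Rscript inst/scripts/methmsp --manifest sim/manifest.tsv --outdir out/
```

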