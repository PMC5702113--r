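# chipTurnover

Sigmoidal modeling of time-course ChIP-seq coverage and locus turnover
kinetics.

Time-resolved ChIP-seq (and conceptually related assays — ChEC-seq,
XR-seq, time-course ATAC-seq) quantifies sequencing coverage at genomic
loci across an ordered series of time points. This package is for
researchers who want to reduce such a time course to a few
biologically interpretable numbers per locus, instead of eyeballing
track snapshots or fitting ad hoc exponentials. It models the coverage
trajectory at each locus with the four/five-parameter log-logistic
sigmoid

```
y = d + (a - d) / (1 + exp(b (x - c)))^f
```

where `a` and `d` are the occupancy plateaus, `b` is the
**incorporation rate index** (IRI; the steepness at the inflection,
negative for rises and positive for falls), `c` locates the
transition, and `f > 0` is an optional asymmetry factor (fixed at 1 by
default). The headline per-locus statistic is the **turnover time
index** (TTI) — the time at which the curve crosses the plateau
midpoint `(a + d)/2`, in closed form `TTI = c + ln(2^(1/f) - 1)/b` —
interpretable as the binding half-life at the locus.

Each locus is classified by the timing of its coverage extrema into
**rise**, **fall**, **hill** (rise then fall; two sigmoids with
separate TTI_rise/TTI_fall), **valley**, or **undefined rise/fall**,
then re-verified against the fitted direction; mismatches are
**eliminated** (flagged, never dropped). The package also covers the
practical scaffolding: per-locus coverage extraction from BAM files
over BED loci, background-maximum/input/user-defined normalization,
replicate averaging, summary analytics (0–1 heatmap matrices, category
proportions, TTI histograms, genome-feature TTI distributions,
replicate log2-TTI ratios, genomic TTI cluster bins), and a synthetic
benchmark generator with a truth table for parameter-recovery scoring.

## Worked example

Simulate a small rise/fall benchmark (2 loci per grid level), add
Poisson background noise, run the analysis, and score recovery:

```r
library(chipTurnover)

spec  <- defaultSimulationSpec("both", nPerLevel = 2)
sim   <- simulateTrueCoverage(spec)
noisy <- addNoise(sim$coverage, 1, seed = 42)
rs    <- analyzeTimeCourse(noisy)
rs
#> TurnoverResultSet: 100 loci
#>   fall             36
#>   hill             11
#>   rise             37
#>   undefined_fall   3
#>   undefined_rise   2
#>   valley           11

ev <- evaluateRecovery(rs, sim$truth)
median(ev$perLocus$deviationPct, na.rm = TRUE)
#> [1] 2.14
```

All 100 loci are truly single rises or falls; the hills/valleys and
undefined calls are what Poisson background noise does to shallow,
low-coverage trajectories at the default thresholds. The median fitted
TTI still lands within ~2% of the true inflection time. Per-segment
parameters are available in long form (hills carry one row per
sigmoid):

```r
head(resultsLongTable(rs)[, c("locus","predicted","final","segment",
                              "b","tti","rss")], 4)
#>            locus predicted final segment          b      tti       rss
#> 1 2L.1_rise_0001      rise  rise    rise -1.1780927 5.711757 4.4956203
#> 2 2L.1_rise_0002      hill  hill    rise -0.4844644 8.252664 4.4128355
#> 3 2L.1_rise_0002      hill  hill    fall 12.1072259 7.826681 0.1878818
#> 4 2L.1_rise_0003      rise  rise    rise -0.5965932 4.846533 6.4152344
```

`b < 0` marks the increasing segment and `tti` its midpoint-crossing
time; `rss` is the segment's residual sum of squares, directly
comparable with the linear-fit residuals reported in the same table.

For real data, start from files instead:

```r
rs <- runPipeline(bedPath = "peaks.bed",
                  bamDirs = c("rep1/", "rep2/"),   # one BAM per time point
                  inputDirs = "input/",
                  timePoints = c(0, 30, 60, 120, 240),
                  outDir = "out/")
```

or, with coverage already normalized elsewhere,
`runPipeline(countsPath = "counts.tsv")`. A thin command-line wrapper
with the same options ships in
`system.file("scripts", "chipturnover-cli.R", package = "chipTurnover")`.

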