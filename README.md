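# SegKinetics

Segmented-regression kinetics for minute-scale RNA-seq time courses.

When cells are sampled for RNA-seq every few minutes after a stimulus —
for example mouse and human pluripotent stem cells during the first ten
hours of neural differentiation — the question is no longer *which* genes
respond but *when* and *how fast*. SegKinetics answers it per gene with a
continuous piecewise-linear (breakpoint) model and compares the resulting
kinetic summaries between two datasets (species, conditions, sampling
designs). It is written for computational biologists analyzing dense bulk
time courses with tens to hundreds of timed samples per series.

## The model

After median-ratio normalization, a mean ≥ 10 expression filter, and
scaling each gene to the unit interval
(X = (Y − min Y) / (max Y − min Y)), each profile is fit with

    X(t) = β₀ + β₁ t + Σₖ γₖ (t − bₖ)₊ ,   k = 1 … K

a continuous piecewise-linear trend whose breakpoints b₁ < … < b_K mark
times at which expression changes course. For K = 0…5 the breakpoints are
optimized by least squares under a minimum-segment rule (each segment must
contain ≥ 5 observed points on a 4-minute grid, ≥ 3 on a 10-minute grid),
and the K with the lowest BIC = n·log(RSS/n) + (2 + 2K)·log(n) wins.
Segments are labelled up/down/same by a slope t-test (α = 0.2); genes with
adjusted R² > 0.2 are *dynamic* (a permutation routine recalibrates that
gate for new designs). Direction sequences map to a pattern taxonomy —
monotonic up/down, (delayed) peak, (delayed) dip, delayed up/down,
immediate on/off, cyclic — and the cross-dataset statistics are:

* **ΔM** — Hodges–Lehmann shift (minutes) of breakpoint or peak times,
  group B relative to group A, with Wilcoxon-inverted 99% CIs (paired for
  1:1 orthologs); positive = A earlier.
* **ΔP%** — difference in the percentage of genes in a category (immediate
  onset, monotonic), with Yates-corrected two-proportion 99% CIs.
* **ΔS** — ratio of median slope magnitudes (A/B) with a seeded percentile
  bootstrap 99% CI; > 1 = steeper (faster) kinetics in A.

A negative-binomial simulator (`simulateTimeCourse()`,
`simulatePairedSpecies()`) generates count matrices with known piecewise
kinetics, a stable background-gene majority, log-normal size factors and
variance μ + φμ², so every stage is testable against ground truth.

## Worked example

Simulate 150 ortholog pairs in which species A runs 2.5× faster than
species B (A on a 4-minute, 145-sample grid; B on a 10-minute, 61-sample
grid), run the full pipeline, and read off the ortholog-paired contrasts:

```r
library(SegKinetics)
cfg <- list(seed = 1,
            simulate = list(nGenes = 150, speedup = 2.5, dispersion = 0.05),
            bootstrapB = 2000)
run <- runPipeline(cfg)
subset(run$comparisons, scope == "ortholog")
```

```
              statistic    scope estimate   ciLow ciHigh  nA  nB
 deltaM_firstBreakpoint ortholog  131.940  49.940 187.43  63  63
        deltaM_peakTime ortholog  220.651 142.489 298.42  17  17
          deltaS_peakUp ortholog    1.889   0.845   4.08  17  17
        deltaS_peakDown ortholog    0.554   0.229   2.26  17  17
       deltaP_immediate ortholog    9.333  -1.960  20.63 150 150
       deltaP_monotonic ortholog  -18.667 -33.895  -3.44 150 150
     deltaS_immediateUp ortholog    1.226   0.937   1.70  74  70
   deltaS_immediateDown ortholog    1.363   0.919   1.94  60  50
```

Reading the output: first breakpoints come ~132 minutes earlier in the
fast species (99% CI 50–187, excluding 0) and first peaks ~221 minutes
earlier; the fast species has ~19 percentage points *fewer* monotonic
orthologs (negative ΔP%, because slow-species trends often run past the
end of the 600-minute window and look unbroken); and up-slopes at peaks
are ~1.9× steeper. In the same run, 55 dynamic genes were monotonic in
species A versus 83 in species B, and A's breakpoint census was 9 / 25 /
80 breakpoints before 60 / 100 / 250 minutes. With `outDir=` the pipeline
writes every table (fits, patterns, censuses, size factors, ground truth,
comparisons) as TSV plus a log.

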