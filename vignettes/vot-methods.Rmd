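---
title: "Detecting variable-occupancy target regions from replicated ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variable-occupancy target regions from replicated ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

ChIP-seq peak calls for the same antibody in the same cell type differ
between biological replicates. The usual response is to keep only the
replicate-consistent peaks (e.g. via IDR) and discard the rest as
noise. But when the *same* genomic region is inconsistent across
replicates for several unrelated protein targets, the inconsistency is
a property of the region, not of any one experiment. `votcaller`
formalizes this idea: it scores per-protein reproducibility on a fixed
genome grid, aggregates proteins, and calls variable-occupancy target
regions (VOTs) where no protein's binding is reproduced.

```{r setup}
library(votcaller)
```

## The model

**Segmentation.** The genome is tiled with consecutive windows of
`bin_width` bp (default 200 bp, the typical scale of a ChIP-seq peak
summit neighborhood). The final window of each chromosome is truncated
rather than discarded, so peaks near chromosome ends are never lost;
segment ids follow the chromosome order of the `chrom.sizes` input, for
determinism. A peak marks a segment when it overlaps it by at least
`min_overlap` bp (default 1 bp — the most permissive deterministic
choice; no minimum-overlap fraction is imposed because peaks and
segments are on the same coordinate scale).

**Per-protein score.** For a protein with $N$ replicates, each
replicate contributes a binary per-segment occupancy; their sum $P_s
\in \{0, \dots, N\}$ counts replicates, not raw peaks, so $P_s \le N$
by construction. Segments with $P_s = 0$ are `NA`. A *block* is a
maximal run of consecutive segments with $P_s > 0$; blocks terminate at
chromosome boundaries because genomic adjacency is meaningful only
within a chromosome. All segments of a block score 1 if any of its
segments reaches $P_s = N$ (the binding is reproduced somewhere in the
contiguous signal region), else all score 0. The block construction
means a scored region is judged as a unit: a peak shifted by one
segment between replicates still yields a reproducible block.

**Final score.** Per-protein scores are the columns of the
reproducibility score matrix. The final score of segment $s$ is the
mean of its non-`NA` entries, defined only when at least `min_non_na`
proteins have data; the default `n_proteins - 1` reproduces the
"at least three of four proteins" rule and generalizes it. With four
proteins the attainable values are $\{0, \tfrac14, \tfrac13, \tfrac12,
\tfrac23, \tfrac34, 1\}$; the package enumerates this set from the data
(`attainable_scores`) instead of hard-coding the four-protein case.

**VOTs.** Maximal runs of consecutive segments at FS equal to
`variable_score` (default 0) are merged into regions. Segments with
undefined FS always break a region — missing evidence is not treated as
agreement. The cut-off is exposed as a parameter because "variable"
could reasonably include low non-zero scores; 0 is the strictest
reading (no counted protein reproduced).

```{r example}
rsm <- build_rsm(
  list(score_protein(c(0, 1, 2, 1, 0, 1, 0), 2, protein = "A"),
       score_protein(c(0, 2, 2, 0, 0, 1, 0), 2, protein = "B")),
  bin_genome(c(chr1 = 1400), 200), min_non_na = 2)
data.frame(FS = rsm$fs)
call_vots(rsm)
```

## The permutation null

Whether the observed number of regions at a score is surprising is
judged against randomized matrices: each protein column is permuted
independently over segment positions, preserving every column's value
multiset (including its `NA`s), and regions are re-counted with the
identical merge rule. This is the weakest null that preserves
per-protein marginal behavior while destroying the spatial arrangement;
a `global` full-matrix shuffle is available as an alternative
interpretation, since the randomization unit is not uniquely determined
by the verbal description of the procedure. With observed count
$\delta$ and null mean and standard deviation $\delta_{rand},
\theta\delta_{rand}$,

$$ z = \frac{\delta - \delta_{rand}}{\theta\delta_{rand}}, $$

and the p-value is the upper-tail standard-normal probability — the
question is whether real data produce *more* same-score regions than
chance; a two-sided option exists. The default 1000 iterations put the
Monte-Carlo standard error of the null mean near
$\theta\delta_{rand}/30$. No multiple-testing correction is applied
across score levels. When the null is degenerate (zero standard
deviation) z and p are reported as undefined with a warning rather
than an error, because this occurs legitimately on tiny or constant
matrices.

## Characterization analyses

*Enrichment* of a region set at a feature is the number of regions
overlapping the feature divided by the mean overlap count of matched
control sets; controls are random relocations that preserve region
count, lengths and (by default) chromosome, are non-overlapping within
a set, and can avoid an exclusion mask. A zero denominator is reported
as undefined rather than patched with a pseudocount (a `pseudocount`
argument exists for users who prefer otherwise). *Interval association*
is tested with a two-sided Fisher exact test whose counting unit is the
grid segment — the method's native resolution, which makes the 2x2
universe well-defined; base-pair or region units would be defensible
alternatives but are not the default. *Dinucleotide composition* is the
per-region frequency of a 2-mer over overlapping windows, excluding
windows that contain `N` from numerator and denominator; group
differences use the Welch t-test. *Replicate clustering* builds the
binary samples x occupied-segments matrix, reports within-protein
Euclidean distances in the full feature space (deterministic and
directly interpretable; distances in PC space can be derived from the
returned projection), and projects samples onto two principal
components without scaling — binary presence features share a scale,
and standardizing them would inflate rarely occupied segments.

## The simulator

`simulate_experiment` emulates the data model the method assumes: a
small genome (default one 200 kb chromosome; large enough for ~30
blocks with spacing, small enough for fast tests), 4 proteins x 2
replicates, 20 reproducible and 10 variable planted blocks of 1-3
segments separated by at least one empty segment so truth regions are
unambiguous. Reproducible blocks get a peak in every replicate of every
protein. Variable blocks are guaranteed, per protein, to have at least
one replicate with and one without the block — in `guaranteed` mode
exactly one replicate is dropped (making truth recovery exact, which
separates algorithmic-correctness tests from stochastic ones), in
`bernoulli` mode replicates are dropped independently with probability
`dropout` (default 0.5), redrawing degenerate all-or-none draws.
Optional background noise adds independent single-segment peaks outside
planted blocks at a per-segment rate; single-segment noise keeps the
analytic expectations for block formation tractable. All randomness
derives from one seed and outputs are byte-stable.

What the simulator does *not* model: read-level noise, peak-width and
signal-strength distributions, antibody efficiency, GC amplification
bias, or correlated artifacts between proteins. Passing tests therefore
demonstrate the correctness of the scoring, merging and testing
machinery under the stated data model — not that real ChIP-seq peak
sets satisfy that model.

## Numerical choices and edge cases

- Score matching in region extraction uses an absolute tolerance of
  1e-9, comfortably below the minimal spacing (~0.0833) between
  attainable FS values for realistic protein counts.
- Degenerate inputs: chromosomes shorter than one bin yield a single
  truncated segment; empty peak files yield an all-`NA` track; an
  all-`NA` matrix yields zero regions at every score and an undefined
  z.
- Coordinates are 0-based half-open in all files (BED dialect) and
  1-based closed inside R (`IRanges` convention); conversion happens
  exactly once at I/O boundaries.
- narrowPeak column 7 is read as fold-change enrichment and column 9 as
  $-\log_{10} q$, per the ENCODE convention; FDR $\le$ 5% therefore
  means column 9 $\ge 1.301$. A negative column 9 encodes "missing".
- `sample.int`-based permutations and placements make every stochastic
  component reproducible from an integer seed.

## Problem sizes in the tests

The bundled tests run the oracle-equivalence property on 1000 random
score vectors (grids up to 50 segments), exhaustive Fisher enumeration
on all 2x2 tables with total up to 30, 20-seed exact-recovery runs on
100 kb genomes, and a 1000-iteration null on toy matrices — sizes
chosen so the whole suite exercises every contract in well under the
time a desk check should take.

## Limitations

- The method needs several proteins assayed in the same cell type under
  comparable protocols; with fewer than three informative proteins per
  segment FS is undefined and nothing is called.
- The normal approximation of the null can be poor when expected region
  counts are very small; the permutation counts are returned so users
  can compute empirical p-values instead.
- VOT calling at FS exactly 0 is strict: regions where a single protein
  reproduces are not VOTs under the default.
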