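---
title: "Benchmarking chromatin loop callers with loopbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking chromatin loop callers with loopbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopbench)
```

## The problem

Chromatin loops are long-range contacts between two genomic loci
(anchors) detected from chromosome-conformation data such as Hi-C. Many
loop callers exist (cLoops, Mustache, HiCCUPS, ...), they disagree
substantially, and a lab choosing one needs comparable, caller-agnostic
metrics. `loopbench` takes the callers' outputs — BEDPE files of anchor
pairs, tagged with the caller name and the contact-matrix resolution —
together with BED tracks of protein-associated regions (CTCF, H3K27ac,
RNAPII peaks) that serve as biological ground truth, and computes a
standard panel of comparison metrics plus a weighted aggregate score for
ranking.

All coordinates are treated as BED-convention 0-based half-open
intervals; abutting intervals do not overlap. Within each loop the two
anchors are sorted by `(chrom, start)` on input, so every downstream
computation is orientation-free.

## The metrics

**Recovery rate (δ).** For a reference track with $N_{ref}$ records and
a loop set, each anchor is padded by a window $w$ (default 50 bp) and

$$\delta = \frac{N_o}{N_{ref}},$$

where $N_o$ is the number of *distinct reference records* overlapped by
at least one padded anchor. Counting recovered reference records (rather
than overlap events or recovering loops) bounds $\delta$ in $[0,1]$ and
makes "recovery of the reference" literal; the alternative loop-counting
normalization is available via `count_mode = "loop"`. Either anchor
suffices — nothing distinguishes the two anchors of a loop biologically
here. The window is applied to the loop anchors only, once; padding both
sides would silently double the effective tolerance.

The *recovery curve* evaluates $\delta$ over cumulative loop prefixes of
1000 (configurable), in file order by default since callers emit
significance-sorted output, or by the score column with
`order = "score_desc"` (ties stable in file order). The curve is
non-decreasing by construction and its endpoint is the full-set recovery
rate.

**Recovery Efficiency Metric (REM, Δ).** $\Delta = \delta / N_c$ with
$N_c$ the loop count. Dividing by the loop count removes the advantage a
tool gets simply by calling enormous numbers of loops.

**Resolution consistency (Λ).** With user-defined high (default 5 kb,
10 kb) and low (default 100 kb, 250 kb) resolution groups,
$\Lambda = |\bar\chi_{low} - \bar\chi_{high}|$, where each $\bar\chi$ is
the unweighted grand mean of Δ over the group's resolutions and all
reference features. Features and resolutions are pooled with equal
weight because no principled feature weighting exists at this stage;
smaller Λ means behaviour that is stable across resolutions. Missing
resolution-feature cells are an error listing the missing pairs, not a
silent average over fewer cells.

**Cross-caller overlap.** Loop identity across callers is fuzzy: two
tools rarely emit identical coordinates for the same contact. Two loops
*match* when they lie on the same chromosome pair and both corresponding
anchor midpoints differ by at most `tol` bp. The default tolerance is
the largest resolution among the sets being compared — coordinates can
legitimately disagree by up to a bin. Because this relation is not
transitive, three-set Venn counts are defined on *connected components*
of the match graph over the union of the three sets ("loop clusters"):
each cluster falls into one of the seven Venn regions according to the
callers it contains. This partition is symmetric and independent of set
and loop order, which no greedy per-set assignment achieves. A cluster
merging several near-duplicate loops from one caller counts once.

The per-tool *consistency percentage* scores a caller against pairs of
partners: for each triplet, 100 × (target loops in a cluster containing
all three callers) / (target loop count), normalized by the target's own
loop count so the score reads as "what fraction of this tool's calls do
two independent tools corroborate". The default policy averages over
*all* partner pairs; a seeded sampling policy (`policy = "sample"`,
`k = 5`) reproduces workflows that score each tool against a fixed
number of triplets, and requires an explicit seed because no canonical
subset exists.

**Size regression.** "Loop size" is the distance between anchor
midpoints — robust to caller-specific anchor widths, which are largely a
resolution artifact (the outer extent `end2 − start1` is available via
`mode = "extent"`). Each caller-resolution pair contributes one point
(mean size, resolution) and `resolution ~ size` is fitted by ordinary
least squares — resolution is the dependent variable. Both kb and bin
(size / resolution) scales are fitted, and per-category fits are
produced when the user maps callers to categories; categories with
fewer than two points are skipped with a warning rather than failing
the job.

**Aggregate score (μ).** Feature scores $X_i$ (biological = mean REM
across features; consistency = mean overlap percentage as a fraction;
optionally a user-supplied computational score) combine as

$$\mu = \frac{\sum_i W_i X_i}{\sum_i W_i},$$

a convex combination: bounded by the component extremes, monotone in
each component, invariant under rescaling all weights. Default weights
are biological = 2, consistency = 1, reflecting the view that biological
corroboration matters more than inter-tool agreement; both are
overridable. The package never measures a computational (runtime) score
itself — that is hardware-dependent — but accepts one. Ranking is by
decreasing μ with lexicographic tie-breaks on the caller name so ranks
are deterministic. Note that the biological and consistency components
live on different natural scales (REM values are small because of the
loop-count normalization); μ is therefore meaningful for *ranking*
under fixed weights rather than as an absolute quantity, and the
bundled `gm12878_tool_scores()` example is validated by its ranking,
not by any printed aggregate.

## Worked example

```{r example}
spec <- fixture_spec(seed = 7, n_refs = 100, recovery_fraction = 0.25,
                     n_loops = 200)
ref <- make_reference(spec)
loops <- make_loops_with_recovery(ref, spec)
recovery_rate(ref, loops, window = 50)
rem(recovery_rate(ref, loops, window = 50), n_loops(loops))
```

```{r bcc}
tab <- gm12878_tool_scores()
ranked <- compute_bcc_table(
  consistency = setNames(tab$consistency_pct, tab$tool),
  biological = setNames(tab$biological_pct / 100, tab$tool))
head(data.frame(caller = sapply(ranked, `[[`, "caller"),
                mu = sapply(ranked, `[[`, "mu")), 3)
```

## The synthetic-data generator

Fixtures are placed on a *guarded lattice*, not sampled uniformly:
reference peaks are spaced with gaps strictly larger than
`2 * (window_guard + peak width)`, recovering loop anchors are planted
inside their peak, and all other anchors live in a decoy zone more than
`window_guard` (default 200 bp) from every peak. Consequently a planted
recovery fraction `p` is returned *exactly* by `recovery_rate` for any
window up to the guard, and tests assert equality instead of
statistical closeness. Venn fixtures likewise emit one shared
coordinate per designed cluster, with clusters spaced beyond twice the
matching tolerance, so designed region counts round-trip exactly.
Default fixture scale — 100 reference peaks, 150–200 loops, 50-bp
analysis window with a 200-bp guard — keeps every planted-truth check
well under a second while exercising all code paths.

Generators are pure functions of the spec seed (which references are
recovered, loop shuffling); they save and restore the global RNG state.
What the fixtures deliberately do *not* emulate: realistic Hi-C
contact-frequency decay, peak-width and loop-size distributions,
chromosome-scale coordinate structure, or correlated errors between
callers. Passing tests therefore demonstrate the *metrics* are computed
correctly, not that any caller performs well on real data.

## Numerical and design choices

- **Determinism of reports.** JSON reports use fixed key order and 10
  significant digits, and contain no timestamps; reruns on identical
  inputs are byte-identical. Timings go to the plain-text log only.
- **Degenerate inputs.** Empty reference sets make δ undefined (error,
  not `NaN`); zero loop counts make REM undefined; a zero-variance size
  column makes the regression singular (error). Empty loop sets,
  duplicate loops and inter-chromosomal loops are surfaced as
  validation warnings; inter-chromosomal loops are excluded from size
  statistics with a warning.
- **Jobs degrade gracefully.** Without reference tracks, recovery and
  the aggregate score are marked skipped while overlap and regression
  still run; resolutions with fewer than three callers skip the Venn
  analysis; an incomplete resolution grid skips Λ for that caller, with
  the reason logged.
- **Dialect tolerance.** Comment/`track`/`browser` lines are skipped,
  trailing BED/BEDPE columns ignored, gzip accepted by extension, and
  an optional `chr`-prefix normalization guards against the silent
  zero-recovery artifact of mismatched chromosome dialects.
- **Size guard.** Inputs above 100 MB (configurable) are rejected
  outright, a sanity limit far above typical loop-caller output.

## Problem sizes in the test and acceptance suites

Oracle-equivalence checks run 100 seeded random instances of up to 200
references × 200 loops against a naive all-pairs scan; the OLS fit is
checked against closed-form normal equations on 100 random instances;
Venn round-trips cover boundary designs plus seeded random designs with
region counts up to 5; the end-to-end determinism check runs a
3-caller × 2-resolution × 2-feature fixture job twice and compares
bytes. These sizes were chosen as the smallest that exercise every
branch of the interval machinery while keeping the whole suite fast
enough to run on every change.

## Known limitations

- Recovery treats each reference record atomically; partial overlaps
  count fully and peak width is not weighted.
- The cluster-based Venn can chain distant loops through intermediates
  at large tolerances (components, not cliques); at the default
  bin-scale tolerance this is rare but not impossible.
- Λ compares exactly two resolution groups; gradients across many
  resolutions are not summarized.
- No statistical testing of δ differences between callers is provided;
  the metrics are descriptive.
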