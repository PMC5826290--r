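---
title: "CATaDa accessibility analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CATaDa accessibility analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catada)
```

# Overview

CATaDa (Chromatin Accessibility profiling using Targeted DamID)
profiles chromatin accessibility by expressing untethered *E. coli* Dam
methylase in a chosen cell type. Dam methylates adenines in GATC
motifs wherever chromatin is open, so the sequencing signal reports
accessibility at the resolution of **GATC fragments** — the genomic
intervals between consecutive GATC motifs. `catada` implements the
full downstream analysis at that native resolution: signal tracks,
peak calling with a permutation false discovery rate, differential
accessibility, enhancer nomination, interval-overlap statistics,
genome-wide accessibility summaries, and metaprofile aggregation. A
synthetic-data module generates genomes, annotations and reads with
known ground truth, so every statistical claim in the package is
testable end to end.

All internal coordinates are 0-based half-open; GFF3 output is 1-based
closed. A GATC motif's four base pairs belong to the fragment that
starts at the motif.

# The fragment map

`find_gatc_sites()` scans a sequence for GATC motif starts and
`build_fragment_map()` partitions each chromosome at those starts:

```{r}
genome <- c(chrT = "AAGATCTTGATCAA")
find_gatc_sites(genome[[1]])
map <- build_fragment_map(genome)
as.data.frame(map)
```

Fragment ids are global and ordered by chromosome then coordinate, so
a run of consecutive ids on one chromosome is a contiguous genomic
interval.

# Signal tracks

Reads are assigned to fragments by their 5' position
(`count_reads_per_fragment()`) and normalised to **rpm** (reads per
million assigned reads, `normalize_rpm()`), the unit used by every
downstream rule. Because rpm always sums to one million over the map,
fragment-level thresholds stated in rpm (20 rpm differential, 10 rpm
enhancer, the 1–3 rpm band) are comparable across samples of different
depth.

On a desk-scale synthetic map the same total mass is spread over far
fewer fragments than in a real genome, which multiplies every
per-fragment rpm by a common constant. The package treats all rpm
thresholds as *intensity units*: the synthetic generator plants
regions whose expected intensities are specified in those units, so
run detection, FDR and recovery behave identically at any scale.

# Peak calling with a permutation FDR

A **candidate peak** is a maximal run of two or more consecutive
fragments with rpm above a floor (default: any non-zero signal),
scored by its mean member rpm (`enumerate_candidate_peaks()`). The
null model is a whole-track permutation: fragment rpm values are
shuffled across the map, destroying spatial structure while keeping
the marginal distribution. For a score threshold `t`,

    FDR(t) = mean over shuffles of #{null candidates >= t} / #{observed candidates >= t}

clipped to [0, 1]. The value reported for a peak of score `s` is the
q-value `min over t <= s of FDR(t)`: the best FDR attainable by any
threshold that still calls the peak. This makes the reported values
monotone in score and immune to the small-denominator noise of the
raw estimate at the very top score, where the denominator is a single
peak. Peaks with q-value below 1% are significant
(`call_significant_peaks()`), and the final peak set is the
fragment-level intersection over replicates
(`intersect_replicate_peaks()`): every reported fragment run is
significant in *all* replicates. Peaks are mapped to overlapping or
nearest genes within 5 kb (`assign_peaks_to_genes()`).

Why this works at fragment resolution: after shuffling, two strong
fragments must land adjacent to form a competing null run. With `m`
strong fragments on an `N`-fragment map the expected number of null
adjacencies per shuffle is about `m (m - 1) / N`, so on realistic maps
(tens of thousands of fragments, tens of strong fragments) the null
rarely produces a high-scoring run and implanted signal separates
cleanly.

# Differential accessibility

Fragment `f` is differential for the ordered cell-type pair (A, B)
when *every* replicate of A exceeds *every* replicate of B by more
than 20 rpm — equivalently `min(A) - max(B) > 20` at `f`
(`find_differential_fragments()`). The reported magnitude is the
minimum cross-replicate difference, the most conservative effect
size. Adjacent differential fragments merge into regions
(`merge_differential_fragments()`); alternatively
`call_differential_regions()` subtracts replicate-mean tracks (zeroing
negatives) and runs the permutation peak caller on the comparison
track, yielding FDR-controlled directional regions. Regions are
summarised in a region-by-cell-type rpm matrix
(`build_region_matrix()`) and clustered by average-linkage
hierarchical clustering of row-standardised profiles
(`hierarchical_cluster()`).

# Enhancer nomination

`predict_enhancers()` applies the published geometric filters to
differential regions: member fragments must differ by more than 10 rpm
in all replicate pairs, the merged region must lie strictly more than
2 kb from every TSS (edge-to-point distance; ties reject), and it must
not overlap annotated coding sequence by even one base pair. Missing
CDS annotation is an error rather than a silent pass. Candidates are
ranked by the magnitude of their accessibility change.

# Interval-overlap statistics

`peak_overlap_fraction()` reports the fraction of a reference peak set
touched by a query, optionally stratified into promoter-proximal and
distal peaks. `monte_carlo_overlap()` tests significance by uniformly
re-placing the query intervals within their chromosomes
(length-preserving) and computing the add-one permutation p-value

    p = (1 + #{null >= observed}) / (n + 1),

which is never zero and is exact for exchangeable placements.
`shared_peak_height_correlation()` and `correlation_matrix()`
(Spearman) quantify signal agreement at shared peaks and across
tracks; `pca_cell_types()` embeds cell types by their track profiles.

# Genome-wide accessibility summaries

`band_fraction()` computes the fraction of fragments in the inclusive
1–3 rpm band — the paper's proxy for the breadth of weakly open
chromatin, high in stem-like cells. `zero_fraction()` counts
fragments with zero raw reads, and `log_density()` summarises the
log1p-rpm distribution. Cell-type band fractions are compared by
Welch's ANOVA with Games–Howell post-hoc tests
(`compare_group_fractions()`), which assume neither equal variances
nor equal group sizes; with two groups the post-hoc test reduces to
Welch's t-test.

# Aggregation metaprofiles

`aggregate_at_points()` averages piecewise-constant fragment signal in
fixed bins around anchor points (e.g. TSS), flipping windows on
minus-strand anchors; `aggregate_at_intervals()` rescales interval
bodies to a common internal length with real-bp flanks. Bins
truncated by chromosome ends contribute only their covered bases.

# Synthetic data with ground truth

`simulation_spec()` describes a study: a multi-chromosome genome with
geometrically spaced GATC motifs (median spacing ≈ mean × ln 2, as in
a random-sequence model of the fly genome's ~200 bp spacing), genes
with TSS and CDS, cell types with optional lineage structure, and
per-cell-type accessibility landscapes. Landscapes are built from a
uniform background with a *closed* fraction of exactly-zero fragments
(fully compacted chromatin breaks runs, as in real data), a
low-accessibility class, and implanted open regions — runs of ≥2
fragments whose immediate flanks are silenced so the region's
boundaries are well defined. Reads are drawn multinomially from the
intensity vector at the configured depth, independently per
replicate. Ground truth records every region, the per-fragment
expected rpm, and which cell-type-specific regions satisfy the
enhancer filters. `simulate_null_track()` produces exchangeable
tracks for which the permutation null is exact, and
`simulate_global_landscape()` directly models zero/low/open fragment
classes for the band-fraction analyses (at depth 10^6 one read equals
one rpm, so the 1–3 band is literal).

```{r}
spec <- simulation_spec(seed = 1, n_chroms = 1L, chrom_length = 1e5,
                        n_genes = 5L, depth = 2e5)
gen <- generate_genome(spec)
sim <- simulate_tracks(spec, gen$map, gen$annotation)
head(sim$truth$regions)
```

# Pipeline and reproducibility

`run_catada()` wires the stages into subcommands (`simulate`,
`fragment-map`, `count`, `peaks`, `diff`, `enhancers`, `overlap`,
`global`, `aggregate`) driven by a single YAML config
(`read_config()`), writing artifacts plus a `manifest.json` with
parameters and input checksums. All stochastic steps take explicit
seeds and deterministic stages are bit-reproducible: re-running a
stage with an identical config reproduces identical files.

# Limitations

* The permutation null models fragment exchangeability, not
  copy-number or mappability structure; real data may need
  fragment-level blacklists.
* rpm thresholds inherit the paper's fixed values (20 rpm, 10 rpm,
  1–3 rpm); on desk-scale synthetic maps they are interpreted as
  intensity units rather than literal sequencing rpm.
* Enhancer nomination is purely geometric (distance and coding
  overlap); it does not consult conservation or chromatin marks.
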