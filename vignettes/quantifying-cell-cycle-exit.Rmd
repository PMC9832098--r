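---
title: "Quantifying cell-cycle exit and TF dosage in neural progenitor cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cycle exit and TF dosage in neural progenitor cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscquant)
```

## The measurement problem

Adult neural stem and progenitor cells exit the cell cycle asynchronously
as they differentiate. A cell's position relative to the
restriction point can be read from a CDK2 kinase translocation reporter
(DHB-mVenus): unphosphorylated sensor accumulates in the nucleus, and
CDK2 phosphorylation during the G1/S transition drives it into the
cytoplasm. The cytoplasm/nucleus fluorescence ratio (C/N) of a single
cell is therefore a proxy for that cell's CDK2 activity, and the
distribution of C/N across a culture summarizes how much residual CDK2
activity persists after mitogen withdrawal.

Extracting C/N from images requires solving three problems per field:
which nuclei belong to cells that actually carry the reporter, how to
split the reporter-positive area between touching cells, and how to
isolate the cytoplasm of each cell. `nscquant` implements the full chain
and, around it, the study's other quantitative readouts: nuclear marker
profiling, comparative-Ct ChIP quantification, dual-luciferase ratios and
the joint categorization of chromatin accessibility and expression
changes.

## The CDK2 reporter workflow

Given a DAPI image and an mVenus image of the same field:

1. **Nuclear segmentation.** Global threshold on the DAPI channel, hole
   filling, connected-component labelling, removal of particles below
   `min_nucleus_area` (default 50 px, small enough to keep any plausible
   nucleus at the magnifications this data comes from while rejecting
   debris). Labels are renumbered contiguously.
2. **Cell segmentation.** Threshold on the reporter channel; the
   foreground is the reporter-positive area (nucleus plus cytoplasm of
   infected cells).
3. **Uninfected-cell removal.** A nucleus is kept iff at least
   `min_overlap_for_infected` (default 0.5) of its pixels fall inside the
   cell mask. The source protocol states only that mVenus-negative nuclei
   are discarded; the 50% overlap default makes that rule robust to
   one-or-two-pixel boundary disagreements between the two channels.
4. **Voronoi separation of touching cells.** The cell mask is partitioned
   among the retained nuclei: every foreground pixel is assigned to the
   nucleus *region* (not centroid) whose nearest pixel is closest in
   Euclidean distance, with ties resolved toward the lowest label so the
   partition is deterministic. This is the natural formalization of a
   seeded Voronoi split of clumped cells; the per-seed distances come
   from EBImage's exact Euclidean distance transform, and the suite
   checks the assignment pixel-for-pixel against an exhaustive
   nearest-seed search.
5. **Cytoplasm derivation.** Per label, cytoplasm = cell region minus
   nucleus pixels (mask XOR). By construction nucleus and cytoplasm are
   disjoint and their union is the cell's Voronoi region; the suite
   asserts this pixel-wise.
6. **Measurement.** Masks are redirected onto the original gray image:
   N and C are mean grays over the nucleus and cytoplasm, the C/N ratio
   their quotient (absent when the cytoplasm mask is empty), and the
   cytoplasmic integrated density (IntDens) the sum of gray over
   cytoplasm pixels. No background subtraction is applied by default; a
   constant-subtraction option exists (`background_subtract`) because C/N
   is a ratio and a nonzero baseline biases it toward 1.
7. **Classification and scoring.** A cell is G0/G1 when it has no
   cytoplasmic mask or C/N is strictly below `cn_g0g1_threshold`; the
   default 0.65 follows the protocol's classification rule. Residual
   CDK2 activity of a condition is the mean IntDens over its G0/G1
   cells, reported as fold change against a reference condition. A
   culture passes QC when at least `min_cells_per_culture` (default 250)
   cells were scored.

### Threshold selection

The thresholding method of the original macro is not documented, so the
choice is this package's own. For the DAPI channel a plain two-class Otsu
works: the histogram is background vs. nuclei. The reporter channel is
different — background, cytoplasm and nucleus often form *three* modes,
and a two-class Otsu can land between the two signal modes, truncating
cytoplasms wholesale (on a synthetic 100/300/1000 gray-level mixture it
cuts at ≈384, above the cytoplasmic level). The default for
`segment_cells()` is therefore the *lower* threshold of a three-class
(two-threshold) Otsu, which separates background from any reporter
signal regardless of how nuclear and cytoplasmic levels relate. Plain
Otsu and fixed numeric thresholds remain selectable through
`workflow_config()`.

The cell mask is deliberately *not* hole-filled: when two touching cells
curve around a background pocket, filling would promote
non-reporter-positive pixels into somebody's cytoplasm and bias C and
IntDens (observed on synthetic clumps as ~7% C/N error in affected
cells). Nuclei, being solid, are hole-filled as usual.

### The 0.65 vs 0.95 threshold

The source describes G0/G1 classification at C/N below 0.65 in its
protocol text but refers to G0/G1 cells as C/N < 0.95 elsewhere. The
package does not resolve this: 0.65 (the protocol value) is the default,
the threshold is a plain config parameter, and the comparison is strict
(`<`) in accordance with the protocol's "lower than" wording.

## Marker profiling

Per-nucleus mean intensities of nuclear markers are measured through the
same label-mask machinery (`measure_nuclear_markers()`), optionally after
a maximum-intensity projection (`max_project()`). Population summaries
follow the study's conventions:

* **Frequency histograms** use bins shared across the populations of one
  comparison (default 50 bins over the pooled range) and are normalized
  by the single maximum bin count of the comparison, so the modal bin of
  the comparison equals 1 and the two curves remain comparable.
* **Percent positive** is computed against either the supplied
  subpopulation or an external denominator (e.g. total DAPI nuclei).
  When no threshold is given, an Otsu split of the supplied intensities
  is used and logged — a reproducible stand-in for manual gating, not a
  claim about the original scoring.
* **Top-fraction "high" calls** label the `ceiling(0.30 * n)` brightest
  cells; the threshold is the dimmest high cell and ties at the
  threshold are included (logged when the set exceeds the nominal
  count). Whether the original "30% brightest in both conditions" pooled
  the conditions or was applied per condition is not stated; the
  function operates on any intensity vector, so both modes are
  available, and neither is asserted as the original.

## Comparative-Ct ChIP quantification

For each region and condition, replicate Cts are averaged per (antibody,
fraction, dilution); each antibody's ΔCt = Ct(bound) − Ct(input) is
formed per dilution; and the fold enrichment of the specific IP over the
non-related antibody is `efficiency^(ΔCt_NRA − ΔCt_IP)`, geometric-mean
combined across dilutions (equivalently the arithmetic mean of ΔΔCt).
Under the default perfect-doubling efficiency the dilution offset cancels
exactly, which the suite asserts. Averaging replicate Cts *before* the
difference (rather than averaging per-replicate folds) is standard
comparative-Ct practice; the source is silent on this point. A region is
called positive only when Ct(IP) < Ct(NRA), strictly, in at least two
distinct dilutions; with fewer than two usable dilutions the call is
"insufficient" rather than negative. Luciferase activities are
firefly/Renilla ratios, optionally relative to a reference ratio.

The synthetic Ct generator inverts this model: template abundances are
mapped to Ct via `Ct = 40 − log2(abundance)` (the 40-cycle offset is
arbitrary and cancels in the double difference), diluting 1:d adds
log2(d) cycles, and the NRA pull-down recovers a fixed 0.001 of input
chromatin so that only the IP/NRA abundance *ratio* — the true fold —
matters. At zero noise the pipeline returns the true fold exactly, for
any fold and any dilution series.

## ATAC × RNA integration

Coordinates are 0-based half-open throughout; BED input is native, with
an explicit flag for 1-based tables. A peak is promoter-associated with a
gene iff it overlaps `[TSS − 3000, TSS + 3000)`; the window is symmetric
around the TSS for either strand, and the 5 kb flanking-gene distance
acts only as a maximum assignment distance (under the defaults the
window already lies within it). When several peaks hit one promoter the
cascade is: nearest peak midpoint to the TSS, then largest overlap with
the window, then lowest start coordinate. The source states the first
two criteria disjunctively ("either … or") without precedence; the
cascade here is a fixed convention so the assignment is deterministic,
and the final tie-break makes it total. DA and DE labels use strict
FDR < 0.05 with the peak's direction and the gene's fold-change sign;
how those FDRs were computed is upstream of this package. Only genes
significant in both modalities receive one of the four categories
(Closed_UP, Closed_DOWN, Open_UP, Open_DOWN); `intersect_conditions()`
then reports per-category Venn counts between two conditions and the
fraction of one condition's categorized genes lost in the other.

## What the synthetic data does and does not emulate

`generate_cell_field()` models cells as disk nuclei with concentric
annular cytoplasms — the simplest geometry that exercises every step of
the workflow, including clump splitting (touching pairs are placed with
overlapping annuli but disjoint nuclei, annulus overlap resolved to the
nearest nucleus). Default geometry (nucleus radius 8–12 px, cytoplasm
thickness 4–8 px at 512×512) corresponds to confluent NSC cultures at
typical confocal sampling. Intensities are uniform per compartment,
drawn per cell and rounded to integers so noiseless images reproduce the
ground truth exactly; noise is optional Poisson (shot) plus additive
Gaussian (read), off by default so exactness tests are exact and on for
robustness tests. RNG draw order is fixed and documented (infected
flags, clumped flags, geometry, intensities, noise) so individual draws
can be replayed independently in tests.

Not emulated: point-spread blur and other optics, intensity gradients
within compartments, z-stacks, photobleaching, irregular cell shapes,
and segmentation-adversarial texture. Passing the recovery tests
therefore demonstrates that the *measurement chain* is correct — masks,
partition, ratios, classification — not that segmentation is robust to
every real-world imaging artifact. The same applies to the gene-table
generator, which places genes in non-overlapping slots so the true
peak-gene assignment is unambiguous: it validates the assignment and
labelling logic, not behaviour on overlapping genes, which real
annotations contain.

## Validation problem sizes

The acceptance suite and `scripts/acceptance.R` use: 300 noiseless cells
(six 50-cell 640×640 fields) per true C/N ratio in
{0.3, 0.5, 0.8, 1.2, 2.0}; clumped 512×512 fields checked
pixel-for-pixel against exhaustive nearest-seed search; 300 cells per
condition for the noisy residual-activity fold (Gaussian sd 5 gray
levels); 100 Monte-Carlo replicates at 0.2 cycles of Ct noise; and
1,000-gene/~1,500-peak tables for the categorizer. Splitting the 300
cells across six fields keeps the per-label distance transform
proportionate (its cost scales with labels × pixels) without changing
any statistical property of the check.

## Known limitations

* Single-plane analysis only; the reporter workflow assumes the provided
  focal plane, and `max_project()` exists for the marker (not reporter)
  path.
* The Voronoi partition is Euclidean, not geodesic: for strongly
  non-convex clumps a pixel can be assigned across a background gap.
  With disk-plus-annulus geometry and the cell-mask restriction this
  does not arise.
* Amplification efficiency is a per-amplicon constant (default 2.0); the
  package does not estimate efficiency from dilution series.
* The categorizer consumes upstream FDRs as given; it performs no
  multiple-testing correction of its own.
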