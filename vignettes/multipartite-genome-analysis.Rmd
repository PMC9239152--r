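---
title: "Quantifying multipartite genome organization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multipartite genome organization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multihic)
```

## The biological problem

Many bacteria carry a multipartite genome: several replicons — here a
circular primary chromosome (Ch1, 2,841 kb), a linear secondary chromosome
(Ch2, 2,076 kb) and two plasmids (pAt, 542 kb; pTi, 216 kb), the
*Agrobacterium tumefaciens* C58 configuration. Chromosome conformation
capture (Hi-C) on such genomes shows three hallmark features beyond the
intra-replicon distance decay: *interarm* interactions (anti-diagonal stripes
within a chromosome whose two arms are juxtaposed), *origin clustering*
(enriched inter-replicon blocks where the ParB/RepB-bound centromeric regions
of all replicons co-locate at the cell pole), and a lengthwise *Ch1–Ch2
alignment* that appears as an X-shaped inter-chromosomal band. Single-cell
fluorescence microscopy complements this with origin focus counts,
green–red focus colocalization, and focus-to-pole distances; ChIP-seq
locates the centromeric and polar proteins on the genome.

`multihic` implements the quantitative core of such a study as a reusable,
tested pipeline: binned contact matrices with iterative correction,
region-based inter-replicon interaction percentages with background
subtraction, ChIP/input enrichment tracks with peak quantification, and
focus-table analytics — plus a synthetic-data generator so that the entire
analysis can be exercised and validated without any sequencing data.

## Coordinate system

Coordinates and bins are 1-based everywhere inside the package; bin `b`
covers base pairs `(b-1)*bin_size + 1 … b*bin_size`, the final partial bin is
kept. At the default 10-kb bins the C58 layout yields global bins Ch1 1–285,
Ch2 286–493, pAt 494–548, pTi 549–570 (570 total). External bedGraph files
are 0-based half-open as the format dictates and are converted at the I/O
boundary only, so there is a single conversion point.

Because the origin of Ch1 sits far from the linearization point of the
circular reference, the Ch1 reference is rotated so that it starts at
1,400 kb before binning (`rearrange_ch1()`); this puts the *ori1* region near
the center of the Ch1 axis (bin ≈143) where the standard quantification
windows expect it. The rotation is a bijection and is inverted when
synthetic contact records are written back in native coordinates.

The layout stores an origin position per replicon. Only two of these have a
printed anchor: *ori1* is stored at 2,825,000 so its rearranged bin (143) is
the midpoint of the standard ori1 window (bins 122–163), and *ori2* at
Ch2:975,000 is the midpoint of the ori2 window (bins 363–402). The plasmid
origins are mid-replicon stand-ins that matter only to the synthetic
generator.

## Iterative correction

Raw contact maps are biased by restriction-site density, GC content and
mappability. The balancing used here repeats, once per sweep,

$$m_{ij} \leftarrow m_{ij} \cdot \frac{T}{R_i \, C_j}$$

where $T$ is the current matrix total and $R_i$, $C_j$ the current row and
column marginals (equal, by symmetry), until the maximum relative deviation
of the marginals from their mean is below $10^{-5}$; the converged matrix is
then divided by the common row sum so every row and column sums to 1.

Design choices, where the procedure leaves room:

* **Per-sweep (Jacobi) updates.** The marginals are recomputed once per
  sweep, not after every entry; the stated update is a map applied to the
  whole matrix. Per-entry Gauss–Seidel updates reach the same fixed point but
  are not what the formula says.
* **Masking.** Bins with zero marginal (unmappable bins) cannot be balanced;
  they are excluded from the convergence criterion and left at zero. This is
  standard practice; the alternative (failing) would make every sparse map
  unusable.
* **Final scaling by a scalar.** Dividing by the *common* converged row sum
  preserves symmetry exactly; dividing each row by its own sum would break
  symmetry for any row still `tol` away from the mean.
* **`max_iter = 1000`** with a warning and a `converged` attribute on
  failure, rather than an error, so partial results remain inspectable.

The update is exactly scale-invariant, idempotent on balanced maps, and on
random symmetric matrices agrees entry-wise with an independently coded
alternating row/column (Sinkhorn) normalization — all of which the test suite
checks, the last against an oracle implemented along a different path.

## Region quantification

Inter-replicon signals are quantified by summing the balanced map over fixed
regions in (column, row) = (x, y) bin space and multiplying by two to count
the mirror image across the main diagonal:

* the **origin–origin rectangle**: x ∈ [122, 163] (ori1), y ∈ [363, 402]
  (ori2) — 1,680 bin pairs;
* the **alignment region**: the union of two parallelograms with vertices
  (13,285), (63,285), (220,492), (270,492) and (13,492), (63,492), (220,285),
  (270,285), with the origin rectangle removed.

Printed bin ranges are treated as inclusive, and parallelogram boundaries are
inclusive — the vertices are cited as endpoints. Region membership is
computed by a generic boundary-inclusive point-in-convex-polygon test on the
stored vertices; the tests validate it against explicit half-plane
inequalities derived by hand from the same vertices, over every bin pair of
the 570×570 lattice.

Two genuinely open readings are resolved as follows and kept switchable:

* The two parallelograms overlap in the middle of the X. The default counts
  the overlap **once** (a true union — "the blue area" is one area);
  `alignment_score(..., double_count_overlap = TRUE)` exposes the other
  reading.
* The excluded "orange square" is taken to be exactly the origin rectangle
  (bins 122–163 × 363–402), not a drawn oval of uncertain extent.

Percentages use the two-anchor convention: the wild-type score is 100%, the
score of a mutant lacking all inter-chromosomal contacts (a *ΔrepB*-like
background) is 0%, and a sample is
`100 * (S - S_bg) / (S_wt - S_bg)`. Values below 0% and above 100% are
meaningful and representable. The 100%/0% identities hold exactly, by
algebra, whatever the maps — this is what the two acceptance targets assert.

## The synthetic world

`simulate_contact_map()` builds the expected map as a sum of additive
features; every default is a fixed statement about the world being emulated,
not a tuning knob:

| parameter | default | rationale |
|---|---|---|
| `decay_exponent` | 1 | short-range power-law decay typical of bacterial Hi-C; circular distance on circular replicons; diagonal capped at 1 |
| `background` | 0.005 | weak flat inter-replicon noise, a few percent of contacts |
| `interarm_strength`, `interarm_halfwidth` | 0.2, 2 bins | visible but sub-diagonal anti-diagonal stripes on Ch1 and Ch2 |
| `ori_cluster_strength`, `ori_halfwidth` | 0.2, ±20 bins | strong origin–origin blocks; the ±20-bin neighborhood mirrors the width of the printed ori1 window (42 bins) |
| `alignment_strength`, `alignment_halfwidth` | 0.025, ±25 bins | an X-band ~5× the background, ~8% of all contacts; the half-width matches the printed parallelogram half-width |

With `noise_pairs > 0` the returned map is a seeded multinomial sample of
that many contact pairs from the expected map (each pair incrementing both
`m[i,j]` and `m[j,i]`, the same convention as `bin_contacts()`), which makes
the generator an exact statistical model of the binning stage.

Two properties make parameter recovery a fair, non-circular test. First,
features are additive and confined to their regions, so on noiseless maps a
triple (wild type at alignment strength $A$, background at 0, sample at
$fA$) recovers exactly $100f$ — linearity, not tuning. Second, sampled maps
are depth-matched (same `noise_pairs`), so their region sums are directly
comparable.

Recovery is quantified on the raw (or expected) synthetic maps rather than
on balanced ones. The generator simulates none of the visibility biases that
iterative correction exists to remove, so balancing would only redistribute
real structure; and the exact-recovery property holds only before
balancing. One distortion is inherent to the published estimator itself and
is worth stating: comparing depth-normalized maps multiplies the recovered
percentage by $T_{wt}/T_f$ (the ratio of expected totals), because the
wild-type map genuinely devotes a larger share of its reads to the alignment
band. With the default world (~8% of contacts in the band) this inflates
mid-range fractions by about two percentage points — well inside the ±5
stochastic tolerance — and it shrinks further as the band's share of reads
drops toward realistic sequencing-scale values.

What the generator does **not** emulate: restriction-fragment and
mappability bias (so a green balancing test on synthetic data shows
correctness of the algorithm, not its benefit on real data), polymer
physics, replication-associated copy-number gradients, and condensin-driven
loop features. A green recovery test establishes that the estimator is
consistent in the stated world, not that the published percentages are
correct.

## ChIP/input enrichment

Tracks are per-base-pair read counts. Enrichment is
`(chip_bp / chip_total) / (input_bp / input_total)` per base pair; positions
with zero input are masked (`NA`) by default, with an optional pseudocount
for sparse real libraries. Display binning (1-kb genome-wide, 100-bp
high-resolution) averages unmasked positions.

The summary statistic behind "reduced to X%" claims is not standardized, so
the package documents its own: `peak_score()` is the **above-baseline area**
`sum(max(value - 1, 0))` over a window (default: the parS2 cluster ±5 kb).
It is linear in occupancy above baseline, additive over disjoint windows and
robust to window width — alternatives (peak maximum, binned value at the
summit) are noisier and scale-dependent. `relative_enrichment()` is then the
plain score ratio ×100.

The synthetic ChIP world: Poisson counts at 20 reads/bp background (deep
coverage, standard for small bacterial genomes), ParB-class Gaussian peaks of
summit enrichment 20 and sd 1,500 bp at the parS1/parS2 clusters. One bias
is acknowledged: the positive-part operator accumulates
`E[max(noise, 0)] > 0` over the window, which inflates a depletion ratio by
roughly one point at these settings; the ±3-point recovery tolerance absorbs
it, and deeper coverage or wider peaks shrink it.

## Focus analytics

Colocalization follows the pixel-distance criterion: a green (ori1) focus is
colocalized when at least one red (ori2) focus in the same cell lies at
Euclidean distance **strictly less than** 6 pixels (the diameter of a
typical focus). The denominator is the number of green foci — the published
phrasing counts "ori1 foci colocalized with an ori2 focus" — not mutual
nearest-neighbor pairs. Distances stay in pixels throughout; no pixel size
is assumed.

The focus generator mirrors the red count to the green count within each
cell (origin copies pair up in a wild-type-like world): each red focus is
either a colocalized partner (uniform displacement in a disk of radius
`coloc_jitter_px`) or an independently mislocalized focus placed uniformly
in the cell. The mirroring is forced by the generator's contract — with
`coloc_prob = 1` and zero jitter the measured fraction must be exactly 1,
which independent per-channel counts cannot deliver. Green foci sit at the
poles with Gaussian scatter (`polar_sigma_px = 3`); cells are 45 × 14 px
(≈ 2.9 × 0.9 µm at typical magnification), large enough that chance
colocalization of a uniform red stays below 0.2. The default count
distribution P(1) = 0.6, P(2) = 0.4 describes a newborn-to-predivisional
wild-type population; depletion phenotypes are modeled by shifting mass to
zero counts.

`focus_count_matrix()` gives the joint (n_green, n_red) percentage table,
marginal means and zero-focus fractions — the comparator for "more than 40%
of cells with no foci" phenotypes. `distance_to_nearest_pole()` is the
minimum Euclidean distance to either recorded pole point.

## Numerical details and degenerate inputs

* The intra-replicon law `|i-j|^(-a)` is undefined at distance zero; diagonal
  entries are set to 1, the natural cap at the distance-1 value.
* `relative_interaction()` refuses `S_wt == S_bg` (undefined scale);
  `region_sum()` warns when a region touches the main diagonal (the mirror
  factor would double-count); `ice_normalize()` refuses all-zero maps.
* Matrix text I/O writes 17 significant digits, so round-trips are exact to
  double precision; malformed rows are reported by row number.
* All generators run under a local RNG scope: they are bit-reproducible
  given a seed and do not disturb the caller's RNG state.

## Limitations

Read alignment, the full ligation-product classification (only the
same-fragment filter is provided), cell segmentation and spot detection are
out of scope: the pipeline starts from contact records, coverage tracks and
focus tables. Reproducing the published full-scale percentages requires the
deposited sequencing data and an external aligner; the package's validation
is the property-based synthetic suite described above.
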