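---
title: "Scoring Rabl-like versus territorial chromosome architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Rabl-like versus territorial chromosome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicarch)
```

## The problem

Interphase nuclei arrange chromosomes along a continuum between two poles:
a Rabl-like (RBL) configuration, with centromeres and telomeres clustered
at opposite ends of the nucleus, and chromosome territories (CT), in which
each chromosome occupies its own volume. In Hi-C maps the RBL pole shows
cis "wings" perpendicular to the main diagonal, trans centromere–centromere
(Cen-Cen) and telomere–telomere (Tel-Tel) enrichment, and a polarized
centromere-to-telomere axis; the CT pole shows cis dominance over trans.
Embryonic time series reveal a conserved RBL-to-CT transition during
development, accompanied by progressive strengthening of A1-subcompartment
interactions. `hicarch` turns those qualitative signatures into calibrated
scalar scores, calls five subcompartment states, and correlates
subcompartmentalization with architecture across a series.

## Coordinate model

Coordinates are 0-based half-open (BED convention). A `genome_spec` carries
chromosome lengths, one centromere interval per chromosome, the bin size,
and a telomeric extent (default one bin; the delimitation of telomeric
regions is a free choice here, as no standard exists). The centromere is an
interval for masking purposes, but its midpoint is the single anchor for
arm assignment and rescaling — this matches BED centromere annotations
while giving aggregation a unique anchor. Each bin gets a relative axis
position `r` on its arm: midpoint distances from the anchor scaled by the
arm's largest midpoint distance, so the most distal bin of every arm sits
at exactly `r = 1`, `r` decreases monotonically to ~0 at the centromere,
and `r` is comparable across arms of unequal length. Chromosomes whose two
arms both hold at least two bins count as metacentric/submetacentric and
enter aggregate chromosome analysis; acrocentric chromosomes are kept in
every other computation.

## Normalization

ICE balancing iteratively divides the matrix by its relative marginals
until unmasked marginals agree to a tolerance (default `1e-6`, capped at
200 iterations; convergence is reported, and an unmasked all-zero block is
flagged rather than silently accepted). Before balancing, all-zero bins and
bins below a marginal-quantile threshold (default the 2% quantile of
nonzero marginals) are masked. Masked bins are zero in the balanced layer
and missing in O/E; missing values propagate as missing into every
aggregate (no zero-filling anywhere).

The cis expectation is one pooled distance-decay curve per genome (mean
balanced value per bin-distance over all chromosomes; a per-chromosome
option exists but the pooled curve is more stable on small genomes). The
trans expectation is a scalar per chromosome pair. O/E therefore has unit
mean on every cis diagonal and in every trans block by construction —
a property the test suite asserts to `1e-9` — and every O/E-derived score
is invariant to rescaling raw counts by a constant.

## Aggregate chromosome analysis and the architecture scores

Each eligible chromosome's O/E block is rescaled onto `2m` bins (default
`m = 20` per arm): P arm onto positions 0..m−1 with the telomere at 0, Q
arm onto m..2m−1 with the telomere at the end, by fractional bp-overlap
weighted, missing-aware averaging. The aggregate cis map is the unweighted
mean over chromosomes (no length weighting — the aggregation is an equal
vote per chromosome); the aggregate trans map is the mean over all
unordered eligible pairs, each pair's block rescaled on both axes and
symmetrized.

On the rescaled axis, CEN is the central `ceiling(2m·cen_fraction)` bins,
TEL the outer `ceiling(m·tel_fraction)` bins at each end, ARM the rest
(defaults 0.1 and 0.1). Two corrections precede scoring, both motivated by
measurements on planted simulations:

1. **Axial profile (rank-1) correction.** Balancing equalizes each bin's
   *total* marginal, but the cis part has a distance-decay deficit at
   chromosome ends, so end bins carry a multiplicative trans surplus. Any
   per-bin multiplicative factor is exactly rank-1 in the trans map, so a
   multiplicative profile `p_u p_v` is fitted on off-band cells (axial
   offset `|Δρ| > 2·tel_fraction`, where clustering kernels are negligible)
   and divided out. Without it the null Tel-Tel score is biased by ~+0.4.
2. **Offset-matched baselines.** A polarized centromere-to-telomere axis
   enriches *every* pair at similar relative arm position — including
   CEN×CEN and TEL×TEL, whose members all sit at `|Δρ| ≈ 0`. Comparing the
   CEN and TEL blocks to a global ARM mean would therefore read pure axis
   polarization as pole clustering. The default baselines are ARM×ARM cells
   at the same axial offset as the scored block, which cancels the shared
   axial geometry; the plain global-ARM baseline remains available as
   `baseline = "global"`.

The scores are then

* `s_cencen = log2(mean trans CEN×CEN / matched ARM baseline)`
* `s_teltel = log2(mean trans TEL corners / matched ARM baseline)`
* `s_centel_axis = log2(ARM in-band / ARM off-band)`, band
  `|Δρ| ≤ tel_fraction`
* `s_ct = log2(mean balanced cis / mean balanced trans)`, on balanced
  counts (not O/E), genome-wide.

`s_ct` has a nonzero null value set by distance decay; null statements
about it are made relative to the score of the noise-free expected map
(`expected_contact_map()`), never a hard-coded constant. Scores are
comparable only within one parameterization (`m`, fractions, resolution);
the upstream method that inspired them does not publish closed formulas,
so these definitions are this package's concrete instantiation — chosen to
be scale-invariant, symmetric in the two architecture poles, zero-centred
under the null, and component-specific (each planted generator weight moves
its own score by ≥ 1 log2 unit while the others stay below 0.2; verified in
the acceptance tests).

## Subcompartments

**Eigenvector.** Per chromosome, the leading eigenvector of the Pearson
correlation matrix of cis O/E rows. Centromeric bins (the interval plus a
flank) can be masked first: strong pericentromeric structure otherwise
polarizes the eigenvector along the arm rather than along compartments.
The sign is oriented per chromosome — each chromosome's eigenvector sign is
independently arbitrary — against the active mark when tracks are given,
otherwise by positive skewness (documented deterministic fallback).

**Depolarization.** All three Rabl components are functions of the two
bins' relative arm positions `(ρ_i, ρ_j)`. Dividing trans O/E by its mean
over a symmetric 20×20 `ρ`-stratum grid therefore removes polarization
exactly, while compartment checkerboards — scattered along the axis —
survive. This is the trans analogue of masking centromeres before
compartment calling, and it is essential: without it, state inference on an
early-embryo-like map returns axis-position clusters (planted-state ARI
~0.1) whose apparent "compartment strength" is pure geometry.

**States.** Each bin's profile is its depolarized trans O/E vector to bins
on other chromosomes. The bin–bin correlation matrix of these profiles is
reduced to its top 10 eigenvectors (scaled by the square root of their
eigenvalues — the eigenvalue scaling outperformed unscaled coordinates in
planted-recovery comparisons), then clustered with k-means, K = 5 fixed (no
model selection; the five-state alphabet A1, A2, B1, B2, B3 is the
contract), 20 restarts under a fixed seed. Clustering runs on a canonically
sorted copy of the embedding with deterministic eigenvector signs, and bins
are assigned to the nearest centroid, making the output equivariant under
bin permutations and reproducible bit-for-bit.

**Labels.** States with positive mean eigenvector form the A pool, the
rest the B pool; pools are forced to sizes (2, 3) by moving the state with
mean e1 nearest zero (a documented rule for the degenerate case where all
states lean one way). Within A, the higher mean active mark is A1; within
B, the highest polycomb mark is B1, and of the rest the state scoring
higher on repeat density plus centromere proximity is B2 (pericentromeric),
the other B3 (telomeric). The full state-by-evidence table is attached to
the result; without tracks the labels honestly fall back to A/B. No
reference-profile adjustment to external cell lines is attempted.

**Strength.** `strength(s) = log2(within-s mean O/E / one-sided-s mean
O/E)` over long-range cis (≥ 2 Mb, following the standard short/long split)
plus all trans pairs — long-range only, so distance decay cannot leak in.
By default the depolarized O/E is used, for the same reason as in
inference; `depolarize = FALSE` counts polarized contacts towards
compartmentalization, which is defensible for the
heterochromatin-associated B2/B3 states but makes early-stage strengths of
every state hostage to label-geometry noise (measured: the sign of the
A1-strength/CT-score series correlation becomes unstable across seeds).

## Synthetic data: what it emulates, and what not

The generator is the package's ground-truth instrument, not a polymer
model. Expected rates are `Z · base · comp · arch` with power-law cis decay
`(d + s0)^(−α)` (α = 1, `s0` = one bin — typical Hi-C regime), a constant
trans base (default set so early-stage trans fraction is ~30–40%, as in
embryonic maps), a multiplicative cis territory factor `t ≥ 1`, a
compartment factor `1 + ε(affinity − mean affinity)` over a symmetric
unit-diagonal 5×5 affinity matrix, and architecture kernels: a Gaussian
same-`|d|` wing on opposite arms in cis, exponential Cen-Cen/Tel-Tel
clustering kernels (length scale 500 kb) and a Gaussian axis kernel in
`Δr` (scale 0.1) in trans. Each architecture factor is normalised to unit
mean over its own pair set, so a clustering weight redistributes contacts
toward the poles without changing cis/trans composition — only `t` moves
that; this keeps the four dials orthogonal and the monotonicity tests
meaningful. Counts are Poisson (no overdispersion: replicate-level
biological variability is deliberately out of scope), symmetrized, with
`Σμ = total_contacts`.

States are planted in geometric-length blocks (mean 5 bins), with B2
up-weighted (×3) in pericentromeric and B3 in telomeric regions. Tracks are
Gaussian around state means whose ordering encodes the expected biology:
active mark and expression highest in A1 then A2, polycomb mark highest in
B1, heterochromatin mark and repeat density highest in B2/B3.

The default desk-scale genome is 3 metacentric chromosomes × 100 bins of
100 kb — large enough for the 2 Mb long-range threshold to bite, small
enough that the full pipeline runs in seconds; the acceptance script and
tests use this size with 10⁷ contacts per map and 5-seed medians.

A developmental series interpolates weights, `t`, `ε` and the affinity
matrix linearly between presets. The Rabl preset has strong clustering
(weights 5), `t = 1`, and an early affinity matrix in which A1 is only
weakly segregated while B2/B3 heterochromatin mixes tightly — early
compartments are heterochromatin-driven. The territory preset has
clustering off, `t = 3`, and the default affinity with strongly segregated
A1. Interpolating the affinity, rather than ramping a single global
contrast, is what "A1 affinity increases" means here, and it is what makes
A1 strength rise across the series. A "mixed" preset (residual Cen-Cen over
territory features, as in differentiated fly tissue) is illustrative only —
the real joint intensity of co-occurring architectures is unknown.

What passing tests on these simulations do **not** show: robustness to
overdispersed counts, TADs/loops (absent by design), unmappable-region
structure, per-replicate biological noise, or genomes of strongly unequal
chromosome sizes. The generator shares its coordinate model with the
scorer; the rank-1 profile correction and depolarization were validated
against artifacts that arise from balancing and planted geometry, which
real maps will exhibit in related but not identical form.

## Numerical choices and degenerate inputs

* ICE tolerance `1e-6` on relative marginal deviation; failure to converge
  and disconnected blocks warn and are flagged, never silent.
* Quantile type 7 (R default) for the coverage mask threshold; bins *below*
  the quantile are masked, so an all-equal marginal vector masks nothing.
* Missing values propagate; every aggregate is a masked mean; empty regions
  yield `NA` scores (reported missing, never 0).
* k-means ties and label arbitrariness are handled by canonical sorting,
  deterministic eigenvector signs, and centroid numbering along the first
  embedding coordinate.
* Correlations require n ≥ 3 and non-constant inputs, else `NA` with the n
  reported; p-values are exact small-n t-based, two-sided, Pearson by
  default (Spearman available).
* Stage seeds derive linearly from the base seed; all outputs, including
  written TSV/BED files, are byte-reproducible for a fixed config.

## Known limitations

* Architecture scores are parameterization-relative; compare them only
  within a run.
* The B2/B3-strength versus Rabl-score correlation is sensitive to whether
  polarized contacts count as compartmentalization (see Strength above):
  with the depolarized default and these planted conditions its sign is
  unstable to negative, because the planted B contrast rises with `ε`
  while the statistic excludes the pericentromeric-clustering component
  that plausibly drives the positive association seen in real embryos.
  The package reports the correlation as computed, with n, rather than
  forcing a sign.
* Subcompartments are called per sample; cross-sample label agreement is
  the user's check (`label_accuracy()` against any reference labeling), and
  no joint multi-stage inference is attempted.
* Interaction fractions describe raw signal composition (documented choice:
  fractions of sequencing signal, not normalized signal) and are therefore
  depth-composition summaries, not architecture scores.
* No cooler/HDF5 I/O; the interchange format is sparse upper-triangle COO
  TSV plus chrom.sizes/BED/bedGraph sidecars.

## A minimal run

```{r, eval = FALSE}
ser <- run_pipeline(list(seed = 1))
ser$scores
ser$correlations
autoplot(ser)
```
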