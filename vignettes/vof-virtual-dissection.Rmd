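---
title: "Virtual dissection and endpoint connectomics of the vertical occipital fasciculus"
author: "vofseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dissection and endpoint connectomics of the vertical occipital fasciculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vofseg)
```

## The problem

The vertical occipital fasciculus (VOF) is the association tract coursing
craniocaudally at the posterolateral corner of the brain, linking the dorsal
("where/how") and ventral ("what") visual streams. In diffusion-MRI
tractography it is identified *virtually*: from a whole-brain tractogram one
keeps exactly those streamlines that (i) terminate with one end in a dorsal
parieto-occipital parcel and the other in a ventral or lateral-occipital
parcel of a cortical atlas (the two-ROI approach), (ii) course dominantly
superior–inferior (the "blue" fibres of an RGB directional map), (iii) avoid
an optional exclusion mask (e.g. along the splenium), and (iv) sit in the
correct position relative to neighbouring bundles — *posterior to the arcuate
fasciculus (AF)* and *lateral to the inferior longitudinal fasciculus (ILF)*
in the sagittal stratum. The surviving bundle is then quantified: a
parcel-by-parcel matrix of termination counts, endpoint-projection and
connection ratio tables, tract volume and mean fractional anisotropy (FA),
and hemispheric laterality.

`vofseg` implements this procedure end to end, together with a fully
synthetic hemispheric phantom whose ground truth makes every stage testable
without imaging data.

## Spatial conventions

Everything internal is world RAS millimetres: x increases to the right, y to
anterior, z to superior; the left hemisphere is `x < 0`, and "more lateral"
means smaller x on the left and larger x on the right. Voxel indices are
0-based; world-to-voxel snapping rounds halves away from zero. Converters do
all dialect work at the boundary: TCK files already store world mm; TRK
files store voxel-mm coordinates measured from the voxel corner and are
mapped through the header's voxel-to-RAS affine (files lacking a usable
affine are refused rather than guessed at — silently mis-guessing the TRK
dialect is the classic tractogram bug). Round-trips are exact to float32
resolution (`< 1e-4` mm at brain-scale coordinates), and the readers are
cross-checked in the test suite against an independent implementation
(nibabel).

## The selection model and its tunables

`selectionCriteria()` collects every tunable of the dissection:

* `groupA`, `groupB` — the two endpoint sets, as parcel-group names
  (`dorsal`, `ventral`, `lateral_occipital`) or explicit parcel names, so a
  gyrus-based ROI variant is just a configuration of the same machinery.
* `endpointRadiusMm` (default 2 mm) — a terminal point falling in background
  is assigned to the nearest labelled voxel centre within this radius
  (ties: smallest distance, then smallest label id). This compensates for
  termination just outside the labelled ribbon. The endpoint is the terminal
  *point* (first and last point only), not a terminal segment.
* `requiredAxis` = `SI` with `minAxisFraction` = 0.5 — the per-axis share of
  summed absolute displacement must favour superior–inferior. The published
  procedure selects fibres that "appear blue" on an RGB map, a visual
  dominance criterion with no stated cutoff; dominance plus a 0.5 fraction is
  the declared operationalisation. Exact ties break SI > AP > LR.
* `slabMm` (default 5 mm) and `lateralMajority` (default 1) — "lateral to
  the ILF" and "posterior to the AF" are anatomical relations with no
  published metric. They are operationalised per z-slab: the z-axis is cut
  into slabs anchored at multiples of `slabMm` (an anchored grid keeps slab
  boundaries identical for every streamline and lets reference medians be
  computed once); in each slab occupied by both candidate and reference the
  candidate's median x (or median y for "posterior") is compared with the
  reference points' median, and the relation must hold in at least
  `lateralMajority` of the shared slabs. Medians resist endpoint splay. A
  candidate sharing no slab with the reference is retained (the filter is
  inapplicable) and flagged.

Filters run in a fixed order — two-ROI, orientation, ROA, posterior,
lateral — and each rejection is attributed to the first failing filter, so
the report's bookkeeping (`accepted + Σ rejected = input`) is exact. The
two-ROI, orientation and ROA predicates are per-streamline and independent,
so any application order yields the same accepted set; the tests assert
this, along with idempotence of the whole procedure on its own output.

## The phantom: what it emulates and what it does not

`phantomConfig()` / `makePhantom()` build a 64×96×80 grid of 2 mm voxels
holding a 22-parcel occipital atlas (7 dorsal, 7 lateral-occipital, 8
ventral parcels named after the HCP MMP1.0 vision-associated areas),
Voronoi-partitioned over three disjoint cortical bands: dorsal
superior-posterior, ventral inferior, lateral-occipital laterally between
them. Four streamline populations are generated:

* **VOF-like** (default 2000): cubic Bézier arcs from a dorsal-parcel voxel
  to a ventral- or lateral-occipital-parcel voxel (70/30 split by default),
  resampled at 1 mm. The endpoint *parcels* are drawn from configurable
  multinomials — this is the phantom's central dial, and the published
  endpoint proportions ship as `vofEndpointProps()` (the figures print only
  each group's prominent parcels; the unprinted remainder is spread
  uniformly over the rest of the group).
* **ILF-like** (300): anterior–posterior streamlines strictly medial to the
  VOF corridor (≥ 6 mm clearance).
* **AF-like** (300): arcs strictly anterior to the VOF corridor (≥ 6 mm).
* **Clutter** (400): random short arcs with random dominant axis, placed so
  that no clutter streamline has both endpoints inside parcels; they
  exercise the rejection paths.

Numerical choices worth knowing:

* **Jitter is smooth and truncated.** Point noise is drawn at ~20 mm knots,
  interpolated between them, and clamped to ±0.99 mm per axis. White noise
  per point at 1 mm sampling would add ~0.5 mm of spurious path length per
  segment *per axis* and destroy the superior–inferior dominance the
  generator must guarantee; the clamp guarantees a jittered endpoint can
  never leave its 2 mm voxel, so endpoint assignment recovers the generator
  truth exactly. A consequence: selection recall is structurally 1 at any
  jitter level, so the phantom is a correctness fixture, not a
  difficulty dial.
* **Superior–inferior dominance is asserted per streamline** (fraction
  ≥ 0.55, above the 0.5 filter threshold); if an extreme parcel pairing plus
  control-point draw fails it, the within-parcel geometry is redrawn — never
  the parcel draws, so endpoint multinomials are exact.
* **Mirror-exactness.** All geometry is generated in a canonical
  left-hemisphere frame on a grid centred so that mirroring maps voxel
  centres onto voxel centres; right-hemisphere phantoms are exact mirrors of
  their left twins under the same seed (including the FA noise field), and a
  bilateral phantom re-seeds per hemisphere and symmetrises the FA noise, so
  it is an exact null for laterality analyses.
* **FA field**: traversed voxels 0.55, background 0.15, plus a smooth field
  (coarse-lattice Gaussian, trilinearly upsampled, s.d. 0.02), clipped to
  [0, 1].
* **Determinism**: one RNG seeded from `seed` drives parcel draws, geometry,
  jitter and FA noise in a fixed documented order; identical configs give
  bitwise-identical phantoms.

What the phantom does *not* emulate: cortical folding, partial-volume
effects at grey/white boundaries, crossing-fibre ambiguity, tracking errors,
or realistic bundle cross-sections. Passing tests therefore demonstrate that
the *analysis* is correct under its stated assumptions, not that the
procedure is robust to tractography artefacts in real data.

## Endpoint analysis

Each accepted streamline increments exactly one unordered parcel pair of a
symmetric connectivity matrix; the upper triangle (including the diagonal)
sums to the accepted count. Endpoint-projection ratios are
endpoints-per-group: a streamline contributes one endpoint to the group of
each of its two parcels (two to one parcel for a diagonal entry), and a
parcel's value is its percentage of the group's endpoints — the convention
matching "ratio of cortical areas in which the endpoints fall". Connection
ratios are percentages of the accepted total per parcel pair. Tract volume
counts *unique* voxels touched by the 1 mm-resampled bundle times the voxel
volume, so overlapping streamlines are not double-counted, and mean FA is
the unweighted mean over that same voxel set, keeping volume and FA on
identical support.

## Laterality

`lateralityIndex()` is `(L − R) / (L + R)`, +1 fully left-lateralized, −1
fully right; `L + R = 0` is undefined and propagates as missing (excluded
from group means with a count) rather than being coerced to 0.
`summarizeSubjects()` reports mean ± SEM (`sd/√n`) and a two-sided Student
t-test. Left and right values come from the same subjects, so the test is
paired by default, with the unpaired variant behind a flag; zero-variance
differences yield a flagged degenerate statistic (0 with p = 1, or signed
infinity with p = 0) instead of a silent error. No multiple-testing
correction is applied across connections by default, mirroring the original
analysis. The test suite checks the paired test's type-I error at the 0.05
level over 10^4 null replicates.

## Validation experiments and problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) runs:

* exact analytic checks of the LI formula and its ±1 boundary behaviour;
* endpoint-ratio recovery: 20,000-streamline single-hemisphere phantoms
  configured with the published multinomials
  (`endpointRecovery()`), where the full pipeline must recover e.g. the
  left-ventral V4 percentage to within ±1 percentage point (binomial s.d.
  ≈ 0.34 pp at n = 20,000);
* selection correctness: precision = recall = 1 against generator truth on
  the default phantom, and exact agreement of every filter with brute-force
  reimplementations on ≤ 100-streamline instances;
* conservation laws (ratio tables sum to 100, matrix total equals accepted
  count, LI bounds/antisymmetry/scale-invariance) and the paired-t size
  check;
* byte-exact format round-trips for TCK, TRK and connectogram tables.

The 20,000-streamline scale matches the precision the recovery claims need;
the routine test phantoms use a few hundred streamlines, which exercise the
same code paths at full coverage.

## Known limitations

* The relative-position rule is a declared operationalisation of an
  anatomical statement; other metrics (e.g. per-slab minima, margins, or
  probabilistic overlap) are defensible and would admit slightly different
  bundles. Note one structural property of the median rule: a candidate
  drawn from the *reference bundle's own* distribution beats the per-slab
  median in all its slabs with probability ≈ (1/2)^k, so such a filter
  separates bundles that are spatially offset, not members of the reference
  from itself.
* Tracking itself is out of scope: the package consumes tractograms and the
  phantom emits streamlines directly.
* Surface-based (CIFTI/greyordinate) atlases, DICOM and raw DWI are not
  handled; the world space of inputs is treated as opaque metadata and must
  be consistent across tractogram, atlas and scalar volumes.
* The laterality analysis follows the original design (10 subjects, paired
  t, no multiplicity correction); with small n the group-level conclusions
  are inherently limited.
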