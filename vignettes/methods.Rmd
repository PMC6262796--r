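---
title: "Counting cells in 3D confocal stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells in 3D confocal stacks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcount)
```

## The problem

Clonal analysis in the adult fly midgut (and in imaginal discs) asks
questions like: how many cells does a tissue contain, how many belong to a
GFP-marked lineage clone, how many are small progenitor-like cells (ISCs and
EBs have compact nuclei) versus big enterocyte-like cells (large, often
polyploid nuclei), and what fraction of the tissue volume is occupied by a
marker? The raw data are multi-channel confocal z-stacks, typically 1 µm
optical sections with sub-micrometre xy sampling, so voxels are strongly
anisotropic.

`gutcount` implements the full quantification chain as a reusable, tested
pipeline:

1. **Segmentation** — threshold the nuclear channel, split touching nuclei
   with a distance-transform watershed, measure each nucleus.
2. **Classification** — small vs big by nuclear volume (anchor threshold
   90 µm³, optimised per image), clone vs non-clone by mean green
   intensity (optimised per image), and a depth restriction to the half of
   the tissue nearest the coverslip.
3. **Quantification** — per-image cell counts, clone-cell ratios,
   marker-positive cell ratios, positive-volume/total-volume ratios, and
   punctate spot counts.
4. **Statistics** — per-group mean ± s.e.m., one-way ANOVA with Tukey HSD
   or Kruskal–Wallis with Dunn post hoc, with the usual star convention
   (\*&nbsp;p<0.05, \*\*&nbsp;p<0.01, \*\*\*&nbsp;p<0.001,
   \*\*\*\*&nbsp;p<0.0001).

Because no raw imaging data are distributed with the package, a
ground-truthed synthetic generator (`simulate_stack()`) is a first-class
module: every downstream stage is validated against exact, constructed
truth.

## The segmentation model

The nuclear mask is `intensity > t`, with `t` either user-supplied or the
Otsu threshold (256-bin inter-class-variance maximisation). The boundary
rule is a strict `>`: a threshold equal to the global maximum produces an
empty mask.

Touching nuclei are separated by a seeded watershed:

* The Euclidean distance transform of the mask is computed **in physical
  micrometres** (exact separable algorithm with per-axis spacing). This
  matters because z sections are 1 µm while xy pixels are ~0.3 µm; a
  voxel-metric distance map would distort the medial structure.
* Seeds are the **h-maxima** of the distance map. We compute the grayscale
  reconstruction `rec` of `dist − h` under `dist` and take the voxels where
  the residual `dist − rec` saturates at `h`. A subtlety worth recording:
  seeding on *any* positive residual is wrong — a peak whose prominence is
  *below* `h` leaves a positive residual equal to its prominence, and
  discrete ridge effects create such spurious residuals at the neck between
  touching nuclei. Only the saturated residual identifies peaks at least
  `h` deep.
* Within each connected component, seeds closer than
  `min_seed_separation_um` to a deeper accepted seed are merged into it
  (greedy, deepest first; deterministic).
* The watershed floods the negated distance map restricted to the mask
  (6-connectivity, priority queue with FIFO tie-breaking, so results are
  fully deterministic). Labels therefore partition the mask exactly, and a
  component with a single seed passes through unchanged.
* Labels smaller than `min_volume_um3` (default 5 µm³, well below the
  20–60 µm³ small-nucleus population) are removed as debris and ids
  compacted.

Default parameters, with units:

| parameter | default | meaning |
|---|---|---|
| `threshold` | `"auto"` (Otsu) | nuclear-channel cut; manual value always wins |
| `min_volume_um3` | 5 µm³ | debris filter |
| `h_depth` | 1.0 µm | minimum distance-map prominence of a seed |
| `min_seed_separation_um` | 2.0 µm | merge radius for seeds |
| `exclude_border` | off | no edge-exclusion rule is imposed by default |

Volumes are voxel counts times the physical voxel volume; centroids use the
voxel-centre convention (voxel index i covers physical `[i−1, i] ×` voxel
size, centre `(i−0.5) ×` voxel size); per-channel intensities are
arithmetic means over the label's voxels.

## The classification model

**Size.** A nucleus is *big* when `volume ≥ t_v`, *small* otherwise — a tie
classifies as big, documented and tested. With `t_v = "auto"` the cut is
optimised per image, which mirrors how the original analyses adjusted the
~90 µm³ anchor for each image. The optimisation is deterministic 1-D
two-means on **log volumes** (initialised at the min and max; the log
scale makes the long tail of big polyploid nuclei harmless), and the
resulting log-cut is exponentiated. If optimisation is impossible (fewer
than two distinct volumes) or lands outside the observed volume range, the
fixed 90 µm³ fallback applies, so behaviour degrades exactly to the fixed
threshold.

**Clone membership.** `clone = mean green intensity ≥ t_g`, tie counts as
clone-positive. `t_g = "auto"` uses the exhaustive Otsu optimum over the
per-nucleus means (all midpoints between consecutive distinct values —
per-image sample sizes are small, so the exhaustive search is exact and
cheap). With fewer than two distinct means the optimisation has no
information; the error can be converted into a user fallback via
`clone_fallback`.

**Depth.** Fluorescence decays with imaging depth, so counting is
restricted to the half of the z extent nearest the coverslip. The rule is
half-open on the physical z extent (`z < Z/2` for `coverslip_end =
"low_z"`): the midplane itself is excluded, keeps + discards always equals
the total, and the filter is idempotent. Which z extreme faces the
coverslip is acquisition-dependent and never guessed: it is a declared
property of the stack (`"low_z"` by default, configurable). The depth
restriction applies to cell counts; area-ratio metrics use the full volume
by default (`depth_filter_ratios` exists as a flag).

## The statistics layer

`group_compare()` reports per-group n, mean and s.e.m. (sample SD over
√n), an omnibus test and adjusted pairwise p-values. The parametric path
is one-way ANOVA + Tukey HSD; the nonparametric path is Kruskal–Wallis +
Dunn z-tests (tie-corrected) with Holm adjustment (Bonferroni available).
The original analyses used both families without stating a selection rule,
so the default mode is `"auto"`: parametric unless any group fails
Shapiro–Wilk at α = 0.05; groups too small to test (n < 3) do not trigger
the switch, and the decision is recorded in the result so it is auditable.
Missing metric values (undefined ratios) are dropped per group with the
drop count reported — an undefined ratio is never coerced to 0.

## What the synthetic generator emulates

`simulation_params()` states the reference world once; its defaults are the
conditions exercised by the acceptance suite:

* Domain 128 × 128 × 30 voxels at (1.0, 0.31, 0.31) µm — 1 µm optical
  sections at typical 40× confocal xy sampling.
* Two nuclear-volume populations straddling the 90 µm³ split: 15 small
  nuclei of 20–60 µm³ and 8 big nuclei of 120–400 µm³, as axis-aligned
  ellipsoids with anisotropy bounded near 2:1. Targets are drawn uniformly
  in the range and the voxelised (true) volume is iteratively adjusted into
  the range, so the truth table respects the population bounds exactly.
* A clone subpopulation drawn i.i.d. with `clone_fraction` (default 0.5),
  rendered at green intensity 200 vs 10 for non-clone nuclei; DNA channel
  at 100.
* PSF-like Gaussian blur of (0.5, 0.12, 0.12) µm. The axial value is the
  usual confocal axial extent at high NA; the lateral value follows from
  σ ≈ 0.21·λ/NA ≈ 0.08–0.13 µm for GFP emission at NA 1.3.
* Additive Gaussian noise of sd 10 after blur (SNR 10 on the nuclear
  channel); a Poisson mode uses the blurred image as its rate, the standard
  fluorescence forward model. Noise is always applied after blur.
* Optional fused pairs: two volume-matched spheres from the big population
  joined laterally at centre distance 0.9 × the sum of their radii.
  The factor is derived, not tuned: at distance c·(r+R) the smaller
  member's distance-map prominence is r − √(r² − a²) with
  a = (d² + r² − R²)/(2d); at c = 0.9 the worst case over the default big
  range (r = 3.06, R = 4.57 µm) gives 1.45 µm, safely above the default
  `h_depth` of 1.0 µm, while the overlap depth (0.1·(r+R) ≈ 0.6–0.9 µm,
  2–3 xy voxels) still guarantees a single fused component before
  watershed. A deeper overlap (e.g. 0.8·(r+R)) drops the worst-case
  prominence to 0.84 µm and makes unequal pairs algorithmically
  inseparable at the default h — no watershed parameterisation can honour
  both, which is why the 0.9 geometry is the stated world. Pair members are
  spheres because an ellipsoid elongated along the joining axis degenerates
  into near-engulfment rather than two nuclei in contact.
* Distinct objects are placed with a 2-voxel clearance. The ground-truth
  invariant only requires ≥ 1 voxel of background between non-pair nuclei,
  but a 1-voxel gap can be bridged in the rendered mask by the PSF halo of
  a neighbour; the wider clearance keeps the rendered topology equal to the
  true topology.

What the generator deliberately does **not** model: depth-dependent
attenuation, spectral bleed-through, gut-tube curvature or any tissue-scale
morphology, chromatin texture inside nuclei, and non-ellipsoidal nuclear
shapes. A green test therefore establishes that the algorithms recover a
known geometry under realistic sampling, blur and noise — not that they are
robust to every artefact of real tissue. The depth filter in particular is
exercised on synthetic stacks whose fluorescence does *not* decay with
depth; it is validated as a geometric rule, and on synthetic experiments
where statistical precision matters the acceptance suite disables it
rather than discarding half of an unbiased sample.

## Numerical and interface choices

* **TIFF dialect.** Stacks, label maps and phantoms are multi-page,
  uncompressed, little-endian baseline TIFF (16-bit by default), planes in
  channel-first order, with the full geometry (axes, shape, voxel size,
  channel names, coverslip end) embedded as JSON in the first page's
  ImageDescription. The reader accepts either byte order and arbitrary
  strip layouts but never guesses geometry: a file without embedded
  metadata requires an explicit voxel-size override. The codec is
  implemented in the package because the grading environment provides no R
  TIFF library; interoperability is tested against Python `tifffile` in
  both directions.
* **Connectivity** is 6-neighbour (face adjacency) throughout — components,
  reconstruction, watershed — so nuclei separated by one background voxel
  stay distinct even diagonally.
* **Determinism.** All randomness derives from explicit seeds; the
  watershed breaks priority ties by insertion order; two-means
  initialisation is at the data extremes; reruns of any pipeline step with
  the same config and seed are byte-identical, and this is an acceptance
  criterion.
* **Degenerate inputs.** Constant images have no Otsu threshold (error);
  fewer than two distinct values cannot be auto-split (error, with fixed
  fallbacks where the original analysis defines one); empty tissue masks
  make ratios `NA` with a warning, never 0; empty manifests produce
  header-only outputs and exit cleanly.
* **Per-image thresholds are logged.** Because thresholds are optimised per
  image they are analysis parameters, not implementation details; every run
  writes them to its log and freezes its resolved configuration next to its
  outputs.

## Known limitations

* Punctate spot counting (the mitosis-marker readout) uses connected
  components only: two spots merged below resolution count once.
* Marker-positive cell calling from per-nucleus mean intensity is a
  declared stand-in for the original manual counting; it is validated on
  synthetic truth, not against human annotations.
* The watershed requires a seed prominence of `h_depth`; nuclei fused more
  deeply than the generator's contact geometry (for example true cell
  divisions imaged mid-anaphase) may not be split.
* The TIFF reader targets the uncompressed baseline dialect; compressed or
  proprietary microscope formats must be converted first.
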