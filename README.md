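# gutcount

Quantification of nuclei, clones and markers in 3D confocal z-stacks of fly
tissues (adult posterior midgut, eye and wing imaginal discs).

## What it does, and for whom

Clonal and lineage experiments in the fly gut produce multi-channel
confocal stacks (DNA stain, GFP clone marker, optional cell-type or
mitosis markers) from which one needs numbers: total cells, clone-positive
cells, small progenitor-like (ISC/EB) vs big enterocyte-like cells,
marker-positive cell fractions, marker-positive volume fractions, mitotic
figures — and then group statistics across genotypes. `gutcount` implements
that whole chain as a scriptable, deterministic R pipeline for people who
would otherwise do it with one-off Matlab/ImageJ macros:

* **Segmentation** — nuclear-channel threshold (manual or Otsu), 3D
  connected components, and a seeded watershed on the anisotropy-aware
  Euclidean distance transform (computed in µm, because 1 µm z-sections
  meet ~0.3 µm xy pixels) to separate touching nuclei. Seeds are h-maxima
  of the distance map with a minimum pairwise separation.
* **Per-nucleus measurement** — volume (voxel count × voxel volume),
  physical centroid, per-channel mean intensity.
* **Classification** — small/big by volume with the 90 µm³ anchor
  threshold, optimised per image (deterministic two-means on log volume,
  with fixed fallback); clone/non-clone by mean green intensity (per-image
  Otsu); depth restriction to the coverslip-proximal half of the z extent.
* **Tissue readouts** — counts, clone-cell ratio, small-clone counts,
  marker-positive cell ratio, positive-volume/total-volume ratio (3D),
  punctate spot counts.
* **Statistics** — mean ± s.e.m. per group, one-way ANOVA + Tukey HSD or
  Kruskal–Wallis + Dunn (Holm), auto-selected via Shapiro–Wilk, with
  significance stars (\* p<0.05 through \*\*\*\* p<0.0001).
* **Synthetic ground truth** — a generator of realistic stacks (two
  nuclear-size populations, clone subpopulation, fused nucleus pairs,
  anisotropic voxels, PSF blur, Gaussian/Poisson noise) with exact label
  maps and truth tables, so the whole pipeline is testable without any
  real data.

Images are read and written as plain multi-page TIFF (16-bit,
uncompressed) with the stack geometry embedded as JSON metadata; records
and summaries are CSV; configurations are YAML; comparisons are JSON +
text tables.

## Worked example

Simulate a stack with a 40% clone fraction and quantify it end to end:

```r
library(gutcount)

p   <- simulation_params(clone_fraction = 0.4, seed = 7)
sim <- simulate_stack(p)
print(sim$stack)
#> image_stack: 2 channel(s) [dna, gfp], 30 x 128 x 128 (z,y,x)
#>   voxel size (um, z/y/x): 1.00 / 0.31 / 0.31; coverslip end: low_z

res <- quantify_stack(sim$stack, run_config(images = data.frame()),
                      image_id = "demo")
str(res$thresholds)
#> List of 3
#>  $ nuclear_intensity: num 49.2
#>  $ volume_um3       : num 104
#>  $ clone_intensity  : num 94.9
print(res$summary)
#>   image_id n_total n_clone clone_cell_ratio n_small_clone marker_cell_ratio
#> 1     demo      12       6              0.5             4                NA
#>   positive_volume_ratio n_spots
#> 1            0.03562826      NA
```

Reading the numbers: the stack contains 23 simulated nuclei of which 12
are clone-positive; after the depth filter (only nuclei in the
coverslip-proximal 15 µm are counted, mirroring how gut images are scored)
12 nuclei remain, 6 of them clone-positive (`clone_cell_ratio` 0.5), 4 of
those small — consistent with the generating clone fraction of 0.4. The
logged thresholds are the per-image automatic choices: the Otsu nuclear
cut (49.2), the optimised volume split (104 µm³, near the 90 µm³ anchor
between the 20–60 µm³ and 120–400 µm³ populations), and the optimised
clone-intensity cut (94.9, between the non-clone level 10 and the clone
level 200). `positive_volume_ratio` is the GFP-positive fraction of the
whole imaged volume (clone nuclei occupy ~3.6% of this field).

Comparing a metric across genotypes:

```r
g <- list(control         = c(0.18, 0.22, 0.25, 0.20, 0.17, 0.24, 0.21, 0.19),
          clone_expansion = c(0.78, 0.81, 0.75, 0.83, 0.80, 0.77, 0.82, 0.79))
group_compare(g, mode = "parametric", metric = "clone_cell_ratio")
#> group_comparison: clone_cell_ratio (parametric mode)
#>   control          n=8   mean=0.2075 +/- 0.009955 (s.e.m.)
#>   clone_expansion  n=8   mean=0.7937 +/- 0.009437 (s.e.m.)
#>   ANOVA F(1,14) = 1826, p = 3.097e-16 ****
#>     control vs clone_expansion: p_adj = 3.142e-14 ****
```

## Command line

```sh
gutcount simulate --config sim.yaml --out data/ --seed 1
gutcount segment  data/sim_001.tif --out seg/ \
                  --voxel-size 1.0 0.31 0.31 --channels dna,gfp
gutcount quantify --config run.yaml --out results/ --seed 1
gutcount compare  --summaries results/summaries.csv \
                  --metric clone_cell_ratio --mode auto --out results/
gutcount all      --config run.yaml --out results/ --seed 1
```

The launcher script is installed at `inst/cli/gutcount` (equivalently:
`Rscript -e 'gutcount::gutcount_cli()' -- <args>`). `run.yaml` maps image
paths to genotype groups and optionally overrides segmentation and
classification parameters; every run writes a log of the per-image
automatic thresholds and a frozen copy of its resolved configuration.

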