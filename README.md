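# spotscreen

Quantification for genome-scale single-molecule FISH (smFISH) / protein-trap
screens of the *Drosophila* larval nervous system — and for any experiment
with the same shape: diffraction-limited mRNA spots and a fluorescent
protein reporter imaged together in 3D across a panel of genes, tissues and
subcellular compartments.

The package implements the full quantitative workflow of such a screen:

- **Spot analysis** — rolling-ball background subtraction (per-slice
  grey-scale top-hat; radius 5 px for smFISH, 20 px for cell markers),
  Laplacian-of-Gaussian candidate detection at the PSF scale with
  anisotropic voxels, subpixel 3D Gaussian refinement (projection fits, a
  Gauss–Newton polish, and a template-scale width scan), separation of
  single molecules from bright nuclear transcription foci (amplitude a
  multiple of the single-molecule unit intensity) and from wide, dim
  background shapes.
- **Codetection** — one-to-one matching of two spectrally separate probe
  channels (exact per connected component of the candidate graph), the
  standard sensitivity control for smFISH probe sets, with a Wilson
  binomial interval.
- **Compartments** — 3D marker-channel segmentation (Gaussian smoothing,
  Otsu threshold, closing, 26-connected components), spot-to-compartment
  assignment, per-compartment transcript counts, ghost-bouton
  classification (presynaptic marker without the postsynaptic Dlg1
  signal), and condition comparisons through an assumption-checked test
  decision tree (Shapiro–Wilk; F test / Levene; Student's t / ANOVA+Tukey;
  Wilcoxon / Kruskal–Wallis+Dunn).
- **Annotation scoring** — strict-majority aggregation of three-or-more
  expert presence/absence calls with NA and tie handling ("fourth expert"
  escalation report), per-gene mRNA/protein discordance classified as
  intercellular (whole cell-class mismatch) or intracellular
  (soma-vs-periphery mismatch within a cell class), four-category
  expression tables, UpSet intersection counts, neuroblast-lineage
  expression-pattern classes, genome-scale extrapolation with a one-sided
  Wilson bound, and a flat MDV-style per-gene export.
- **Synthetic data** — a seeded generator producing multichannel 3D stacks
  (singles, foci, blobs, marker/nuclear/bouton channels, a second probe
  channel sharing a configurable fraction of positions) and annotator
  tables with configurable error rates — with complete ground truth, so
  the whole pipeline is testable without any microscope data.

## Worked example

Simulate a two-probe stack with a true shared-spot fraction of 0.85, then
recover it end to end:

```r
library(spotscreen)

cfg <- sim_config(codetection_fraction = 0.85, seed = 7)
sim <- simulate_image_stack(cfg)
sim$stack
#> <image_stack> 20 x 160 x 160 voxels (z,y,x), voxel 0.35 x 0.13 x 0.13 um,
#>   channels: probe_a, probe_b, marker, nuclear

spots_a <- detect_spots(sim$stack, cfg$psf, detection_params(), channel = "probe_a")
unit <- estimate_unit_intensity(spots_a)
#> unit intensity: 195.6 photons (MAD 13.0, n = 177)   # truth: 200
spots_a <- classify_spots(spots_a, unit, cfg$psf, detection_params())
table(spots_a$spot_class)
#>    focus rejected   single
#>        2        3      192

spots_b <- detect_spots(sim$stack, cfg$psf, detection_params(), channel = "probe_b")
spots_b <- classify_spots(spots_b, estimate_unit_intensity(spots_b),
                          cfg$psf, detection_params())
codetect(spots_a, spots_b, psf = cfg$psf)
#> <codetection> 82.8% (159/192 matched; 95% CI 76.8-87.5%; radius 0.26 um)
sim$truth$true_codetection_fraction
#> [1] 0.845
```

The unit intensity is the robust centre of the single-molecule amplitude
distribution (the top decile is excluded because transcription foci
contaminate it); spot classes follow the screen's gates — foci at \>= 2.5x
the unit intensity, rejects wider than 2x the PSF or dimmer than 0.4x the
unit. The recovered codetection fraction (82.8%) agrees with this
simulation's realised truth (84.5%) well within its binomial interval; in
the published screen the same statistic was 85% in the brain and 78% in
muscle.

Screen-level arithmetic works the same way from annotation tables; for
example, 12 of 200 screened genes showing a pattern extrapolates to the
genome as

```r
extrapolate_genome(12, 200, genome_protein_coding = 13900)
#> estimate 834, one-sided 95% Wilson lower bound 525 -> "at least 525 genes"
```

## Command line

All stages are scriptable through one entry point (see `?run_cli`, wrapper
in `inst/scripts/spotscreen`):

```sh
spotscreen simulate --config cfg.json --seed 7
spotscreen detect   --in sim/stack.tif --channel probe_a --out spots_a.csv
spotscreen codetect --a spots_a.csv --b spots_b.csv --out codet.json
spotscreen segment  --in sim/stack.tif --channel marker --out mask.tif
spotscreen count    --spots spots_a.csv --mask mask.tif --out counts.csv
spotscreen compare  --a counts_wt.csv --b counts_mut.csv --compartment nmj_axon_terminal --out cmp.json
spotscreen score    --in annotation.csv --out scored/
spotscreen report   --in annotation.csv --metadata genes.csv --out report/
```

Exit codes: 0 ok, 2 configuration error, 3 input error, 4 internal error.
Runs with a fixed seed are bit-reproducible.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices made where the published description was qualitative.
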