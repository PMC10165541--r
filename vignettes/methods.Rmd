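---
title: "spotscreen: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotscreen: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A protein-trap screen images hundreds of genes in intact nervous tissue,
each with two aligned readouts: single mRNA molecules rendered as
diffraction-limited smFISH spots, and the protein made visible by a
fluorescent exon inserted into the same gene. The scientific questions are
quantitative: how many transcripts sit in a given 3D compartment, how often
do two independent probe sets detect the same molecule (the sensitivity
control), where do mRNA and protein disagree across cell classes and
subcellular territories, and how do transcript counts shift between genetic
conditions. `spotscreen` implements that pipeline end to end, together
with a synthetic-data generator that produces stacks and annotation tables
with complete ground truth so every stage is testable at the desk.

## Image and spot model

A stack is a set of channels on a common voxel grid with physical voxel
sizes (defaults 0.35 um axially, 0.13 um laterally — ordinary spinning-disk
sampling). Coordinates are 0-based `(z, y, x)` voxel indices with half-open
bounds; physical positions are `index * voxel_size`.

A diffraction-limited spot is an anisotropic 3D Gaussian with lateral and
axial widths `psf_model(sigma_lateral = 0.13, sigma_axial = 0.35)` um. Three
object classes share this shape family:

* **singles** — amplitude near a common unit intensity (tiled probe sets
  make single transcripts remarkably uniform in brightness);
* **transcription foci** — nuclear spots whose amplitude is the transcript
  count times the unit intensity;
* **background blobs** — wider (default 2.5x PSF) and dimmer (default 0.3x
  unit) shapes standing in for autofluorescent debris.

## Detection and measurement

1. **Background subtraction.** Per-z-slice grey-scale opening with a disk
   (white top-hat), radius 5 px for smFISH channels and 20 px for cell
   markers. The 2D-per-slice form matches how the radii are specified
   (pixels per image). The operation is anti-extensive, non-negative and
   idempotent, which the tests assert against a brute-force opening oracle.
2. **Candidates.** A scale-normalised Laplacian of Gaussian at the PSF
   scale (anisotropy from the voxel size), 3D local maxima above
   `detection_threshold_k = 5` robust sigmas (MAD) of the filtered image.
   No numeric threshold is published for this stage; k = 5 is exposed in
   `detection_params()`. Maxima within a PSF-sized border shell are
   discarded — the band-pass response and the local fits are both
   unreliable against the image edge, and border maxima were the only
   false positives observed on blank stacks.
3. **Refinement.** Each candidate gets a local window (2.5 sigma per axis).
   The window's border-shell median removes the local pedestal. Centre and
   widths come from log-quadratic (Guo) fits to Gaussian-weighted
   projections — for a pure Gaussian the weighted projection is still a
   pure Gaussian, so the fit is exact on noise-free data, and the weights
   suppress neighbouring spots. A fit that drifts off its own candidate
   maximum by more than ~1 voxel signals a neighbour inside the window;
   the centre is then reset to the candidate and resolved locally. A
   Gauss–Newton polish of centre, amplitude and a free offset against the
   PSF-width template follows; the free offset makes the amplitude
   estimate independent of the pedestal estimate. Finally the width is
   re-estimated by a template-scale scan (explained-sum-of-squares over a
   log-spaced scale grid with parabolic refinement, amplitude and offset
   free), which is exact at the true scale for a pure Gaussian and has far
   lighter tails under noise than moment- or log-fit widths. Amplitudes of
   PSF-scale spots use the PSF-width template — noise in a fitted width
   would otherwise bias the amplitude low; wide objects (scan scale >= 1.6)
   report the peak height of their own template instead.
4. **Merging.** Duplicates within one lateral PSF sigma
   (anisotropy-scaled distance, axial differences scaled by
   `sigma_lateral / sigma_axial`) merge keeping the brighter.

**Unit intensity.** The single-molecule unit is the median amplitude after
excluding the top decile (foci live there), spread as the MAD; at least 10
candidates are required, otherwise the caller is told to pool images.

**Classification.** A spot is a *focus* at `focus_intensity_factor = 2.5`
times the unit (and, when a nucleus mask is supplied, only inside it —
nuclear foci also override the size gate, since nascent-transcript clusters
can exceed the PSF width). Otherwise it is *rejected* when the fitted
lateral sigma reaches `max_size_factor = 2.0` times the PSF sigma or the
amplitude is below `min_intensity_factor = 0.4` units; otherwise it is a
*single*. The size gate treats the boundary as rejecting (>=, not >) so
that an object at exactly twice the PSF width — the canonical background
blob — is excluded. The published criteria are qualitative ("larger than
diffraction-limited", "lower intensity than the single molecules"); the
numeric factors are this package's defaults, all exposed and recorded in
the provenance snapshot. Focus transcript content is `amplitude / unit`.
Because every gate is a ratio against the unit estimated with the same
template, residual template bias cancels.

## Codetection

Both tables are restricted to singles. Candidate pairs within
`match_radius` (default 2 lateral PSF sigmas) form a graph; each connected
component is solved exactly for the maximum number of one-to-one matches
and, among those, minimum total distance (components beyond 10 spots fall
back to deterministic greedy nearest-neighbour ordered by amplitude, ties
by position — in practice components hold 2–4 spots). The distance is
anisotropy-aware. The fraction `matched_A / total_A` is reported with a
Wilson interval; an empty reference table yields an explicit
`"undefined"` status, distinct from zero. An `any_neighbor` mode is also
provided because the published control does not state its matching rule;
one-to-one is the default and the stricter of the two.

## Compartments, boutons, and comparisons

Marker channels are segmented by Gaussian smoothing (1 voxel), a global
Otsu threshold (manual override available), binary closing, 26-connected
components, and a minimum volume (default 30 voxels; 10 for boutons).
Components are ordered by centroid so labels are deterministic. A blank
channel is recognised by requiring the automatic threshold to clear the
background median by `min_contrast = 3` MADs; otherwise Otsu would happily
split pure noise. Spots take the label of their nearest voxel ("outside"
when unlabelled); totals are conserved by construction. Counts keep
singles and foci separate, with the focus transcript sum alongside, and can
add mean protein intensity per compartment.

Bouton maturity follows the ghost-bouton definition: presynaptic marker
present, postsynaptic-density marker absent. The PSD threshold defaults to
Otsu over per-object PSD means, overridable.

Condition comparisons report the percent change of arithmetic means of
per-image counts with SEMs and a delta-method CI. The test is chosen by
the published decision tree: Shapiro–Wilk per group; equal variances by F
test (2 groups) or Levene (more); normal + equal -> Student's t or one-way
ANOVA with Tukey; non-normal -> Wilcoxon rank sum or Kruskal–Wallis with
Dunn. The published tree does not cover normal-but-unequal-variance data;
that cell uses Welch's t / Welch ANOVA. One-tailed tests are used only
when forced explicitly (as the transport experiment's figure legend does);
the default is two-tailed. No multiple-testing correction is applied
across compartments by default.

## Annotation scoring

Aggregation is a strict majority of non-NA votes per gene x tissue x
compartment and per molecule. Ties (including 1–1 with an NA) are
`escalated_unresolved`: excluded from every denominator downstream and
exported in a conflict report for a fourth expert, never guessed.

**Discordance.** A gene x tissue is discordant when some compartment
carries exactly one molecule. The inter/intracellular split is this
package's explicit operationalisation of a verbal distinction: within each
cell class present in the tissue, *intercellular* evidence is one molecule
present somewhere in the class while the other is absent across the whole
class; *intracellular* evidence is both molecules present in the class but
with different soma/periphery presence patterns. One gene x tissue can
carry both. The unit of the inter/intra shares is the gene x tissue event;
a gene-level roll-up is also reported. A truth-table oracle over all 16
soma/periphery x mRNA/protein patterns pins the rule down in the tests.
Peripheral-mRNA flags use the taxonomy's periphery subregions per cell
class (for neurons: the neuropils, segmental nerve and axon terminal; for
glia: the glial processes) — the published text does not enumerate the
set, so it is configurable through the taxonomy table.

**Neuroblast patterns.** Per-cell detection floors default to >= 2 single
mRNAs (or a transcription focus) and protein above background + 3 robust
sigmas; the background level and sigma are inputs because a lineage with
homogeneous expression contains no internal background reference. A gene
is `not_detected` when the expressing-cell fraction stays at or below 0.1
for both molecules — a thresholded form of "all cells below the floors",
necessary because a scoring error rate of a few percent makes the literal
all-cells rule vanish with lineage size. `homogeneous` needs >= 0.9
expressing for both; otherwise per-cell presence agreement >= 0.8 separates
transcriptional from post-transcriptional cell-specific expression.

**Extrapolation.** `extrapolate_genome()` scales k/n to the protein-coding
genome (default 13,900, configurable) with a Wilson interval. Because the
result is reported as an "at least" claim, the default bound is the
one-sided 95% Wilson lower limit: for 12/200 it gives 525, consistent with
the published "over 500"; the two-sided bound (482) is available via
`one_sided = FALSE`.

## The synthetic world

The generator is the package's stated experimental world, not a tuning
knob. Defaults: 200 singles per probe channel in a 20 x 160 x 160 stack
(a density of roughly one spot per 8 um^3, comparable to a moderately
expressed transcript in neuropil), amplitude 200 photons with CV 0.05
("uniform intensity"), camera baseline 100 photons with Poisson shot noise
and Gaussian read noise (sd 2), a handful of nuclear foci at 3–8
transcripts each, five background blobs at 2.5x width and 0.3x amplitude,
codetected partners jittered by an isotropic Gaussian of 0.5 lateral PSF
sigma (chromatic/localization offset), and a soma + nucleus + axon-terminal
layout drawn from ellipsoids and capped tubes. Annotation tables draw a
pattern class per gene (defaults: 2.5% concordant, 49.7% intercellular,
47.8% intracellular — the screen-scale world in which nearly every gene is
discordant somewhere and the two discordance types are equally common),
then flip each individual call at 5% and inject 2% NAs. The neuroblast
panel uses 40-cell lineages (a type-I neuroblast, a few GMCs and a few
dozen progeny) with the published class mix as priors.

What the generator does **not** emulate: optical aberrations and
field-dependent PSFs, autofluorescence texture beyond the blob primitives,
photobleaching, tissue-scale intensity gradients, or segmentation-hostile
marker morphologies. A green test therefore establishes that the
algorithms are correct and well-calibrated on data obeying their stated
model — not that the defaults transfer to any particular microscope
without re-tuning the exposed parameters.

## Numerical choices and degenerate inputs

* All randomness flows from one seed per generator call, restoring the
  caller's RNG state; identical config + seed gives bit-identical output.
* The profile-likelihood width grid is `{0.6 … 4.0}x` PSF with parabolic
  interpolation accepted only when it genuinely explains more signal, so
  exact grid-point solutions (noise-free data) are returned exactly.
* Blank images: detection returns an empty table (not an error);
  segmentation of a blank channel warns and returns an empty mask;
  an empty codetection reference is `"undefined"` rather than 0.
* Matching tie-breaks are deterministic (amplitude descending, then
  lexicographic position); component labels are centroid-ordered.
* CSV output is UTF-8, comma-separated, `.` decimal, `NA` for missing;
  manifests carry md5 checksums and record counts but no wall-clock
  fields, so fixed-seed runs are byte-identical.

## Known limitations

Dense fields (spot spacing approaching 2 PSF sigmas) lose close pairs to
candidate merging, which no single-emitter fitter can recover; multi-emitter
deconvolution is out of scope. The rolling-ball radius-20 marker setting
flattens structures much wider than the ball, so marker segmentation skips
background subtraction by default. Wide-object amplitude is a template
peak height, not an integrated intensity. The Hungarian-style exact
matcher enumerates per component and falls back to greedy beyond 10 nodes.
TIFF support covers uncompressed single-sample baseline files (float32,
uint16, uint8) — sufficient for this pipeline's round trips, not a general
reader.
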