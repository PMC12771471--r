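---
title: "Methods: quantifying elytral spot dimorphism and Dsx-motif content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying elytral spot dimorphism and Dsx-motif content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(elytramorph)
```

This vignette describes the models and procedures implemented by
`elytramorph`, the assumptions behind them, and the numerical and design
choices made where the procedure leaves latitude. The package addresses a
concrete biological question: in the red morph of *Harmonia axyridis*,
female elytra carry larger black spots than male elytra, and the
sex-differentiation factor Doublesex is implicated both in that phenotype
(via RNAi) and in the *cis*-regulatory landscape of the color-pattern
locus (via Dsx-binding motifs in ATAC-seq peaks). Each stage below is a
module of the package with its own tests.

## 1. Image pipeline

### Segmentation

An elytron photograph is a red, roughly elliptical wing on a bright
background, with black spots. Segmentation proceeds channel-wise:

* **Median smoothing** with a disc of radius 4 px on each RGB channel
  removes sensor noise while preserving edges. Whether the original
  acquisition software used a disc or square window is unknowable; we use
  a disc by default (`median_shape` switches). Median filtering of a
  curved boundary has a small curvature bias (the boundary retreats by
  roughly $\kappa r_f^2/6$, about 0.2 px for our spot sizes), which is the
  main systematic error of the whole pipeline (about $-2\%$ on areas).
* **Wing mask:** Otsu's threshold on the blue channel. The red wing is
  blue-dark and the background blue-bright, so the wing is the
  below-threshold class. We keep the largest 8-connected component, fill
  interior holes (elytra are simply connected), and smooth the contour by
  morphological opening followed by closing with a disc of radius 8 px.
  Opening-then-closing removes protrusions and fills notches
  symmetrically; the operation order matters little on smooth blobs
  (area change $<1\%$ on discs, asserted by a test).
* **Spot mask:** Otsu's threshold on the red channel restricted to wing
  pixels (spots are red-dark on the red wing). Restricting the histogram
  to the wing prevents the background from dominating it. The result is
  intersected with the wing and smoothed the same way.
* **Guard rails.** Otsu's method always returns a threshold, even for
  unimodal data, so two quality checks turn silent failures into errors:
  the two classes' means must differ by at least `min_contrast` (30
  intensity units), and the wing mask must neither hug the image border
  nor cover under 5% of the image. A spotless wing yields an empty spot
  mask rather than an error, since specimens genuinely lacking spots are
  a valid phenotype (reported as area 0).

`otsu_threshold()` is the exact argmax of between-class variance over the
256-bin histogram (ties to the lowest bin); tests compare it against an
exhaustive search and, for the filter, against a sorted-neighbourhood
median oracle.

### Registration and the ten-spot template

Spot identity (positions 1–10 of the standard schematic) is established
by registering all wings into one frame:

1. translate the wing-pixel centroid to the canvas center;
2. rotate so the first/second principal components of the wing pixel
   coordinates lie along X/Y. The 180° ambiguity is resolved by requiring
   non-negative third central moment (skewness) along X; if the skewness
   along Y is then negative, the mask is mirrored, which folds left and
   right elytra into one chirality. For shapes with vanishing third
   moments (the synthetic ellipse) the angle is normalized to
   $(-90°, 90°]$ and no flip is applied;
3. scale each wing's tight bounding rectangle onto the cohort-median
   rectangle (anisotropic, nearest-neighbour so masks stay binary; the
   median is robust to outliers);
4. average the rescaled spot masks into a per-pixel frequency image.

The average image is thresholded at the smallest value in
$\{0.05, 0.10, \ldots, 0.95\}$ that separates exactly ten 8-connected
components. "Smallest" makes the choice reproducible and favours the
largest template extent. Components are numbered by matching their
centroids to the package's canonical layout (`elytra_spot_layout()`)
scaled onto the common bounding box, via greedy closest-pair assignment.
We originally ordered components lexicographically by centroid (x, then
y), but that rule is unstable for spot pairs sharing nearly the same x;
anchoring to the layout constant is stable and keeps the numbering
aligned with the schematic.

### Constrained watershed

Fused spots are split by a marker-based watershed of the negated
Euclidean distance transform, restricted to the spot mask
(8-connectivity, priority flood with deterministic tie-breaking).
Markers are the local maxima of the distance transform (plateaus
collapsed to one representative; greedy thinning to a minimum separation
of 8 px, matching the smoothing radius, since no peak-detection
parameters are published for the original analysis). Crucially, each peak is first assigned to a
template spot region — its containing region, else the nearest one by
Euclidean distance, ties to the lower label — and peaks sharing a label
are merged into a single marker. This is what suppresses
over-segmentation: a complex blob with several distance peaks still
yields one basin per *template spot*, not per peak. On fused synthetic
fixtures the unconstrained one-basin-per-peak variant produces 11–15
segments for ten planted spots, while the constrained version recovers
exactly ten. Fragments unreachable from any marker keep label 0 and are
counted in a QC field rather than into any spot.

Areas are measured on the rigidly aligned but **unscaled** masks: the
bounding-box scaling is anisotropic, which would distort areas, so it is
used only to build the template, which is mapped back into each
individual's frame by inverting the box transform. Normalized area is
`spot pixels / wing pixels`, one record per individual and spot index;
absent spots are 0.

## 2. Sexual-dimorphism statistics

Normalized spot areas are bounded, often skewed, and group variances can
differ (females have both larger means and larger spreads), so group
comparisons use the **Brunner–Munzel** test of the relative effect
$\hat p = P(X < Y) + \tfrac12 P(X = Y)$: pooled midranks, within-group
variances of the difference between pooled and internal ranks, a
t-reference with Satterthwaite-type degrees of freedom, two-sided
p-values. Complete separation makes the rank variance zero; we report
$\hat p \in \{0, 1\}$, an infinite statistic, p = 0 and a warning rather
than an error, since for our effect sizes separation is routine. The
test is validated against a brute-force midrank oracle to $10^{-10}$ and
holds its size empirically (rejection rate in [0.04, 0.06] at nominal
0.05, n = m = 20 over 2000 null replicates).

The multiple-testing family is the **ten spots within one comparison
panel**, adjusted by Holm's step-down method (base R `p.adjust`); the
source protocol states Holm but not the family, and per-panel families
match how per-spot results are presented. Tests are two-sided. Stars
follow the 0.05/0.01/0.005 convention. Categorical traits (frons
melanization scored 0/1/2; hypopygium normal/abnormal) use Fisher's
exact test: exact for 2x2, Monte Carlo conditional on margins with
B = 10,000 otherwise, with an explicitly recorded seed.

## 3. Regulatory scan

The Dsx motif is a position-specific scoring matrix. Probabilities add a
pseudocount of 0.01 per cell; scores are natural-log likelihood ratios
against a uniform background, summed over positions, with detection
threshold 5. The score base and pseudocount of the original scanning
program are not published, so both are configurable and no claim is made
that threshold-5 hit lists on real scaffolds are reproduced
exactly — the scanner is instead validated against an exhaustive
per-window scorer. Both strands are scanned (minus-strand hits reported
in forward coordinates); windows containing ambiguous bases are skipped.

Intervals follow the 0-based half-open BED convention; a motif belongs
to a peak iff they overlap by at least 1 bp. Per allele we report peak
count, total motif hits in peaks, peaks with motifs (A), without (B),
and the ratio A/B to 3 significant figures (undefined when B = 0 and
flagged). Every overlapping hit is counted in the motif total, but only
presence/absence feeds the ratio. FRiP is the fraction of read intervals
overlapping any peak, with the conventional quality verdict (ideal
> 0.3, acceptable > 0.2). A peak is **conserved** iff, for *every* other
allele, some ortholog-map pair links a region overlapping the peak to a
partner region overlapping a peak of that allele (a relaxed k-of-n mode
exists but is off by default); the ortholog map itself is an input,
produced upstream by homology tools. Sex-sharing merges the union of
female and male peaks by overlap and reports the fraction of merged
clusters present in both sexes.

## 4. Synthetic data: what it emulates, and what it does not

The image generator renders an elliptical wing (semi-axes 215 x 140 px
in a 480 x 320 canvas) with up to ten circular-to-elliptical spots at
the canonical layout, global rotation/translation, and additive clipped
Gaussian noise (sd 5 by default). Females scale all spot radii by
`female_scale` (default 1.3, so areas scale by 1.69); per-individual
variation is lognormal on radii (sdlog 0.1, a ~10% CV typical of
morphometric traits), isotropic Gaussian on centers (sd 2 px), plus
small whole-wing rotation (sd 4°) and translation (sd 3 px). Fusion
pairs pull two spots together until their disks overlap. Ground truth
records exact pre-noise pixel areas with disjoint per-spot label masks
(overlap pixels go to the nearest center, ties to the lower index).
Canvas and spot sizes are free choices (the acquisition pixel scale is
not published); they were fixed once so that the smallest spots are
~15 px in radius, keeping rasterization and boundary-bias quantization
well below the 5% accuracy band used in validation.

The genome generator draws i.i.d. bases at a configurable GC content (no
higher-order structure, as none is specified), lays out non-overlapping
peaks, and overwrites planted positions with the motif consensus
(reverse-complemented on the minus strand). The bundled matrix
(`dsx_motif_synthetic()`) is a synthetic 13-bp stand-in with a
DM-domain-like CAATGT core; it is deliberately non-palindromic so a
planted site is detected on exactly one strand, and its columns are
sharply polarized so that threshold-5 false positives in fixture-sized
sequences are vanishingly rare. It is *not* the measured Dsx binding
profile, and no conclusions about real scaffolds follow from it.

Passing tests on these fixtures demonstrates correct recovery of known
geometry and planted motif content under the stated noise model. They do
not demonstrate robustness to illumination gradients, specular
reflections, cuticle texture, partially damaged wings, or non-uniform
genomic background composition — real-data concerns outside this
package's scope.

## 5. Problem sizes and determinism

Validation workloads were sized to be decisive yet quick: 20-image
cohorts for area recovery (accuracy band 5%, observed max ~4%), 20 fused
images for the watershed comparison, 2000 null replicates for the
type-I check, 200 simulated cohorts of 15 per sex for power (the power
simulations reuse the generator's ground-truth areas rather than
re-rendering and re-segmenting thousands of images, because the imaging
stage is validated separately and the statistical question only needs
the area distributions). All generators are pure functions of
(configuration, seed); identical seeds give byte-identical images and
sequences.

## 6. Known limitations

* The curvature bias of median filtering plus morphological smoothing
  gives a small systematic underestimate of spot areas (~2%, worse for
  small spots). It cancels in F-vs-M comparisons, which are the
  scientific target.
* The PCA orientation rule assumes wings are not rotationally symmetric
  in practice; for the synthetic ellipse the angle convention alone
  disambiguates. Wings whose first two principal components are nearly
  equal would register unstably.
* Peaks, reads and the ortholog map are taken as given; peak calling,
  IDR and homology search are upstream of this package.
* The template requires some threshold to separate exactly ten
  components; cohorts whose average image cannot do so raise an error
  listing achievable counts rather than guessing.
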