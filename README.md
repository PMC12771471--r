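# elytramorph

Quantification of sexually dimorphic black spot patterns on ladybird
beetle (*Harmonia axyridis*) elytra, and of Doublesex (Dsx) binding-motif
content in open-chromatin regions of the color-pattern locus.

In the sexually dimorphic red morph of *H. axyridis*, females carry larger
elytral black spots than males; the sex-differentiation transcription
factor *doublesex* drives this dimorphism, and candidate *cis*-regulatory
elements can be ranked by whether accessible chromatin intervals contain
Dsx-binding motifs. This package re-implements that analysis chain as
tested, reusable R code for researchers quantifying insect color patterns
or motif content of ATAC-seq peaks:

1. **Image pipeline.** Median smoothing (disc radius 4 px), Otsu
   thresholding of the blue channel for the wing outline and of the
   within-wing red channel for the black spots, morphological contour
   smoothing (opening + closing, disc radius 8 px), centroid/principal-axis
   alignment, bounding-box normalization, construction of an average
   ten-spot template, and a template-constrained marker-based watershed
   that splits fused spots while suppressing over-segmentation. Output:
   per-spot areas normalized to total elytral area,
   `a_k = |spot_k| / |wing|`.
2. **Dimorphism statistics.** Per-spot Brunner–Munzel tests of the
   relative effect `p = P(X < Y) + 0.5 P(X = Y)` with Satterthwaite-type
   degrees of freedom, Holm step-down correction across the ten spots of a
   comparison panel, significance stars at 0.05/0.01/0.005, and Fisher's
   exact test (Monte Carlo, B = 10,000 beyond 2x2) for ordinal head/abdomen
   scores.
3. **Regulatory scan.** PSSM scanning of both strands with natural-log
   likelihood-ratio scores `sum_i log(p_i(base)/q(base))` at detection
   threshold 5, intersection of hits with open-chromatin peak intervals
   (0-based half-open, >= 1 bp overlap), and the per-allele ratio of peaks
   with (A) versus without (B) Dsx motifs; plus FRiP, conserved versus
   lineage-specific peak classification from an ortholog interval map, and
   the fraction of peaks shared between sexes.
4. **Synthetic data.** Ground-truthed generators for elytron images
   (elliptical wing, ten canonical spots, sex-specific radius scaling,
   optional spot fusion, Gaussian noise) and for motif-planted genomic
   sequences with peak intervals, so every stage is testable without
   downloads.

## Worked example

```r
library(elytramorph)

# simulate a control cohort: female spot radii 1.3x male (area effect 1.69x)
coh <- render_cohort(10, female_scale = 1.3, seed = 20011)
meta <- data.frame(individual_id = sapply(coh, `[[`, "individual_id"),
                   sex = toupper(substr(sapply(coh, `[[`, "sex"), 1, 1)),
                   treatment = "GFP_RNAi")
q <- quantify_cohort(lapply(coh, `[[`, "image"), meta)
res <- run_dimorphism_battery(q$records, list(c("GFP_RNAi:F", "GFP_RNAi:M")))
sum(res$p_holm < 0.05)
#> [1] 10
```

All ten spots are significantly larger in females after Holm correction.
Running the analysis drivers in order reproduces the full narrative:

```sh
Rscript analysis/01_simulate_cohorts.R   # control + dsx-knockdown cohorts
Rscript analysis/02_quantify_elytra.R    # image pipeline -> results/spot_areas.tsv
Rscript analysis/03_dimorphism_stats.R   # Brunner-Munzel/Holm + Fisher
Rscript analysis/04_motif_scan.R         # motif scan -> results/motif_ratio_table.tsv
```

`02_quantify_elytra.R` reports planted-area recovery (median relative
error 1.9%, max 4.9% on the default cohorts); `03_dimorphism_stats.R`
prints `10/10` significant spots for control F vs M and `0/10` after the
simulated *dsx* knockdown; `04_motif_scan.R` prints the per-allele ratio
table whose ratio column reads 1.67, 1.14, 0.900, 1.10 for the
Red-nSpots, Black-nSpots, Black-4Spots and Black-2Spots designs.

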