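# SIMDomains

Quantifying the 3D morphology of H3K27ac-marked chromatin domains in
multi-channel structured illumination microscopy (SIM) stacks of cell
nuclei.

Active enhancers carry the histone mark H3K27ac, and super-resolution
imaging shows that this mark is organized into discrete nuclear domains
whose shape, size and position change with the activation state of
estrogen receptor alpha (ERα): stimulation produces larger, elongated,
centrally placed domains, while hormone deprivation or ER antagonists
produce compact, spherical, peripheral ones. SIMDomains is an R package
for researchers analyzing such data: it turns a raw multi-channel z-stack
(DAPI + H3K27ac + ERα/p300) into a per-domain feature table and the group
statistics needed to compare experimental conditions.

## The pipeline

1. **Z enhancement** — raw SIM stacks have 0.06 µm X/Y pixels but 0.15 µm
   slide spacing. Two slides are interpolated between each real pair,
   `Î = ⅔·I_closer + ⅓·I_farther`, giving 3N−2 slides at 0.05 µm.
2. **Nucleus segmentation** — per-slide DAPI threshold (ON strictly
   above 500 counts), 8-connected components (top 15 by size),
   morphological refinement (fill, 10 dilations, fill), acceptance at
   ≥ 100 000 px and circularity 4πA/P² > 0.4, Sobel boundary extraction,
   and stacking into 3D nuclei.
3. **Channel alignment** — exhaustive Pearson cross-correlation over
   integer shifts finds the systematic ER-channel offset; the median
   correction is applied rigidly.
4. **Domain detection** — the threshold is the top 0.1 percentile of the
   out-of-nucleus background intensities; in-nucleus voxels above it form
   26-connected 3D components, refined per component (fill, 2 dilations,
   fill) and retained at 10–100 000 voxels.
5. **Features** — per domain: H3K27ac–ER Pearson correlation, volume
   (voxels and µm³), sphericity `φ = π^⅓ (6V)^⅔ / S` (S from isosurface
   meshing; φ = 1 for a ball), distance from the domain centroid to the
   nearest nuclear boundary, and a four-level volume class (pooled
   quartiles); per cell: Gini heterogeneity index
   `G = Σᵢⱼ|xᵢ−xⱼ| / (2n²x̄)` for each feature.
6. **Statistics** — one-sided Welch t tests with per-batch t summaries;
   or, behind a Shapiro–Wilk/Kolmogorov–Smirnov normality gate,
   Kruskal–Wallis followed by Bonferroni-corrected pairwise Mann–Whitney
   tests; configurable significance stars.

A seeded synthetic-stack generator (`generateStack()`,
`generateCohort()`) produces DAPI/H3K27ac/ER stacks with an ellipsoidal
nucleus, sphere or capsule domains, controllable ER colocalization, a
known channel shift, and full ground truth — every pipeline stage is
tested against it.

## Worked example

```r
library(SIMDomains)

specs <- defaultConditionSpecs()          # "ED-like" and "E2-like"
g <- generateStack(specs[["E2-like"]], seed = 7)
g$stack
#> MultiChannelStack: 10 slides x 256 x 256 px
#>   channels: DAPI, H3K27ac, ER
#>   spacing: 0.060 um (X/Y), 0.150 um (Z)
#>   slides: 10 real, 0 interpolated

cfg <- runConfig(minNucleusPx = 5000,     # nucleus gate scaled to 256 px
                 maxShift = 6, alignSlides = c(8L, 14L, 20L))
res <- runPipeline(g$stack, cfg, condition = "E2-like")
res$shift
#> ShiftEstimate (dx = -3, dy = 2), peak r = 0.7817 [per-stack median]
head(res$features[, c("corr", "volumeVox", "sphericity", "boundaryDistUm")], 3)
#>        corr volumeVox sphericity boundaryDistUm
#> 1 0.9659143      2888  0.8500680      0.3992885
#> 2 0.9650500      2928  0.8460858      0.3195494
#> 3 0.9623183      3078  0.8544705      0.7166832
```

The recovered shift (−3, +2) is exactly the correction for the generator's
built-in (+3, −2) channel offset. Each feature row is one detected domain:
elongated "E2-like" domains score sphericities well below the ≈ 1.0 of the
compact "ED-like" spheres, with volumes several times larger.

A two-condition cohort contrast in one call:

```r
bench <- benchmarkCohort(seed = 101)
bench$conditionMeans
#>   condition volumeVox sphericity boundaryDistUm      corr
#> 1   E2-like 3041.9288  0.8549238      1.5626219 0.9641358
#> 2   ED-like  858.0612  1.0073004      0.9330834 0.8668917
bench$checks       # all TRUE: volume up, sphericity down, distance up, ...
```

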