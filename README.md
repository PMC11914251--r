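# periloc

Quantitative analysis of the 3D radial position of fluorescently tagged
gene loci relative to the nuclear periphery, from multi-channel z-stacks —
with the chromatin-channel quantifications, the statistical framework and
the genomic-interval analytics that accompany such experiments, plus a
synthetic-data generator with exact ground truth for validating every
step.

## Who this is for

Labs using LacO/LacR-GFP (or FISH) reporters to ask whether a locus is
tethered to the nuclear lamina: the reporter shows 1-3 GFP dots per
nucleus, and the question is how far each dot sits from the nuclear
border, whether that distribution shifts between conditions (e.g. after
knocking out nuclear-envelope proteins), and how the surrounding
heterochromatin and the genome-wide binding landscape of candidate
tether proteins behave.

## The measurement

For each nucleus segmented from the DNA-stain channel (Huang
fuzzy-entropy threshold, 3D connected components), each detected GFP dot
(prominence-filtered local maxima on the maximum z-projection) receives

* an absolute radial distance `d` — the shortest 3D vector from the spot
  to the nuclear border, computed with an anisotropy-aware Euclidean
  distance transform (per-axis sampling = voxel spacing), and
* a normalized radial position `r = 100 · d / (Z/2)`, where `Z` is that
  nucleus's height. Cultured nuclei are flat, so Z is the smallest
  nuclear dimension and `Z/2` is the largest distance a locus can attain
  in 3D: `r = 0%` at the border, `100%` at the center.

Distributions of `r` are compared with two-sample, two-sided
Kolmogorov-Smirnov tests (exact p for small samples), Hochberg-corrected
across comparisons; group measurements use Kruskal-Wallis + Dunn,
pooled/Welch t-tests and Cohen's d. Chromatin-mark channels yield
peripheral-layer thickness (ray casting, mean of 100 distance values),
nucleoplasmic/peripheral intensity ratios from line profiles, and
intranuclear focus counts and areas. Interval analytics cover
bedtools-style merging, genome coverage, cCRE overlap classification
with precedence, same-chromosome/same-length shuffle nulls, signed
closest distances, 2500-bp binned-coverage Pearson correlation,
meta-profile matrices (±3 kb), promoter windows (TSS ± 1 kb) and
expressed-gene classification (mean replicate counts ≥ 5).

## Worked example

```r
library(periloc)

## simulate a small experiment with known ground truth
fld <- makeNucleusField(3, seed = 11)          # ellipsoidal nuclei, hoechst
ps  <- plantSpots(fld, spotsPerNucleus = 2, seed = 12)   # gfp dots
seg <- segmentNuclei(ps$stack)
seg
#> SegmentationResult: 3 nucleus(ei), threshold 594.6
#>   heights (um): 4, 5, 4

spots <- spotTable(ps$stack, seg, noiseTolerance = 2000)
round(spots$rNormPct, 1)
#> [1] 14.1 78.3 25.3 28.3  5.0 64.2

## compare two conditions and test the shift
set.seed(1)
ex <- runPositionExperiment(list(
  wt = 100 * rbeta(200, 1.2, 3),
  ko = pmin(100, 100 * rbeta(200, 1.2, 3) + 15)))
ex$tests[["wt vs ko"]]
#> TestResult [two-sample KS]: D = 0.38, p = 5.74e-13,
#>   adj. p = 5.74e-13, Cohen's d = -0.828 (n = 200/200)
```

The `rNormPct` values are percent of the maximum attainable distance:
here two dots sit essentially at the border (5-14%), others midway
(25-28%) or toward the center (64-78%). The KS comparison reports the D
statistic, raw and Hochberg-adjusted p, and the effect size (group
medians here: 25.2% vs 40.5%); medians and kernel densities for
violin/density plots come from `summarizeDistribution()` /
`plotRadialDensity()`.

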