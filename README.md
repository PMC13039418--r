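# mplexquant

Quantification of multi-round, multiplexed immunofluorescence whole-slide
images in R: cross-round registration, single-cell segmentation and feature
extraction, pancreatic-islet analysis, and expression-landscape clustering —
validated end to end against a synthetic tissue phantom with complete ground
truth.

## Who this is for

Groups doing cyclic multiplexed tissue imaging (cyclic IF, CODEX-style,
imaging mass cytometry after conversion to TIFF) who need per-cell and
per-structure measurements from whole-slide data: for example, mapping
senescence markers (P16, P21, P53, 53BP1) and endocrine hormones (insulin,
glucagon, somatostatin-28) across human pancreas sections.

## What it computes

1. **Registration.** Rounds are aligned to a reference round on the nuclei
   channel: a global rigid transform (rotation θ about the image centre,
   translation t, optional scale) estimated by normalised cross-correlation
   on down-sampled images, then a local deformable correction represented as
   a grid of displacements (step 500 px) estimated by windowed
   cross-correlation at full resolution. An aligned pixel is
   `aligned(p) = moving(R(p + D(p)))` with `R` the rigid map and `D` the
   bilinearly interpolated grid field.
2. **Segmentation.** Classical nucleus detection (background subtraction,
   Gaussian smoothing, Otsu threshold, distance-transform watershed) with a
   plug-in interface for external detectors, followed by bounded label
   expansion: every pixel joins its nearest nucleus within 4.5 µm (7 px at
   0.65 µm/px), equidistant pixels splitting at the midline between nuclei.
3. **Features.** Per cell: morphology (area, aspect ratio, Crofton-perimeter
   circularity `4πA/P²`, equivalent radius `√(A/π)`) and per-channel nuclear
   and whole-cell mean/total intensity after median-filter background
   removal (7×7 window on 10× down-sized images).
4. **Islets.** Thresholding of insulin/glucagon channels, morphological
   closing/opening, hole filling, and a 400 µm² minimum-area rule; islet
   features, Pearson correlation matrices with two-tailed p-values, and
   occurrence-versus-size profiles.
5. **Expression landscape.** Non-overlapping 2000×2000 px ROIs, per-marker
   z-scoring, PCA retaining 95% of variance, k-means (k-means++, 10
   restarts, default k = 20), positivity calling (manual / quantile / Otsu
   on log intensities), endocrine subtyping
   (Insulin+ / Glucagon+ / SST-28+ / negative), co-occurrence fractions with
   Wilson intervals, and 2×2 group means.

Every stage is exercised against `simulateTissue()`, a tissue-phantom
generator that plants nuclei, cell regions, islets, mutually exclusive
marker clusters, smooth background, shot-like noise, and known rigid +
deformable misalignments — and returns the exact ground truth for all of it.

## Worked example

```r
library(mplexquant)

cfg <- phantomConfig(imageSizePx = c(512, 512), nCells = 260, nIslets = 2,
                     isletRadiusRangeUm = c(30, 45), seed = 1)
ph <- simulateTissue(cfg)
ph
#> TissuePhantom: 260 cells, 2 islets
#> MultiplexImage 'round1': 512 x 512 px (0.65 um/px)
#>   channels (6): DAPI, INS, GCG, SST, P16, 53BP1
#>   nuclei channel: DAPI

nuclei <- detectNuclei(getChannel(ph@image, "DAPI"))
cells  <- expandCells(nuclei, 7L)
max(nuclei)
#> [1] 256        # 256 of the 260 planted nuclei detected

feats <- extractFeatures(nuclei, cells, ph@image)
head(feats[, c("cell_id", "nucleus_area_um2", "circularity",
               "INS_cell_mean", "P16_cell_mean")], 3)
#>   cell_id nucleus_area_um2 circularity INS_cell_mean P16_cell_mean
#> 1       1           76.050       1.000        75.111        10.620
#> 2       2           76.473       0.987         2.734         6.282
#> 3       3           81.120       1.000         2.845         3.681

islets <- segmentIslets(getChannel(ph@image, "INS"),
                        getChannel(ph@image, "GCG"))
isletFeatures(islets, ph@image)[, c("islet_id", "area_um2", "aspect_ratio",
                                    "INS_mean", "GCG_mean")]
#>   islet_id area_um2 aspect_ratio INS_mean GCG_mean
#> 1        1  2609.78         1.33    59.93    76.83
#> 2        2  2473.74         1.27    74.84    63.52

sce <- buildExpressionMatrix(feats,
         markers = c("INS", "GCG", "SST", "P16", "53BP1"),
         localization = defaultPhantomProfiles()$localization)
cl <- clusterCells(sce, k = 5, seed = 1)
cl$model
#> ClusterModel: 5 markers -> 4 components (95.4% variance), k = 5
round(cl$occurrence, 3)
#> [1] 0.543 0.090 0.086 0.250 0.031
```

The first cell sits in an islet: its whole-cell insulin mean (75.1 a.u.) is
an order of magnitude above the acinar cells below it, while nucleus areas
(~76–81 µm²) and circularities (≈1) reflect the planted ellipse geometry.
The two recovered islets cover most of the planted disks (true areas 3627
and 3976 µm²; thresholded staining is eroded at islet rims). Cluster
occurrences show one dominant marker-low population plus smaller
marker-high subtypes.

Islet-level statistics recover planted effects; with a population
correlation of 0.4 between islet area and a marker level:

```r
pop <- simulateIsletPopulation(1e4, rTarget = 0.4, seed = 1)
isletCorrelationMatrix(pop, c("area_um2", "marker_mean"))$r[1, 2]
#> [1] 0.411
```

A full run over several rounds — registration through clustering, with all
tables, label maps, aligned OME-style TIFFs and a parameter log written to
disk — is one call:

```r
out <- runPipeline(pipelineConfig(), list(round1, round2), "outdir")
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`simulate` and `all` subcommands).

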