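# cartct

Automated morphometry of mouse articular cartilage from contrast-enhanced
microCT.

Mouse osteoarthritis models are conventionally read out by histopathology:
slow, destructive, and 2D. After incubation in a phosphotungstic-acid (PTA)
contrast bath, the cartilage layer of a dissected tibia becomes the
brightest structure in a conventional microCT scan — brighter than the
subchondral calcified plate, which is brighter than the immersion fluid.
`cartct` exploits that ordering to quantify cartilage structure in 3D,
automatically and reproducibly, for researchers comparing operated
(e.g. destabilised-meniscus) joints against contralateral controls.

The pipeline: coronal re-slicing → optional Hounsfield calibration →
multilevel Otsu segmentation of the cartilage and mineralized compartments
→ automatic placement of one 500 × 800 µm region of interest (ROI) per
tibial condyle, from the detected top edge and the condylar mirror-symmetry
axis → voxel-count volume and mean local thickness per ROI → planar
thickness maps and profiles → paired statistics. A synthetic tibia phantom
with analytic ground truth makes every stage testable without scan data.

## The core quantities

* **Segmentation.** Thresholds minimise the weighted intra-class variance
  ω₀σ₀² + ω₁σ₁² (+ ω₂σ₂²) of the grey histogram (Otsu's criterion, 2- or
  3-class, exhaustive over bin edges); the brightest class is cartilage.
* **Local thickness.** At voxel *p*, τ(p) = 2·max{ r : ∃c,
  sphere(c, r) ⊆ mask, |c − p| ≤ r } — the diameter of the largest
  inscribed sphere containing *p*, computed by exact Euclidean distance
  transform, distance-ridge reduction and sphere painting, and validated
  voxel-for-voxel against an exhaustive search oracle.
* **Volume.** Voxel counting inside the half-open ROI box times the voxel
  volume — integer-exact and additive.
* **Contrast.** SBR = 100·(μ_signal − μ_reference)/μ_reference, tracked
  over stain-incubation time with plateau detection.
* **Statistics.** Two-tailed paired/unpaired t tests with 95% CIs, exact
  Wilcoxon signed-rank for small n, Kolmogorov–Smirnov normality check,
  linear regression with R², coefficient of variation, and percent
  differences of treated over control means.

## Worked example

Generate a control phantom and a "operated" twin whose medial cartilage
shell is thinned to 85.2 % of control, then run the full pipeline on each:

```r
library(cartct)

spec <- phantomSpec(seed = 41)          # 5 µm voxels, 60 µm shells
ctrl <- makeTibiaPhantom(spec)
dmm  <- applyThinning(spec, 0.852, "medial")

res <- runPipeline(pipelineConfig(), ctrl$volume)
res$morphometry
#>      side volume_mm3 mean_thickness_um n_voxels
#> 1  medial 0.02500875          59.05885   200070
#> 2 lateral 0.02501088          59.03579   200087
```

Each row is one automatically placed condylar ROI: `volume_mm3` is the
cartilage volume inside the 100 × 160-voxel footprint (voxel count ×
125 µm³), and `mean_thickness_um` the volume-weighted mean inscribed-sphere
diameter — 59.1 µm against a programmed 60 µm shell, the ~0.4-voxel
digitisation bias discussed in the vignette. Running the same pipeline on
the thinned twin and forming percent differences per side recovers the
programmed loss on the medial side and ~0 % laterally:

```r
thin <- runPipeline(pipelineConfig(), dmm$volume)
g <- function(r, s) r$morphometry$mean_thickness_um[r$morphometry$side == s]
percentDifference(g(thin, "medial"),  g(res, "medial"))   # -> -14.42
percentDifference(g(thin, "lateral"), g(res, "lateral"))  # -> 0
```

A command-line interface wrapping the same functions is installed as
`exec/cartct` (subcommands `phantom`, `segment`, `roi`, `morpho`, `map`,
`uptake`, `stats`, `export-mesh`, `run`).

## Package layout

* `R/`, `src/` — S4 classes and pipeline stages; Rcpp implementations of
  the exact EDT, local thickness (+ brute-force oracle), 26-connectivity
  components, separable Gaussian blur, marching tetrahedra.
* `tests/testthat/` — unit, property and end-to-end recovery tests; all
  fixtures are generated in code.
* `vignettes/cartilage-morphometry.Rmd` — the methods vignette: models,
  parameter meanings, design decisions, limitations.
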