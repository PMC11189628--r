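# mitoSpGFP

Quantification of mitochondrial split-GFP reporters in budding yeast:
per-cell image analysis, flow-cytometry gating, and genome-wide
knockout-screen hit calling, with seeded synthetic-data generators that
carry full ground truth.

## The problem

Split-GFP complementation reports import of a tagged protein into the
mitochondrial matrix: matrix-targeted GFP₁₋₁₀ (delivered together with an
mCherry marker that fills the mitochondrial network) reconstitutes
fluorescence only with proteins whose GFP₁₁ tag has entered the matrix.
Labs using this reporter need three quantitative readouts, all
implemented here:

1. **Per-cell imaging.** From a two-channel confocal z-stack: sum the
   channels along z, separate background from cells by seeded
   random-walker diffusion, split adjoining cells by a seeded watershed
   on the distance transform, detect mitochondria per cell as pixels with
   mCherry ≥ 5% of that cell's maximum, and report the median reporter
   intensity over the mitochondrial mask,
   `spgfp_median = median{ GFP(p) : mCherry(p) ≥ 0.05 · max mCherry }`,
   plus the ratio to the mCherry median over the same support.
   A nucleocytoplasmic module measures N/C = mean nuclear / mean
   cytoplasmic-ring reporter intensity against a nuclear marker.
2. **Flow cytometry.** A positivity gate calibrated on a negative
   control so that strictly fewer than 1% of control events are called
   positive (nearest-rank rule), positive fractions, population means of
   ≥ 25,000 events, and comparisons of a second channel (e.g. the
   membrane-potential dye TMRM) between gate-positive and gate-negative
   cells.
3. **Screen hit calling.** Per knockout strain, the background-subtracted
   fold change of the populational reporter mean after heat shock;
   candidates fall below 1.1. Candidates are classified from per-cell
   measurements with Welch's t-test at α = 0.01: Class 1 (elevated signal
   at 30 °C vs wild type), Class 2 (no significant increase after heat
   shock), otherwise Responsive; known import-pathway genes can be
   excluded. The packaged hits table of validated regulators (5 Class 1,
   140 Class 2) ships in `inst/extdata/table1_hits.csv`.

A synthetic-data module generates microscopy fields (elliptical cells
containing tubular mitochondrial networks), nuclear-marker fields with
prescribed N/C ratios, lognormal flow samples with an optional shifted
positive subpopulation, and whole screens — each with a `GroundTruth`
object, so every pipeline stage is testable against known truth.

## Worked example

```r
library(mitoSpGFP)

# a 20-cell synthetic field, shot + read noise (SNR ~ 13)
spec  <- synthImageSpec(fieldShape = c(6L, 256L, 256L), nCells = 20,
                        noiseSd = 1, shotNoise = TRUE, seed = 11)
field <- generateImageField(spec)
q <- quantifyCells(field$stack)
head(q$cells[, c("cell_id", "cell_area", "mito_area",
                 "spgfp_median", "spgfp_ratio")], 4)
#>  cell_id cell_area mito_area spgfp_median spgfp_ratio
#>        1       501       147     83.71659   0.7021310
#>        2       403       147     84.91254   0.7247961
#>        3       387        98     86.03526   0.7275409
#>        4       338       118     85.26166   0.7037829
q$summary
#>  n_cells mean_spgfp_median mean_spgfp_ratio
#>       20          84.78745        0.7100882
mean(field$truth@trueSpgfpMedian)   # ground truth: 85
```

All 20 cells are recovered; the populational mean of the per-cell median
reporter intensity (84.8) sits within 0.3% of the generator's truth (85;
60 mitochondrial + 25 cytosolic units). Gating a synthetic
ethanol-control-like null sample:

```r
ctl  <- generateFlowSample(nEvents = 25000, seed = 2)
gate <- calibrateGate(ctl$sample, "spgfp")
gate
#> GateModel on 'spgfp': threshold 255.666 (control 'sample' kept < 1% positive)
positiveFraction(ctl$sample, gate)
#> [1] 0.00996
countByClass()
#> Class 1 Class 2
#>       5     140
```

The gate leaves 0.996% of its own calibration sample positive — under the
1% bound by construction of the strict nearest-rank rule — and the
packaged hits table reproduces the published class totals.

## Command line

A thin wrapper ships in `exec/magic-spgfp`:

```sh
magic-spgfp run --config config.yaml --seed 1 --out results/
magic-spgfp quantify --in stack.tif --fraction 0.05 --out results/
```

`run` executes a YAML-configured simulation + analysis pipeline
(`loadConfig()` / `runEndToEnd()`); unknown configuration keys are
rejected by name and an empty configuration resolves to the assay
defaults (fraction 0.05, cutoff 1.1, alpha 0.01, gate bound 0.01,
25,000-event minimum, 3 px dilation radius).
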