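# rblmeasure

Radiographic bone loss (RBL) measurement and periodontitis bone-loss
staging from per-tooth segmentation masks of dental panoramic radiographs.

Marginal alveolar bone loss is the key radiographic feature of
periodontitis. Clinicians quantify it as RBL — the fraction of root length
lying coronal to the alveolar bone crest — and stage its severity from the
dentition's maximum RBL: stage I (< 15%), stage II ([15, 33)%), stage III
(≥ 33%). Measuring this by hand (locating the cemento-enamel junction,
bone crest and apex on every tooth) is slow and inconsistent between
raters.

`rblmeasure` is the *post-processing* side of an automated pipeline: given
a four-class region label map (background / intrabony root / suprabony
root / crown) and a stack of per-tooth position masks in the universal
numbering system (1–32, masks may overlap), it computes each tooth's RBL
and stage. No neural network, radiograph pixel data or DICOM I/O is
involved — any segmentation system (or human annotator) can feed it.

## The measurement

For each tooth, with pixel sets merged from positions × regions:

1. the tooth's longitudinal axis is the principal eigenvector of the
   covariance matrix of the set-pixel (row, col) coordinates (PCA over the
   whole tooth body);
2. the infinite line through the centroid along that axis is clipped
   against the convex hull of the **suprabony** root region, giving length
   *A*, and the hull of the **whole root** (suprabony ∪ intrabony), giving
   length *B*;
3. RBL% = 100 · *A*/*B*, then staged at the 15 / 33 cut-offs.

The convex hull bridges the inter-root gap of multi-rooted teeth, so the
axis length is well defined across the root system. Degenerate axes
(near-equal eigenvalues), missing regions and crown-only teeth are flagged
or rejected explicitly — never NaN.

Also included: the two manual landmark formulas used as clinical
references (`manual_rbl_length()`, `manual_rbl_distance()`), framework-free
reference implementations of the per-pixel multi-label and cross-entropy
losses and the five standard segmentation metrics (IoU, F1, pixel
accuracy, sensitivity, specificity) with report builders, a LabelMe JSON /
indexed-PNG / CSV I/O layer, a seeded synthetic tooth-phantom generator
with exact ground truth, and a command-line interface
(`inst/cli/rbl.R`: `measure`, `evaluate`, `simulate`).

## Worked example

Simulate a small dentition with known ground truth, run the full
crop → merge → measure pipeline, and compare:

```r
library(rblmeasure)
library(dplyr)

specs   <- sample_tooth_specs(6, seed = 7)           # random bone-loss fractions, tilts
phantom <- generate_panorama(specs, overlap_shift = 8, seed = 7)

teeth <- crop_dental_region(phantom$positions, padding = 10)$positions |>
  merge_positions_with_regions(phantom$regions)

analysis <- measure_dentition(teeth)
tidy(analysis) |>
  left_join(phantom$truth, by = "tooth_number") |>
  select(tooth_number, rbl_percent, true_rbl, stage = stage.x)
#> # A tibble: 6 × 4
#>   tooth_number rbl_percent true_rbl stage
#>          <int>       <dbl>    <dbl> <fct>
#> 1            1       23.2     23.3  II
#> 2            2       22.3     22.4  II
#> 3            3       78.9     78.9  III
#> 4            4        9.40     9.92 I
#> 5            5       18.9     18.9  II
#> 6            6       39.2     39.3  III

glance(analysis)
#> # A tibble: 1 × 5
#>   n_teeth max_rbl_percent max_rbl_tooth stage n_flagged
#>     <int>           <dbl>         <int> <fct>     <int>
#> 1       6            78.9             3 III           0
```

Measured RBL tracks the generator's ground truth to well under a
percentage point per tooth, and the dentition is staged from the maximum
RBL (third molars excluded by default). `autoplot(analysis)` draws the
per-tooth bars with stage cut-offs; `plot_tooth_measurement(teeth[[3]])`
overlays one tooth's regions, hulls and clipped axis.

The same pipeline from the shell:

```sh
Rscript inst/cli/rbl.R simulate --out-dir phantom --seed 7 --n-teeth 6 --overlap-shift 8
Rscript inst/cli/rbl.R measure --regions phantom/region_map.png \
    --positions phantom/positions --out results.csv
```

## Scope

The package measures and stages bone loss from masks; it does not diagnose
periodontitis (no extent, grading or clinical attachment assessment), does
not segment radiographs, and does not model angular or furcation defects.
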