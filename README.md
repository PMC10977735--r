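# mitomorph

Automated, single-cell quantification of mitochondrial network morphology
from 2D three-channel fluorescence microscopy.

## Who this is for

Cell biologists and imaging facilities who stain live adherent cells with
a nuclear dye (blue), a plasma-membrane dye (green) and a
membrane-potential-dependent mitochondrial dye (red), image single optical
sections, and want an objective, batch-scale readout of mitochondrial
fragmentation, fusion, swelling, branching and intracellular positioning —
without hand-tracing organelles or binning cells into subjective
categories like "punctate" vs "tubular".

## What it computes

For every field the pipeline derives five label masks in sequence:

1. **nuclei** — difference-of-Gaussians band-pass (σ = 3, 12 px), median
   threshold (with a MAD noise guard), 2000 px size filter, hole fill,
   3 px disk dilation, watershed split, border clearing;
2. **cells** — seeded watershed on the negated membrane channel (nucleus
   interiors forced to the global minimum), iterative merging of residual
   basins by lowest mean boundary intensity, then a user-adjustable
   intensity floor; cell *k* contains nucleus *k*;
3. **mitochondrial clusters** — band-pass (σ = 1, 4 px), threshold at
   mean + 1 SD, 10 px size filter, intersected with cells;
4. **skeleton branches** — topology-preserving thinning; end points (one
   8-neighbor), junction points (≥ 3), branches between them;
5. **isolated mitochondria** — clusters re-segmented by branch-seeded
   watershed, conserving cluster pixels exactly.

From these it measures **31 descriptors per cell** (areas, perimeters,
moment-ellipse elongation/compaction, roundness, Euler number, perimeter-
ratio solidity, box-counting fractal dimensions at box sizes 4/16/64 px,
skeleton length/width/branch/end-point counts, intensity statistics, and
mean distances of the skeleton to the nuclear envelope and plasma
membrane, plus the ratio dN/(dM+dN)). Mitochondrial areas and lengths are
summed per cell, all other per-object features averaged. The box-counting
fractal dimension is

    FD = -gradient(log N) / gradient(log R),   R = 2^0 .. 2^P,

with the mask zero-padded to a 2^P square. Condition-level results are
min–max normalized, `Vn = (Vp − Vmin)/(Vmax − Vmin)`, drawn as a spider
(radar) profile with t-test significance circles (`*` p < 0.05, `**`
p < 0.01, `***` p < 0.001), and classified into a three-axis morphospace
code (mitochondrial state M1–M7, localization I1–I3, cell shape C1–C6).

A built-in synthetic-field generator (`generate_field`) renders cells,
nuclei and random-walk mitochondrial tubules with tunable fragmentation,
swelling and perinuclear bias, plus ground-truth masks — so every stage
is testable without microscope data.

## Worked example

```r
library(mitomorph)

# a synthetic field: 4 cells, moderately fragmented mitochondria
sim <- generate_field(synth_params(seed = 7, fragmentation = 0.3))
res <- process_field(sim$field)

res$cells
#> <label_mask> kind=cells, 512 x 512 px, 4 objects (field synth)

round(res$features[, c("cell_id", "Cell_Area", "MitoCluster_Count",
                       "Skel_Length", "Skel_EndPointsCount",
                       "Mito_Length", "DistToNuclei")], 1)
#>   cell_id Cell_Area MitoCluster_Count Skel_Length Skel_EndPointsCount Mito_Length DistToNuclei
#> 1       1     31768                11       280.2                  27       280.2          5.8
#> 2       2     32804                10       289.5                  28       289.5         11.0
#> 3       3     31173                12       308.8                  32       308.8         12.2
#> 4       4     29852                 9       332.0                  28       332.0          7.5
```

Each row is one cell: `MitoCluster_Count` mitochondrial clusters were
found in it, their skeletons total `Skel_Length` px with
`Skel_EndPointsCount` free ends, and the skeleton sits on average
`DistToNuclei` px from the nuclear envelope. Comparing two conditions and
rendering the spider profile:

```r
ctrl <- do.call(rbind, lapply(1:3, function(i)
  process_field(generate_field(synth_params(seed = i, fragmentation = 0.1),
                               condition = "ctrl")$field)$features))
frag <- do.call(rbind, lapply(1:3, function(i)
  process_field(generate_field(synth_params(seed = i, fragmentation = 0.9),
                               condition = "stress")$field)$features))

cmp <- compare_conditions(reference = "ctrl", out_dir = "cmp",
                          cell_table = rbind(ctrl, frag))
cmp$sigils$stress
#> <sigil_code> mito: M5+M6+M7 | localization: I3 | cell: C4
#>   composite axes: mito

subset(cmp$tiers, tier != "ns") |> nrow()
#> [1] 24
head(cmp$tiers[order(cmp$tiers$p_value),
               c("feature", "p_value", "tier", "direction")], 4)
#>                           feature      p_value tier direction
#> 14          MitoCluster_Roundness 1.019085e-14  ***         1
#> 16             Mito_MeanIntensity 1.404949e-13  ***        -1
#> 24 Skel_BranchPointsEndPointsRatio 2.623025e-13 ***        -1
#> 25                Mito_Compaction 7.466480e-13  ***         1
```

24 of the 31 features shift significantly. The stressed condition is
called fissioned (M6: cluster count up, mitochondrial length down,
roundness up) with dislocation (M5: skeleton length and branch points
down, solidity up) and an apparent swelling component (M7 — here an
artifact of compact grains inflating the area/length width proxy), plus
perinuclear repositioning (I3) — the signature of a fragmentation
stress. `cmp/spider.svg` holds the radar plot; `cmp/feature_stats.csv`
the per-feature p-values and tiers.

Batch processing a folder of TIFF triplets and the command-line wrapper:

```sh
Rscript inst/cli/mitomorph run --input data/ctrl --out out/ctrl \
    --condition ctrl --workers 4
```

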