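# retinaquant

Quantification machinery for zebrafish retinal-regeneration experiments,
packaged as tested, reusable R components. After a neurotoxic (ouabain)
lesion, zebrafish retinas regenerate: Müller glia re-enter the cell cycle,
microglia/macrophages respond, and inner retinal neurons are replaced.
Experiments of this kind quantify that response three ways, and this package
implements all three on a common synthetic-data test bed:

1. **Automated two-channel colocalization counting** in confocal cryosection
   images. Proliferating nuclei are PCNA+DAPI+ objects: each channel is
   preprocessed (unsharp mask, Gaussian blur, optional edge step), binarized
   by an ensemble of thresholds (Otsu, multi-Otsu, local mean; majority
   vote), components below 15 px² are excluded as artifacts, the channel
   masks are overlaid with a binary logical AND, and surviving 8-connected
   objects inside a region of interest are counted — normalized per mm² of
   polygon area or per mm of curvilinear distance along a polyline. Manual
   scoring rules (L-plastin+ cells scored for nuclear PCNA; HuC/D signal
   surrounding a DAPI nucleus) are implemented as explicit mask operations.
2. **ΔΔCt qPCR fold-change analysis** (Livak): ΔCt = Ct_target − Ct_ref,
   ΔΔCt = ΔCt − mean(ΔCt over the saline calibrator group),
   fold = 2^(−ΔΔCt), with reference-gene stability screening on the
   2^(Ct range) fold scale and explicit non-detect handling at the 40-cycle
   limit.
3. **Nonparametric group statistics**: Welch's t-test (plus a permutation
   mode), Kruskal–Wallis with tie correction, Conover–Iman post hoc pairwise
   comparisons with configurable multiplicity adjustment.

A first-class synthetic-data module generates confocal-like retinal sections
(layered DAPI nuclei, a PCNA+ subset, leukocyte bodies; PSF blur, Poisson +
Gaussian camera noise) with **exact ground truth**, and qPCR Ct tables with
programmed log2 fold changes — so every stage is testable without any
download, and counting accuracy is measured against truth, not eyeballs.

## Worked example

```r
library(retinaquant)

cfg <- scene_config(seed = 7)          # 150 nuclei, 30% PCNA+, 8 leukocytes
sec <- generate_section(cfg)
sec$stack
#> image_stack: 360 x 360 px, 1 z-plane(s), channels [DAPI, PCNA, Lplastin], 0.5 um/px
sec$truth$counts[["DAPI&PCNA"]]
#> [1] 43

roi <- roi_polygon(rbind(c(0, 0), c(0, 359), c(359, 359), c(359, 0)))
rec <- count_coloc(sec$stack, "DAPI", "PCNA", roi,
                   segmentation_params(), sample_id = "retina01")
as.data.frame(rec)
#>   sample_id line treatment dpi marker_combo raw_count roi_normalizer roi_unit  density
#> 1  retina01 <NA>      <NA>  NA    DAPI&PCNA        43     0.03222025      mm2 1334.564
```

The pipeline recovers the ground-truth count of 43 proliferating nuclei
exactly under the default noise model; `density` is count per mm² of the
ROI (`density * roi_normalizer == raw_count` always holds exactly).

```r
tab <- generate_qpcr(qpcr_design(
  programmed_log2_fold = data.frame(gene = "ascl1a", line = "mpeg1:FP",
    treatment = "ouabain", dpi = 4L, log2_fold = 2), seed = 7))
screen_reference(tab, "18s")
#>   gene inter_sample_ct_range fold_scale_range  verdict
#> 1  18s             0.6034012         1.519294 suitable

res <- delta_delta_ct(tab, "ascl1a", "18s", match_on = c("dpi", "line"))
mean(res$fold_change[res$treatment == "ouabain"])
#> [1] 3.99                                  # programmed fold was 4

kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#> Kruskal-Wallis rank sum test (tie-corrected)
#> statistic = 7.2, df = 2, p = 0.0273237
```

`run_experiment(run_config(...))` chains simulate → count → qpcr → stats
into a deterministic end-to-end run (byte-identical CSVs for identical
configs), and `retinaquant_cli()` exposes `simulate`, `count`, `qpcr`,
`stats` and `run` subcommands for shell use:

```sh
Rscript -e 'retinaquant::retinaquant_cli()' count \
  --stack section.tif --channels DAPI,PCNA --roi roi.txt --out counts.csv
```

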