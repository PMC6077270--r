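# eduquant

Quantitative evaluation of in-vivo drug target efficacy from two-channel
fluorescence images of tumor sections.

## The problem

After dosing tumor-bearing mice with a candidate compound, the standard way
to ask "did the drug hit its target in vivo?" is a western blot on
whole-tumor lysate — semi-quantitative, insensitive, and unable to separate
compounds with a similar mode of action. A sharper strategy analyzes protein
expression inside a *defined compartment* of the tumor section instead of
the whole tumor. EdU (5-ethynyl-2′-deoxyuridine) injected before sacrifice
labels replicating DNA; the EdU⁺ area of a section delimits the
proliferating compartment, its complement within the tissue the
non-proliferating compartment. Tumor-related proteins localize strongly to
one of the two (e.g. Akt, AIF, Aurora A → proliferating; HIF-1α, EGFR →
non-proliferating), so the compartment serves as an internal standard that
is comparable across animals and treatment arms.

`eduquant` turns that strategy into a reproducible pipeline for people who
quantify drug effects in xenograft imaging studies. For each section
(red = EdU, green = target-protein immunofluorescence) it

1. segments the proliferating area from the EdU channel
   (smooth → Otsu → hysteresis reconstruction → closing → fill → size filter),
2. detects positive cells in both channels as multiscale
   Laplacian-of-Gaussian blob centroids,
3. decides the protein's compartment from the fraction of protein cells
   inside the proliferating mask (pooled over control sections),
4. samples k random circles fully inside the relevant compartment
   (k = 3 by default, containment guaranteed via the distance transform),
5. converts per-circle counts to **cells/mm²** and reports the efficacy
   statistic

   percent change = 100 × (1 − treated density / control density)

   for the two readouts: EdU density in the proliferating area (tumor
   proliferation) and protein density in the protein's own compartment
   (target efficacy).

A ground-truthed synthetic section simulator (Poisson point process per
compartment, Gaussian-spot rendering, known true percent change) makes
every stage testable without real data; no real dataset ships with the
package.

## Worked example

Simulate a control-vs-treated experiment in which the drug removes 75% of
proliferating cells and of target-protein⁺ cells, then analyze it blind:

```r
library(eduquant)

ctrl <- simulation_scenario(seed = 1)        # 512x512 px @ 2 um/px defaults
trt  <- ctrl
trt$lambda_edu_in  <- ctrl$lambda_edu_in  * 0.25
trt$lambda_prot_in <- ctrl$lambda_prot_in * 0.25
class(trt) <- "simulation_scenario"

ex  <- generate_experiment(ctrl, trt, n_per_group = 5, seed = 42,
                           target_name = "p-Akt")
cfg <- default_config(); cfg$seed <- 42L
res <- analyze_experiment(ex$sections, cfg, quiet = FALSE)
```

which prints (abridged):

```
eduquant pipeline: 10 sections, master seed 42
  ctrl_01: proliferating 27.2% of frame; 261 EdU cells, 215 protein cells
  ...
  trt_05: proliferating 29.7% of frame; 86 EdU cells, 71 protein cells
  compartment call for p-Akt: proliferating (overlap 0.918 from 1322 pooled control cells)
  proliferation readout [proliferating]: control 887.5 vs treated 222.7 cells/mm^2 -> 74.9% change
  target readout [proliferating]: control 635.8 vs treated 206.2 cells/mm^2 -> 67.6% change
```

Reading the numbers: the protein is called *proliferating-compartment*
(91.8% of control protein cells lie inside the EdU mask), so both readouts
sample circles inside the proliferating area. The pipeline estimates a
74.9% reduction in proliferating-cell density and a 67.6% reduction in
target-positive cell density — both within a few points of the simulated
truth (75%), the accuracy the shipped validation demands (±10 points across
reduction levels of 25–90%).

`analyze_experiment(..., output_dir = "results/")` additionally writes all
artifacts: per-section proliferating masks (8-bit TIFF + JSON provenance),
`*_detections.csv` (sample_id, channel, row, col, peak_intensity),
`rois.csv` (sample_id, roi_id, row, col, radius_px, compartment),
`densities.csv` (per-sample counts, circle area, mean density),
`comparisons.csv` (group means, percent change), `calls.csv`, `report.csv`
(the tidy summary), `provenance.json` (package version, seed, config hash)
and `pipeline.log`. Re-running with the same config and seed reproduces
every artifact byte for byte.

Real images enter through a YAML config (per-channel 8/16-bit TIFF or PNG,
or multichannel TIFF with a channel map):

```yaml
pixel_size_um: 2.0
seed: 7
target_name: p-Akt
samples:
  - {sample_id: c1, group: control, edu: c1_edu.tif, protein: c1_protein.tif}
  - {sample_id: t1, group: treated, edu: t1_edu.tif, protein: t1_protein.tif}
```

```sh
Rscript inst/cli/eduquant.R run --config config.yaml --out results/
```

The CLI also exposes the stages individually (`simulate`, `segment`,
`detect`, `classify`, `sample`, `quantify`, `compare`; `config` prints all
defaults). Exit codes: 0 ok, 2 validation error, 3 stage failure.

## Package layout

- `R/` — simulator (`scenario.R`, `synthetic.R`), stages
  (`segmentation.R`, `detection.R`, `localization.R`, `roi.R`,
  `quantification.R`), I/O and orchestration (`io.R`, `pipeline.R`).
- `inst/cli/eduquant.R` — command-line entry point.
- `vignettes/eduquant-methods.Rmd` — the model, parameter rationale and
  validation design.
- `tests/testthat/` — unit, property and acceptance tests
  (fixtures generated in code; one small archived golden CSV).
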