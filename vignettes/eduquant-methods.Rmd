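---
title: "Quantifying in-vivo target efficacy from EdU / immunofluorescence sections"
author: "eduquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in-vivo target efficacy from EdU / immunofluorescence sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eduquant)
```

## The measurement problem

Western blots on whole-tumor lysate average a drug's effect over very
heterogeneous tissue, which makes it hard to compare the in-vivo target
efficacy of compounds with a similar mode of action. An alternative is to
measure protein expression inside a *defined sub-compartment* of the tumor
section. EdU (5-ethynyl-2'-deoxyuridine), injected before sacrifice, is
incorporated into replicating DNA and marks the proliferating cells; the
EdU-labeled area of a section therefore delimits the proliferating
compartment, and its complement within the tissue the non-proliferating
compartment. Tumor-associated proteins localize strongly to one of the two
(Akt-family and mitotic proteins in the proliferating area; hypoxia-related
proteins such as HIF-1&alpha;, and EGFR, in the non-proliferating area), so
the compartment acts as an internal standard: the same, biologically
defined region can be compared across animals and treatment arms.

`eduquant` implements this strategy as a deterministic image-analysis
pipeline. For each two-channel section (red = EdU, green = target-protein
immunofluorescence):

1. **Segmentation** partitions the section into proliferating /
   non-proliferating compartments from the EdU channel.
2. **Detection** finds fluorescence-positive cells in both channels as
   blob centroids.
3. **Localization** decides which compartment the protein occupies, from
   the fraction of protein cells inside the proliferating mask (pooled
   over control sections).
4. **ROI sampling** places `k` random circles fully inside the relevant
   compartment (proliferating for the EdU readout; the protein's called
   compartment for the protein readout).
5. **Quantification** converts per-circle counts into cells/mm² and the
   two arms into the efficacy statistic

   $$\text{percent change} = 100\left(1 -
     \frac{\bar d_{\text{treated}}}{\bar d_{\text{control}}}\right),$$

   where $\bar d$ is the mean over per-section densities, so each animal
   counts once regardless of how many cells it contributed.

A synthetic section simulator with known ground truth accompanies the
pipeline; every stage is validated against it.

## The synthetic data model

The simulator (`simulation_scenario()`, `generate_experiment()`) emulates
the statistical structure the method relies on, not the full optics of a
slide scanner:

* **Region geometry.** The proliferating region is the union of a few
  uniformly placed disks, Gaussian-smoothed and re-thresholded at 0.5 —
  a single connected, blob-like region occupying 5–80% of the frame
  (geometry is redrawn otherwise).
* **Cell placement.** Within each compartment cells follow a homogeneous
  Poisson point process: counts are Poisson with mean
  $\lambda \times \text{area}$, positions uniform. This is the simplest
  model consistent with counting cells per unit area, and it makes the
  density estimator's target unambiguous.
* **Rendering.** Each cell is an isotropic Gaussian spot (the PSF model)
  of peak `spot_amplitude` on a constant `background_level`, evaluated
  exactly at pixel centers for its continuous (subpixel) position, with
  optional photon (Poisson) noise and additive Gaussian read noise;
  intensities are clipped to be non-negative.
* **Treatment.** A treated arm is the same scenario with per-compartment
  intensities scaled down; the generator records the true percent change
  $100(1-\lambda_t/\lambda_c)$ per channel and compartment (`NA` when
  $\lambda_c = 0$ and $\lambda_t > 0$, since the ratio is undefined; 0 when
  both vanish).

Defaults — the paper-style study conditions — were chosen once, on
realism grounds, and then frozen: 512 × 512 px at 2 µm/px (a ~1 mm² field),
PSF σ = 2 px (4 µm, a nucleus-scale spot), EdU⁺ density 1000 cells/mm²
inside the proliferating region (a plausible fraction of tumor nucleus
densities of several thousand per mm²) and 20 cells/mm² outside;
protein⁺ 800 / 20 cells/mm²; spot amplitude 10× the read noise. At these
densities the mean nearest-neighbour distance (≈ 16 µm) stays above the
PSF merging scale, so counting by blob detection is physically possible —
denser scenes would conflate the method's statistical error with an
irreducible resolution limit.

What the simulator deliberately omits: autofluorescence gradients,
staining artifacts, vignetting, 3-D sectioning effects, cell-size
variability and spatial clustering beyond the two-compartment structure.
Passing tests on synthetic data therefore demonstrate the *estimator's*
correctness under the stated model, not robustness to every pathology of
real slides.

## Segmentation choices

The boundary of the EdU area was drawn by hand in the original protocol;
any automated rule is a design decision. Ours:
Gaussian smooth (σ = 8 px) → Otsu threshold → hysteresis reconstruction →
binary closing (disk radius 40 px) → hole filling → drop components
< 2000 px. Two elements deserve justification:

* **Hysteresis reconstruction** (default 0.3 of the threshold-to-background
  gap). The smoothed intensity of a Poisson spot field has a large shot-noise
  component; with a single global threshold, dips inside a genuinely labeled
  region fragment the mask. Keeping weak-threshold components that contain
  at least one strong pixel (the Canny construction transplanted to regions)
  repairs these dips without moving the boundary materially: in the dense
  regime the region IoU against simulator truth rises from ≈ 0.84 to ≥ 0.91
  across seeds. The rule is monotone, so raising a fixed threshold still
  never grows the mask.
* **Closing at the region scale, not the cell scale** (40 px ≈ 80 µm).
  In heavily treated sections the EdU labeling becomes sparse, and a
  cell-scale closing leaves the mask as islands hugging the surviving cell
  clusters. Densities measured inside such self-selected islands are
  biased high by factors of 2–4 — enough to turn a true 90% reduction into
  an estimated 55–65%. A closing radius comparable to the region's own
  scale merges the islands into one coherent area (what a human would
  outline) and removes most of that selection bias, at a cost of ~1% IoU
  from rounded concavities in dense sections. Sections much smaller than
  the default frame should scale this radius down accordingly.

The tissue mask defaults to the full frame (xenograft sections typically
fill the field); an optional low-threshold tissue detector
(`detect_tissue()`) can replace it.

## Detection choices

Cells are counted, not graded by brightness. The detector computes a
multiscale scale-normalized Laplacian-of-Gaussian response
(σ ∈ {0.8, 1.15, 1.5} × PSF σ) on the background-subtracted channel
(background = 50 px Gaussian estimate), takes 8-neighbourhood local maxima,
thresholds them, applies greedy non-maximum suppression at 4 px, and
refines peaks to subpixel positions by per-axis quadratic interpolation.

The threshold is the maximum of two terms: a *relative* cutoff
(`rel_threshold = 0.10` × the strongest response, which adapts to staining
intensity) and an *absolute noise floor*, `noise_k = 5` × the image noise
scale mapped into response units by the LoG kernel's L2 norm. The noise
scale is MAD-estimated from the unrectified background residual, which is
robust to the spots themselves. The floor matters precisely when the drug
works: in a section with a 90% reduction the brightest blob is an ordinary
single cell, the relative cutoff alone drops to ~2σ of the noise response,
and hundreds of noise maxima would be counted as cells.

Circle membership is boundary-inclusive (distance ≤ r counts), detections
are computed once per section and re-counted per ROI, and a flat channel
yields an empty detection set rather than an error (an empty treated
section is a legitimate, informative observation).

## ROI sampling and the density estimator

Circle centers are drawn uniformly from the set of pixels whose Euclidean
distance to the nearest background pixel (frame border included) exceeds
the radius, which guarantees full containment by construction and makes an
infeasible radius detectable before any drawing. `k = 3` circles per
section is the protocol default. The radius is not part of the original
protocol; the default is scale-free — the radius whose disk covers
10% of the compartment area, clamped to feasibility and always recorded in
provenance. A 1–2% disk at realistic densities holds under ten cells and
produces unusably noisy per-section densities; 10% (three circles ≈ 30% of
the compartment) matches the generously sized circles of standard practice.
Circles are sampled independently and may overlap; `allow_overlap = FALSE`
switches on rejection of overlapping pairs.

Densities are `mean(counts) / (π r² (pixel size in mm)²)` in cells/mm².
With true centroids supplied as detections the estimator is unbiased for
the generating intensity (it inherits unbiasedness from the Poisson model);
the simulator tests verify recovery to within 3% at λ = 200 cells/mm².

## Localization

The compartment call uses the fraction of detected protein cells whose
nearest pixel lies inside the proliferating mask, pooled over *control*
sections only — after an effective drug the treated target expression can
be marginal, and a per-treated-section call would be unstable. The
three-way rule (≥ 0.75 proliferating, ≤ 0.25 non-proliferating, otherwise
ambiguous) deliberately refuses to force a binary call on mixed expression,
because a wrong call silently redirects every downstream ROI; the pipeline
aborts on ambiguity unless a compartment is forced in the configuration.
An area-overlap variant (`compute_area_overlap_fraction()`) is provided
for mask-level analyses; the cell-count metric is the default because the
downstream statistic counts cells.

## Numerical and reproducibility choices

* Coordinates are 1-based `[row, col]` with pixel centers at integer
  positions, shared by images, masks, detections and ROIs.
* Smoothing and LoG filtering are separable convolutions implemented as
  banded-matrix (BLAS) products with replicate boundaries — exact,
  deterministic, and free of FFT wrap-around at frame edges.
* All randomness is driven by explicit integer seeds; per-section and
  per-stage sub-seeds are derived from the master seed by a fixed
  Lehmer-style 31-bit mixing function, so datasets and analyses are
  reproducible bit for bit across runs and platforms, and stage-by-stage
  CLI runs can reproduce `run`'s artifacts.
* Images are written as 16-bit grayscale TIFF on a fixed 0–65535 range;
  masks as 0/255 8-bit TIFF with a JSON provenance sidecar; tables as
  fixed-format CSV; every pipeline output directory carries a
  `provenance.json` with the package version, master seed and a config
  fingerprint.
* Degenerate inputs fail loudly and specifically: constant EdU channel
  (degenerate threshold), empty mask or infeasible radius (with the
  largest feasible radius reported), zero protein detections (undefined
  overlap fraction), zero control density (undefined percent change).
  Percent change is not clamped: a treated increase is reported negative.

## Validation problem sizes

The shipped tests validate, per module: Poisson means/variances over 500
draws; exact equality of circle counting and overlap fractions with
brute-force membership scans on hundreds of random instances; detection
F1 ≥ 0.95 at amplitude/noise = 5 with spots spaced ≥ 4 PSF σ; segmentation
IoU ≥ 0.90 over 20 seeds in the dense-labeling regime; 20/20 correct
compartment calls for strongly one-sided targets; and full-pipeline
recovery of 25/50/75/90% true reductions to within ±10 percentage points
(5 sections per arm, 20 master seeds per level). Those sizes keep the
whole suite in the tens of minutes on one core while leaving the Monte
Carlo error of each check several times smaller than the tolerance it
asserts.

## Known limitations

* Counting by blob detection undercounts at high density (merging within
  ~2 PSF σ); at the default densities this costs ~10–15% of control-arm
  cells and partially cancels in the treated/control ratio, but percent
  changes of dense targets are mildly conservative.
* The segmentation defaults assume the proliferating region is a single
  connected area at the hundreds-of-µm scale, as in xenograft sections;
  multifocal or necrotic-core geometries are out of scope.
* With fewer than ~30 labeled cells in a section the compartment boundary
  is intrinsically ill-defined; the pipeline still reports densities, but
  their interpretation should lean on the recorded per-circle counts.
* No hypothesis test is attached by default (the protocol reports none);
  an opt-in nonparametric bootstrap CI over sections is available in
  `compare_groups()`.
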