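---
title: "Sizing membrane pores with a dextran probe ladder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing membrane pores with a dextran probe ladder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescope)
```

## The assay

Pulsed electric fields (PEF) and mechanical compression open transient or
permanent pores in the plasma membrane of walled microalgae such as
*Chlamydomonas reinhardtii*. The pore radius can be bracketed with a
size-exclusion assay: incubate cells with fluorescein-labelled dextrans of
increasing molecular weight (a *probe ladder*), apply the treatment, and ask
for each probe whether it reached the cytoplasm. Probes smaller than the
pores enter; larger probes stay out. The pore radius then lies between the
coil radius of the largest entering probe and that of the smallest excluded
probe.

`porescope` implements the full quantitative chain: probe sizing, confocal
image segmentation, equal-area radial intensity profiling, penetration
calling, and interval inference — plus a synthetic-scene generator that lets
every stage be validated without microscope data.

## Probe sizes: the Flory coil

A dextran of molecular weight $M$ is a flexible glucose polymer with
degree of polymerization $N = M / 180.16$ (glucose molar mass in g/mol).
In a good solvent its effective size is the radius of gyration of an ideal
chain,

$$R_g = \frac{a N^\nu}{\sqrt 6},$$

with monomer size $a = 0.35$ nm (hydrodynamic size of glucose) and Flory
exponent $\nu = 3/5$. For the standard 3/10/40/70 kDa ladder:

```{r ladder}
build_ladder(c(3000, 10000, 40000, 70000))
```

The 40 kDa radius computes to 3.654 nm, i.e. 3.65 at two decimals; reference
tabulations sometimes print 3.66 for the same inputs, a one-ulp rounding
difference. `coil_radius()` carries full precision internally and leaves
rounding to display code. Branched-polymer and hydrodynamic-radius models are
out of scope: $\nu$ is a plain parameter, not fitted to solvent quality.

Dosing sanity checks use `molecules_per_cell()`: at the assay concentrations
(2.5–50 µM against ~10⁷ cells/mL) each cell sees $1.5\times10^8$ to
$3\times10^9$ probe molecules, so depletion of the bath by uptake is
negligible and the extracellular background is a stable normalization
reference.

## From image to profile

Input images are multi-channel confocal planes: a cell-wall stain (ConA), the
dextran (FITC) channel, chlorophyll autofluorescence and optionally
transmission. The pipeline (`profile_scene()`) runs per image:

1. **Segmentation** (`segment_cells()`). The wall stain draws a bright ring
   around each cell. The channel is smoothed (Gaussian, σ = 2 px) and
   thresholded; ring interiors are filled and connected components labelled.
   Each cell yields three masks: *outer* (filled ring), *wall* (thresholded
   annulus) and *inner* (outer minus wall — the cytoplasm). All radial
   analysis uses the inner mask, so the wall's own signal is excluded.
   The default threshold is the *half-maximum* between the background level
   (image median) and the ring peak (0.999 intensity quantile): for a narrow
   smoothed band this crossing is an unbiased edge estimator. Otsu's method
   is available (`method = "otsu"`) but on ring images — where almost every
   pixel is background — it sets the cut low and widens the band by about
   half a pixel, which measurably depresses rim-zone intensities.
   Cells touching the image border are dropped: their zones would be
   incomplete and bias any profile they contribute to.
2. **QC filters** (`apply_exclusion_filters()`). Debris and exceptional
   individuals are excluded by equivalent diameter (default 7–13 µm, centered
   on the ~10 µm cell) and solidity (default ≥ 0.9, which removes fused
   doublets); with a chlorophyll channel, components holding more than one
   chlorophyll body are rejected as multibodies. Reason codes are kept in the
   attached QC table. Touching cells are rejected, not watershed-split.
3. **Background** (`estimate_background()`). Mean dextran intensity over
   pixels farther than 2 µm from every cell. It is estimated per image rather
   than per experiment so that slow illumination drift between fields cancels
   in the ratios; the margin keeps halo pixels out of the reference.
4. **Zonation** (`zonate()`). The inner mask is divided into ten zones of
   equal area: nine concentric rings (zone 1 just inside the wall) and a
   central circle (zone 10). Pixels are ranked by distance to the mask
   boundary and cut into equal-count quantile blocks, which makes the areas
   equal *by construction* (within one pixel) and lets zones follow the
   outline of non-circular cells. On a perfect disk of radius $R$ the zone
   boundaries land at the analytic radii $R\sqrt{k/10}$ — the inner circle
   has radius $R/\sqrt{10} \approx 0.316R$. Ties in depth are broken by
   row-major pixel index, so the partition is deterministic. For markedly
   non-circular cells a concentric-circle construction is undefined; the
   distance-quantile generalization is this package's choice.
5. **Profiling** (`profile_cell()`). Mean dextran intensity per zone,
   each divided by the background mean — dimensionless ratios where 1 means
   "as bright as the medium". The wall annulus mean is reported as a separate
   `wall_signal_ratio`, because a probe can sit in the wall without having
   crossed the membrane.
6. **Aggregation** (`aggregate_treatment()`). Per-zone arithmetic mean and
   sample (n−1) standard deviation over cells; at least 10 cells are required
   by default, matching the usual 10–20 cells per condition. Per-cell values
   are retained for the statistics below. Cells are not diameter-matched
   beyond the QC range: the equal-area construction already removes the
   first-order size dependence, and discarding cells would cost power.

## Penetration calls and interval inference

A probe is called *entered* under a treatment (`call_penetration()`) when
both of:

* **effect size** — the mean normalized ratio over zones 1–3 (where entry
  signal is strongest) reaches θ = 0.2, and
* **significance** — a one-sided Welch test of per-cell zone 1–3 means
  against the matched untreated control rejects at α = 0.05.

The dual criterion is deliberate: significance alone would let a large sample
promote a negligible brightening to an "entry", and the score alone would let
one bright outlier decide. The published analyses report entry/no-entry
qualitatively; θ and α are this package's explicit operationalization, and
both are exposed as arguments. Each treatment is compared to the single
untreated control; no multiple-testing correction is applied across probes —
the calls are thresholded effect sizes, not headline p-values.

Wall entry is called separately: mean wall/background ratio ≥ 1.5 (the wall
visibly brighter than the medium; no published number exists, and 1.5 sits
well between the ~0.1 of probe-free walls and the several-fold accumulation
of wall-permeable ones).

`infer_pore_bounds()` turns the calls over the ladder into an interval:
lower bound = largest entering coil radius (0 if none), upper bound =
smallest excluded radius (unbounded if all enter). Patterns impossible under
pure size exclusion (a larger probe in, a smaller one out) are flagged
`non_monotone` and resolved on the monotone closure with a warning — never
silently. `summarize_study()` tabulates intervals and the treatment × probe
wall-permeability matrix; `report_to_json()` serializes it.

Intermediate effects — a probe that brightens cells without meeting both
entry conditions — are visible in the reported `score` and are deliberately
not a third call category; users can threshold the scores themselves.

## The synthetic scene model

`generate_scene()` renders fields of disk-shaped cells (default 15 cells of
radius 5 ± 0.25 µm, wall 0.8 µm, at 0.1 µm/px so a cell spans ~100 px) with
four channels, and returns per-cell ground truth. The dextran channel is the
modelled one: background $B$ outside cells (default 100 a.u.) and, inside,
one of three regimes:

* `none` — 0 everywhere in the cell (control; probe fully excluded);
* `wall_only` — probe in the wall annulus only, at 3 × B (wall-permeable,
  membrane-blocked cells show strong wall accumulation), 0 in the cytoplasm;
* `gradient` — $I(\rho) = B\,p\,e^{-(1-\rho)/\ell}$ for normalized radius
  $\rho$, the simplest two-parameter monotone family reproducing the
  observed rim-to-center decrease (slow inward diffusion past crowded
  cytoplasm). Defaults $p = 0.8$, $\ell = 0.5$: strong rim signal below bath
  level, about five-fold attenuation at the center. No quantitative
  intracellular diffusion data exist to calibrate against, so the defaults
  are shape-constrained choices, fixed once. The wall annulus of a gradient
  cell carries the rim value $pB$, continuous across the membrane.

Disk edges are anti-aliased by 2×2 subpixel sampling, keeping zone
statistics stable at moderate radii. Noise is the standard confocal detector
model — Poisson shot noise (4 counts per intensity unit, i.e. SNR ≈ 20 at
background) followed by Gaussian read noise (sd 2 a.u.) — applied to all
channels; read noise may take pixels slightly negative, as offset-subtracted
detectors do. Placement is rejection sampling with a one-radius in-frame
margin and a 1.5 µm minimum gap (so smoothing cannot merge neighbours);
infeasible requests fail loudly rather than overlap. All randomness flows
from the spec's seed: the same spec is bit-identical.

`expected_zone_profile()` is the closed-form per-zone mean of $I(\rho)/B$
over exact equal-area annuli (with a series branch for $\ell > 10^6$, where
the closed form cancels catastrophically). It is the oracle for the
recovery tests: measured profiles on clean scenes agree with it to well
under 2% per zone at the default geometry, and within 5% at default noise.

What the generator does **not** emulate: point-spread-function blur,
3-D sectioning, photobleaching, autofluorescence bleed-through between
channels, and irregular cell shapes. Passing the recovery tests therefore
shows the *measurement chain* is unbiased on its stated model, not that
segmentation would survive every real-world artifact.

## Validation summary

The test suite builds every fixture in code and checks, among others:

* Table reproduction: the 3/10/40/70 kDa ladder gives 0.77, 1.59, 3.65/3.66,
  5.11 nm; dosing arithmetic spans 1.5×10⁸–3×10⁹ molecules per cell.
* Zonation: zone areas equal within one pixel on disks of radius 40–150 px;
  boundaries within 1.5 px of $R\sqrt{k/10}$; zone 1 forms a closed band on
  elliptical masks.
* Profile recovery at default noise, 15 cells per condition, 10 seeds:
  aggregate profiles within 5% of the oracle per zone; control scenes below
  0.05 everywhere; wall-blocked scenes call `entered_wall` without
  cytoplasmic entry.
* End-to-end: planted exclusion thresholds at 0.77/1.59/3.66 nm are
  recovered as interval-containing estimates in ≥ 9/10 seeds, with ≤ 1/20
  false entries under control-vs-control nulls.

Problem sizes (15-cell 900×900 px scenes, 10 seeds per condition) were
chosen to mirror the 10–20 cells per condition of a realistic acquisition
while keeping the whole suite comfortably fast on a laptop.

## Known limitations

* 2-D only; a mid-plane section stands in for the cell volume.
* Touching cells are discarded, so dense fields lose throughput.
* The penetration call presumes a matched control imaged under the same
  illumination; there is no cross-image intensity calibration beyond the
  per-image background ratio.
* Pore-size bounds are as coarse as the ladder: nothing between two
  consecutive coil radii can be resolved, and "at least 5.11 nm" is the
  strongest statement the 70 kDa probe permits.
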