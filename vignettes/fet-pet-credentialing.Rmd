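---
title: "Semi-automatic FET PET tumour volume delineation and inter-observer agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automatic FET PET tumour volume delineation and inter-observer agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetagree)
```

## The problem

Amino-acid PET with O-(2-[18F]-fluoroethyl)-L-tyrosine (FET) delineates
glioma burden where contrast MRI is ambiguous, and multi-centre trials
that rely on it must first demonstrate that their readers segment and
interpret the images consistently.  The workflow this package
implements is the semi-automatic one used in such credentialing
programmes:

1. **Background.** The reader draws a crescent-shaped region spanning
   grey and white matter on one axial slice of the hemisphere
   contralateral to the lesion; the region is extruded into a short
   tube and the background is its mean standardised uptake value
   (SUV~mean~).
2. **Thresholding.** A spherical search volume is placed around the
   suspected tumour and every voxel inside it with SUV at least
   1.6 x background forms the thresholded volume **GTV0**.
3. **Editing.** The reader removes obvious non-tumour uptake (scalp,
   sinus) and may add regions; the result is the **biological tumour
   volume (BTV)**.  Every edit is kept in an audit log.
4. **Quantification.** TBR~max~ = SUV~max~(BTV) / background,
   TBR~mean~ = SUV~mean~(BTV) / background.
5. **Dynamics.** A 1-mL sphere centred on the SUV~max~ voxel of the BTV
   yields a time-activity curve (TAC) from the dynamic frames; its time
   to peak (TTP) and shape class (type I increasing, II late
   peak/plateau, III early peak then washout) feed the clinical
   interpretation of suspected progression.

Inter-observer agreement of the resulting contours and metrics is
quantified with the coefficient of variation (CoV = SD/mean, sample
SD), pairwise Dice/Jaccard overlap, the exact symmetric Hausdorff
distance (HD), the mean absolute surface distance (MASD), and the
intraclass correlation for a two-way model with absolute agreement and
a single rater,

$$\mathrm{ICC}(2,1)=\frac{MS_R-MS_E}{MS_R+(k-1)MS_E+\tfrac{k}{n}(MS_C-MS_E)},$$

where $MS_R$, $MS_C$ and $MS_E$ are the between-subject, between-rater
and residual mean squares of the $n \times k$ ratings matrix.

## Geometry conventions

Every module shares one coordinate contract: voxel indices are 0-based
conceptually, and the world coordinate of a voxel centre is
`origin + (index + 0.5) * spacing`.  Sphere and crescent membership are
decided by the voxel **centre** (a voxel belongs to a sphere iff its
centre is within the radius).  Surfaces for HD/MASD are the border
voxels (those with a 6-neighbour outside the mask) taken at their
centre coordinates; the discretisation bias this induces is at most
half a voxel and identical for both masks of a pair.  Mask volumes are
voxel count x voxel volume, reported in cm^3^.  If these conventions
differed between the phantom, the delineation and the distance metrics,
surface distances would silently shift by half a voxel — hence they are
centralised in one module.

## Numerical and procedural choices

* **Threshold comparison is closed** (`SUV >= 1.6 x background`).  The
  protocol phrase "1.6 threshold" does not state strictness; the closed
  form makes the invariant *TBR~mean~ of any all-threshold-passing mask
  is at least 1.6* hold with equality cases.  A reader can push
  TBR~mean~ below 1.6 only by manually adding sub-threshold voxels
  (e.g. central necrosis), which the edit log records with a warning —
  reproducing the mechanism behind real-world TBR~mean~ outliers.
* **Background is frozen before thresholding**; later edits never
  trigger recomputation (the workflow order is background, threshold,
  edit).
* **Ties in SUV~max~** break at the lowest linear voxel index, so the
  reported location and the 1-mL sphere centre are deterministic.
* **Empty GTV0 is a flagged result, not an error** — legitimate for
  photopenic cases.
* **Connected components use 26-connectivity** by default
  (conservative for thin scalp arcs); configurable to 6.
* **Crescent geometry.** The vendor tool behind the original workflow
  draws the crescent freehand; its exact annulus is unpublished.  Here
  it is a parametric annular arc (defaults: annulus at 0.45–0.85 of the
  brain footprint radius on the drawn slice — so it straddles the
  grey/white boundary on any grid — with a 120° span, extruded ±1 slice
  into a 3-slice tube) validated never to cross the midline toward the
  lesion.
* **ICC confidence interval.** The 95% CI uses the F-distribution
  method with the Satterthwaite approximation to the denominator
  degrees of freedom — the standard procedure for the
  absolute-agreement single-rater form.  The interval is summarised
  into a reliability label by the conventional bands (below 0.5 poor,
  0.5–0.75 moderate, 0.75–0.9 good, above 0.9 excellent) applied to its
  endpoints, e.g. a CI of 0.63–0.97 reads "moderate to excellent".
* **Hausdorff variant** is the exact (100th percentile) symmetric
  maximum; a percentile option exists for outlier-robust reporting but
  is not the default, because sensitivity to small discrepant islands
  is exactly what the metric is used to expose.  MASD is the symmetric
  average of the two directed mean nearest-surface distances.
* **Percent rounding** in compliance reports is half-up to one decimal,
  matching clinical-report conventions (R's `round()` would round ties
  to even).
* **TAC classification thresholds.**  The literature rule the workflow
  references does not print numeric boundaries.  The defaults — an
  early-peak cutoff of 20 min and a 10% post-peak plateau tolerance —
  are parameters, not constants, and every classification carries a
  rule trace.  A late peak followed by a descent beyond tolerance is
  reported as type III (washout behaviour); curves peaking at the final
  frame are type I.
* **Interpretation rule table.**  Real interpretation combines these
  metrics with qualitative reading, which is out of scope; the default
  table (TBR~max~ ≤ 2.3 treatment-predominant change; above 2.3 type I
  equivocal, types II/III consistent with progression) is a
  transparent, fully configurable stand-in, and the 2.3 boundary is
  exclusive (a case at exactly 2.3 is not "above threshold").

## The synthetic phantom

No patient scans ship with the package; a parametric phantom makes the
full pipeline testable.

```{r}
spec <- phantom_spec(grid_shape = c(48, 48, 24), lesion_volume_cm3 = 10,
                     lesion_tbr = 2.0, psf_fwhm_mm = 0, noise_sd_suv = 0,
                     gm_wm_contrast = 0, seed = 1)
ph <- make_static_phantom(spec)
ph$volume
ph$truth$true_volume_cm3
```

The phantom emulates: an ellipsoidal brain with grey/white compartments
around a configurable mean background (default 1.0 SUV, ±15%
grey/white contrast); a lesion of exact known volume (the voxelisation
picks the n nearest voxels to the centre so the realised volume matches
the request to within half a voxel) and known true TBR; a scalp-like
confounder of elevated uptake just outside the brain surface; Gaussian
point-spread blur (default 4 mm FWHM, matching a clinical
post-reconstruction filter); and additive Gaussian noise in SUV space.
The default voxel grid is 2.03135 x 2.03135 x 3 mm, a clinical brain
PET reconstruction spacing.  Noise is Gaussian in SUV space rather than
Poisson in counts because the pipeline consumes reconstructed SUV
images; dynamic frames default to eight 5-min mid-frames over a 40-min
acquisition.

It deliberately does **not** emulate: sinogram-level reconstruction,
attenuation/scatter artefacts, anatomical MRI, lesion texture
heterogeneity, or infiltrative margins.  Passing tests on the phantom
therefore demonstrate the *correctness of the computations* (threshold
arithmetic, geometry, statistics) and the qualitative mechanisms of
inter-observer variability — not clinical segmentation accuracy on real
tumours.

The simulated rater cohort perturbs the *inputs* of the workflow, not
the output masks: sphere placement error, crescent slice choice, a
signed boundary edit (applied through the audited edit mechanism) and
probabilistic failure to remove the confounder.  This mirrors where
variability arises in practice — initial sphere placement is a known
dominant source.  Note that boundary offsets below one voxel pitch
quantise to no change; simulated jitter standard deviations should be
chosen relative to the grid.

```{r}
mdl <- rater_model(n_raters = 3, boundary_jitter_mm = 0,
                   sphere_offset_mm = 0, p_include_confounder = 0,
                   seed = 5)
masks <- make_rater_cohort(ph$truth, ph$volume, mdl)
dsc(masks[[1]], masks[[2]])   # zero-variance cohort: perfect agreement
```

## What the tests establish

The suite checks, among others: exact recovery of the ground-truth
lesion and of TBR~mean~ = true TBR on a noiseless, blur-free phantom;
equality of DSC/Jaccard/HD/MASD with naive brute-force oracles on
random mask pairs; equality of ICC(2,1) with a hand-computed
sums-of-squares evaluation and recovery of the closed-form
variance-component value $\sigma_s^2/(\sigma_s^2+\sigma_r^2+\sigma_e^2)$
on simulated two-way data (500 replicates of a 200 x 3 design); 100%
TAC-type recovery over 100 noise seeds per shape at 5% noise; and the
qualitative island effect — retained confounders collapse Hausdorff
agreement far faster than MASD.  Simulation sizes (48^3^-scale grids,
hundreds of replicates) were chosen as the smallest designs at which
these properties are stable.

## Known limitations

* Compliance records are data about expert judgement, not a model of
  it: the package never decides acceptability from contours.
* DICOM RTStruct input is out of scope; NIfTI is the canonical
  interchange, and origins survive NIfTI headers only at float32
  precision.
* The ICC implementation assumes a complete ratings matrix; incomplete
  designs are rejected rather than imputed.
* Recomputing a CoV from a mean and SD that were rounded for printing
  is only determined up to the propagated rounding interval — roughly
  ±0.1 percentage points when the mean is printed at two decimals near
  5 — which is why tabulated CoV checks use propagation bounds rather
  than a fixed tolerance.
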