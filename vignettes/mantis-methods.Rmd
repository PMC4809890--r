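---
title: "Morphologically adaptive neonatal tissue segmentation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphologically adaptive neonatal tissue segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tissue classification of neonatal T2-weighted MR images is hard for the
standard atlas-prior machinery built for adults: neonatal scans have low
SNR, reversed GM/WM contrast from incomplete myelination, and — especially
after preterm brain injury — grossly enlarged, distorted ventricles and
white matter with abnormal (CSF-like) signal. A probabilistic atlas gives
stable classification when the subject resembles the template, but when the
ventricles are much larger than the template predicts, the classification
undersizes them: the atlas prior gates CSF away from periventricular voxels
and the white-matter intensity model absorbs them instead.

This package combines the stable atlas-prior route with data-driven
morphological adaptation:

1. **Phase 1** — atlas-prior Gaussian-mixture EM classification with smooth
   multiplicative bias correction.
2. **Phase 2** — a marker-controlled watershed on a multiscale gradient
   image re-segments the CSF; the CSF prior is replaced by the voxelwise
   maximum of the watershed CSF and the original prior.
3. **Phase 3** — grayscale reconstruction by dilation, seeded with the
   phase-1 CSF, flattens isolated bright white-matter regions without
   moving class edges.
4. **Phase 4** — a second classification on the filtered image with the
   adapted template.
5. **Phase 5** — isolated pockets of CSF (and WM) that the filtering
   suppressed are restored by comparing the phase-4 and phase-1 gray-matter
   classifications.

Eight classes are produced: cortical gray matter (1), white matter (2),
deep nuclear gray matter (3), CSF (4), brainstem (5), cerebellum (6),
hippocampus (7), amygdala (8); 0 is background. Codes are stable across
every stage and serialized output.

## The classifier (phases 1 and 4)

The phase-1/4 backend is a simplified stand-in for unified segmentation:
per class $k$ a mixture of $J$ Gaussians (default $J = 2$) with weights
$w_{kj}$, means $\mu_{kj}$ and variances $\sigma^2_{kj}$; the posterior
responsibility of class $k$ at voxel $i$ is

$$ r_{ik} \propto \pi_k(i) \sum_j w_{kj}\,
   \mathcal{N}(y_i / b_i;\, \mu_{kj}, \sigma^2_{kj}) $$

where $\pi_k(i)$ is the (spatially varying) atlas prior and $b$ a smooth
multiplicative bias field. EM alternates responsibilities, M-step updates,
and a bias re-estimation step that fits a ridge-penalized polynomial
(total degree 3 by default) to $\log y_i - \log \hat\mu_i$ over the brain
bounding box; a bias update is kept only when it does not lower the
observed-data log-likelihood, which makes the likelihood trace monotone by
construction. All mixture evaluation is done in log space (log-sum-exp),
so extreme likelihood ratios never underflow.

Deliberate simplifications, and why they are safe here:

* **No nonlinear registration.** Priors are assumed grid-aligned (or
  affinely pre-aligned with `resampleTo()`). The original method uses the
  registration machinery of its host package unchanged; the novel, testable
  content is the morphological adaptation, which is downstream of however
  the priors were aligned. A `phase1Posteriors` bypass accepts externally
  computed probability maps so the morphological phases can be driven by
  any classifier.
* **Polynomial bias instead of a DCT basis.** The contract is "smooth
  multiplicative field"; the 60 mm FWHM setting of the reference
  implementation is recorded in the configuration as the smoothness analog.
  The default degree-3 polynomial represents fields of roughly that scale
  over a neonatal field of view.
* **Priors gate.** A voxel with zero prior for a class gets zero posterior
  for it — this mirrors how template priors behave in practice and is
  exactly the mechanism behind the undersized-ventricle failure that the
  watershed phase repairs. Only a class with zero *total* prior mass falls
  back to a uniform epsilon (with a warning).
* **Variance floor** at $10^{-6}$ times the in-mask intensity variance
  prevents component collapse.
* **Initialization** is deterministic: component means at evenly spaced
  prior-weighted intensity quantiles (the prior-weighted mean for a single
  component), variances at the prior-weighted class variance, uniform
  weights. Classes whose prior weighting is identical (e.g. flat priors)
  would otherwise start at the same parameters — a symmetric saddle EM
  cannot leave — so such groups are spread across their quantile range in
  class order. Given the configuration, the whole fit is deterministic;
  the recorded seed is provenance, not a source of randomness.

## The morphological operators (the heart of the method)

**Marker-controlled watershed.** The control image is a multiscale Gaussian
gradient magnitude with scales $\sigma = 0.25$ mm and the minimum voxel
dimension; derivatives are taken per-mm so anisotropic slices do not bias
edge strength, and scales are combined by voxelwise maximum (the strongest
edge at either scale is what ridge-based flooding needs). Markers are:
CSF = phase-1 CSF posterior $\ge 0.9$ with connected components smaller
than 500 mm$^3$ removed; cortical GM = GM posterior $\ge 0.7$; background =
all voxels outside the brain mask. Flooding is a priority queue ordered by
(control value, insertion counter): no watershed lines, every voxel
assigned, FIFO among equal priorities, seeds pushed in label order then
linear-index order, neighbors enumerated in a canonical offset order. This
makes the output deterministic and invariant under monotone transforms of
the control image, and it is exactly reproducible by a brute-force
priority-flood oracle (tested). The volume threshold is physical: mm$^3$
are converted with the voxel volume, so anisotropic data behave correctly.

**Reconstruction by dilation.** Iterated unit dilation of a marker image
clipped by voxelwise minimum with the mask image until stable; each output
voxel is the lowest value on the highest-intensity path connecting it to
the marker. With the phase-1 CSF as marker (T2 values on those voxels, the
in-mask minimum elsewhere) and the T2 image as mask, isolated bright
white-matter regions are flattened to their surround while seed-connected
CSF and class edges are untouched. The implementation is the raster-scan +
FIFO hybrid; because the reconstruction is a unique fixed point, it is
bit-identical to the naive iterate-until-stable oracle (tested).

Connectivity defaults to face (6) everywhere — the conservative choice for
thin neonatal structures; 18 and 26 are available in the configuration.

## Phase-5 restoration

"Isolated pockets" is operationalized by connected-component adjacency: a
component of voxels labeled cortical GM in phase 4 but CSF in phase 1 is a
pocket iff it does not touch the phase-4 CSF segmentation; pockets are
relabeled CSF, and the symmetric rule restores WM pockets. A subtlety
follows from the phase-3 seed being the phase-1 hard-label CSF: a pocket
that phase 1 detected is part of the reconstruction marker and therefore
keeps its intensity through phase 3 (reconstruction equals the mask image
on marker voxels), so in a well-posed world the restoration pass is a
safety net that fires rarely; the mechanism is exercised directly in unit
tests with constructed phase-1/phase-4 maps, and end-to-end tests assert
that planted pockets are CSF in the final map and that pocket-free worlds
trigger zero restorations.

## The synthetic phantom: what it emulates, and what it does not

The generator builds a nested-ellipsoid brain (peripheral CSF rim ~2 mm,
cortical GM shell ~2.5 mm, WM interior, central ventricular CSF, deep GM,
cerebellum, brainstem, hippocampus and amygdala blobs) at 64^3 / 1 mm by
default, with T2-like intensity ordering CSF (250) > WM (150) > deep GM
(115) > cortical GM (100) and distinct means for the remaining classes.
Key dials, chosen once:

* `ventricleScale` — a **volume** enlargement factor applied to the truth
  while priors keep scale 1 (radii scale with its cube root). The base
  ventricle is ~1.3 cm$^3$, a realistic neonatal ventricular volume; this
  matters because the 0.9-threshold marker core must survive the 500
  mm$^3$ filter, and because a scale-4 ventricle must still fit the brain.
* `noiseSd = 2` — additive Gaussian (not Rician): no pipeline step is
  noise-model specific, and Gaussian keeps the oracles analytic. Low
  relative to clinical SNR, which is intentional: properties measured on
  the phantom should fail only because of pipeline defects, not phantom
  ambiguity (the separability invariant makes this explicit).
* `biasAmplitude = 0.1`, `biasSmoothnessMm = 60` — a unit-mean exponential
  of max-normalized smoothed white noise; 60 mm matches the classifier's
  stated bias smoothness scale.
* `priorBlurMm = 1` with kernels truncated at 3 sigma — a well-matched
  population template with ~1 mm residual uncertainty and finite support.
  Finite support is what lets priors gate (see above).
* Bright WM lesions are intensity anomalies (labels stay WM), planted
  disconnected from all CSF; CSF pockets are label anomalies planted in
  deep WM, disconnected from other CSF, with exact voxel-count volume
  control. Pockets appear in the priors (a template does capture
  peripheral CSF); lesions do not (they are not label anomalies).

What the phantom does **not** emulate: cortical folding, partial-volume
mixing beyond Gaussian blur, Rician noise, acquisition artifacts, or
multi-subject template variability. A green phantom test therefore
establishes the *mechanisms* — prior adaptation, edge-preserving
filtering, topological restoration, metric correctness — not clinical
accuracy on real data, which requires external validation images.

Empirically the phantom reproduces the published failure mode: at
ventricle scales 3-4 a white-matter mixture component migrates to CSF-like
intensity and absorbs enlarged-ventricle voxels wherever the WM prior
dominates, so phase-1 ventricular Dice degrades with scale, and the
watershed adaptation recovers it.

## Numerical choices and degenerate inputs

* Tie-breaks: watershed (FIFO + label order, above); hard labels break
  exact posterior ties toward the lowest class code; components are
  numbered in first-voxel linear-index order.
* Reconstruction marker above its mask is clipped with a warning
  (probability rounding can violate the precondition by 1 ulp); geometry
  mismatches are errors.
* Surface distances use face-connectivity boundary voxels at voxel-center
  coordinates — reproducible and oracle-checkable, adequate at the ~1
  voxel agreement scale; both-empty Dice is defined as 1; an empty mask
  makes surface distance an error (reported as NA by the evaluator).
* Sensitivity/specificity counts are restricted to an evaluation domain
  (default: the union brain mask), since whole-volume true negatives would
  make specificity meaningless.
* Degenerate classifier inputs (empty mask, constant image) are errors
  naming the degeneracy; gradient scales and component-filter volumes must
  be positive.
* NIfTI I/O is a self-contained NIfTI-1 reader/writer (the deployment
  environment carries no NIfTI package): little/big endian, gzip, sform
  and quaternion geometry, slope/intercept scaling; volumes are reoriented
  to a canonical axis order on load and written back in their original
  orientation.

## Known limitations

* The classifier is not a replacement for full unified segmentation: no
  registration refinement, single-channel only, myelinated/unmyelinated WM
  combined.
* The 60 mm FWHM to polynomial-degree mapping is a documented
  approximation, not a numeric equivalence.
* Phase 4 re-runs bias estimation from scratch rather than warm-starting
  from phase 1 (simpler, deterministic; the cost is a few EM iterations).
* Hippocampus and amygdala are small structures; like the original method,
  their segmentations are the least reliable and can be merged into
  cortical GM for evaluation (`mergeNeoBrainS = TRUE`).
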