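---
title: "Level-set segmentation of ischemic mouse brain lesions: models, numerics and validation design"
author: "strokeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-set segmentation of ischemic mouse brain lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After transient middle cerebral artery occlusion (tMCAo) in the mouse,
vasogenic edema elevates the spin-spin relaxation time T2 in the infarcted
territory. On a quantitative T2 map the lesion is therefore bright — but so
are the CSF-filled ventricles and parts of the periventricular zone, and
both lesion shape and ventricle shape vary strongly between animals and
time points; in severe cases the lesion engulfs the ventricles. A plain
threshold cannot separate these structures, which is why manual or
semi-automated tracing has remained the norm. `strokeseg` implements a
fully automated alternative built on two assumptions only:

1. the T2 distribution of infarcted tissue differs from that of healthy
   tissue, and
2. only one (ipsilateral) hemisphere is affected, so the contralateral
   hemisphere supplies within-subject models of healthy tissue and CSF.

## The energy functional

Every stage minimises the same region-based level-set energy (a
Chan–Vese-type model with general region probability terms):

$$E(\phi) = \alpha \, g(\mathbf{x}) \, \mathrm{Length}(\partial\Omega_O)
  + \mu \, \mathrm{Area}(\Omega_O)
  - \sum_{\Omega_O} \log P(I(\mathbf{x});\Omega_O)
  - \sum_{\Omega_B} \log P(I(\mathbf{x});\Omega_B),$$

where $\phi$ is the level-set field, $\Omega_O = \{\phi \ge 0\}$ the
object, $\Omega_B$ its complement inside the evolution domain, and
$P(\cdot;\Omega)$ a per-region intensity model — either a Gaussian
(maximum-likelihood mean and divide-by-$n$ standard deviation) or a 64-bin
histogram over the unit intensity range. The data terms are written as
sums over voxels: the continuous formulation's integrals discretise to
region sums on the voxel grid. Length is the (optionally $g$-weighted)
count of 6-neighbour faces between object and background voxels, and Area
is the object voxel count; both are kept in voxel units because the stage
weights below were tuned on unitless images — physical millimetres enter
only in the final volume report.

The optional gradient map
$g(\mathbf{x}) = 1 - e_v^2(\mathbf{x})$, with
$e_v = -\log P_{\mathrm{Gaussian}}(I(\mathbf{x}); R_{CV})$ min–max scaled
to $[0,1]$, is derived from the segmented contralateral ventricle and acts
as a brake on the length term: near CSF-like intensities $g \approx 1$
(full regularisation weight), far from them $g \to 0$, which stops the
ventricle contour at intensity transitions toward lesion tissue.

## The four-stage cascade

| stage | input | object / background model | $\alpha$ | $\mu$ | $n_{iter}$ | $g$ | domain |
|---|---|---|---|---|---|---|---|
| whole brain | 4th echo | Gaussian / Gaussian | 5 | 2 | 80 | – | full grid |
| contralateral ventricle | T2 map | Gaussian / Gaussian | 0.1 | 0 | 120 | – | $R_{CBH}$ |
| ventricles | T2 map | histogram (fixed) / histogram | 2 | 1.5 | 120 | + | $R_{WB}$ |
| stroke | T2 map | histogram / histogram (fixed) | 0.3 | 0 | 80 | – | $R_{IBH}\setminus(R_V \cup M_{PVZ})$ |

Each stage is initialised from the propagated template labels (whole
brain: $M_{WB}$; contralateral ventricle: $M_{CV}$; ventricles:
$M_{IV}\cup M_{CV}$) except the stroke stage, which is initialised from

$$R_{s_{init}} = P(I;\,R_{WB}\setminus(R_V\cup M_{PVZ})) >
  P(I;\,R_{CBH}\setminus(R_V\cup M_{PVZ})),$$

evaluated on the ipsilateral side, followed by the dense-area filter:
a voxel is *dense* when at least 75% of its in-slice neighbours within a
disk of radius 4 (48 neighbours, evaluated in exact integer arithmetic;
at borders the fraction is over in-bounds neighbours) also belong to
$R_{s_{init}}$, and only 26-connected components touching a dense voxel
survive. The stroke-stage background histogram is fitted on the full
contralateral hemisphere $R_{CBH}$ and frozen; the object histogram adapts
each iteration. Two readings in the source material conflict: the prose
asks for voxels where the *energy* of the whole-brain model is larger,
the displayed formula for voxels where its *probability* is larger. These
are opposite under $E = -\log P$; the probability reading is implemented,
since the energy reading would select the complement of the lesion.
Similarly, the formula's region subscript $R_B$ is read as $R_{WB}$, which
the surrounding prose states explicitly.

Whole-brain postprocessing is per-slice 2D hole filling, per-slice opening
with a radius-2 disk, and extraction of the largest 26-connected
component. Disk-shaped morphology and the dense-area disk act within
slices because slices are 4–7 times thicker than the in-plane voxel size;
connectivity for component analysis is 3D.

## Numerics

The engine uses an explicit descent on a clamped signed-distance field:

* update $\phi \mathrel{+}= dt\,[\alpha(g\kappa + \nabla g \cdot
  \nabla\phi/|\nabla\phi|) - \mu + \log P_O(I) - \log P_B(I)]$ applied at
  every domain voxel (not only near the interface), so that the
  segmentation can converge to the per-voxel maximum-likelihood partition
  wherever the regularisers vanish;
* the data force (a log-likelihood ratio) is clamped to
  $\pm\log(10^8) \approx \pm 18.4$. The histogram probability floor
  ($10^{-8}$) already bounds histogram forces at exactly this value, and
  the Gaussian clamp adopts the same scale so that both model families
  exert comparable, bounded forces and astronomical Gaussian tail ratios
  (air vs brain) cannot stall the time step;
* the time step is CFL-like: $dt = 0.45 / \max|F|$, so no voxel moves
  more than 0.45 units per iteration;
* $\phi$ is clamped to $[-3, 3]$ and, while the length term is active
  ($\alpha > 0$), reinitialised to a chamfer signed distance every 20
  iterations. With $\alpha = 0$ the update is purely local per voxel and
  reinitialisation is skipped: it would repeatedly erase the slow progress
  of weakly driven voxels, whereas its only purpose is to keep the
  curvature estimate healthy;
* curvature is the standard central-difference mean-curvature expression,
  clamped to $[-1, 1]$; the combined regulariser term is clamped to
  $\pm 2\alpha$;
* adaptive (non-fixed) models are re-estimated from the current partition
  every iteration;
* evolution stops after $n_{iter}$ iterations, or earlier once fewer than
  0.01% of domain voxels change label between consecutive iterations,
  *sustained over ten consecutive iterations*. The persistence window is
  needed because the CFL step caps front speed: a front that has not yet
  flipped its first voxel is indistinguishable, over a single iteration,
  from a converged one;
* ties at $\phi = 0$ count as object;
* degenerate regions: the Gaussian standard deviation is floored at
  $10^{-3}$ (of the unit intensity range) and histogram masses at
  $10^{-8}$ with renormalisation, so all log-probabilities stay finite.
  A constant image yields $g \equiv 1$.

Everything is deterministic: identical inputs give bit-identical masks.

## Preprocessing

Scans are cropped to the bounding box of the propagated whole-brain label
(no margin) and intensities scaled to $[0,1]$ (a constant image maps to
zeros). Echo images additionally receive a per-slice normalization that
maps each slice's cumulative intensity distribution onto the
maximum-entropy reference slice (256 quantile levels, monotone mapping).
Two robustness choices matter here. First, in the pipeline the per-slice
CDFs are estimated inside the propagated brain mask *eroded by 3 in-plane
voxels* — the nominal label-propagation error margin — because the
mask boundary otherwise drags skull and air intensities into the
estimate; the fitted map is applied to the whole slice, extended linearly
beyond its knot range with the robust inter-decile slope (a per-slice
gain estimate), and clamped to the unit interval. Second, the
normalization is never applied to the quantitative T2 map, whose absolute
values are the point of quantitative imaging. Entropy for reference-slice
selection is computed after unit rescaling on a 64-bin histogram; ties go
to the lowest slice index.

## Registration and label propagation

The built-in registration maximises the Normalized Correlation
Coefficient between the subject's echo-sum image and the template scan,
coarse-to-fine: four pyramid resolutions for the rigid stage, two for the
affine stage, Nelder–Mead at each level with a shrinking iteration
budget, plus an exhaustive coarse-level translation search that keeps the
simplex out of rotation-compensated local optima. The pyramid is
anisotropy-aware: an axis is only halved while its spacing is within a
factor two of the finest axis, so thick-slice stacks keep their z
resolution at coarse levels. Labels move by nearest-neighbour warping,
and the atlas nesting invariants (hemispheres disjoint inside the brain,
ventricles inside their hemispheres) are re-enforced by masking after
warping. The third, non-rigid B-spline stage of a full registration
pipeline is intentionally out of scope; externally computed transforms
(4×4 affine text files, mm units, or dense displacement-field NIfTIs) are
accepted instead.

## The phantom generator

`generatePhantom()` builds the study conditions the segmentation assumes,
at the acquisition geometry of a 7 T multi-slice multi-echo protocol:
96×96×16 voxels at 0.12×0.12×0.50 mm, TE 9 ms, 20 echoes. Tissue T2
values are healthy 40 ± 3 ms, ventricle/CSF 90 ± 8 ms, lesion 65 ± 6 ms —
chosen so the lesion lies between healthy tissue and CSF with partial
overlap, reproducing the central difficulty of the real task — plus
additive measurement noise (default 1.5 ms) on the map and additive noise
(0.01 a.u.) on the echoes. Geometry choices that matter:

* the brain is a superellipsoid flattened along z, so coronal
  cross-sections stay comparable across the slice stack as they do in a
  real mouse brain; a plain ellipsoid's vanishing polar slices would make
  per-slice histogram matching meaningless at the stack ends;
* the brain is surrounded by a dark cortical-bone gap (T2 ≈ 6 ms, low
  proton density) and extracerebral head tissue (muscle, T2 20 ± 3 ms,
  the literature range for rodent skeletal muscle at high field) spanning
  the whole slice stack — real fields of view contain the head, not
  empty air, and the brain/background contrast of real scans comes from
  the skull gap;
* echo images carry a per-slice multiplicative gain (sd 5%), the
  slice-profile/coil inhomogeneity that per-slice normalization exists to
  correct;
* lesion archetypes: `striatal` (deep single blob), `corticostriatal`
  (striatal blob plus cortical rim), `fragmented` (two disjoint blobs,
  each with a dense core), `large-edema` (a large lesion abutting the
  ventricle and periventricular zone) and `none`. A bisection on the
  shape scale hits the requested target volume within 5%;
* the template atlas is the truth atlas warped by a smooth random
  displacement with a maximum amplitude of 2 in-plane voxels, isotropic
  in millimetres (so the 0.5 mm slice axis moves by proportionally fewer
  voxels) — residual registration error is physical, and letting the
  mask hang a full slice into air would simulate a failed registration,
  which the real pipeline catches by visual inspection;
* the contralateral hemisphere never contains lesion voxels, and with
  `archetype = "none"` the hemispheres are statistically exchangeable.

What the phantom does **not** emulate: partial-volume point-spread
(boundaries are voxel-crisp), Rician magnitude statistics, coil
sensitivity profiles beyond the scalar slice gain, motion, and
anatomical texture correlations (tissue texture is voxel-iid). Passing
the phantom suite therefore demonstrates correctness of the machinery and
of the statistical logic under the method's own assumptions; it does not
certify accuracy numbers on real scans.

## Validation design and problem sizes

The test suite checks every operation against independent oracles
(closed-form estimators, brute-force energy summation, exhaustive
neighbourhood counting, per-voxel maximum-likelihood classification,
ANOVA mean-squares ICC) and runs the full cascade on 10-phantom suites at
the default 96×96×16 geometry: corticostriatal recovery (mean lesion Dice
and volume error), fragmented-component detection, lesion-free
specificity, and a ±50% perturbation of each stroke-stage parameter
(α, μ, $n_{iter}$), re-running only the stroke stage against cached
upstream results. `scripts/acceptance.R` recomputes the same quantities
from scratch with lesion sizes spanning 12–57 mm³ so that the volume ICC
is measured across a meaningful spread.

## Known limitations

* **Specificity on exact nulls.** On a lesion-free phantom with exactly
  exchangeable hemispheres, the stroke initialization reduces to a
  per-histogram-bin coin flip between two empirical rates, selecting
  about half of the healthy-tissue mass; the selected voxels form a
  spatially iid field far above the 3D 26-connectivity percolation
  threshold, so one giant component forms and survives the dense-area
  filter whenever a single dense voxel exists. Measured across ten seeds,
  only a minority of lesion-free phantoms yield a near-empty lesion. With
  any real lesion present the whole-brain model's healthy bins are
  systematically diluted and the initialization is reliable; the
  instability is a property of the published initialization rule at the
  exact-null boundary, and is reported honestly rather than patched.
* The whole-brain stage operates close to the balance point between the
  area penalty $\mu = 2$ and the boundary data force; on data whose
  background model is much wider than the brain's (e.g. bright
  extracerebral tissue with no skull gap) it slowly erodes the brain rim.
* No non-rigid registration: severe deformations (large edema at late
  time points) need an externally supplied displacement field.
* Runtime is dominated by the level-set iterations; a 96×96×16 phantom
  segments in a few seconds on one core.
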