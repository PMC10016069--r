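---
title: "Mapping frontoinsular cortex from diffusion microstructure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping frontoinsular cortex from diffusion microstructure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ficmap)
```

## The problem

The frontoinsular cortex (FI) — the ventral anterior insular region rich in
von Economo neurons — has a distinctive gray-matter microstructure: its
neurites are unusually aligned, which lowers its orientation dispersion
index (ODI) and raises its fractional anisotropy (FA) relative to the
surrounding cortex.  `ficmap` turns that signature into an individualized
segmentation: it fits microstructure models to multi-shell diffusion MRI,
projects the fitted parameters onto white/pial cortical surface models,
thresholds the smoothed surface map inside an anterior-insula restriction
mask, and quantifies the volume, surface area and thickness of the
resulting parcel, together with cohort-level reliability, heritability and
behavioral-association statistics.

## Microstructure models

**NODDI.**  The normalized signal is a three-compartment mixture

$$S/S_0 = (1 - v_{iso})\,\big(v_{ic} A_{ic} + (1 - v_{ic}) A_{ec}\big)
  + v_{iso}\, e^{-b d_{iso}},$$

where $A_{ic}$ is a Watson-dispersed stick (axial diffusivity $d_\parallel$,
zero radial diffusivity), $A_{ec}$ a Watson-dispersed zeppelin with the
tortuosity coupling $d_\perp = d_\parallel (1 - v_{ic})$, and the isotropic
compartment has fixed diffusivity $d_{iso}$.  The Watson concentration
$\kappa$ maps to the orientation dispersion index by
$\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)$.  Defaults follow the
gray-matter-optimized kernel: $d_\parallel = 1.1\times10^{-3}$ mm$^2$/s and
$d_{iso} = 3.0\times10^{-3}$ mm$^2$/s (the CSF value; the source work
states it explicitly for the free-water tensor model, and we adopt the same
standard value for the NODDI isotropic compartment).

Fitting is accelerated with the spherical mean technique (SMT): the
per-shell mean of the signal over gradient directions is independent of the
orientation distribution, so stage 1 estimates $(v_{ic}, v_{iso})$ from the
shell means alone (coarse grid plus bounded quasi-Newton refinement).
Stage 2 estimates $\kappa$ and the mean orientation — and refines the
fractions — by bounded nonlinear least squares on the full signal,
initialized from stage 1 and from the principal axis of a log-linear tensor
fit.  Which parameters the original SMT-accelerated implementation froze in
its second stage is not documented; refitting the fractions is the more
conservative choice and changes noiseless round trips by less than the
optimizer tolerance.  The Watson orientation average is evaluated by
Gauss–Legendre (48-point polar) × uniform (32-point azimuthal) quadrature,
accurate to well below $10^{-3}$ for $\kappa \le 64$ (ODI $\ge 0.01$, the
fit bound).

**Free-water-eliminated DTI.**  A two-compartment tensor model
$S/S_0 = (1 - f) e^{-b\, g^\top D g} + f e^{-b d_{iso}}$ with
$d_{iso} = 3.0\times10^{-3}$ mm$^2$/s.  The tissue tensor is initialized by
two-pass weighted linear least squares on the log signal and refined by
bounded nonlinear least squares with $f \in [0, 1]$.  Tissue diffusivities
are bounded below $d_{iso}$ (at $0.97\,d_{iso}$): without that constraint a
pure-CSF voxel is equally well explained by $f = 0$ with an isotropic
tensor at $d_{iso}$, i.e. the compartments are not identifiable.  FA and MD
are computed from the eigenvalues with small negative values (noise)
clamped to zero.  Voxels with $f > 0.95$ are flagged tensor-unreliable.

Both fits use bounded Levenberg–Marquardt (maximum 200 iterations,
tolerance $10^{-8}$); voxels with non-finite or all-zero signals are
flagged and skipped, and voxels whose shell means show no measurable decay
(minimum above 0.98) are flagged rather than fit.

## Depth-weighted cortical sampling

For each vertex, 15 sampling points are spaced equally along the straight
segment from the white to the pial vertex, endpoints included — inclusive
spacing puts samples exactly at the boundaries and the midpoint, where the
weighting is calibrated.  Samples are weighted by a Gaussian in normalized
depth centered at the midpoint with weight 1, its width solved so both
boundary samples receive exactly 0.05; this de-emphasizes voxels prone to
partial-volume contamination at the tissue boundaries.  Outliers are then
rejected in a single pass at $|z| > 3$, computed from the unweighted mean
and SD of the raw samples (the weights enter only the recomputed estimate;
which of the two conventions the original tool used is not documented, and
the unweighted form is the simpler and more stable detector).  The
recomputed weighted mean and SD per vertex form the surface map.

Interpolation uses a separable Catmull–Rom tricubic kernel (it reproduces
linear fields exactly) both for depth sampling and for rigid resampling of
parameter volumes into structural space; trilinear is available through the
sampling configuration.  The kernel is evaluated as a normalized
convolution: non-finite voxels (outside the fitted mask or field of view)
are dropped and the remaining weights renormalized, and a sample that loses
half its weight mass — or whose center leaves the grid — is flagged missing
(`NA`), never zero.  Missing vertices propagate through atlas resampling
(barycentric, with weights renormalized over non-missing corners) and are
excluded from smoothing averages.

Depth is parameterized linearly along the white→pial segment; streamline or
equivolumetric trajectories are out of scope.

## Vertex-wise morphometry

Area, thickness and volume are computed per vertex so that parcel metrics
are exact sums:

* **area** — each mid-thickness triangle (vertices averaged between white
  and pial) contributes a third of its area to each of its vertices; the
  mid-surface matches the sampling scheme's center of mass, and vertex
  areas sum exactly to the total mid-surface area;
* **thickness** — Euclidean distance between corresponding white and pial
  vertices (the inputs are FreeSurfer-style paired meshes);
* **volume** — the oblique truncated prism between each triangle's white
  and pial copies is decomposed into three tetrahedra with a fixed,
  orientation-consistent diagonal rule, computed as signed volumes and
  split equally among the triangle's vertices.  Self-intersecting prisms
  can go negative; these are clamped to zero with a warning count.

On level-4 icospheres the totals agree with $4\pi r^2$ and
$\tfrac{4}{3}\pi(R^3 - r^3)$ to 0.12% and 0.22% respectively.

## Parcellation

The FI parcel is extracted by: Laplacian smoothing of the vertex map
(2 iterations, $\lambda = 0.3$; per iteration
$v \leftarrow v + \lambda(\overline{v}_{nbr} - v)$ over edge neighbors);
strict thresholding inside the restriction mask (below the threshold for
ODI, above for FA — boundary-equal vertices excluded, per the stated
directionality); one synchronous mode-filter pass over closed neighborhoods
with ties keeping the current label; and largest edge-connected component,
with size ties broken by summed vertex area and then lowest vertex index so
results are deterministic.  Adjacency is triangle-edge connectivity.  The
number of mode-filter passes and the neighborhood definition are not
documented in the source work; one pass over the closed neighborhood is the
minimal regularizer.  Thresholding happens on the atlas topology (where the
restriction mask lives), after atlas resampling.

Parcel metrics are sums of vertex area/volume over the mask, area-weighted
mean thickness, and percent metrics against whole-cortex totals.

## Cohort statistics

* **Threshold optimization** sweeps 41 candidate thresholds (0 to 1 in
  steps of 0.025), runs the full parcellation chain per subject and
  threshold, and selects the threshold minimizing the absolute adjusted
  Fisher–Pearson skewness of the parcel-volume distribution (ties to the
  lower threshold); degenerate distributions get undefined skewness and are
  excluded.
* **Reliability** uses a one-way decomposition over two sessions:
  with between/within mean squares $MS_B, MS_W$,
  $\mathrm{ICC} = (MS_B - MS_W)/(MS_B + MS_W)$ — for two sessions exactly
  the classical one-way random-effects ICC(1) — and
  $\mathrm{CoV} = \sqrt{MS_W}/\mu$.  The $\sigma$ symbols of the formula
  are interpreted as mean squares: that is the only reading under which
  the ratio coincides with the classical ICC, which we take as intended.
* **Heritability** uses double-entry sibling correlations (each pair in
  both orders, so the estimate is order-invariant) for MZ, DZ and non-twin
  pairs matched on both parental identifiers, and Falconer's formula
  $H^2_b = 2(r_{MZ} - r_{DZ})$.
* **Group contrasts** are Student's t-tests: paired for left–right, Welch
  two-sample for male–female.
* **Behavioral regression** standardizes all continuous variables on the
  full cohort, excludes Tukey-fence outliers of outcome and predictor
  (fences from the full cohort, $1.5\times$IQR beyond the quartiles,
  type-7 quantiles), fits OLS with a fixed covariate set (replacing the
  loosely specified stepwise procedure with a deterministic one), and
  reports $R^2$, standardized $\beta$, SE, $t$, $p$, and
  $\Delta\mathrm{BIC} = \mathrm{BIC}_{without} - \mathrm{BIC}_{with}$ with
  $\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ (positive favors keeping
  the predictor).  Multiple comparisons use Benjamini–Hochberg q-values.
* **Probability maps** are per-vertex subject fractions of parcel
  membership.

## Synthetic data: what it emulates, and what it does not

The generator provides every downstream stage with a parameter-recovery
test and no external data.

**Phantom.**  Concentric white/pial icospheres (defaults: 30/33 mm, level
3, i.e. 642 vertices) with a planted low-ODI, high-FA patch around a center
direction.  The parameter field is purely angular — every voxel within the
patch angular radius takes the patch value — so the field is constant along
each sampling ray and interpolation near the ribbon boundaries stays clean.
The default patch radius (0.52 rad) sits at the midpoint of a gap in the
icosphere's vertex-angle spectrum, so no vertex lies near the planted
boundary and exact noiseless recovery is well-posed.  Ground truth is the
vertex set whose mid-thickness point falls inside the patch radius —
exactly how parcels are scored.  Noise is additive Gaussian (clipped to
(0,1)): the high-SNR regime of modern multi-shell acquisitions, and it
keeps the oracles analytic; Rician bias is deliberately not simulated.
DWI phantoms evaluate the NODDI forward model per voxel (radial neurite
orientation by default, as in a spherical cortex) with seeded Gaussian
noise.

**Twin/retest cohorts.**  Latent traits follow an ACE model
($a^2 + c^2 + e^2 = 1$): MZ co-twins share the full additive and shared
components, DZ co-twins half the additive and the full shared component;
non-twin siblings have DZ-like genetic sharing but are labeled distinctly,
since they are analyzed as a separate group.  Observed metrics add
measurement noise; the retest table is a second independent draw; a
behavioral column has a chosen standardized slope against the latent trait.
Expected latent pair correlations are $a^2+c^2$ (MZ) and $a^2/2+c^2$
(DZ/NT).

**Threshold-sweep cohort.**  Each subject carries a fixed uniform score,
and its parcel volume at threshold $\tau$ is the corresponding quantile of
a scaled Beta distribution with shapes
$a = s_0 e^{g(\tau - \tau^*)}$, $b = s_0 e^{-g(\tau - \tau^*)}$
(defaults $s_0 = 4$, $g = 30$, $\tau^* = 0.375$): symmetric exactly at the
planted optimum and increasingly skewed away from it, with across-subject
sample skewness monotone in $\tau$ (the Beta family is ordered by convex
transforms in this direction), hence a unique zero crossing.  The vertex
map inverts this volume profile through the mesh's empirical cap-volume
function, and — because the chain smooths before thresholding — the maps
are returned as the pre-image of the designed profile under the linear
smoothing operator, so the planted structure lives in the domain where the
threshold operates.  Toward the sweep extremes the volume distribution
degenerates smoothly to all-empty/all-full parcels (undefined skewness,
excluded) rather than saturating; an earlier shifted-log-normal design
saturated at window edges and produced spurious skewness zero crossings,
which is why the bounded family was adopted.

What the phantoms do **not** emulate: gyrification and curvature (spheres
only), susceptibility/eddy artifacts and motion, Rician noise, spatially
varying SNR, and registration error (surface–volume alignment is exact by
construction).  Passing tests therefore demonstrate the correctness of the
numerics and the recoverability of planted effects, not robustness to
real-world artifacts, which the upstream acquisition pipeline is assumed to
have handled.

## Numerical choices and conventions

* World coordinates are RAS mm; the NIfTI voxel-to-world affine uses
  0-based voxel indices; vertex indices are 1-based in R (0-based on disk
  in FreeSurfer formats, converted on read/write).
* Shell grouping tolerates ±100 s/mm$^2$; b-values ≤ 50 count as b=0.
* Seeds: every stochastic generator takes an explicit integer seed and is
  bit-reproducible; pipelines record seed and configuration in a
  provenance JSON sufficient to re-execute any stage.
* Surfaces are read/written as FreeSurfer binary triangle files, maps as
  curv or CSV, masks as label files or index lists; no GIFTI reader is
  bundled.
* Test and acceptance problem sizes: parameter-grid round trips use 75
  voxels per model on a 96-measurement protocol; patch-recovery phantoms
  use level-3 icospheres (642 vertices) on a 74³ voxel grid; the sweep
  cohort uses 40 subjects on level-4 icospheres (2562 vertices); twin
  simulations use 2000+2000 pairs.  These sizes make every recovery
  property measurable at tight tolerances while keeping a full run in the
  low minutes on a single core.

## Known limitations

Depth sampling is linear (no equivolumetric correction), thickness is
corresponding-vertex distance (not symmetric closest-point), the two-stage
alignment refinement of the original tool is represented only by its
weighting scheme, heritability is Falconer's formula rather than a fitted
SEM ACE model, and the restriction mask must be supplied (the original was
drawn manually).
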