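---
title: "Bilateral Compton-camera XFCT: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral Compton-camera XFCT: model, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccxfct)
```

## The imaging problem

X-ray fluorescence computed tomography (XFCT) maps the spatial
distribution of a high-Z tracer (here gold nanoparticles, K-edge
80.7 keV) by exciting its characteristic fluorescence and localizing
the emitted photons.  Mechanical collimation throws away most of the
fluorescence; a Compton camera replaces it with *electronic
collimation*: a photon that Compton-scatters in a thin scatter layer
(Si) and is then fully absorbed in a second layer (CdZnTe) constrains
its origin to a cone.  With two such two-layer cameras flanking the
object, every effective event contributes one cone, and a list-mode
iterative reconstruction turns the cone ensemble into an image.

`ccxfct` implements the full chain: a seeded Monte Carlo event
generator standing in for a full transport simulation, effective-event
screening, cone/attenuation system-matrix assembly, list-mode MLEM with
total-variation (TV) regularization, 3D post-processing, and the
standard evaluation metrics.

## Compton kinematics

For an incident photon of energy $E_0$ depositing $E_1$ on the recoil
electron and $E_2 = E_0 - E_1$ in the absorber,

$$\theta = \arccos\!\left(1 - m_ec^2\Big(\frac{1}{E_2} -
\frac{1}{E_0}\Big)\right),$$

with $m_ec^2 = 511$ keV.  `scatterAngleFromEnergies()` evaluates this;
`energiesFromAngle()` is its closed-form inverse, used by the
simulator.  Arguments of $\arccos$ that fall outside $[-1,1]$ by more
than a $10^{-9}$ round-off guard identify kinematically impossible
energy pairs and raise a dedicated condition class, so downstream code
can distinguish measurement noise from misuse.  Angles are radians
internally; degrees appear only in reports.

## The synthetic event generator

The generator emulates a specific acquisition: a 25 mm-radius,
5 mm-high air cylinder with six 2.5 mm-radius inserts of Au solution
(0.2–1.2 % w/v in 0.2 steps, on a 15 mm circle at 60° spacing — the
circle radius is our choice, since it is the natural one keeping the
inserts disjoint and centered) plus a central water control.  Two
Si(20×20×5 mm)/CdZnTe(50×50×5 mm) camera pairs sit at ±60 mm along x,
with a 20 mm scatter-to-absorber gap per side (we read the quoted
20 mm as the within-camera gap: the two cameras themselves must flank
the phantom at 60 mm).  The 81 keV excitation is bookkeeping only; the
transported photon is the Au Kα1 fluorescence line at 68.8 keV, a
configurable choice since the imaged line is not uniquely determined
by the K-edge.

Per emitted photon the generator:

1. samples the emission point uniformly inside an insert, with insert
   multiplicity proportional to concentration × volume (fluorescence
   yield is taken proportional to tracer mass);
2. directs it at a uniformly sampled point on one side's scatter-layer
   entry face (importance sampling of the acceptance solid angle, with
   the bookkeeping retained in the efficiency summary);
3. applies Beer–Lambert attenuation through the phantom (analytic
   chord lengths through each insert) as a rejection weight;
4. samples the interaction depth in Si from the exponential law, the
   scattering angle from the Klein–Nishina distribution at 68.8 keV
   (an isotropic and a fixed-angle law exist for analytic tests), and
   the azimuth uniformly;
5. propagates the scattered ray, requires it to hit the same side's
   absorber, samples the absorption depth exponentially;
6. blurs both deposited energies with Gaussian resolutions
   $\sigma/E$ of 5 % (scatter) and 2 % (absorber).

The per-layer blurs are our defaults: the spectral widths printed for
a full transport simulation are distribution widths, not intrinsic
detector resolutions, so they cannot be inverted into simulator
parameters; 5 %/2 % are typical of Si and CdZnTe at these energies.
The attenuation constants (`defaultMuTable()`: water 0.019/mm, Si
Compton component 0.04/mm, CdZnTe 2.5/mm, Au 0.002/mm per % w/v) are
order-of-magnitude working values at 68.8 keV, configurable and used
consistently everywhere; no energy interpolation is attempted.

One global RNG seeded from `rng_seed` drives the whole dataset with a
fixed draw order (side, face point, attenuation, depth, angle, azimuth,
absorber depth, blur), so a fixed seed gives a bit-identical event
stream.

What the generator deliberately does **not** model: Doppler
broadening, coherent scattering, multiple scattering chains, detector
pixelation, or the photoelectric channel in the scatterer.  Passing
tests therefore demonstrate correctness of the reconstruction chain
under idealized single-scatter physics, not fidelity to a full
transport code: quantities that depend on the neglected physics (such
as an absolute ARM width, which here reflects only the energy blur)
will differ from values measured on real or fully simulated systems.

## Effective-event screening

An effective Compton event scatters once in the scatter layer and is
fully absorbed in the absorber.  `filterEffective()` applies, in fixed
order: (i) containment of the scatter point in a scatter layer and the
absorption point in the same side's absorber; (ii) a minimum
scatter-to-absorption distance (default 1 mm — the mechanism is
standard, the value is ours and is configurable; it sits well below
the physical layer separation, so it removes only degenerate records);
(iii) a total-energy window of 68.8 ± 2 keV, the operational form of
"complete absorption".  The report counts each rejection against the
first failed rule, so the counts always sum to the input size.

## System matrix

Voxelization is axis-aligned with half-open voxels, linear index
$j = i_x + n_x(i_y + n_y i_z)$, default 50×50×5 mm at 1 mm.  Each
event's cone has apex at the scatter point, axis along
scatter-minus-absorption, and half-angle from the kinematics.  The
element $a_{ij}$ combines three factors:

* **cone membership** — the integral of the cone probability over the
  voxel is approximated at the voxel center with a Gaussian angular
  kernel $\exp(-\Delta^2/2\sigma_{\text{cone}}^2)$, $\Delta$ the
  angular distance from the cone surface, $\sigma_{\text{cone}}$ = 2°
  by default (no cone-thickness model is prescribed by the method;
  this is the standard differentiable discretization);
* **interaction** — the deposition fraction $1-e^{-\mu_j \ell_j}$
  along the voxel chord toward the apex; for $\mu_j = 0$ it degrades
  to the geometric weight $\ell_j/\bar h$.  A configuration switch
  selects the raw $\mu_j \ell_j$ weight instead, since the printed
  formulas admit both readings;
* **attenuation survival** — $\prod_k e^{-\mu_k d_{ik}}$ along the
  voxel-center→apex path through the phantom attenuation map, with
  chords from an Amanatides–Woo traversal.

Entries below $10^{-6}$ of the row maximum are dropped.  The assembly
kernel is compiled (Rcpp); a pruning bound derived from the global
deposition/survival extremes skips voxels that provably cannot pass
the floor, so the sparse result carries exactly the voxel support of a
brute-force per-voxel evaluation, with weights agreeing to better than
one part in 10^12 (this is tested).  Rows are assembled in blocks
directly into compressed-sparse-row storage; at the default study size
(~2×10⁴ events, 12 500 voxels) the matrix holds ~1.5×10⁸ entries
(~1.8 GB), which is why the matrix–vector products also run through
compiled CSR kernels.

## 2D reconstruction

The list-mode MLEM update with unit observation weight per event is

$$f_j^{(n+1)} = \frac{f_j^{(n)}}{s_j} \sum_i
\frac{a_{ij}}{\sum_k a_{ik} f_k^{(n)}},\qquad s_j = \sum_i a_{ij},$$

initialized to 1 on all voxels with positive sensitivity.  The
column-sum sensitivity is the convention the fused iteration's
denominator implies; `mlemStep()` accepts any sensitivity vector for
the generic form.  After each EM step (from the second iteration on),
a Split-Bregman TV correction is added:

$$f^{(n+1)} = f^{(n+1,\text{EM})} +
\frac{\lambda_{TV}}{\beta}\,\mathrm{div}(d),$$

where the dual fields $d$ and residuals $b$ follow one inner Bregman
update per outer iteration.  Two dual updates are available:
`as_written`, which normalizes $\nabla f + b$ by its global
per-direction L2 norm (the printed form of the scheme), and
`shrinkage`, the conventional componentwise soft threshold at
$1/\beta$.  The default is `as_written` for fidelity; the fused
iteration as printed reuses the EM intermediate multiplicatively,
which is redundant, so the additive form above is what is computed.
Gradients are forward differences with zero boundary components; the
divergence is the exact negative adjoint (backward differences), so
discrete integration by parts holds to round-off (tested).  Negative
intensities after the correction are clipped — intensities are photon
source densities.  With $\lambda_{TV} = 0$ the trajectory is
bit-identical to plain MLEM.

Every iterate is kept, with per-iteration TV and list-mode
log-likelihood logged.

## 3D post-processing

The selected iterate is rescaled to unit maximum first: MLEM fixes
only relative intensities, and the thresholds below are meaningful on
a normalized scale.

**Anisotropic TV diffusion.** The edge-preserving flow
$\partial f/\partial t = \lambda\,\nabla\!\cdot(\nabla f/(|\nabla f| +
\varepsilon))$ is integrated explicitly with per-axis face
conductances $1/(|\nabla f|+\varepsilon)$: smooth regions diffuse,
edges persist.  Each face weight is limited at $1/(2\cdot 3)$ so that
every step is a convex average of neighbors — the scheme then
conserves the mean exactly (flux form), never increases the variance,
and obeys the discrete maximum principle for any
$\varepsilon > 0$, including the small default $\varepsilon=10^{-6}$
for which the unlimited explicit scheme would be unstable in flat
regions.  The limiter only engages where the gradient (and hence the
flux) is already negligible, so it does not alter the visible
smoothing.  Step sizes for which even the limited scheme would break
monotonicity ($\Delta t\,\lambda\cdot 2\sum_k h_k^{-2} > 1$) raise an
error stating the bound.  Defaults: $\lambda = 0.01$, $\Delta t =
0.1$, 10 steps.

**Wavelet sparsity.** Per z-slice (the constraint is formulated on 2D
slices), a separable orthonormal DWT (Haar default; `db2`, `db4`
selectable — the family is otherwise unconstrained and Haar admits
exact small-case oracles) with periodic extension and edge padding for
non-dyadic sizes; soft thresholding ($T = 0.01$ on the normalized
scale) of the detail subbands at all levels, approximation untouched
— noise is modelled as high-frequency; inverse transform.  $T = 0$
reproduces the input to round-off, and energy is preserved at
$T = 0$ for the orthonormal families (both tested).

**Isosurface.** Marching tetrahedra over the voxel-center lattice at a
level specified as a fraction of the volume maximum (default 0.001, as
an absolute level would be meaningless after MLEM), shared interpolated
edge vertices, outward normals from the interpolated gradient, ASCII
PLY/OBJ export.  Note that at this package's event statistics
(~2×10⁴ events) the MLEM background floor after 10–15 iterations is
above 0.001 of the maximum, so the default level set is often empty;
useful surfaces appear either at more iterations or at levels around
0.1–0.5.  Rendering is limited to normals plus a static shaded slice
export; the scientific output is the mesh.

## Metrics

* $\theta_i$ — energy-derived scattering angle (same kinematics code
  as the projector, cross-checked); invalid pairs are excluded and
  counted.
* $\theta_c$ — geometry-derived angle between source→scatter and
  scatter→absorption.
* ARM $= \theta_i - \theta_c$ per event; its distribution's FWHM is
  estimated from a histogram (Freedman–Diaconis bin width floored at
  0.1°, peak bin, half-maximum crossings by linear interpolation) with
  a Gaussian-moment estimate reported alongside and a multimodality
  flag for secondary peaks above half maximum.
* Energy resolution $R = \sigma_E/\mu_E \times 100\%$ with the
  $n-1$ standard deviation over whatever sample the caller windows.
* CNR $= (\mu_{ROI}-\mu_{bg})/\sigma_{bg}$ and SNR $=
  \mu_{ROI}/\sigma_{bg}$ on ROI disks placed at the known insert
  centers (ground truth is available for synthetic data), background =
  slice minus ROIs dilated by a 1-voxel margin; the conventional
  CNR ≥ 4 detectability threshold is reported as a flag only.

## Problem sizes and what the tests show

The package's study condition is the default configuration:
5×10⁵ emitted photons → ≈2×10⁴ screened events, 50×50×5 grid at 1 mm,
10 fused iterations (the iteration at which CNR/SNR peak on this
phantom), post-processing at the defaults above.  At that size the
end-to-end checks recover every insert centroid to well under 2 mm,
rank the six concentrations with Spearman ρ ≥ 0.8, and detect the
0.2 % insert with positive CNR.  Unit and property tests run at much
smaller sizes (3–12 500 voxels, 10²–10⁵ events) chosen so each
mathematical property is exercised without redundancy.

## Known limitations

* Single-scatter, line-emission physics; no Doppler broadening, so
  absolute angular-resolution numbers are optimistic.
* The attenuation constants are scalar per material at one energy.
* The `as_written` dual update is a normalization rather than a
  proximal step; it reproduces the printed scheme but has no
  convergence guarantee, and because the normalized correction does not
  scale with the image (whose magnitude falls as the voxel count
  grows), its TV-reducing effect is reliable at the coarse-grid
  operating point (2 mm in-plane) but can invert on finer grids — the
  `shrinkage` mode is the numerically conventional alternative.
* Wavelet processing is slice-wise, not volumetric.
* The isosurface default level suits strongly converged, low-noise
  volumes; see above.
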