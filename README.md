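# ccxfct

Simulation and image reconstruction for X-ray fluorescence computed
tomography (XFCT) with **bilateral Compton cameras**, for researchers in
radiological imaging and detector physics who want a self-contained,
reproducible implementation of the full list-mode reconstruction chain.

Conventional XFCT collimates mechanically and discards most of the
fluorescence signal. A Compton camera replaces the collimator with
*electronic collimation*: a photon that Compton-scatters in a Si layer
(depositing `E1` at position `r_s`) and is then absorbed in a CdZnTe
layer (depositing `E2` at `r_a`) is constrained to a cone with apex
`r_s`, axis `r_s − r_a`, and half-angle

    θ = arccos(1 − m_e c² (1/E₂ − 1/E₀)),   E₀ = E₁ + E₂.

From ~10⁴ such cones, a list-mode MLEM iteration

    f_j^(n+1) = (f_j^(n) / s_j) Σ_i a_ij / Σ_k a_ik f_k^(n)

with a Split-Bregman total-variation correction
`f ← f_EM + (λ_TV/β)·div(d)` recovers the tracer distribution; the
system matrix `a_ij` combines Gaussian cone membership, the deposition
fraction `1 − exp(−μ_j ℓ_j)`, and Beer–Lambert survival
`Π_k exp(−μ_k d_ik)` along the voxel-to-apex path. 3D post-processing
adds anisotropic TV diffusion, slice-wise wavelet soft thresholding,
and marching-tetrahedra isosurface extraction; evaluation covers the
angular resolution measure (ARM = θ_energy − θ_geometry) with its FWHM,
energy resolution σ_E/μ_E, and per-ROI CNR/SNR.

The package ships a seeded Monte Carlo generator for the standard test
object — a 25 mm cylinder with six 2.5 mm Au-nanoparticle inserts at
0.2–1.2 % w/v plus a water control, flanked by two Si/CdZnTe camera
pairs — so every result is reproducible from a single seed.

## Worked example

```r
library(ccxfct)

phantom  <- buildPhantom()           # six Au inserts + water control
geometry <- detectorGeometry()       # bilateral Si/CdZnTe pairs
events   <- simulateDataset(phantom, geometry,
                            simulationConfig(nEmissions = 5000, seed = 1))
eventMetadata(events)$efficiency
#> $etaS      0.1702355     # P(Compton scatter | reached scatterer)
#> $etaA      0.2553459     # P(absorbed | scattered)
#> $eta       0.04346895    # overall detection efficiency
kept <- filterEffective(events)      # effective-Compton-event screen
kept$report
#>  input  kept  rejectedContainment  rejectedDistance  rejectedEnergy
#>    203   169                    0                 0              34
```

203 of 5000 emitted fluorescence photons become effective Compton
events; the total-energy window (68.8 ± 2 keV) removes 34 whose blurred
deposits are inconsistent with complete absorption. At study scale
(`nEmissions = 5e5`, ≈2×10⁴ kept events) the reconstruction

```r
grid <- makeGrid(c(50, 50, 5), 1)                 # 1 mm voxels
rec  <- reconstruct2d(kept$events, grid, muMap(phantom, grid),
                      recon2dConfig(nIter = 10, lambdaTV = 0.01))
cnrSnr(intensities(rec$volumes[[10]])[, , 3], grid, phantomROIs(phantom))
```

localizes all six insert centroids to well under 2 mm, ranks the
concentrations correctly (Spearman ρ ≈ 0.83 at seed 11), and gives the
0.2 % insert positive CNR. `reconstruct3d()` and `runPipeline()` take it
through to meshes, slice renders and metric tables; a thin CLI wrapper
lives at `inst/scripts/ccxfct`.

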