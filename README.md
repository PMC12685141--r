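# nanodimer

Quantitative metrology and simulation for gold-nanoparticle (AuNP)
fiducial labels in cryo-electron tomography, focused on the
discrimination of monomeric labels from covalently bridged dimers
("dumbbells"). The package is aimed at structural biologists and
image-analysis developers who need a transparent, fully testable
counterpart to the measurements that characterize such labels: no
external data are required — every analysis can be exercised end to end
on synthetic scenes with known ground truth.

## What it computes

**Class-average metrology.** Monomer size is measured from the radial
intensity profile of recentered 2D class averages: with the profile
normalized to its maximum, the cutoff radius at intensity fraction *f*
is the outermost crossing r_f, and the operational diameter is 2 r_f.
For a noiseless projected sphere of radius R the chord-length profile
P(r) = sqrt(1 − (r/R)²) gives r_f = R sqrt(1 − f²) exactly, which the
tests verify to half a pixel. Dimer separations are measured per class
by iterative two-lobe centroid splitting; the intensity sampled along
the intercentroid axis must show two maxima with a central dip for the
class to be accepted, and the per-class separations (weighted by
particle counts) are aggregated into 2 Å bins spanning 26–46 Å.

**SAXS models and PDDF inversion.** Scattering from a homogeneous
sphere is I(q) = (Δρ V)² Φ²(qR) with Φ(x) = 3(sin x − x cos x)/x³; an
orientation-averaged two-sphere dimer at center separation d scatters
as I_dimer(q) = 2 I_sphere(q) [1 + sin(qd)/(qd)]. The pair distance
distribution p(r) is recovered by a sine-series indirect transform
(p(r) = Σ aₙ sin(nπr/D_max) fit to I(q) through the Debye kernel, with
a curvature penalty set by the discrepancy principle), scanning D_max;
R_g² = ∫p r² dr / (2∫p dr) and I₀ = 4π∫p dr follow from the fit.

**Geometry.** Sphere-volume footprints (V = 4/3 π r³), the dimer
surface gap (gap = d − D) and end-to-end extent (d + D), the
torsion-dependent S–S span of a biphenyl dithiol linker, bridging
feasibility of n linkers in series, and a 1-D normal-to-membrane reach
model calibrated to a 110–190 Å label-height interval.

**Tomogram discrimination.** A classical, fully inspectable pipeline:
band-passed blob detection with subvoxel refinement, mutual-nearest
pairing within the measured separation window, dumbbell validation
along the intercentroid axis, and an evaluation harness (accuracy,
per-class precision/recall, nearest-neighbor confusion sweeps) against
generated ground truth — including Fourier missing-wedge degradation
for realistic tilt ranges.

**Membrane distances.** Exact point-to-plane and point-to-triangle-mesh
shortest distances, label-to-membrane distance statistics with
fraction-in-reach, cleft-width sampling between membrane pairs, and a
Welch comparison between labeled/unlabeled conditions.

## Worked example

```r
library(nanodimer)

## dimer geometry: 40 A separation, 26.4 A monomer diameter
g <- dimer_geometry(separation = 40, monomer_diameter = 26.4)
interparticle_gap(g)                                   # 13.6
g$end_to_end                                           # 66.4
bridge_feasible(13.6, linker_model(n_linkers = 2))$feasible  # TRUE

## invert a simulated dimer scattering profile
prof <- dimer_intensity(dimer_model(sphere_model(12.5), 40),
                        seq(0.01, 0.5, by = 0.002))
pddf_moore(prof, dmax_scan = seq(40, 100, by = 1))
#> PDDF (indirect sine-series transform)
#>   D_max    : 63.1 A
#>   R_g      : 22.22 A
#>   I_0      : 2.677e+08
#>   terms    : 12, residual 8.76e-07

## classify a synthetic tomogram (10 A voxels, -48..+48 deg wedge)
spec <- scene_spec(pixel_size = 10, shape = c(96L, 96L, 96L),
                   n_particles = 75L, monomer_fraction = 50/75,
                   dimer_fraction = 25/75, dimer_separation_mean = 40,
                   dimer_separation_sd = 0, snr = 5, seed = 1,
                   min_center_distance = 60, tilt_range = c(-48, 48))
vol <- generate_tomogram(spec)
evaluate_classification(vol$truth, classify_volume(vol))
#> Classification accuracy: 0.947 (75 truth, 75 predicted, tol 20 A)
#>   monomer  precision 0.931  recall 0.982
#>   dimer    precision 1.000  recall 0.850
```

The gap of 13.6 Å is what the dithiol linkers must bridge: a single
linker spans at most 10.6 Å, so two in series are required. The R_g of
22.2 Å matches the parallel-axis value sqrt(R_g,sphere² + (d/2)²) for
the generating model, and the recovered p(r) shows the two-peak dimer
signature. The fitted D_max of ~63 Å sits slightly below the geometric
2R + d = 65 Å of the generating model; the methods vignette analyzes
why the support endpoint of a pair distribution is soft at this q
range. Accuracy on single volumes fluctuates around 0.95–0.99; dimers
whose axis points along z are the hard class under the missing wedge.

A thin command-line wrapper is provided in
`inst/scripts/nanodimer.R` (subcommands `simulate`, `profile`,
`separation`, `saxs`, `geometry`, `classify`, `sweep`, `distances`).

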