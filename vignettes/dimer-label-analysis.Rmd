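---
title: "Models and methods behind nanodimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanodimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodimer)
```

# The problem

Small gold nanoparticles (~2.6 nm core) are the workhorse fiducial
labels of cryo-electron tomography, but a single size class carries one
bit of information. Covalently bridging two such particles with
dithiol linkers produces a dimeric label whose fixed interparticle
spacing gives it a recognizable "dumbbell" signature, enabling
multiplexed labeling in crowded compartments such as the ~28 nm
synaptic cleft — if, and only if, monomers and dimers can be measured
and told apart reliably. `nanodimer` implements that measurement chain
as transparent, testable code: the solution-scattering and
class-average metrology that establishes the dimer geometry, the
geometric feasibility arguments for the linker, the monomer/dimer
discrimination task in missing-wedge-degraded volumes, and the
label-to-membrane statistics used to argue that labels sit where their
target receptor sits. Everything runs on synthetic scenes with exact
ground truth, so each stage is a parameter-recovery experiment rather
than a re-measurement of archived data.

# Synthetic scenes

## Density model

Particles are homogeneous balls of radius R (default 13.2 Å, the 20%
intensity-cutoff radius adopted as the monomer radius). In projection a
ball contributes the chord length 2·sqrt(R² − ρ²) at in-plane distance
ρ; in volumes it is drawn as a soft-edged indicator (the voxel value
ramps linearly across one voxel at the surface) so that total density
matches the analytic ball volume to better than 1%. No atomic gold
lattice and no contrast transfer function are simulated: the analyses
this package implements all operate on reconstructed or class-averaged
densities, where those factors are already folded into an effective
point-spread that the missing-wedge model captures at the relevant
scale.

## Noise and the SNR convention

Noise is additive Gaussian, applied after rendering. SNR is defined as
peak noiseless particle intensity divided by the noise standard
deviation — a deliberately simple, controllable convention matching the
thin-ice, high-contrast imaging regime the discrimination task assumes.
A class average of n aligned images is generated as the noiseless
render plus one Gaussian field scaled by 1/sqrt(n); this is identical
in distribution to averaging n independent noisy copies (alignment is
taken from truth — reference-free classification is out of scope).

What the generator does *not* emulate: structured background (ice
gradients, neighboring macromolecules), alignment and classification
errors, per-tilt dose and drift, CTF ringing, and reconstruction
artifacts other than the missing wedge. Passing tests therefore
demonstrate correctness of the measurement chain under its stated
model, not performance on arbitrary real micrographs.

## Dimer geometry and placement

Dimer separations are drawn from a normal distribution (mean 34.8 Å,
SD 3.6 Å) truncated to the 26–46 Å support of the measured separation
histogram; orientations are uniform on the sphere (normalized Gaussian
triples). Placement uses rejection sampling against a minimum
center-to-center distance with a 1000-retry cap per particle; failure
raises an error reporting the achieved count. Membrane pairs are two
50 Å-thick slabs perpendicular to z with mid-planes one cleft width
(default 280 Å) apart. All coordinates are in Å with
coordinate = (index − 1) × pixel size.

## Missing wedge

A tilt series about the y axis with range [α₁, α₂] samples, in the
(k_x, k_z) plane, only the directions whose angle (folded to
(−90°, 90°]) lies in the range; `apply_missing_wedge()` zeroes all
other Fourier coefficients. The mask depends only on (k_x, k_z), is
Hermitian-symmetric by construction, and the output is real. The
default ranges mirror the two acquisition geometries of interest,
−48°…+48° (in-water) and −68°…+28° (tissue lamella).

# Class-average metrology

`recenter()` subtracts the median of a 2-pixel border frame, floors
negatives at zero, and iterates subpixel Fourier shifts until the
intensity centroid sits on the geometric center within 0.01 px. Images
whose maximum does not rise above five times the border MAD have no
reliable centroid and raise an error.

`radial_profile()` averages one-pixel-wide annuli, weights classes by
their particle counts, and normalizes to a maximum of one
(max-normalization is a convention choice; the profile is reported as
measured, with no monotonicity imposed). `cutoff_radii()` takes, for
each fraction f, the *outermost* descending crossing with linear
interpolation between annuli — robust to small central dips from noise.
For a projected sphere the crossing obeys r_f = R·sqrt(1 − f²); note
that a hard-edged binary disc aliases its edge across one annulus, so
only the half-intensity crossing of a step profile is sharp to half a
pixel.

`split_centroids()` seeds the two-lobe split from the principal axis of
the second-moment tensor, then alternates side-assignment and centroid
updates (re-splitting at the current centroid midpoint) until both
centroids move < 0.01 px, up to 50 iterations. A class is accepted only
if the intensity along the intercentroid axis (bilinear sampling, 1 Å
steps, ±50 Å about the midpoint) shows two maxima with a central dip of
at least 10% of the weaker lobe peak — an explicit number standing in
for "clearly separated" classes. Because flooring rectified noise
leaves a small uniform pedestal that biases lobe centroids outward, the
moment computations additionally zero pixels below three border-MADs;
this removed a ~0.6 Å outward bias at SNR 3 without affecting noiseless
oracles.

`aggregate_separations()` bins per-class separations into 2 Å bins on
[26, 46), assigns each class's full particle count to its bin, and
reports particle-weighted mean and SD. The `representative` value is a
*configuration*, defaulting to the weighted mean but overridable —
mirroring the judgment call of adopting a round working value (40 Å)
when counts fall off sharply above it; the package deliberately does
not equate the two.

# SAXS forward models and the PDDF

The sphere form factor, its core–shell extension, and the
orientation-averaged two-sphere interference model are standard closed
forms (see the README). `pddf_direct()` provides the brute-force
oracle: ≥10⁵–10⁶ uniformly sampled point pairs histogrammed onto the r
grid, with the closed-form ball pair-distance density available for
cross-checks.

`pddf_moore()` expands p(r) in a sine series on [0, D_max] (which pins
p(0) = p(D_max) = 0 exactly) and fits the coefficients to I(q) by
weighted least squares through the Debye kernel, evaluated by
trapezoidal quadrature on 1024 intervals (equivalent to the closed-form
transform at double precision, with simpler handling of the q·r → 0
limit). The series order is fixed at 12 by default across the D_max
scan; systems that are ill-conditioned at small D receive the smallest
curvature ridge that stabilizes them. On top of that, the curvature
penalty (diagonal in the sine basis, ∝ (nπ/D)⁴) is raised by the
discrepancy principle to the largest value costing at most 1% extra
misfit — suppressing ringing without biasing the fit.

## Selecting D_max, and why the endpoint is soft

Admissible D_max candidates must satisfy near-nonnegativity
(min p ≥ −1% of max p). Without uncertainties the admissible candidate
with the smallest residual wins, followed by parabolic sub-grid
refinement of the log-residual so the estimate is not quantized to the
scan step. With per-point uncertainties the misfit bottoms out at the
noise floor (reduced χ² ≈ 1) and every candidate on the floor is
statistically equivalent; the center of the contiguous floor run is
reported.

The support endpoint of a pair distribution is intrinsically soft:
distances near D_max carry vanishing pair mass (for two 12.5 Å-radius
spheres 40 Å apart, less than 10⁻⁴ of all pairs lie beyond 63 Å), and a
profile measured to q_max = 0.5 Å⁻¹ has ~6 Å endpoint resolution. On
such data *any* faithful inversion — including a fully
nonnegativity-constrained one — fits to machine precision already at a
support of ~63 Å, so the scan reads D_max ≈ 63 Å for a model whose
geometric extent is 65 Å. This ~3% shortfall is a property of the
estimation problem, not of the implementation; by-eye reads of smooth
p(r) tails on experimental data tend to land on the generous side of
it. The tests pin the estimate to the 65 Å scale at 3% tolerance and
verify the parallel-axis law R_g,dimer² = R_g,sphere² + (d/2)² at 2%.

`guinier_fit()` is the usual ln I vs q² regression with a post-hoc
q·R_g ≤ 1.3 validity warning.

# Linker and reach geometry

The linker span interpolates its two experimentally constrained torsion
endpoints (10.6 Å at φ = 0°, 7.5 Å at φ = 90°) as
L(φ) = sqrt(L₉₀² + (L₀² − L₉₀²) cos²φ) — any smooth monotone
interpolant through the endpoints is admissible; this form is isolated
behind `linker_span()` so it can be swapped. Bridging treats n linkers
as rigid segments with freely rotating joints: reachable span
[0 (n ≥ 2) or L₉₀ (n = 1), n·L₀].

The reach model is one-dimensional along the membrane normal:
min = epitope height + minimum Fab reach − label offset,
max = epitope height + maximum Fab reach + label offset, clamped at
zero. The shipping defaults (135, −10, 40, 15 Å) are explicitly
calibrations chosen to reproduce the 110–190 Å working interval — the
underlying structural modeling (receptor plus Fab) is not reproduced
here, so these numbers should be treated as a parameterization of that
result, not as independent measurements.

# Volume discrimination

Detection computes a Laplacian-of-Gaussian band-pass in Fourier space
at scale σ (default: lobe radius/√3, floored at one voxel — the
canonical LoG scale for a blob of that radius), takes strict 26-
neighborhood maxima above both a relative threshold (0.3 × maximum
response) and an absolute noise floor (6 × response MAD, so pure-noise
volumes yield zero picks), refines to subvoxel precision by center of
mass over 3³ voxels, and merges maxima closer than σ. Pairing accepts
candidate pairs inside the separation window (default [26, 46] Å)
greedily by increasing distance with lexicographic tie-breaks; each
pick joins at most one pair, and the procedure is deterministic.

Two classifier gates are wedge-aware, and both matter for the hard
class (dimers whose axis points near z):

* the missing wedge stretches apparent z separations, so the window's
  upper edge is inflated by 5% when a wedge has been applied;
* the wedge transfers density into the interparticle gap, collapsing
  the central dip of z-oriented dimers nearly to zero — the dumbbell
  validation gate is therefore 0.02 under a wedge versus 0.1 in fully
  sampled volumes. The dumbbell score still orders orientations
  (in-plane dimers score higher than z-oriented ones), which the tests
  assert.

Axis-profile sampling for validation uses a lightly smoothed copy of
the volume (σ = half a voxel); heavier smoothing erases the ~14 Å gap.
Evaluation matches predictions to truth greedily by distance within a
20 Å tolerance (two voxels); accuracy is correct-class matches over all
truth. Under the benchmark conditions (10 Å voxels, −48°…+48° wedge,
40 Å dimers, monomer nearest neighbors ≥ 60 Å, SNR 5) the pipeline
averages ≥ 95% accuracy; the residual errors are almost exclusively
z-oriented dimers, the same orientation class that limited sampling
makes "less well defined" in real tomograms. The nearest-neighbor
confusion sweep shows accuracy is stable down to ~60 Å spacing and
collapses once monomer pairs enter the pairing window (40–45 Å), where
a geometric classifier *cannot* distinguish a monomer pair from a true
dimer — the ~4.5 nm crowding limit, reproduced rather than assumed.

The classifier replaces a trained neural picker deliberately: the
scientific content of the task is its feasibility and its geometric
failure modes, and a transparent pipeline makes both reproducible
without training data.

# Membrane statistics

Shortest distances use exact point-to-plane projections and exact
point-to-triangle distances (region-decomposition algorithm) for
meshes; membranes enter as already-segmented geometry. Distances are
measured from the dimer midpoint by default. Cleft widths sample a grid
(default 10 Å spacing) on the postsynaptic membrane and take shortest
distances to the presynaptic one — exact for parallel planes; for
tilted membranes the shortest-distance convention keeps the mean at the
perpendicular separation while spreading the widths (a normal-ray
convention would instead inflate the mean by the secant of the tilt;
the shortest-distance definition is used consistently).
`compare_conditions()` is a Welch test reported with effect size, never
thresholded internally; its type-I error calibrates to ~5% over 1000
null replicates in the tests. The distance-recovery experiments use the
in-situ sample size (n = 93) with generating law N(156 Å, 28² Å²), and
the fraction inside the 110–190 Å reach interval is checked against the
normal-probability oracle.

# Problem sizes and runtimes

Test and acceptance workloads are sized for a desk machine: 96³-voxel
volumes with 75 particles for the discrimination benchmark (three
seeds), 80³ volumes for the confusion sweep (3 replicates per spacing),
20 classes × 1000 particles for separation recovery, 5 × 10⁵
Monte-Carlo pairs for PDDF oracles, and 1000 replicates for the
type-I-error calibration. The full suite runs in well under a minute on
one CPU.

# Known limitations

* The D_max estimator inherits the endpoint softness discussed above;
  on band-limited data it reads a few percent low for particles with
  gently tapering pair distributions.
* The discrimination pipeline is tuned for the high-SNR, sparse regime
  it is benchmarked in; tissue-like low-SNR scenes will need lower
  thresholds and will show the same z-orientation failure mode more
  strongly.
* Class-average metrology assumes perfect alignment and centering from
  the generator; real 2D classification introduces class impurity that
  is not modeled.
* The reach model is a calibrated 1-D stand-in for full structural
  modeling of the receptor–Fab–label assembly.
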