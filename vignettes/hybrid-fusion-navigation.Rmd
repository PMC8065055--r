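---
title: "Tracker-based MR/US fusion: models, calibrations and error propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracker-based MR/US fusion: models, calibrations and error propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackfuse)
```

## The problem

Fusing a pre-procedure volumetric modality (MR) with intra-procedure
ultrasound normally requires an inter-modal image registration, which is
fragile for MR/TRUS because ultrasound has poor signal-to-noise, few
well-defined features, and a very different intensity statistics from MR.
`trackfuse` implements the alternative: replace the inter-modal
registration entirely with a chain of *tracked-device calibrations* plus a
single *intra-modal* US/US affine registration. An optical tracking
system (OTS) observes marker tools on the US probe, the MR table and
gantry; point-based calibrations tie each image coordinate system to its
tool; and homogeneous transform composition carries points from the
intra-procedure TRUS frame all the way into MR millimetre coordinates:

\[
P_{MR} = T_{US}^{MR} \cdot T_{TRUS}^{US} \cdot P_{TRUS}, \qquad
T_{US}^{MR} = T_{ORF}^{MR} \cdot T_{trans}^{ORF} \cdot T_{US}^{trans},
\]

where `trans` is the probe tool frame and `ORF` an optical reference
frame on the table or gantry. When the table moves between the MR scan
and the US acquisition, the tracked rigid shift of the table tool is
spliced into the chain
(`T_ORF_TABLE^MR^{-1} . T_ORF_moved^ORF_TABLE . T_trans^ORF_moved . T_US^trans`).

Because no physical tracker or scanner is available to an R session, the
package carries a first-class synthetic-data layer that emulates every
physical object of the study — multi-cone calibration phantoms, a
tissue-equivalent prostate phantom, tracker jitter — with exact ground
truth, so every calibration and the full chain can be verified by
recovery tests.

## Transform algebra and conventions

All coordinates are millimetres in right-handed frames; the internal
anatomical convention is LPS, with RAS-coded files (NIfTI affines, Slicer
FCSV) converted at I/O. Points are column vectors and transforms act by
left-multiplication, so `compose(a, b)` applies `b` first; every
composition checks that frames chain head-to-tail and refuses to multiply
otherwise — in a system whose whole output is a product of eight
matrices, silent frame mix-ups are the dominant failure mode. Rotation
blocks are validated to be orthonormal with determinant +1 within 1e-9;
drift below 1e-6 (e.g. from quaternion round trips) is repaired by polar
decomposition, larger drift is an error. Quaternions appear only at I/O
(scalar-last, as in the pose CSV dialect) and are rejected when their
norm deviates from 1 by more than 1e-6.

## Point-based registration and its statistics

Every calibration reduces to paired-point rigid registration
(`register_points()`): the closed-form SVD solution with a
determinant-sign guard, which also handles coplanar configurations such
as the in-plane TRUS pointer sweep without ever returning a reflection.
Correspondence is by label — the physical workflow identifies each cone
tip manually, so no automatic matching (ICP) is implemented.

The error statistics follow the standard fiducial framework: FRE is the
RMS residual over the fiducials used for the fit, TRE the distance error
at held-out targets. Under isotropic fiducial localization error the
classic expectation `E[FRE^2] = (1 - 2/N) FLE^2` holds and is used as a
test oracle (at N = 7, 10^4 Monte-Carlo replicates reproduce it within a
few percent). One convention caveat is worth stating explicitly because
the two families of noise parameters differ: *tracker and stylus jitter*
sigmas in this package are per-axis SDs (so the RMS 3D jitter magnitude
is `sigma * sqrt(3)`), while *FLE* in the Fitzpatrick identity is the 3D
RMS magnitude. Tests that exercise the identity therefore set the
per-axis SD to `FLE / sqrt(3)`.

`average_repeats()` collapses repeated stylus readings per tip. Readings
farther from the per-label median point than the median distance plus 5
scaled MADs are discarded before averaging. The cut is deliberately
conservative: with only 5-10 readings per tip the MAD estimate is noisy,
and a tighter cut (3 MADs) measurably trims clean Gaussian readings and
biases the reported jitter estimate low by several percent, while gross
stylus slips sit far outside either threshold. `refine_fiducials_via_cad()`
implements the CAD-based phantom refinement: registering the noiseless
CAD tip coordinates onto the stylus measurements and replacing the
measurements by the mapped CAD points reduces the per-tip noise to the
much smaller rigid-fit error (verified as a variance-reduction
Monte-Carlo).

## Device calibrations

* **Pivot calibration** (`calibrate_pivot()`): algebraic least squares
  for the stylus tip and pivot point simultaneously; a pose stream whose
  orientations span too little solid angle is rejected by a condition
  check rather than silently returning a sliding solution.
* **3D US probe** (`calibrate_us_probe()`): for each image of the
  cone-tank phantom, tank tips are mapped into the probe-tool frame via
  `invert(pose_probe) . pose_tank`; pairs are *pooled* across images and
  one registration is solved. Pooling is the lower-variance estimator
  compared with averaging per-image transforms (whether the original
  physical workflow pooled or averaged is not recorded; pooling is this
  package's choice).
* **TRUS probe** (`calibrate_trus_probe()`): pixel coordinates are
  lifted to image millimetres in the z = 0 plane with 0-based indices at
  pixel centres, and the coplanar-tolerant registration produces the
  image-to-tool transform.
* **MR calibration** (`calibrate_mr()`): 18 cone tips measured with a
  repeated stylus relative to the table (or gantry) reference tool,
  registered onto their MR image coordinates. Averaging the repeats
  demonstrably lowers the calibration FRE.
* **Table shift** (`track_table_shift()`): epoch-averaged poses before
  and after the move; translation averages arithmetically, rotation by
  the chordal mean (projection of the averaged matrix onto SO(3)),
  adequate for sub-degree jitter.

### The table-shift world model

The simulated world fixes a subtlety in the shift-compensated chain: the
MR image frame is anchored to the table reference tool *at the MR-scan
epoch*. The imaged object stays put in the tracker frame while the table
tool moves away from it; the tracked shift `T_ORF_moved^ORF_TABLE`
restores the scan-epoch anchor from post-shift readings (e.g. after line
of sight to the old position is lost). Under this model the gantry-path
and table-path chains are algebraically identical, an identity shift
reduces the compensated chain bit-for-bit to the plain chain, and the
zero-noise simulation closes to numerical precision — all three are
asserted in the test suite.

## Intra-modal affine registration

`register_affine()` maximizes a Mattes-style mutual information metric
over a 12-parameter affine (translation, Euler rotations, log-scales,
shears) centred at the fixed-mask centroid. Choices that the upstream
workflow delegated to 3D Slicer's defaults are made explicit here:

* 32 histogram bins per image over the robust 0.5th-99.5th percentile
  intensity range, with partial-volume (bilinear Parzen) weighting;
* three resolution levels (downsample x4 / x2 / x1, Gaussian smoothing
  matched to the factor); at full resolution a mild 0.75-voxel smoothing
  remains, which suppresses speckle noise in the metric without moving
  structure boundaries — on the synthetic speckled pairs this measurably
  improves sub-voxel convergence;
* derivative-free Nelder-Mead at each level with one restart (a fresh
  simplex from the first optimum), which recovers the well-known
  premature-collapse failure of NM in 12 dimensions;
* all in-mask voxels are sampled at the coarse levels and a seeded
  random 25% sample at full resolution, making the result deterministic
  given the seed and inputs;
* the returned transform is guaranteed not to be worse than the
  initialization: MI at both is evaluated on the full in-mask sample and
  the better one is returned.

The registration is validated on rendered prostate-phantom pairs with
independent speckle realizations differing by up to 10 degrees of
rotation, 5 mm of translation and 3% anisotropic scale; on a 20-seed
grid at 1.5 mm voxels, at least 18 cases recover the motion to a mean
lesion-centroid error below 1 mm (typically ~0.5 mm).

## Evaluation metrics

Dice, exact Hausdorff distance and symmetrized mean boundary distance
operate on binary masks sharing a voxel grid (nearest-neighbour
resampling is applied first when grids differ, and recorded). Surfaces
are face-connected boundary voxels and distances are between voxel
centres in millimetres — reproducible without mesh extraction, at the
cost of a grid-resolution bias that the sphere-oracle tests quantify
(Dice of equal 5 mm spheres offset 2 mm matches the analytic lens-volume
value 0.704 within 0.005 on a 0.2 mm grid). The mean boundary distance
is symmetrized (directed values are also reported, since the upstream
definition does not say which variant was printed). PSNR is
`10 log10(peak^2 / MSE)`; identical inputs return `Inf` with an explicit
flag.

## The synthetic-data layer

`make_multicone()` produces the 7- and 18-cone tip layouts
(deterministic grid placement, golden-ratio height spread over 15-40 mm
so the sets are far from coplanar); the real phantom's exact cone
geometry is only depicted in a CAD render, so the layout is
representative, not a reconstruction. `phantom_spec()` /
`render_phantom()` rasterize the prostate phantom — gland ellipsoid with
semi-axes (20, 22.5, 20) mm matching the 4 x 4.5 x 4 cm gland, three
5 mm-radius spherical lesions placed non-collinearly inside it — with
partial-volume edge ramps; MR appearance is piecewise-constant plus
Gaussian noise, US appearance multiplies gamma speckle
(shape 16) and exponential depth attenuation. This appearance model is
deliberately simple: it stresses intensity-based registration but is not
an acoustic or k-space simulator, so passing tests demonstrate the
machinery's correctness on controlled data, not clinical image quality.
Lesion masks are exact by construction (voxel centres inside the
analytic sphere; volume within 2% of `4/3 pi r^3` at 0.5 mm spacing).

`experiment_truth()` fixes every ground-truth transform and the noise
parameters; `simulate_experiment()` derives per-component seeds from one
master seed and emits every observation the physical workflow would
produce. Default noise levels are the printed device classes: tracker
jitter 0.3 mm per axis (middle of the 0.25-0.35 mm static-accuracy
class) with 0.05 degree rotational jitter, stylus FLE 0.3 mm, cone-tip
localization 1.0 mm in US images and 0.5 mm in MR images (chosen once as
representative of manual tip picking at the respective resolutions).
Five calibration images, 10 stylus repeats per tank tip, 5 per MR tip
and 100 tracker readings per averaged epoch mirror the stated protocol.

## Error propagation

`quadrature_total()` combines independent chain errors as
`sqrt(sum(e_i^2))`; the worked example combines the volunteer US/US
registration error (3.7 mm) with the TRUS calibration FRE (1.18 mm) to
3.88 mm — the "about 3.9 mm" total. Which components enter that figure
is not uniquely recorded upstream (3.7 with 1.0 and 0.87 also rounds to
3.9), so the operation takes an explicit budget rather than hard-coding
one. `monte_carlo_chain_tre()` is the numerical counterpart: it
re-simulates the entire experiment per replicate, re-runs every
calibration, rebuilds the chain and measures target error against truth.
It is zero at zero noise, strictly increasing in the noise scale, and
scales linearly under simultaneous sigma-doubling within 10% — the
in-silico validation of the quadrature assumption. Replicates with
degenerate calibrations are excluded and counted; more than 1% excluded
aborts, signalling a broken configuration rather than bad luck.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10^4 replicates for the
FRE expectation; a 0.2 mm grid (~76^3 voxels) for the sphere metric
oracles; 20 registration cases at 1.5 mm voxels (~60^3) for the MI
recovery grid; 300-500 Monte-Carlo replicates for the propagation laws.
These sizes were chosen so each law is measured well inside its
tolerance on a single CPU. Degenerate inputs fail loudly everywhere:
collinear fiducials, rotation-free pivot sweeps, empty masks, empty MI
overlap and singular affines all raise descriptive errors instead of
returning numbers.

## Known limitations

No anisotropic-noise (weighted) registration and no spatial TRE(r) map —
only the expectation identity is used. No temporal calibration between
tracker and image streams, no freehand-3D-US volume reconstruction, no
deformable or learning-based registration, no DICOM or real-tracker
streaming I/O. The US appearance model ignores shadowing, refraction and
anisotropic speckle; real US/TRUS pairs are harder than the synthetic
ones, and the MI registration's accuracy on them is bounded below by
what these tests show, not established by it.
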