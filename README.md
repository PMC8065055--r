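# trackfuse

Tracker-based multimodal image fusion for ultrasound-guided navigation.

`trackfuse` implements a hybrid navigation pipeline that fuses a
pre-procedure volumetric modality (MR) with intra-procedure 3D ultrasound
**without any inter-modal image registration**: marker tools tracked by an
optical tracking system (OTS) are calibrated to each imaging device by
paired-point rigid registration, and a single *intra-modal* US/US affine
registration bridges the pre-procedure abdominal 3D-US and the
intra-procedure 3D-TRUS. Points then travel through a homogeneous
transform chain

    P_MR = T_US^MR · T_TRUS^US · P_TRUS
    T_US^MR = T_ORF^MR · T_trans^ORF · T_US^trans

(`trans` = probe tool frame, `ORF` = optical reference tool on the MR
table or gantry), with tracked compensation of the table shift between
the MR scan and the US acquisition. The package is aimed at
image-guided-intervention researchers who want to prototype, test and
error-budget such a system entirely in software: it ships a synthetic
layer that emulates the physical study objects (multi-cone calibration
phantoms, a tissue-equivalent prostate phantom with 5 mm lesions,
tracker jitter of the 0.25–0.35 mm class) with exact ground truth.

What is inside:

* homogeneous transform algebra between named frames with strict
  head-to-tail chain checking (`compose()`, `invert()`,
  `apply_transform()`);
* paired-point rigid registration (SVD with reflection guard) and its
  error statistics — FRE, TRE at held-out targets, the Fitzpatrick
  `E[FRE²] = (1 − 2/N)·FLE²` expectation as a test oracle
  (`register_points()`, `compute_tre()`);
* device calibrations: stylus pivot, tracked 3D-US probe, 2D-TRUS probe,
  MR gantry/table, CAD-based fiducial refinement, table-shift tracking;
* fusion chains with and without table-shift compensation, point mapping
  TRUS→MR, volume resampling with overlay/checkerboard fusion;
* masked affine registration maximizing Mattes-style mutual information
  (multi-resolution, deterministic under a seed);
* evaluation metrics: Dice, exact Hausdorff, symmetrized mean boundary
  distance, lesion-centroid TRE, PSNR;
* Monte-Carlo propagation of fiducial/tracker errors through the full
  chain and quadrature error budgets;
* I/O for the field's formats: NIfTI-1, MetaImage, 3D Slicer FCSV and
  markups JSON (RAS↔LPS handled), pose CSV, 4×4 transform text files,
  plus a thin CLI (`inst/cli/trackfuse`).

## Worked example

Simulate a complete experiment under the printed device noise classes,
run every calibration, build the shift-compensated chain and measure the
target registration error against ground truth:

```r
library(trackfuse)

truth  <- experiment_truth()            # default: tracker 0.3 mm, stylus 0.3 mm,
                                        # US tips 1.0 mm, MR tips 0.5 mm
bundle <- simulate_experiment(truth, seed = 7)
fusion <- fuse_experiment(bundle)       # probe cal -> MR cal -> shift -> chain
fusion
#> <fusion_result>
#>   probe calibration FRE: 1.703 mm (5 images)
#>   MR calibration FRE:    0.739 mm
#>   cone-target TRE:       2.034 +/- 0.118 mm (n=7)
#>   lesion TRE (US->MR):   0.387 mm
#>   lesion TRE (TRUS->MR): 0.387 mm
```

The probe calibration FRE pools 7 cone tips over 5 images whose US-image
localization noise (1 mm per axis) dominates; the MR calibration FRE is
sub-millimetre because 5 stylus repeats per tip are averaged first; the
cone-target TRE is the end-to-end chain error at 7 held-out tips — at
these noise levels it lands in the same low-millimetre range as physical
phantom experiments. With `experiment_truth(noise_scale = 0)` every
number above drops to numerical zero (the chain closes exactly), which
is the package's central correctness property.

The error budget of the full MR→TRUS mapping, combining the intra-modal
US/US registration error with the TRUS calibration FRE in quadrature:

```r
quadrature_total(c(us_us_registration = 3.7, trus_fre = 1.18))
#> [1] 3.883607
```

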