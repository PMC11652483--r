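---
title: "From sequential portal images to a machine log: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sequential portal images to a machine log: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidlog)
```

## The problem

Volumetric modulated arc therapy (VMAT) delivers dose while the gantry
rotates, with the multi-leaf collimator (MLC), dose rate and gantry speed all
modulated simultaneously. Patient-specific quality assurance must confirm
that this choreography was actually delivered. Log-based QA recalculates dose
from the machine's own trajectory record, but it is not an independent
measurement; portal-image (EPID) QA is a true measurement but is usually
reduced to a single composite fluence, losing the control-point resolution.

`epidlog` implements the hybrid approach: time-ordered EPID frames captured
during delivery are converted, frame by frame, into a machine-log style
record of per-frame MLC bank positions and cumulative monitor units (MU).
That record can feed a log-driven dose recalculation while remaining a
measurement. The package also implements the standard plan-complexity
indices and the rank-correlation analysis used to relate complexity to gamma
passing rates.

## Image model and processing chain

The panel exports 16-bit frames whose intensities are *inversely*
proportional to dose, so the first step is the involution

$$I_\mathrm{proc} = 65535 - I_\mathrm{raw}.$$

Scatter blurs the processed image. We model the blur as a convolution with a
normalized Gaussian kernel $K$ and invert it with the additive (van
Cittert-type) iteration

$$x_{n+1} = x_n + (I_\mathrm{proc} - x_n * K), \qquad x_1 = I_\mathrm{proc},$$

monitoring the residual $r_n = \lVert x_n * K - I_\mathrm{proc}\rVert_2$ and
stopping when its relative change falls below `tol` or at `max_iter`.

Numerical choices, all surfaced in `pipeline_config()`:

* **Kernel width** `sigma` (default 2 px). The acquisition chain does not
  report its scatter width; on synthetic data the generator and the
  deconvolver share `sigma`. A mismatched kernel still sharpens edges (this
  is tested) but exact recovery is only claimed for the matched case.
* **Stopping rule** `|r_n - r_{n-1}| / r_1 < tol`, `tol = 1e-4`,
  `max_iter = 50`. The iteration is linear and contractive for a normalized
  kernel, so the residual history is non-increasing on noiseless input; the
  suite asserts this with a `1e-9` float allowance.
* **Boundary handling**: reflective padding, which avoids dark-border
  ringing for apertures near the edge. Convolution is executed as two 1-D
  passes via a precomputed banded operator (a dense matrix product), which
  is exact and fast enough to reuse across a whole frame sequence.
* **Negative undershoot** is permitted *during* iteration and clipped only
  in the returned image. Clipping removes the Gibbs-type negative lobes
  just outside the field, so re-blurring the *clipped* image does not
  reproduce the input to the same accuracy as the internal estimate; the
  re-blur oracle in the tests therefore reads the recorded residual, which
  is exactly the re-blur mismatch of the estimate.

## Threshold calibration and leaf extraction

Binarization uses a single absolute threshold. It is calibrated from
deconvolved images of square box fields of 5, 10, 15 and 20 cm: candidate
thresholds sweep 40-60% of the maximum pixel value in absolute steps of 100,
and a candidate is valid when the cross-plane pixel widths of the 10/15/20 cm
boxes are 2x, 3x and 4x the 5 cm width within ±0.02. The chosen threshold is
the midpoint of the maximal contiguous valid interval. On the default
synthetic geometry (512 px, 0.5 mm/px, plateau 40000 of 65535) the deconvolved
boxes give ratios 2.000/3.000/4.000 at the midpoint; `scripts/acceptance.R`
recomputes the 10/5 and 15/5 ratios from scratch.

Leaf edges are read per leaf pair from its projected detector row band: a
column is open when at least half the band rows exceed threshold, the pair's
aperture is the longest contiguous open run (islands warn), and edges use
half-open pixel spans converted to signed mm at the isocenter plane. There is
no sub-pixel refinement: the underlying panel measurement is integer-pixel,
and fractional offsets only appear as averages in the calibration tables.
Closed pairs report a configurable park position (default 0 mm).

Two detector-pose effects are calibrated from 10x10 cm box images:
gravity-induced panel sag, tabulated per bank against gantry angle
(0-350 degrees, 10-degree grid, periodic linear interpolation), and the
additional center shift from collimator rotation, tabulated on a
30x30-degree (gantry x collimator) grid with bilinear interpolation. By
construction offsets vanish at the reference pose (gantry 0, collimator 0);
the collimator table stores only the shift *beyond* the sag at the same
gantry angle. Cross-plane corrections translate extracted edges; in-plane
corrections re-index the leaf row bands before extraction.

## MU conversion and frame records

The acquisition normalizes every raw frame to the 16-bit range; the sidecar
pixel scaling factor (PSF — a per-frame scalar, not a point-spread function)
restores dose proportionality:

$$I_\mathrm{MU} = I_\mathrm{proc} / \mathrm{PSF}.$$

A per-frame scalar is needed for MU bookkeeping; we use the *mean* in-field
intensity (robust to aperture size), with `"sum"` available. Per-frame
MU-equivalents are normalized so their running sum projects exactly onto the
plan's total MU — absolute dosimetric calibration of the panel is out of
scope, and the downstream dose engine expects plan-consistent MU. Each frame
then receives a gantry angle by inverse interpolation of the plan's
cumulative-MU-vs-gantry polyline; this resolves the mismatch between the
plan's spatially uniform control points and the temporally uniform frames. A
timestamp-proportional mapping is available behind `angle_map = "time"`.

## The log dialect

The output is a versioned, open text dialect (`EPIDLOG/1.0`): a `# key:
value` header and one tab-separated record per frame (positions to 0.01 mm,
MU to 0.0001, angles to 0.01 degrees), chosen to round-trip byte-for-byte.
The vendor-ingestible binary formats are deliberately not emulated, and
ingestion by any commercial dose engine is unverified here. Two further
format substitutions were forced by the environment: plans are read from an
equivalent open JSON dialect (`RTPLAN-JSON/1.0`) rather than DICOM, and
frames are stored as 16-bit PGM rather than a compressed raster — both carry
the same payload as their clinical counterparts and are documented in their
readers. The pipeline configuration serializes as JSON for the same reason.

## Complexity indices

For each control point, over the in-field leaf pairs (pairs open anywhere in
the arc): the leaf sequence variability (LSV) per bank is
$\sum_{n<N} (p_\max - |p_n - p_{n+1}|) / ((N-1)\,p_\max)$ with
$p_\max = \max p - \min p$ (an aligned bank contributes 1), and the control
point LSV is the product of the banks; the aperture area variability (AAV)
is the total opening divided by the total of per-pair arc-maximum openings.
MCSv is the MU-weighted sum over control-point transitions of the
segment-averaged AAV times LSV, so an unmodulated constant-aperture sweep
scores exactly 1. Leaf travel (LT) averages total absolute leaf displacement
over the moving leaves; SAS is the MU-weighted fraction of open pairs with
gap below 10 mm (configurable); LTMCS is $\mathrm{MCSv}\cdot\max(0,
1 - \mathrm{LT}/L)$ with $L = 500$ mm by default. LT and SAS constants are
configuration because no standard value exists. Transition metrics report
the mean and sample SD (n-1; a single transition reports 0) of the
per-transition mean/max leaf displacement and MU increment.

The packaged 18-plan table ships percentages on the 0-100 scale. The rank
correlation between the two gamma passing rates reproduces at 0.737 (0.919
on the twelve 6 MV plans, average-rank ties, t-approximation p-values).
Three indices (SAS, LSV, LT) correlate opposite to their usual complexity
interpretation in that data and are flagged `excluded` in
`correlate_table3()` output; they are computed regardless. Note the table's
SAS column exceeds 1 for every plan, which is inconsistent with a
proportion; this package implements the proportion definition and makes no
attempt to reproduce that column's absolute values.

## What the synthetic world does and does not establish

`gen_vmat_acquisition()` emulates: frame-by-frame export at a fixed period
(default 0.3 s), 512x512 16-bit frames at 0.5 mm/px projected pixel pitch,
acquisition-normalized intensities with the dose scale in the PSF sidecar,
Gaussian scatter blur, optional multiplicative intensity noise, and
pose-dependent detector shifts. Aperture edges are snapped to the pixel grid
and the snapped values are the recorded truth, so noiseless extraction can
legitimately be exact.

It does **not** emulate: energy-dependent detector response, ghosting/lag,
tongue-and-groove and rounded leaf tips, off-axis response of
flattening-filter-free beams, or Monte-Carlo scatter (the blur kernel *is*
the forward model by construction). A green end-to-end test therefore
establishes the correctness of the inference chain, not the physics of a
particular panel. The published patient-level results (mean gamma passing
rate 95.2% ± 3.7% over 18 plans) depend on confidential patient data and a
commercial dose engine and are represented here only by the packaged
per-plan table; the 2D gamma comparator (`gamma_2d()`, global normalization,
3%/3 mm, 10% low-dose cut, 0.1 px search step) is a fluence-level stand-in,
not a 3D dose recalculation.

## Known limitations

* Deconvolution assumes a shift-invariant Gaussian kernel; real scatter
  kernels have long tails and spatial variance.
* Threshold calibration assumes the four box fields share the detector
  plateau; strongly flattening-filter-free profiles would need profile
  correction first.
* The offset model is integer-pixel per measurement; sub-pixel sag appears
  only through interpolation between poses.
* `read_rtplan()` reads the package's open dialect; clinical DICOM RT-Plan
  export requires a one-time conversion outside this package.
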