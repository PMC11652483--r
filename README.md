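# epidlog

Control-point specific VMAT quality assurance from sequential portal images.

## What problem this solves

VMAT (volumetric modulated arc therapy) delivers radiation while the gantry
rotates and the multi-leaf collimator (MLC), dose rate and gantry speed are
modulated together. Log-file QA recalculates dose from the machine's own
trajectory record — efficient, but not an independent measurement, and it can
miss MLC positioning faults. Portal-image (EPID) QA is a measurement, but is
usually collapsed into one composite fluence with no time resolution.

`epidlog` combines the two: it turns a time-ordered sequence of 16-bit EPID
frames captured during delivery into a machine-log style file with per-frame
MLC bank positions (mm at isocenter) and cumulative monitor units (MU), which
can drive a log-based dose recalculation while remaining an actual
measurement. It is aimed at medical physicists building or validating
measurement-based VMAT QA pipelines.

The processing chain per frame:

1. **Inversion** — raw panel intensities are inversely dose-proportional:
   `I_proc = 65535 − I_raw`.
2. **Deconvolution** — scatter blur is removed by an additive iterative
   scheme with a normalized Gaussian kernel `K`:
   `x_{n+1} = x_n + (I_proc − x_n ∗ K)`, starting from `x_1 = I_proc`,
   stopping when the re-blur residual saturates.
3. **Binarization** at a threshold calibrated so that 5/10/15/20 cm box
   fields give cross-plane pixel widths in exact 1:2:3:4 proportion
   (midpoint of the valid 40–60%-of-max window).
4. **Leaf-edge extraction** per projected leaf row band, with gantry-sag and
   collimator-shift detector offset correction interpolated from calibrated
   pose tables.
5. **MU conversion** — `I_MU = I_proc / PSF` with the per-frame pixel
   scaling factor from the acquisition log; per-frame values are projected
   onto the plan total and gantry angles assigned by inverse interpolation
   of the plan's cumulative-MU-vs-gantry curve.
6. **Serialization** as an open, versioned text dialect (`EPIDLOG/1.0`).

It also computes the six standard VMAT plan-complexity indices (SAS, LT,
MCSv, LTMCS, AAV, LSV), six control-point transition metrics, a 2D global
gamma comparator (3%/3 mm default), and Spearman rank correlations between
complexity and gamma passing rate, including the packaged 18-plan reference
table.

A fully synthetic acquisition generator (`synthetic_arc_plan()`,
`gen_vmat_acquisition()`, `gen_box_series()`, `gen_offset_acquisition()`)
produces every input with known ground truth, so the whole chain is testable
without a linac.

## Worked example

```r
library(epidlog)

# a synthetic sliding-window arc with known ground truth
plan <- synthetic_arc_plan(n_cp = 31, n_pairs = 12, sweep_mm = 20,
                           window_mm = 24, total_mu = 120)
acq  <- gen_vmat_acquisition(plan, n_frames = 10,
                             geometry = detector_geometry(256, 0.5))

# frames -> log (invert, deconvolve, binarize, extract, MU-assign)
log <- process_acquisition(acq$frames, acq$log, plan,
                           pipeline_config(detector = list(resolution = 256L,
                                                           pixel_mm = 0.5)))
log
#> <epid_log> 10 records x 12 leaf pairs | plan synthetic-arc | 120 MU

recover(acq, log)   # compare against the generator's ground truth
#> <recovery_report> 10 frames | leaf RMSE 0.000 px (max 0.000) | MU rel err 1.84e-05 | gantry max err 0.001 deg

plan_complexity(plan)
#> <plan_complexity>
#>   SAS 0.000 | LT 40.0 mm | MCSv 0.234 | LTMCS 0.215 | AAV 0.990 | LSV 0.236
#>   MLC mean 1.33+/-0.12 mm, max 1.50+/-0.00 mm | dMU 4.00+/-1.43
```

The recovery report says the extracted leaf edges match the ground truth to
0 px RMSE (noiseless frames with grid-aligned edges are exactly
recoverable), per-frame MU to ~2e-5 relative, and gantry angles to ~1e-3
degrees. The complexity report shows a lightly modulated arc: MCSv 0.234
(1 = unmodulated), mean leaf displacement 1.33 mm per control-point
transition.

Statistics of the packaged 18-plan gamma passing rate table:

```r
str(reproduce_table3_stats())
#> List of 7
#>  $ mean_gpr  : num 95.2
#>  $ sd_gpr    : num 3.75
#>  $ n_below_90: int 2
#>  $ rho_all   : num 0.737
#>  $ p_all     : num 0.000479
#>  $ rho_6mv   : num 0.919
#>  $ p_6mv     : num 2.35e-05
```

## Command line

A thin wrapper is installed as `exec/epidlog`:

```sh
epidlog simulate --preset arc --out run/ --frames 60
epidlog convert --frames run/ --plan run/plan.json --out run/arc.epidlog
epidlog complexity --plan run/plan.json
epidlog correlate --out correlations.csv
epidlog table3-stats
```

## Further reading

`vignettes/epid-log-methods.Rmd` documents the image model, every tunable
parameter with units and defaults, what the synthetic generator does and
does not emulate, and the package's design decisions and limitations.
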