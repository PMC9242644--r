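# lysoratio

Quantification of lysosomal pH from dual-excitation ratiometric fluorescence
images, and of slowly gating whole-cell transporter currents from
voltage-clamp recordings — with synthetic data generators that carry exact
ground truth, so the entire analysis chain is testable end to end.

## Who this is for

Cell biologists and biophysicists measuring organelle pH with ratiometric
dyes (e.g. Oregon Green 488-dextran, apparent pKa ≈ 4.8) and probing the
lysosomal counterion pathway with patch clamp. The package reproduces, as
tested reusable code, the analysis behind a typical study of drug-induced
lysosomal hyperacidification and lipid inhibition of a lysosomal
chloride/proton antiporter:

* **Imaging:** per-channel local background subtraction (rolling-ball-style
  grayscale opening), Otsu thresholding, connected-component ROI extraction,
  optimal cross-channel ROI pairing, low-intensity filtering, a
  four-parameter logistic calibration

  R(pH) = r_min + (r_max − r_min) / (1 + 10^(h·(pH50 − pH))),

  its analytic inversion with out-of-range clamping, and the aggregation
  chain lysosome → cell → condition ending in ΔpH, the proton fold change
  10^(−ΔpH), size statistics, ECDFs, pH–size correlation and two-sample
  t-tests.
* **Electrophysiology:** simulation of sweep families of an outwardly
  rectifying, slowly gating current with time- and dose-dependent inhibition
  after break-in; single-exponential activation/deactivation fits;
  late/early (3 min / 30 s) inhibition ratios for maximum and tail currents;
  Hill dose–response EC50 estimation.

## Worked example

A complete synthetic experiment — calibration images, two imaging conditions,
segmentation, pairing, calibration fit, inversion, summaries:

```r
library(lysoratio)
res <- run_quantify(quantify_config(seed = 20260923))
res$conditions[, c("condition", "n_cells", "mean_ph", "sem_ph", "mean_area_um2")]
#>   condition n_cells  mean_ph      sem_ph mean_area_um2
#> 1   control      10 4.337973 0.008592088     0.4771418
#> 2  apilimod      10 4.030064 0.013186740     4.3516587
res$shift
#>   control  treated   delta_ph proton_fold delta_area_um2
#> 1 control apilimod -0.3079087     2.03193       3.874517
```

The generator's truth for this run was pH 4.32 (control) versus 4.02
(treated): the pipeline recovers the means within a few hundredths of a pH
unit, a −0.31 shift, and a twofold proton-concentration increase. The
treated condition's swollen puncta give a ~3.9 µm² mean size shift.

The ephys side, at a saturating 100 µM pipette concentration:

```r
eph <- run_ephys(ephys_config(seed = 20260923, n_cells_per_conc = 8,
                              protocol = ephys_protocol(step_v = c(100, 120, 140))))
eph$summary[, c("conc_um", "mean_max_ratio", "mean_tail_ratio")]
#>   conc_um mean_max_ratio mean_tail_ratio
#> 1       0      1.0005615       0.9987602
#> 2      25      0.8486446       0.7643314
#> 3      50      0.7025498       0.5102003
#> 4     100      0.6081606       0.3376544
eph$dose_fit
#> <dose_response_fit> EC50=34.39 uM  n=2  floor=0  ceiling=0.438  rmse=0.00173
```

Drug-free recordings are stable (ratio ≈ 1); 100 µM depresses the maximum
current by ~39% and the tail amplitude by ~66% between 30 s and 3 min after
break-in, and the measured inhibition follows a Hill curve with an apparent
EC50 in the low-tens-of-µM range.

## The analysis workflow

Numbered drivers under `analysis/` run the study as a narrative, writing all
tables under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate_imaging.R` | renders the experiment's TIFFs + ground truth |
| `analysis/02_quantify_ph.R` | wild-type-like and knockout-like pH/size arms |
| `analysis/03_ephys_kinetics.R` | stability, inhibition ratios, dose–response, mutant control |
| `analysis/04_figures.R` | calibration curve, pH ECDF and dose–response figures |

Output tables: `lysosomes.csv`, `cells.csv`, `conditions.csv`, `shifts.csv`,
`ecdf.csv`, `calibration.json`/`calibration_points.csv` plus a manifest with
the seed and config hash (per imaging arm); `ephys_metrics.csv`,
`ephys_summary.csv`, `dose_response.json` (ephys). Columns follow the field
names documented in the function reference (`?measure_lysosomes`,
`?run_quantify`, `?run_ephys`).

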