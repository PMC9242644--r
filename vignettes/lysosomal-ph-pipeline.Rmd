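---
title: "Methods: ratiometric lysosomal pH quantification and voltage-clamp kinetics"
author: "lysoratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric lysosomal pH quantification and voltage-clamp kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoratio)
```

## The measurement problem

Lysosomal pH sits in a narrow acidic band (roughly 4.3–5.0) and is read out
with a ratiometric dye such as Oregon Green 488-dextran: the dye is delivered
to lysosomes by fluid-phase endocytosis, and separate excitation at 445 nm and
488 nm yields two images whose per-organelle intensity ratio depends on pH but
not on how much dye each lysosome accumulated. The 445 nm channel is close to
the dye's isosbestic behaviour and serves as the reference; the 488 nm signal
grows with pH. An in-situ calibration — replacing the medium with a series of
pH-clamped buffers containing the ionophores nigericin and monensin so that
lysosomal pH equals buffer pH — converts measured ratios into absolute pH.

`lysoratio` implements this chain end to end and, because raw microscope data
for such experiments are rarely deposited, ships a synthetic-scene generator
with exact ground truth so that every stage can be validated quantitatively.

## The ratio–pH law

Calibration uses the four-parameter logistic in pH (base-10 slope):

$$R(\mathrm{pH}) = r_{\min} + \frac{r_{\max} - r_{\min}}
{1 + 10^{\,h\,(\mathrm{pH}_{50} - \mathrm{pH})}}$$

with floor $r_{\min}$, ceiling $r_{\max}$, midpoint $\mathrm{pH}_{50}$ (the
apparent pKa, about 4.8 for Oregon Green) and slope $h > 0$. Commercial curve
fitters describe the same family with a base-$e$ slope; the two are identical
up to rescaling $h$, and base-10 is used here throughout. The analytic
inverse,

$$\mathrm{pH}(R) = \mathrm{pH}_{50} - \tfrac{1}{h}\log_{10}
\left(\frac{r_{\max}-r_{\min}}{R - r_{\min}} - 1\right),$$

is applied per lysosome. Ratios at or beyond the fitted dynamic range cannot
be inverted — the dye saturates — so they are clamped to the ends of the
calibration's validity range (the span of buffer pHs) and flagged rather than
dropped; summaries report the flagged fraction. Fits are initialized from the
observed ratio extremes and the interpolated midpoint, bounded
($r_{\min} \ge 0$, $h \in [0.1, 5]$), and run to a residual tolerance of
1e-10. A fit that comes back non-increasing is an error, not a result.
Calibration points are per-cell mean ratios (4–5 cells per buffer), not
per-lysosome values, matching how such standard curves are plotted.

## Segmentation and pairing

Each channel is processed independently:

1. **Local background subtraction.** The background is the grayscale
   morphological opening of the image with a disk (default radius 20 px), a
   rolling-ball analog. The envelope is estimated on a lightly smoothed copy
   of the image (Gaussian sigma 1.5 px): an opening of the raw image tracks
   the *lower* envelope of the shot noise and leaves a positive offset
   (around ten counts under realistic noise) beneath every object, which
   propagates into a pH-dependent ratio bias; smoothing the estimate removes
   the offset while the subtracted signal itself stays untouched. The disk
   radius must exceed the radius of the largest punctum; 20 px covers even
   strongly swollen lysosomes at the default rendering scale.
2. **Otsu thresholding**, computed on a 256-bin histogram spanning
   [min, max] of the background-subtracted image. The threshold is the bin
   edge maximizing the between-class variance $w_0 w_1 (\mu_0-\mu_1)^2$;
   class means use exact per-bin intensity sums, so for integer images with
   at most 256 distinct values the result coincides with exhaustive
   maximization over all splits (this equivalence is oracle-tested). Ties
   break toward the lowest threshold, and foreground is *strictly greater*
   than the threshold.
3. **Connected components** under 8-connectivity (configurable to 4) with a
   minimum area of 4 px. Each ROI carries its unweighted centroid, area, and
   mean/minimum background-subtracted intensity, ordered deterministically by
   top-left pixel.

ROIs are then matched across channels by optimal one-to-one assignment
(maximum-weight bipartite matching) restricted to centroid distances of at
most 3 px: cardinality dominates, then total distance is minimized. A greedy
matcher would be order-dependent; the optimal assignment is not, and it is
verified against a brute-force oracle. Unmatched, single-channel detections
are discarded, as are pairs whose minimum pixel intensity falls below 5
counts in either channel (the "low-intensity pixels" filter). The per-pair
readout is the ratio of ROI means, each over its own channel's pixel set —
robust to sub-pixel registration error; a pixel-wise-ratio variant was
considered and rejected because edge pixels with near-zero reference
intensity make it noise-fragile.

Lysosome "size" is the area of the 445-channel ROI converted by
`pixel_size_um^2`; the reference channel is used because its segmentation
does not depend on pH. No watershed splitting is attempted: touching puncta
merge into one ROI, which is acceptable for mean-pH and mean-size statistics
at the densities simulated.

## Aggregation conventions

Per-lysosome pH values average to per-cell means (unweighted), and condition
statistics are computed over cell means with equal cell weights — the
convention behind "each pale symbol is one cell" plots. Cells contributing
fewer than 5 paired lysosomes are excluded and logged. The treatment effect
is `delta_ph = treated - control` (acidification is negative) and the proton
fold change is $10^{-\Delta \mathrm{pH}}$; when several independent
experiments are pooled, per-experiment shifts and folds are computed first
and then averaged, which is why a pooled fold differs slightly from
$10^{-\overline{\Delta \mathrm{pH}}}$. ECDFs of single-lysosome pH, the
Pearson pH-size correlation, and plain two-sample Student's t tests (pooled
variance by default, Welch by flag; paired variant on differences) complete
the statistics layer. These call the standard `stats` routines; the tests
pin hand-computed examples.

## The synthetic imaging generator

Scenes emulate sparse adherent cells: non-overlapping elliptical cell masks
on a jittered grid, each holding a fixed number of lysosomes placed by dart
throwing with a minimum-separation rule (relaxed gradually in crowded
fields). Each lysosome is an isotropic 2-D Gaussian spot truncated at
3 sigma, with

* `true_ph` drawn from a Normal truncated to [3.0, 7.5] (the calibration
  span plus margin), via the inverse-CDF so draws are exact;
* `dye_amount` log-normal (sdlog 0.3), emulating variable dextran loading;
* radius (the Gaussian sigma) Normal, floored at half a pixel.

The dye's two-excitation photophysics is reduced to "445 pH-independent,
488 proportional to $R(\mathrm{pH})$", which makes the ground-truth ratio of
a noiseless render *exact* — the identity `sum(ch488)/sum(ch445) =
R(true_ph)` holds to 1e-9 and anchors the whole validation chain. Noise is
Poisson shot noise on expected counts (peak about 300 counts per unit dye),
a flat background (20 counts) plus a planar gradient (10 counts), and
Gaussian read noise (sd 2 counts), clipped at zero; a `shot_noise` switch
turns sampling off for exact expected-value renders. Calibration series
reuse the generator with every `true_ph` clamped to the buffer pH, which is
precisely what the ionophore clamp does to real cells.

Default study conditions mirror the experiment the package reproduces:
a control around pH 4.32 (sd 0.15) with compact puncta (sigma 1.6 px,
30 per cell) and a treated condition at pH 4.02 with fewer, swollen puncta.
The treated radius defaults (sigma 4.9 px wild-type-like, 3.6 px
knockout-like at 0.16 um/px) were set once, from the approximate thresholded
area of a Gaussian spot ($A \approx 2\pi\sigma^2 \ln(\mathrm{peak}/T)$), so
that the measured mean-size shifts land near 4 and 2 um^2 respectively.
What the generator deliberately does **not** model: 3-D structure and
point-spread functions, photobleaching, chromatic misregistration, vesicle
motion between the two exposures, and autofluorescence. Passing the
end-to-end tests therefore demonstrates correctness of the analysis chain
under this forward model, not robustness to every real-world artifact.

### Known estimator bias

Even noiselessly, a mixed-pH field carries a small upward pH bias
(~+0.02 at pH 4): the 488 threshold is global per image, so puncta dimmer in
488 than the field's typical punctum get smaller cores, and the mean over a
smaller core overstates the ratio. The clamped calibration does not see this
(all puncta share one pH, making the two channels exactly proportional), so
it cannot absorb it. With the smoothed background estimate the residual
end-to-end bias is within ±0.04 pH at the default conditions — inherent to
global-threshold ratio imaging, and worth remembering when comparing
absolute pH values across analysis pipelines.

## The voltage-clamp module

The simulated current is a deliberately minimal phenomenology of a slowly
gating outward rectifier (it makes no mechanistic claim): Boltzmann
steady-state activation $p_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$
($V_{1/2} = +80$ mV, $k = 25$ mV), mono-exponential relaxation with
$\tau_{act}(V) = \tau_0 e^{-V/V_\tau}$ ($\tau_0 = 1$ s, $V_\tau = 200$ mV,
i.e. ~0.5 s at +140 mV), an instantaneous fraction of 0.1, and
mono-exponential deactivation at holding ($\tau = 80$ ms). The default
protocol is a 0.1 s baseline at -60 mV, 2 s steps from -80 to +140 mV in
20 mV increments, and a 0.5 s tail, sampled at 1 kHz.

Dialysis inhibition after break-in follows
$s(c, t) = 1 - f_{\max}(c)\,(1 - e^{-t/\tau_{wash}})$ with a Hill
$f_{\max}(c) = f_{ceil}\, c^n/(c^n + EC_{50}^n)$ and $\tau_{wash} = 60$ s,
so inhibition is near steady state by 3 min. The pulse current and the tail
amplitude carry **separate ceilings**. A single conductance scale cannot
depress tail currents more than pulse currents, yet that asymmetry is the
observed phenotype (the lipid also speeds deactivation, pointing at the
gate rather than the transport cycle); modeling the tail's extra
sensitivity as its own ceiling keeps every late/early ratio analytic:
`max_ratio = s_max(c,180)/s_max(c,30)` exactly, and likewise for the tail.
With $EC_{50} = 30$ uM and $n = 2$, the ceilings 0.60 (pulse) and 0.88
(tail) were chosen in closed form so a saturating 100 uM dialysis gives
late/early ratios of 0.61 and 0.34 — i.e. a 39% maximum-current and 66%
tail-current decrease. Deactivation is additionally sped up by a factor 0.6
whenever genuine inhibition is present. Setting both ceilings to zero
reproduces a coupling-dead mutant: its recordings are bitwise those of the
drug-free control.

### Fitting choices

Single-exponential fits (activation `offset + A(1 - e^{-t/tau})`, decay
`offset + A e^{-t/tau}`) initialize $\tau$ from the integral identity
$\int z\,dt = A\tau$ of the detrended signal — mean-zero noise integrates
out, unlike log-linear slopes, which low-SNR tails corrupt — and refine by
Levenberg–Marquardt with $\tau$ bounded below by a tenth of the sample
interval (a smaller $\tau$ is not resolvable and is a known degenerate sink
for the optimizer). Non-convergence, including constant traces, is reported
as `converged = FALSE`, never as an exception. The "maximum" pulse current
is the mean of the final 5% of the pulse (a steady-state reading, robust to
noise, and within 0.5% of the closed form at the defaults); the tail
amplitude is the fitted decay extrapolated to the repolarization onset after
blanking the first 5 ms (capacitance transient), which recovers the onset
amplitude exactly for an exponential tail. Whether "maximum" and "tail"
currents are read as peaks or as steady-state/fitted values varies between
labs and is rarely written down; the operationalizations above are this
package's own and are stated in the function documentation.

The dose-response is a Hill fit of per-cell fractional inhibition
$1 - \mathrm{ratio}_{max}$. `run_ephys` pins the floor at zero because its
zero-dose arm is a true blank; with only a handful of concentrations a free
floor is poorly identified and roughly doubles the EC50 error. Note the
*apparent* EC50 of the late/early-ratio readout sits slightly above the
model's underlying EC50 (about 34 vs 30 uM at the defaults) because some
inhibition has already developed by the early time point — the same
compression affects any wash-in protocol.

## Numerical and testing notes

Problem sizes were chosen to make the full validation cycle comfortable on a
single core: end-to-end recovery runs five seeds of 10 cells x 30 lysosomes
per condition against a 6-buffer x 4-cell calibration (about 30 s in total),
the Otsu and pairing oracles sweep 1000 and 500 random instances, calibration
and dose-response Monte Carlos use 200 replicates, and exponential-fit
recovery uses 100 noisy traces at SNR 20. All randomness is seeded; scene
construction and rendering are bit-reproducible for a fixed seed, and
`run_quantify` reruns with an identical configuration produce byte-identical
CSVs (manifests record the seed and a configuration hash, never timestamps).
Images are written as 16-bit TIFFs, which quantizes counts to integers;
sweep families travel as CSV plus a JSON sidecar carrying protocol and
concentration metadata, and a missing sidecar is a hard error rather than a
guessed default.

## Limitations

Absolute pH accuracy inherits the global-threshold ratio bias discussed
above; ANOVA-style multiple-comparison corrections are out of scope (plain
two-sample tests only); touching lysosomes are not split; and the
electrophysiology module is a self-consistent phenomenology whose
quantitative tests are recovery tests against its own generator, not claims
about any particular transporter's biophysics.
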