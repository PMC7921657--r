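---
title: "ergkit: measurement conventions, generative model, and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ergkit: measurement conventions, generative model, and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergkit)
```

## What this package does

`ergkit` analyses full-field electroretinogram (ERG) flash luminance series
from two-group studies — typically a transgenic mouse model against wild-type
controls — recorded dark-adapted (DA, rod-pathway-dominated) and
light-adapted (LA, cone-pathway-dominated, on a 30 cd/m² rod-suppressing
background). It has three parts:

1. a **synthetic cohort simulator** with known ground truth, used both as a
   first-class data generator and as the basis of the package's
   parameter-recovery tests;
2. **component measurement** operators that turn a time–voltage trace into
   amplitudes (µV) and implicit times (ms) for the a-wave, b-wave,
   oscillatory potentials (OPs) and photopic negative response (PhNR);
3. **median-based group statistics**: a quantile regression of each measure
   on group and log flash luminance with animal-level cluster-bootstrap
   inference, per-luminance follow-ups with Bonferroni correction, bootstrap
   median CIs, and Spearman correlation against a biomarker.

## Measurement conventions

All measurements are referenced to the pre-flash baseline (mean over
[−20, 0) ms, subtracted). Ties between equal extrema go to the earliest
sample; all windows are parameters of `window_config()`, not constants.

* **a-wave**: magnitude of the most negative voltage in the early search
  window ((0, 50] ms DA, (0, 30] ms LA); implicit time is the time of that
  trough. A secondary amplitude is read at a fixed early time — 6 ms after
  the flash in DA, 5 ms in LA, linearly interpolated between samples — which
  minimizes post-receptor intrusion into the a-wave.
* **b-wave**: measured from the a-wave trough to the largest peak up to
  150 ms. If no negative a-trough exists, the reference is the pre-peak
  minimum (or 0 µV), and the row carries flag `a_absent`.
* **Oscillatory potentials**: the baseline-corrected trace is band-passed
  70–300 Hz with a linear-phase windowed-sinc (Hamming) FIR applied forward
  and reverse, so the net phase is zero and peak times are unshifted. Within
  the OP window the four most prominent local maxima are kept (prominence =
  peak height above the higher adjacent trough), re-ordered by time. Each
  OP's amplitude is its trough-to-peak height; the four amplitudes are
  averaged into the mean OP (mOP) amplitude and the four peak times are
  *summed* (literally summed, not averaged) into a single timing measure.
* **PhNR** (LA only): magnitude of the most negative voltage after the
  b-wave peak, up to 150 ms, measured from the 0 µV baseline. Requesting a
  PhNR on a DA recording is an error by definition.

### Smoothed slow-component cursors

By default the slow components (a, b, PhNR) are measured on a copy of the
trace low-passed at 60 Hz (`window_config(smooth_cutoff = 60)`, zero-phase;
set `smooth_cutoff = 0` for raw-trace cursors). The rationale is numerical:
with realistic noise (8 µV SD), picking a trough as the raw argmin over a
window has an extreme-value bias that grows as the underlying component
shrinks — so two groups with unequal amplitudes are biased by *different*
amounts and median group differences are distorted (we measured a ~0.8 µV
distortion of a 6.79 µV PhNR effect in raw mode). The 60 Hz cutoff removes
the OP band and most noise while attenuating the slow components by well
under 1%; the OP stage always runs on the raw (band-passed) trace. The cost
is a few-percent attenuation of the fast a-wave trough, identical in both
groups and therefore neutral for group contrasts.

### Reliability flags

An implicit time is flagged `*_it_unreliable` when its component's amplitude
is below `reliability_k` (default 3) times the pre-flash noise SD. All LA
implicit times at flashes below 1.0 cd·s·m⁻² are additionally flagged
(`la_it_low_luminance`): dim light-adapted flashes evoke little or no
measurable response, so their timing is meaningless. Flagged implicit times
are excluded from downstream statistics, and LA models only use flashes at
or above 1.0 cd·s·m⁻².

## The generative model

Each noise-free trace is a sum of unimodal component kernels plus an OP
burst:

\[
v(t) = -A\,k_a(t) + B\,k_b(t) + \mathrm{OP}(t) - P\,k_{phnr}(t) + \varepsilon(t),
\]

* **Kernels** are log-normal in time,
  \(k(t) = \exp\{-\ln^2(t/T_p)/2\sigma^2\}\) for \(t > 0\): smooth,
  unimodal and right-skewed like real ERG components, with peak value exactly
  1 at the peak time \(T_p\). The width parameter is expressed in ms at the
  component's base peak time, so latency shifts move a kernel without
  reshaping it. This family is a declared modelling choice — the source
  study publishes no generative model.
* **Amplitudes** follow a Naka–Rushton luminance–response function
  \(V(I) = V_{max} I^n / (I^n + K^n)\); **latencies** shorten linearly in
  \(\log_{10} I\). LA components carry higher semi-saturation constants so
  flashes below ~0.1 cd·s·m⁻² evoke essentially no LA response.
* **OPs** are `op_count` (default 4) Gabor wavelets at `op_frequency`
  (default 120 Hz, period 8.3 ms) with a fixed relative amplitude profile
  (0.6, 1, 0.9, 0.5 — middle wavelets dominate), riding the b-wave rising
  limb.
* **Between-animal variability**: each animal draws one log-normal factor
  (log-SD `animal_sd`, median 1) multiplying *all* its component amplitudes
  across all its recordings — the generative analogue of an animal-level
  random intercept.
* **Noise** is Gaussian, band-limited below 500 Hz, with SD `noise_sd`
  (default 8 µV) *after* band-limiting.
* **Group effects** apply to the MODEL group per component × adaptation ×
  luminance range: amplitude scale (multiplicative), amplitude shift
  (subtractive µV), latency shift (ms). The group-level amplitude is
  \(\max(0,\ s\,V(I) - d)\), multiplied afterwards by the animal factor — so
  the conditional-median group difference at every luminance is exactly the
  configured shift \(d\) (the animal factor has median 1), which is what
  makes an injected shift a well-defined pooled truth for recovery testing.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| cohort | 13 WT / 22 MODEL | the reference study design |
| protocol | 0.01–25 cd·s·m⁻², 8 steps | ~0.5 log-unit spacing, the conventional series |
| sampling rate | 2000 Hz | unpublished in the source; comfortably above twice the 300 Hz OP band edge; configurable |
| record | −20 … 250 ms | covers baseline, b-wave and PhNR search windows |
| DA b-wave | 600 µV, K = 0.05, n = 0.7 | large, sensitive rod-driven response |
| DA a-wave | 250 µV, K = 1 | appears at moderate flashes, saturating high |
| LA b-wave | 120 µV, K = 3 | small cone-driven response, absent at dim flashes |
| LA PhNR | 40 µV, K = 1.5 | measurable at ≥ 1 cd·s·m⁻², clearly above the smoothed noise floor |
| `animal_sd` | 0.12 | ~12% between-animal amplitude scatter; chosen once to give plausible bootstrap CI widths (the source reports no numerical within-group variability) |
| `noise_sd` | 8 µV | lets OP detection succeed at high luminance while reliability flags trigger at dim LA flashes |

The kernel geometry was chosen so that components overlap by less than
0.5 µV at each other's measurement cursors (e.g. the b-wave kernel
contributes < 0.001 of its peak at the a-trough), keeping the configured
amplitudes and the measured trough-to-peak quantities consistent.

### Two flavours of ground truth

`synth_cohort()` returns, per recording, the **configured** truth (kernel
amplitudes and peak times after all scalings) and the
**measurement-convention** truth (`*_conv` columns): brute-force cursor
scans of the noise-free composite trace under the same windows and
smoothing. They differ where the convention itself creates offsets — the
b-wave is trough-to-peak, so its convention truth includes the a-trough
depth by definition. Recovery tests assert that extraction on noise-free
cohorts reproduces the convention truth to 0.5 µV and one sample;
configured-truth equality is asserted on isolated single-component
waveforms, where the two notions coincide.

### The shipped effect configuration

`paper_effects()` injects the reference two-group pattern: a pooled DA
b-wave reduction of 130.49 µV; a DA OP delay of 0.7925 ms per wavelet
(3.17 ms on the summed four-peak measure); a 1.01 ms DA a-wave delay at
flashes ≤ 0.3 cd·s·m⁻² only; and a uniform LA PhNR reduction of 6.79 µV.
Real data additionally show the PhNR deficit peaking at the brightest flash
(about 17.7 µV at 25 cd·s·m⁻²); we deliberately do **not** inject that
luminance-varying component, because under a parallel-shift estimand a
luminance-dependent shift makes the pooled truth ill-defined — empirically
it biased the pooled estimate to ≈ −8.9 µV and collapsed CI coverage of the
6.79 µV truth. A green recovery test therefore establishes that the
pipeline recovers a *uniform* injected shift; it does not establish
recovery of luminance-varying effect profiles.

## Statistical design

The estimand is the median MODEL − WT difference of one component measure,
adjusting for flash luminance. The paper-style linear quantile mixed model
(random-intercept median regression) is implemented as:

* a pooled **median regression** (τ = 0.5) of the measure on a MODEL
  indicator and \(\log_{10}\) luminance (luminance enters in log units, the
  scale on which the protocol is spaced);
* **animal-level cluster bootstrap** inference: whole animals are resampled
  with replacement within group, honouring the repeated measures per animal.
  The two-sided p-value is the symmetrized null-centred percentile
  \((1 + \#\{|\hat\theta^*_b - \hat\theta| \ge |\hat\theta|\})/(B + 1)\),
  and the 95% CI is the interval that inverts the same statistic,
  \(\hat\theta \pm q_{0.95}(|\hat\theta^*_b - \hat\theta|)\) — so
  \(p < 0.05\) exactly when 0 falls outside the CI. `n_boot` ≥ 1000
  (default 2000). (The per-group medians plotted in luminance-series
  reports use plain percentile bootstrap CIs, `bootstrap_median_ci()`.)

This preserves the estimand (median group difference with animal-clustered
uncertainty) without the asymmetric-Laplace quadrature machinery of a full
mixed quantile fit, which is out of scope.

Per-luminance follow-ups fit the within-stratum median difference with the
same cluster bootstrap and carry two significance flags: nominal
(`p < α = 0.05`) and Bonferroni (`p < α/m`; 0.05/8 = 0.00625, displayed
0.0063). Bonferroni flags are a subset of nominal flags by construction.

### The quantile-fit solver

No linear-programming quantile solver is available in the target
environment, so `fit_quantile()` is self-contained: a smoothed
iteratively-reweighted (MM) scheme with a shrinking smoothing parameter,
finished by exact minimization along coordinate directions and along the
edge directions of the vertex spanned by the p smallest residuals (an
optimal solution interpolates p observations). Each 1-D step is an exact
weighted-quantile breakpoint scan, so the finisher terminates at a point
where no basis edge improves the pinball loss — a global LP optimum. Tests
verify it beats dense coefficient grids and random probes and that the
intercept-only fit returns the sample median exactly (odd n).

Two numerical caveats are documented behaviour: with many repeated design
rows the LP optimum can be a tie *face* rather than a vertex, so
coefficients are determined only to within that face (observed ~0.02 µV on
cohort-sized problems); and degenerate (rank-deficient) designs are flagged
`degenerate` rather than solved.

### Calibration

The package asserts its own statistical calibration in the acceptance
suite: the overall test's type-I error over 400 null-effect cohort
simulations must lie in [0.025, 0.085] at nominal 0.05, and
`bootstrap_median_ci()` coverage over 500 standard-normal replications
(n = 50) must lie in [0.92, 0.98].

## What a green test run does and does not establish

The simulator emulates: saturating luminance–response growth,
luminance-dependent latency, component overlap, a 70–300 Hz OP burst,
animal-level amplitude clustering, band-limited noise, absent/small LA
responses at dim flashes, and uniform injected group effects. It does
**not** emulate: biophysical phototransduction dynamics (no saturating-PIII
a-wave, no capacitive a-wave "nose"), the photopic-hill non-monotonicity of
bright-flash LA amplitudes, luminance-varying group effects, trial-to-trial
(within-stimulus) variability, electrode drift, or non-Gaussian artifacts.
Green parameter-recovery tests therefore certify the pipeline's correctness
on this stated world, not the biological fidelity of the world itself; and
no synthetic result reproduces any real cohort's numbers, which depend on
unavailable raw data.

## Known limitations

* The pooled model treats luminance as a linear log-luminance term; a
  saturating true median profile makes this a working approximation whose
  group contrast remains unbiased only for group effects that are constant
  across luminance (see the effect-configuration discussion above).
* OP peak times are quantized to the sample grid (0.5 ms at 2000 Hz), so a
  3.17 ms injected timing sum difference is recovered as 3.0–3.5 ms.
* The cluster bootstrap's percentile CI can undercover slightly with few
  clusters; with 13 + 22 animals the observed coverage in the acceptance
  studies is compatible with the nominal 95%.
* `synth_biomarker()` implements a linear negative link with Gaussian
  noise; it is a stand-in for a concentration assay, labelled synthetic.
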