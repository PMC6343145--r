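---
title: "Fingerprinting and quantitation methods in dilongqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting and quantitation methods in dilongqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilongqc)
```

## The problem and the measurement model

Guang Dilong — the dried body of the earthworm *Pheretima aspergillum* — is
commonly adulterated with *Metaphire magna* and *Amynthas obscuritoporus*.
On a 260 nm LC-DAD trace, all three species show hypoxanthine, xanthine,
uridine, inosine and guanosine; only the adulterants also show adenosine.
Quality control therefore combines two layers: a *chromatographic
fingerprint* (is the pattern of common peaks consistent with authenticated
material?) and *marker quantitation* (is adenosine present, and at what
content?).

`dilongqc` treats a chromatogram as a uniformly sampled intensity trace
$x(t)$ (mAU, minutes). The simulated instrument writes

$$x(t) = \sum_a \frac{A_a}{\sigma\sqrt{2\pi}}
         \exp\!\left(-\frac{(t-\mu_a-\delta_a)^2}{2\sigma^2}\right)
       + D\sin\!\left(\frac{2\pi t}{T}+\phi\right) + \varepsilon(t),$$

with per-analyte area $A_a = a_a c_a + b_a$ (the published calibration line
reused as the true response, clipped at zero; a concentration of exactly
zero emits no peak), peak width $\sigma$, retention-time jitter
$\delta_a \sim N(0, \tau^2)$, one slow drift sinusoid over the run span $T$,
and white noise $\varepsilon \sim N(0, s^2)$. Because the response model and
the calibration lines coincide, quantitation round-trips exactly — which is
what makes the published per-batch contents usable as exact fixtures.

## Default parameters and why

| parameter | default | unit | rationale |
|---|---|---|---|
| grid | 0–16 by 0.01 | min | covers the 0–15 min gradient window with margin; 0.6 s sampling |
| `peak_sigma` | 0.05 | min | ~7 s base width, typical of sub-2 µm UHPLC peaks; 5 grid points per sigma keeps trapezoid integration effectively exact |
| retention times | 3.20, 4.60, 6.10, 9.35, 11.20, 13.40 | min | inosine is anchored at 9.35 min (the reference peak); the others are fixture constants in elution order, spaced ≥ 1.2 min so assignment is unambiguous |
| `noise_sd` | 0.05 | mAU | a realistic UV detector noise floor; peak heights are hundreds to thousands of mAU, so true peaks sit far above it |
| `drift_amplitude` | 0.2 | mAU | slow baseline wander well within what opening-based correction removes |
| `rt_jitter_sd` | 0.01 | min | 0.6 s run-to-run variation, an order of magnitude below the matching tolerance |
| `rt_tolerance` | 0.10 | min | > 10x the grid step and jitter, « the inter-peak spacing |
| `min_snr` | 10 (quantifiable), 3 (detectable) | — | the LOQ / LOD conventions |
| `prevalence_threshold` | 0.9 | — | a characteristic peak must appear in ≥ 90% of batches |
| `similarity_floor` | 0.80 | — | advisory only, motivated by the 0.811 empirical minimum of authenticated batches |

Batch compositions are sampled log-uniformly within the per-species content
ranges observed across the 42 reference batches. The distribution between
batches is genuinely unknown; log-uniform spans the printed variability
without asserting more than the ranges, and it is declared here once rather
than tuned. Where an implied extract concentration exceeds an analyte's
linear range, the generator applies the smallest integer dilution and
records it — a declared stand-in, since the reference protocol is silent on
dilution even though several printed contents imply concentrations above
the calibrated ranges (e.g. inosine 2692 µg/g ⇒ ~135 µg/mL against an
83.2 µg/mL ceiling).

## Signal processing

**Baseline.** The baseline estimate is a lightly smoothed morphological
opening (rolling minimum then rolling maximum, structuring width 1 min) of
the pre-smoothed trace. Opening is anti-extensive and reproduces constants
and linear ramps exactly while deleting any feature narrower than the
window, so correction is idempotent up to the noise level. Pre-smoothing
(0.2 min moving average) stops the noise floor from biasing the rolling
minimum downward.

**Peak detection.** Apex candidates are local maxima of a 9-point smoothed
copy, thresholded on baseline-corrected height (default 3x a robust noise
floor, `mad(diff(y))/sqrt(2)`) and on S/N. Noise apexes riding on peak
flanks are pruned by prominence: an apex must rise at least half its height
above the deeper of its flanking valleys, measured on the smoothed trace.
Integration bounds walk outward tracking the running minimum and stop
either where the trace falls below a tiny fraction of the apex height
(`bound_frac`, default 1e-6 — effectively baseline-to-baseline, so
noiseless areas are analytic to ~1e-5) or where it climbs a
noise-calibrated rise above the running minimum (the valley before an
adjacent peak; shared valleys split at the minimum — a perpendicular drop).
A 1 min half-width cap stops bounds wandering through flat noise. Areas are
trapezoid integrals of the *unsmoothed* corrected trace; heights are read
from it too, so smoothing never attenuates reported quantities.

**S/N.** Defined as baseline-corrected height over the standard deviation
(n−1) of a peak-free quiet window — the simplest auditable convention; the
reference instrument's convention is unpublished. A noiseless window yields
`Inf`.

## Fingerprinting

Common peaks are single-linkage clusters of pooled apex times: a new
cluster starts at any gap larger than the tolerance, and clusters wider
than twice the tolerance are split at their largest internal gap (ties
toward the earlier-eluting side). With 0.01 min jitter against a 0.10 min
tolerance, no time warping is needed; retention-time normalization reduces
to assignment against cluster mean times. The reference peak is, by
default, the highest-mean-area peak present in every batch — on authentic
material that is inosine at 9.35 min, since inosine dominates the content
ranges; a `fixed-rt:<t>` strategy is available as an override and selects
the same peak on the default fixtures.

The similarity index is the Pearson correlation between a batch's
baseline-corrected trace and the *mean fusion* chromatogram (the pointwise
mean over the reference batches), computed on the full grid. Correlating
full traces rather than the 5–6 dimensional relative-peak-area vector is a
deliberate choice: with so few peaks the peak-vector correlation is
unstable to a single constituent, while the full-trace correlation is
dominated by shared peak positions and relative intensities. The
peak-vector mode (`rpa_similarity()`) and a cosine mode are provided as
options. Characteristic peaks are common peaks with prevalence ≥ 0.9: five
on authentic studies (no adenosine), six on either adulterant species.

## Quantitation and validation

Calibration is ordinary least squares of area on concentration (`stats::lm`),
with `r` the Pearson correlation — reported as the correlation coefficient,
not R². LOD and LOQ interpolate a measured (concentration, S/N) series
linearly at S/N 3 and 10, extrapolating the first segment down to zero
concentration if needed; a series that never reaches a target yields `NA`
with a warning rather than an error. Inversion is $(y-b)/a$ with sub-blank
signals clamped to zero (warning) and out-of-range values either rejected
or, inside the pipeline, permitted with the recorded dilution factor
reapplied. Measurements with S/N in [3, 10) are reported with a
`below_loq` flag instead of being censored; S/N < 3 maps to not-detected.

Validation simulates the replicate design (six intra-day injections, three
days, six preparations, five stability time points, three spiked
replicates at 100% of the sample's own amount, on the composition of
reference batch 23) and aggregates RSDs and recoveries. The inter-day RSD
is computed across the three day means; the alternative (all 18 values) is
equally defensible but unstated in the reference protocol, so one choice is
declared. Because the generator models only instrumental noise, drift and
jitter — not preparation or injection-volume variability — simulated RSDs
are orders of magnitude below the 0.1–2.8% seen on real extracts; the
validation criteria are upper bounds, so they remain meaningful, but
passing them says nothing about real-world preparation variance.

## Classification

The verdict is driven entirely by the adenosine marker: a detected
adenosine peak (S/N ≥ 3) means adulterant, regardless of the similarity
index, because authentic material contains none and even trace-level
presence is informative. Similarity below the floor only attaches a
"fingerprint-atypical" warning. This mirrors how the marker is actually
decisive for these species, and keeps the similarity index in its proper
advisory role — it guards against degraded or atypical material, not
against this specific adulteration.

## Numerical choices and degenerate inputs

- Trapezoid integration on a 0.01 min grid with sigma = 0.05 min is exact to
  well below 0.01%; the dominant area error is tail truncation at the
  bounds, ~1e-5 relative at the default `bound_frac`.
- Flat or all-zero traces yield an empty peak table (not an error); every
  analyte then reports not-detected.
- Equal-concentration calibration input raises a singular-fit error;
  zero-variance traces make the similarity undefined and raise an error.
- All generators are pure functions of (inputs, seed): seeding is local and
  the caller's RNG state is restored.
- Ties in reference-peak selection and cluster splitting resolve toward the
  earlier-eluting peak.

## Problem sizes used in the checks

The test-suite and the acceptance script work at the study's own scale:
42 batches (22 authentic / 20 adulterant), 6-level calibration series,
3-replicate recovery, 1601-point traces. Seed-sweep properties use 20
seeds for the similarity floor and end-to-end classification accuracy and
60 pure-noise traces for the false-positive rate, sizes at which the
binomial uncertainty of the checked rates is already far below the margins
being asserted.

## Known limitations

- Peaks are symmetric Gaussians: no tailing (EMG), co-elution,
  deconvolution or gradient physics. The detector is single-wavelength; no
  DAD spectral peak-purity assessment.
- The species content profiles are ranges from 42 batches; real sourcing
  variability (region, season) is richer than log-uniform sampling within
  min–max.
- The similarity floor of authenticated real material (0.811) emerges from
  composition variability in the simulation, but real traces also vary in
  ways the generator does not model (matrix peaks, baseline artefacts), so
  simulated similarities are optimistic.
- Classification accuracy of 100% on simulated studies reflects the clean
  separation built into the species profiles (adenosine ≥ ~129 µg/g in
  adulterants, absent in authentic material); real mixtures of authentic
  and adulterant material at low blend ratios would sit between and are not
  simulated.
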