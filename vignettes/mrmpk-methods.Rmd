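---
title: "Methods: simulated MRM assays, validation statistics and NCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated MRM assays, validation statistics and NCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmpk)
```

`mrmpk` implements a complete targeted LC–MS/MS bioanalytical workflow —
peak integration, response-ratio calibration, the FDA-style validation
battery and non-compartmental pharmacokinetics — together with a
synthetic-data generator that produces every input with known ground
truth. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot tell you
about real assays.

## The generative models

### Concentration–time profiles

Profiles come from a one-compartment model with first-order absorption
and elimination:

$$C(t) = \frac{F\,D\,k_a}{(V/F)\,F\,(k_a-k_e)}
 \left(e^{-k_e (t-t_{lag})}-e^{-k_a (t-t_{lag})}\right),\qquad t>t_{lag},$$

zero otherwise. This is the simplest model producing the single-peak
profiles typical of an oral dose; its analytic anchors,
$t_{max} = \ln(k_a/k_e)/(k_a-k_e)$ and
$\mathrm{AUC}_\infty = F D/(F\,(V/F)\,k_e)$, are what the NCA tests
recover. `ka = ke` is rejected (the closed form degenerates) and the
default `ka >> ke` avoids flip-flop kinetics, where the terminal slope
would reflect absorption rather than elimination.

Two documented presets target a metformin-like and a canagliflozin-like
single 850 mg / 50 mg oral dose:

| preset | dose (ng) | ka (1/h) | ke (1/h) | V/F (mL) | implied t½ | implied AUC∞ |
|---|---|---|---|---|---|---|
| MET-like | 8.5e8 | 0.58 | ln 2/6.03 ≈ 0.115 | 5.88e5 | 6.03 h | ≈ 12 576 ng·h/mL |
| CFZ-like | 5e7 | 0.55 | ln 2/8.19 ≈ 0.085 | 1.491e5 | 8.19 h | ≈ 3 963 ng·h/mL |

These are simulation presets, not fitted estimates. A known limitation:
with the CFZ-like ke, a one-compartment model cannot simultaneously match
that AUC∞ and a Cmax near 380 ng/mL, because
$C_{max}/\mathrm{AUC}_\infty = k_e e^{-k_e t_{max}} \approx 0.060$ caps
Cmax near 239 ng/mL at that exposure. The preset prioritises AUC∞, t½,
tmax and Kel; Cmax runs low. Matching all five would need a
multi-compartment model, which is out of scope.

### Measurement error and BLQ

Observed values are `c·(1 + N(0, cv)) + N(0, sd)`, truncated at zero —
a combined proportional + additive Gaussian model, the standard shape
assumed when bioanalytical assays report roughly constant RSD% across
levels. The default proportional CV is 5 % with no additive term, a
mid-range value for validated LC–MS/MS assays. Values below the LLOQ are
kept but flagged BLQ rather than deleted, so downstream BLQ policies stay
testable. All generators take an explicit integer seed and are
bit-reproducible.

### Calibration runs and chromatograms

Calibration/QC measurements are generated on a true response-ratio line
`ratio = slope·X + intercept` (presets: `0.0016·X − 0.0088` for MET over
50–5000 ng/mL, `0.0056·X − 0.0036` for CFZ over 10–1000 ng/mL), scaled
by per-lot factors and perturbed by the error model; the recorded
analyte/IS area pair reproduces the perturbed ratio exactly. Additive
noise, specified in concentration units, is mapped to ratio units through
the slope.

Chromatograms span 0–5 min sampled every 0.01 min (0.6 s, 501 points),
with Gaussian peaks (default σ = 0.05 min) at each transition's retention
time (MET 0.9, PPL 1.1, TDF 3.0, CFZ 4.5 min), amplitude proportional to
concentration, plus optional white noise. When simulating noise, set the
`baseline` offset well above the noise SD: intensities clamp at zero, and
a clamped noise floor would bias S/N estimates. What the generator does
*not* emulate: tailing/fronting peak shapes, co-eluting interferences,
retention-time drift, carryover, and heteroscedastic detector saturation.
Passing tests therefore demonstrate the correctness of the statistics,
not robustness to every chromatographic pathology.

## Numerical and design choices

**Peak bounds.** Integration bounds walk outward from the apex on a
5-point moving average and stop at the first flanking local minimum after
the smoothed trace drops below half its prominence (apex minus trace
minimum), or at a 0.5 % prominence floor, or at the trace edge. The
half-prominence qualifier walks over fluctuations near the top while
honouring the valley between partially resolved peaks; the 0.5 % floor —
rather than a coarser cut — keeps noise-free amplitude and area recovery
within 1 %, which is the round-trip guarantee the tests enforce. Height
is apex minus the linear baseline interpolated between the smoothed bound
intensities; with `baseline = "linear"` the area is invariant to constant
offsets, with `baseline = "none"` it is exactly additive over adjacent
sub-intervals.

**S/N.** Height divided by the SD of a peak-free noise region (default
the first 0.4 min; configurable, and rejected if it overlaps the peak).
A zero-variance region reports infinite S/N with a warning flag rather
than failing. LLOQ support is declared at S/N ≥ 10.

**Calibration.** `fit_calibration()` defaults to unweighted least
squares — consistent with reference lines quoted without weighting — and
offers `1/x` and `1/x²`. The pipeline's default config, however, uses
`1/x²`: with proportional response error over a 100-fold range,
unweighted fits concentrate leverage at the top and routinely push the
back-calculated LLOQ outside its ±20 % band, which is precisely why
weighted regression is standard bioanalytical practice. Acceptance bands
are inclusive (a deviation of exactly 15.00 % passes), and the curve
passes when ≥ 75 % of standards pass including the LLOQ and the highest
level. Negative back-calculated concentrations are reported with a BLQ
flag, not silently dropped; the range check carries a 1e−9 relative
guard so a standard at exactly the range edge is not flagged by round-off.

**Validation statistics.** Accuracy is `100·mean found/nominal` and
precision is the sample RSD (n−1 denominator); both are reported
round-half-away-from-zero to two decimals, matching how validation tables
are conventionally printed (base R's `round()` rounds half to even).
Inter-day statistics pool all replicates across days (n = 6 × 3) rather
than averaging day means. Stability is judged primarily against nominal,
with the stressed/fresh ratio reported alongside. Selectivity thresholds
are 20 % of the LLOQ response for analytes and 5 % for internal
standards, the FDA/EMA convention. The matrix factor is unnormalised
(per-analyte); an IS-normalised variant can be built from the same
per-lot table.

**NCA.** The default AUC method is linear-up/log-down — the logarithmic
trapezoid `(C₁−C₂)Δt/ln(C₁/C₂)` is exact on mono-exponential decay,
which is why the closed-form oracle tests hold to 1e−9. λz selection in
auto mode fits every contiguous terminal subset (last 3, 4, …, all
points strictly after tmax), maximising adjusted R², with exact ties
going to the larger subset; when fewer than three points lie strictly
after tmax (a profile already in pure decay), the tmax point joins the
pool. The regression uses a closed-form simple-regression path rather
than `lm()` so numerically perfect fits do not trigger spurious
warnings. BLQ policy: leading BLQ → 0, embedded and trailing BLQ →
excluded. Extrapolation beyond 20 % of AUC∞ is flagged unreliable.
Cohort SDs use the n−1 denominator, with SD 0 reported for single-subject
cohorts by convention.

**Pipeline.** A single config (R list or YAML overlay on
`default_config()`) drives all stages. Per-stage seeds are derived
deterministically from the base seed, every output carries an FNV-1a
fingerprint of the config, and identical config + seed gives
byte-identical bundles. The default cohort is 2 subjects, the size of a
small exploratory volunteer study; the QC battery uses 6 replicates × 3
days.

## Problem sizes used in testing

The test suite and the acceptance script run entirely on generated data:
200 seeded subjects for cohort half-life recovery, 50 seeds × 3 bias
levels (±10 %, 0) for QC-battery calibration, 40 seeded profiles for the
exhaustive λz subset oracle, 20–30 seeds for Monte-Carlo S/N and CV
checks, and 10⁴ replicates for the noise-model CV check. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands (e.g.
the battery-mean accuracy SE is ≈ 0.17 percentage points against a 1.5
point band).

## Known limitations

* One-compartment kinetics only; no lag-time variability, no
  multi-compartment or food-effect simulation.
* No peak deconvolution: partially resolved peaks are split at the
  valley minimum, which under-estimates both heights when overlap is
  severe.
* The simulated lot, stability and recovery effects are simple
  multiplicative factors; real matrix effects can be analyte- and
  level-dependent in ways the generator does not model.
* Vendor raw files and mzML are not parsed; chromatograms enter as CSV.
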