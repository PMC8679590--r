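---
title: "Methods: preclinical radioimmunoconjugate dosimetry with mirdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical radioimmunoconjugate dosimetry with mirdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The problem

A therapeutic radioimmunoconjugate — here an IgG antibody chelated to the
pure β-emitter ⁹⁰Y, with ¹¹¹In as its imaging surrogate — must be dosed so
that tumor receives a therapeutic radiation dose while no normal organ
exceeds its tolerance. Before first-in-human dosing, the whole chain runs on
preclinical data: γ-counter counts from blood samples and conjugate-view
planar γ-camera images of a nonhuman primate are converted to fractions of
the injected activity over time, integrated into time-integrated activity
coefficients (TIACs), mapped to absorbed dose per unit administered activity
on a reference adult phantom, and finally compared against organ dose limits
to find the dose-limiting organ and the maximum administrable activity.
`mirdose` implements that chain as composable, tested pieces, plus the
supporting assay models (saturation binding, serum stability, xenograft
bookkeeping) and a synthetic-data generator that provides analytic ground
truth for every stage.

## Quantification

**γ-counter pathway.** A counting standard (a diluted aliquot of the
administered solution) anchors everything:

- administered activity (cpm) = standard cpm × dilution × administered
  volume / counted volume;
- %ID/mL = (sample cpm / mL) / administered activity × 100.

The same arithmetic yields %ID/g when the sample amount is a mass; no
density assumption is ever introduced.

**Conjugate-view pathway.** Per view (anterior/posterior) and timepoint,
background counts-per-pixel (CPP) is estimated by *pooling* counts and
pixels over all background regions — four field-of-view corners for the
plain background, eight muscle regions for the body background. Pooling
(total/total) rather than averaging per-region ratios makes the estimate
invariant to how the same pixels are partitioned into regions; that
invariance is tested. Whole-body and calibration-source ROIs are corrected
with the corner CPP, organ ROIs with the body-background CPP. Anterior and
posterior net counts are combined by their **arithmetic mean** — not the
conventional geometric-mean conjugate-view estimator with attenuation
correction, because the upstream measurement protocol this package models
used a plain average and described no attenuation correction. The
calibration source, whose activity relative to the administered dose is
known from the γ-counter (`std_ratio`), converts image counts to %ID.

Negative net counts (faint organs at late timepoints) are **retained**, with
a classed warning. Clamping them to zero would bias the whole-body-minus-
organs remainder downstream; retaining them keeps the arithmetic unbiased at
the cost of occasionally unphysical single values.

## Noncompartmental analysis

`nca()` computes Cmax/Tmax from observed samples, AUC by trapezoid,
λ_z by log-linear regression, AUC₀–∞ = AUC₀–last + C_last/λ_z, T½ = ln2/λ_z,
CL = dose/AUC₀–∞, MRT = AUMC₀–∞/AUC₀–∞, Vss = CL × MRT. Choices where
commercial NCA tools have defaults and the protocol stated none:

- **Tail selection:** every run of the last k ≥ 3 points that starts
  strictly after Tmax and is everywhere positive is a candidate; the best
  adjusted R² wins, ties broken toward more points. This mirrors the
  default automatic selection of the standard tools.
- **Trapezoid rule:** linear throughout by default, with `"linuplogdown"`
  available as a switch. Linear is the common default and keeps AUMC simple;
  the log-down variant integrates falling exponentials exactly and is
  covered by a test.
- Extrapolated AUC fraction > 30% warns (classed) but does not error —
  slow-clearing antibodies sampled over ~1.5 terminal half-lives genuinely
  live in that regime.
- AUC runs from the first observed sample; no back-extrapolation to t = 0
  is attempted. For the sampling schedules modeled here the missed sliver is
  ≪0.5% and both the pipeline and its oracles share the convention.

## Humanization and TIACs

Blood: %ID/mL → FIA/mL (= %ID/100) → ⁹⁰Y decay imposition
(× 0.5^(t/64 h)) → humanization (× monkey mass / 73,700 g) → scaling so the
peak whole-blood content equals 1 (peak scaled FIA/mL = 1/5,300 mL⁻¹ by
construction — an invariant the tests enforce for arbitrary input curves).
The integral of the scaled curve (h/mL) feeds the blood-based red-marrow
method: T_marrow = T_blood/mL × 1,120 g × 0.19 / (1 − 0.47) ≈
T_blood/mL × 401.51 mL.

Organs: imaging with a co-counted calibration source self-corrects the
imaging nuclide's physical decay, so organ curves are treated as biological
retention and the therapy nuclide's 64 h decay is imposed before
integration (`decay_organs = TRUE`; the alternative reading — integrating
the measured effective activities directly — sits behind the same flag).
The remainder of body is whole body minus the four imaged organs. The
blood-derived red marrow is *not* subtracted when forming the remainder:
marrow activity is inside the measured whole body, but no double-counting
correction is described for the protocol modeled here, and inventing one
would change the remainder by an unverifiable amount.

A useful physical bound, used as a property test: any max-normalized curve
with imposed 64 h decay integrates to at most 64/ln2 = 92.33 h.

## The simplified dose engine

For a pure β-emitter the particle range is millimetric, so the engine takes
the self-absorbed fraction as 1 and cross-organ β dose as 0:

- S_self = Δ/m, with Δ = mean β energy × 1.602×10⁻¹³ J/MeV × 3.6×10⁹
  decays/(MBq·h); for ⁹⁰Y (0.9337 MeV) and 1,000 g, 0.5385 mGy/(MBq·h);
- D(target) = TIAC(target) × S_self(target) + TIAC(remainder) × Δ/M_body
  (uniform remainder irradiation);
- heart *contents* (the imaged blood pool) deposits its self-dose in the
  heart *wall* target via an explicit, configurable source→target map;
- total body = Δ × ΣTIAC / M_body (the mass-weighted mean dose);
- osteogenic cells are reported `NA`: they require a skeletal dosimetry
  model this engine deliberately does not contain.

Consequently published organ-dose tables produced by full phantom codes
(photon cross-dose, bremsstrahlung, skeletal model) are **planning inputs**
here, shipped as fixtures — never a reproduction target. The engine's
contracts are its linearity in every TIAC, inverse-mass scaling, and the
uniform-remainder identity, all tested; a spleen worked example (TIAC 4 h on
183 g → 11.77 mGy/MBq) lands at the same order as the corresponding
published value (12.0), which is exactly the agreement the approximation
promises — no more.

## Dose planning and interspecies conversion

Max activity per organ = limit/dose with limits 3,000 mGy (red marrow) /
20,000 mGy (any other organ); the dose-limiting organ is the argmin.
Reported activities are rounded half-up to integer MBq and mg/kg doses to
two decimals — the conventions that reproduce every printed planning value.
"Total body" and "osteogenic cells" rows participate under the generic limit
(they never bind with these limits); an `exclude` argument removes them if a
stricter reading is wanted.

Interspecies conversion uses fixed km factors (mouse 3, cynomolgus 12,
human 37): mg/kg × km = mg/m², and a per-animal mouse dose uses the 25 g
reference mouse. Activity extrapolation uses MBq/kg × km_mouse = MBq/m² and
a 1.89 m² reference-adult BSA. The 60 kg/km = 37 pairing and the 1.89 m²
BSA imply slightly different humans; both constants are kept and each is
used only in the conversion that uses it, because together they reproduce
every printed conversion exactly — they are reverse-validated constants,
not derived ones.

## Assay models

Saturation binding uses y = Bmax·x/(Kd + x) on specific binding (total
wells minus negative-control wells per concentration — per-concentration
subtraction, not a fitted linear nonspecific component). Fitting is
unweighted nonlinear least squares (the common graphing-software default;
1/y² weighting is an option) via `nls` with the `port` algorithm — the
default Gauss-Newton rejects exactly-fitting noiseless data, which the
round-trip tests require. Initialization: Bmax₀ = max bound, Kd₀ =
interpolated half-saturation concentration. The Scatchard transform is
provided for display only; no fitting happens in transformed coordinates.

Tumor volume is L×S²/2; the euthanasia rules are weight < 80% of baseline,
or tumor exceeding 10% of body weight under the documented assumption
1 mm³ ≡ 1 mg of tumor tissue (the rule is stated without a units bridge;
this is the standard reading).

## The synthetic world

The generator states one fixed world, chosen once:

- **Mouse blood:** FIA/mL(t) = 0.103·e^(−1.2t) + 0.26·e^(−(ln2/260)t), so
  the 5-min sample reads ≈35.3 %ID/g and the terminal biological half-life
  is ~260 h — the intact-IgG picture in mice.
- **Monkey:** blood 0.0012·e^(−2.5t) + 0.004·e^(−(ln2/147)t) FIA/mL
  (peak ≈0.5 %ID/mL, T½ ≈147 h); organs follow f·(e^(−k_w t) − e^(−k_u t))
  with fractions/rates set so 3 h values sit at ≈8 (heart), 11 (liver),
  3 (spleen), 5 (lungs) %ID; whole body 0.754·e^(−0.00188t) (≈75 %ID at
  3 h, ≈55 %ID at 168 h). These are plausibility calibrations to the
  reported ranges, not estimates of any real animal's kinetics.
- **Planar projector:** exact inverse of the quantifier in noiseless mode.
  Anterior/posterior counts are (1±0.1)× the true net so their arithmetic
  mean is exact; backgrounds are uniform CPP surfaces. Noise is Poisson on
  counts and multiplicative lognormal (given CV) on continuous
  measurements — the standard counting-instrument model.
- **Binding assay:** 8-step 2-fold dilution from 20 nM, one-site specific
  binding plus a linear nonspecific component carried by negative-control
  wells.
- **Tumors:** V(t) = V₀[(1−e)·exp(gt) + e·exp(−dt)] from 200 mm³, n = 6 per
  group, twice-weekly calipers.

Truth sidecars carry closed-form integrals (organ TIACs under imposed decay
are integrated over [first imaging time, ∞), the same support the numeric
pipeline sees). What a green test establishes: the pipeline inverts its own
stated measurement model and integrates to analytic truth within stated
tolerances. What it does not establish: attenuation/scatter behavior, organ
overlap in projections, inter-animal variability — the generator does not
emulate image-domain physics at all.

## Numerical choices and degeneracies

- Rounding: analysis is full precision; half-up rounding only at report
  emission.
- Errors are classed conditions (`mirdose_insufficient_data`,
  `mirdose_incomplete_timepoint`, `mirdose_inconsistent_tiacs`, …) so
  callers can branch without string matching; pipeline stages re-raise them
  with a stage label.
- Degenerate inputs: all-zero curve → TIAC 0; curve ending at 0 → no tail
  extrapolation; constant binding → non-converged flagged fit; organ TIACs
  exceeding whole body → hard error (inconsistent measurement, not noise).
- Config files are JSON (phantom, nuclide, limits, species): no YAML parser
  is assumed on the deployment target, and JSON round-trips through
  `jsonlite` losslessly.

## Known limitations

- The dose engine is deliberately order-of-magnitude physics: no photon or
  bremsstrahlung cross-dose, no skeletal model, adult-male phantom only.
- NCA is single-curve; no population/sparse-sampling support.
- The conjugate-view quantifier implements the arithmetic-mean protocol it
  models; it is not a general geometric-mean conjugate-view code.
- Excretion pathways are not modeled (whole-body decline absorbs them).

```{r example}
# one noiseless end-to-end run
spec <- default_monkey_spec()
organs <- gen_organ_curves(spec)
blood <- gen_blood_curve(spec)
std <- counting_standard(2e5, 1, dilution_factor = 1000, administered_volume = 2)
cfg <- run_config(
  planar_rois = gen_planar_study(organs$curves, calibration_ratio = 1e-3),
  gamma_counts = gen_gamma_counts(blood$curve, std),
  counting_standard = list(monkey1 = std),
  calibration_ratio = 1e-3, body_weight_kg = spec$body_weight_kg,
  therapeutic_mbq = 1678)
res <- suppressWarnings(run_pipeline(cfg))
res$tiacs
res$plan
```
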