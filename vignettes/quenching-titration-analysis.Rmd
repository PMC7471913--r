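---
title: "Fluorescence quenching titration analysis: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence quenching titration analysis: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchfit)
```

## The measurement and the model

When a nanoparticle binds near a protein's intrinsic fluorophores
(chiefly tryptophan), the emission intensity drops. Titrating a fixed
protein concentration with increasing quencher concentration $[Q]$ and
recording the peak emission intensity $F$ against the quencher-free
reference $F_0$ yields the raw material for four classical analyses,
all implemented here on a single shared data model
(`titration_series` / `titration_set`).

All four are views of one generative family,

$$F = \frac{F_0}{1 + K [Q]^n},$$

with association constant $K$ (units $\mathrm{mol}^{-n}\,\mathrm{L}^{n}$)
and Hill/site coefficient $n$:

* **Stern–Volmer** ($n = 1$): $F_0/F = 1 + K_{SV}[Q]$. The slope
  $K_{SV}$ measures quenching efficiency; $K_q = K_{SV}/\tau$ is the
  bimolecular quenching rate given the unquenched fluorophore lifetime
  $\tau$.
* **Double-log binding plot**:
  $\log_{10}\frac{F_0 - F}{F} = \log_{10} K + n \log_{10} [Q]$, which
  the family satisfies *exactly*, since $(F_0 - F)/F = K[Q]^n$.
* **Hill plot**: the same line in natural logarithms,
  $\ln\frac{F_0-F}{F} = n \ln [Q] - n \ln k_D$, so the dissociation
  constant obeys $k_D = K^{-1/n}$ (the textbook $K = 1/k_D$ is the
  $n = 1$ special case; the package always applies the general
  relation and reports both constants).
* **Hill saturation model** on the quenching fraction
  $Q = (F_0 - F)/F_0$:
  $Q/Q_{max} = [Q]^n / (k_D^n + [Q]^n)$, which the family reproduces
  with $Q_{max} = 1$. `hill_saturation_fit()` fits this nonlinearly
  (Levenberg–Marquardt, parameter tolerance $10^{-10}$), optionally
  with $Q_{max}$ held fixed, and provides an independent cross-check of
  the linearized fits.

Because the three linearizations are algebraically consistent *only*
under this family, it is also the synthetic-data model
(`generate_titration()`): a fit applied to noiseless generated data
must return the generating parameters to numerical precision, and the
test suite holds every estimator to that round trip at $10^{-6}$
relative or better.

Thermodynamics comes from the temperature dependence of $K$:
$\Delta G^0 = -RT\ln K$ per temperature, and the van't Hoff regression
$\ln K = -\Delta H^0/(RT) + \Delta S^0/R$ across temperatures
($R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$, fixed). The sign pattern of
$(\Delta H^0, \Delta S^0)$ labels the dominant intermolecular force:
both positive — hydrophobic; both negative — van der Waals / hydrogen
bonding; $\Delta H^0 < 0,\ \Delta S^0 > 0$ — electrostatic. Any other
pattern, or an enthalpy within `zero_tol` of zero, is reported as
indeterminate, so every point of the plane receives exactly one label.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tau` | `1e-8` | s | fluorophore lifetime converting $K_{SV}$ to $K_q$; the conventional average for intrinsic biomacromolecule fluorophores |
| `kq_ceiling` | `2e10` | L/(mol s) | diffusion-controlled maximum of $K_q$; exceedances are *advisory* flags |
| `coop_tol` | `0.15` | — | half-width of the non-cooperative band around $n = 1$ |
| `zero_tol` | `500` | J/mol | half-width of the "$\Delta H^0 \approx 0$" band in the force rules |
| `vant_hoff_source` | `"binding"` | — | whether the van't Hoff fit consumes double-log association constants or Stern–Volmer constants |

Two of these deserve comment. The mechanism call (dynamic vs static
quenching) rests on the **sign of the OLS trend of $K_{SV}$ versus
$T$**, not on strict monotonicity and not on the $K_q$ ceiling: with
three temperatures a significance test has no power, and the ceiling
comparison — while conventionally read as evidence of static
quenching — frequently contradicts the temperature trend on real
titrations. The trend takes precedence; the ceiling result is kept as
a flag. Likewise the Stern–Volmer intercept is estimated freely rather
than forced to its theoretical value of 1; forcing it would bias the
slope whenever the first titration point departs from the model, so
deviations beyond 0.1 are flagged instead.

The cooperativity tolerance of 0.15 reflects how site numbers from
6-point log-log regressions are read in practice: estimates in the
high 0.8s are routinely called "approximately one site", and a band
of $\pm 0.15$ encodes that reading while still letting genuinely
cooperative systems ($n$ of 1.5, or 0.5) be labelled as such.

## The synthetic generator

`synthetic_spec()` defaults describe a desk-scale titration typical of
protein–nanoparticle corona studies: fixed protein (0.58 µM scale),
six quencher concentrations at 8, 16, 32, 64, 96 and 128 µM,
temperatures 298.15 / 310.15 / 320.15 K, and peak-intensity readout.
Noise is **multiplicative Gaussian on $F$** — fluorescence noise
scales with intensity — truncated by resampling to keep $F > 0$.
$F_0$ is published noise-free by default so the ground truth of the
quenching fraction stays exact for oracle tests (`noisy_f0 = TRUE`
enables the realistic variant). The generator is deterministic for a
fixed seed and restores the caller's RNG stream.

What it deliberately does *not* emulate: inner-filter absorption,
photobleaching, instrument drift, buffer-background structure, or
competition between plasma proteins. Passing round-trip tests on
generated data therefore demonstrates estimator correctness under the
stated noise model, not robustness to those artifacts.

## Numerical choices and degenerate inputs

* Concentrations are converted to mol/L once, at CSV parse time; the
  unit is declared per file, never per row, because titration tables
  habitually mix µM text with M constants and a single canonical unit
  prevents silent $10^6$ errors.
* $F_0$ comes from the zero-concentration row when present; an
  explicit `f0` column overrides it, and a disagreement beyond 0.1%
  relative is an error rather than a silent preference.
* Points with $F \ge F_0$ have no defined log transform; they are
  **dropped and listed**, never clamped — clamping would bias both
  slope and intercept.
* A constant series ($F = F_0$ everywhere) is a legitimate input:
  the Stern–Volmer slope is 0 with intercept 1, and the zero total sum
  of squares is scored as a perfect fit rather than `NaN`.
* A Hill plot with non-positive slope leaves $k_D$ undefined and is a
  degenerate-fit error; the nonlinear fit reports non-convergence with
  its starting values attached.
* The pipeline never aborts on advisory inconsistencies (intercept
  away from 1, $K_q$ above the ceiling, non-monotone $K_{SV}$); it
  completes and aggregates each warning exactly once in `flags`.

## Known limitations

The association constant from the double-log intercept is an
**extrapolation**: with the 8–128 µM design the centroid of
$\log_{10}[Q]$ sits about 4.5 decades below $[Q] = 1$ M, so slope
noise is amplified ~4.5-fold into $\log_{10} K$. Under 1%
multiplicative intensity noise the site number is recovered with a
median relative error of about 2%, but $K$ itself carries a median
relative error near 16–18% — the fitted line is accurate where the
data live (the regression value at the design centroid is an order of
magnitude more stable than the intercept), and the $K$ and $n$ errors
are almost perfectly correlated. `scripts/acceptance.R` measures both
numbers on 200 seeded replicates. By the same mechanism, a van't Hoff
regression of three noisy constants over a 22 K span propagates the
$K$ scatter into $\Delta H^0$ strongly; on real three-temperature
designs the *signs* of $\Delta H^0$ and $\Delta S^0$ (and hence the
force label) are far more robust than their magnitudes.

The thermodynamic analysis assumes $\Delta H^0$ and $\Delta S^0$
constant over the range (no heat-capacity term), and the package does
not model combined static+dynamic (sphere-of-action) quenching,
multi-site heterogeneous affinity, or fluorescence-lifetime data.

## Problem sizes used in validation

The shipped tests run entirely on generated data: 6-point series at up
to three temperatures, 50–200 noise replicates for recovery studies,
and 1000 single-point replicates for the noise-scaling check. The
acceptance script reruns the published-constant arithmetic
(instantaneous) plus the 200-replicate recovery study; everything
completes in seconds on one CPU.
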