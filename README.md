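# quenchfit

Analysis of protein–nanoparticle binding from intrinsic fluorescence
quenching titrations.

When a nanoparticle adsorbs a protein — the protein "corona" that forms
around any particle in plasma — the protein's tryptophan fluorescence is
quenched, and the shape of the intensity-vs-concentration curve encodes
the binding constant, the number of binding sites, the quenching
mechanism, and the thermodynamic driving force of the interaction.
`quenchfit` implements the full classical analysis chain for such
titrations, for spectroscopists and nanomedicine researchers who record
peak intensities $F$ at a fixed protein concentration over a quencher
concentration series $[Q]$, at one or several temperatures.

The four stages, all exact views of the single model
$F = F_0/(1 + K[Q]^n)$:

| Stage | Relation | Estimates |
|---|---|---|
| Stern–Volmer | $F_0/F = 1 + K_{SV}[Q] = 1 + K_q\tau[Q]$ | $K_{SV}$, $K_q$, dynamic/static mechanism from the $K_{SV}$-vs-$T$ trend |
| Double-log binding | $\log_{10}\frac{F_0-F}{F} = \log_{10}K + n\log_{10}[Q]$ | association constant $K$, binding sites $n$ |
| Hill | $\ln\frac{F_0-F}{F} = n\ln[Q] - n\ln k_D$, and $Q/Q_{max} = \frac{[Q]^n}{k_D^n + [Q]^n}$ | $k_D = K^{-1/n}$, cooperativity label |
| Thermodynamics | $\Delta G^0 = -RT\ln K$, $\ln K = -\frac{\Delta H^0}{RT} + \frac{\Delta S^0}{R}$ | $\Delta G^0$, $\Delta H^0$, $\Delta S^0$, dominant-force label |

A seeded synthetic titration generator built on the same model provides
ground truth for every estimator, so the whole chain is testable without
laboratory data.

## Worked example

Simulate a three-temperature titration (6 points, 8–128 µM, 1%
intensity noise) whose association constants follow a van't Hoff
relation with ΔH⁰ = −16.1 kJ/mol and ΔS⁰ = +13.3 J/(mol K), then run
the full pipeline:

```r
library(quenchfit)
ts  <- generate_titration_set(vant_hoff_spec(-16100, 13.3), hill_n = 0.89,
                              noise_rel = 0.01, seed = 42)
res <- run_pipeline(ts)
res
```

```
== Quenching ==
Stern-Volmer fit at 298.15 K: Ksv = 8592 L/mol, intercept = 1.036, R2 = 0.9988
  Kq = Ksv/tau = 8.592e+11 L/(mol s)  (tau = 1e-08 s, 6 points)
...
Quenching mechanism: static (Ksv-vs-T trend slope = -133.9 L/(mol K))
== Binding ==
Double-log binding fit at 298.15 K: K = 4690 mol^-n L^n, n = 0.9281 sites, R2 = 0.9966 (6 points)
...
== Cooperativity ==
Hill fit at 298.15 K: n = 0.9281, kD = 0.0001107 mol/L -> non-cooperative cooperativity
...
== Thermodynamics ==
Thermodynamics: dH0 = -15.11 kJ/mol, dS0 = 18.28 J/(mol K) -> electrostatic
  T = 298.15 K: K = 4690, dG0 = -20.95 kJ/mol (spontaneous)
  T = 310.15 K: K = 2194, dG0 = -19.84 kJ/mol (spontaneous)
  T = 320.15 K: K = 3230, dG0 = -21.51 kJ/mol (spontaneous)
```

Reading the output: the binding-site number stays near 1 at every
temperature (non-cooperative, single-site binding); all three Gibbs
energies are negative, so the association is spontaneous; the negative
enthalpy with positive entropy classifies the driving force as
electrostatic — and both recovered values sit close to the generating
−16.1 kJ/mol and +13.3 J/(mol K). Because the generated constants
*decrease* with temperature (ΔH⁰ < 0), the Stern–Volmer trend reads as
static quenching here; a data set with rising constants would be called
dynamic. The Kq flags illustrate the advisory diffusion-ceiling check:
apparent quenching rates above ~2×10¹⁰ L/(mol s) are reported but never
override the temperature-trend mechanism call.

Real data enter through a CSV
(`temperature_K,quencher_conc,intensity[,f0]`, zero-concentration rows
supply F₀):

```r
ts <- read_titration_csv("titration.csv", conc_unit = "uM")
validate_set(ts)                 # warnings, e.g. points with F >= F0
res <- run_pipeline(ts)
write_report(res, "report.json") # quenching/binding/cooperativity/thermodynamics/flags
plot_pipeline(ts, res)           # the four classical plots
```

A thin command-line front end with `simulate` and `analyze` subcommands
is installed at `system.file("cli", "quenchfit.R", package = "quenchfit")`.

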