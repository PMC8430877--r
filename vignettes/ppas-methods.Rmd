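---
title: "Methods: the PPAS uptake model and exposure estimation chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PPAS uptake model and exposure estimation chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppas)
```

## The measurement principle

A personal passive air sampler (PPAS) for chlorine gas is a thin
polydimethylsiloxane (PDMS) sheet doped with the redox dye *o*-dianisidine.
Chlorine diffuses into the gas-permeable polymer and oxidises the dye to
dianisidine quinonediimine, turning the patch green. Because the reaction is
irreversible, the dye consumed over a deployment integrates the exposure:
extracting the sheet and measuring how much reduced dye is left converts the
colour change into a time-weighted-average (TWA) air concentration, with no
pump and no instrument on the wearer.

This package implements the full analysis chain around such a sampler:
unit conversions and concentration–time (CT) dose metrics, processing of
reference PTR/SRI-MS isotopologue channel data, a forward model of sampler
uptake, the extraction-to-exposure estimation equations, a synthetic
chamber-experiment generator, and the inverse machinery (parameter fitting,
capacity estimation, changepoint detection) needed to characterise a
sampler from chamber data.

## Uptake model

Two processes move chlorine into the reacted pool. Diffusion from air into
the sheet follows Fick's first law with an overall (air-side plus
polymer-side) mass-transfer coefficient $k_O$:

$$F_\mathrm{diffusion} = k_O A_s \left(C_A - \frac{c_\mathrm{free}}{K_{SA}}\right),$$

where $A_s$ is the exchange area, $C_A$ the air concentration
(mol m$^{-3}$), $c_\mathrm{free}$ the dissolved *unreacted* chlorine in the
sheet and $K_{SA}$ the sampler–air partition constant. Consumption of
dissolved chlorine by the dye is first order:

$$F_\mathrm{reaction} = \frac{k_\mathrm{reac} A_s\, c_\mathrm{free}}{\delta}\, g(r),$$

with sheet thickness $\delta$ and a capacity-limiting factor $g$ that
depends on the remaining dye fraction $r = 1 - C_s/C_\mathrm{cap}$; $C_s$
is the cumulative reacted chlorine per sampler volume and $C_\mathrm{cap}$
the saturation capacity.

A single-pool description that composes these two fluxes as literal series
resistances, $1/(1/F_\mathrm{diffusion} + 1/F_\mathrm{reaction})$, is
degenerate at start-up: with nothing yet dissolved the reaction flux is
zero, forcing the total flux to zero, which contradicts the observed
initial linear uptake. The package therefore keeps the two pools distinct
(`simulate_uptake(mode = "two_state")`):

$$\frac{dc_\mathrm{free}}{dt} = \frac{F_\mathrm{diffusion} - F_\mathrm{reaction}}{V_s},
\qquad
\frac{dC_s}{dt} = \frac{F_\mathrm{reaction}}{V_s}.$$

The literal harmonic composition is retained as a diagnostic evaluator
(`total_flux_literal()`), not an integrator.

Because the dissolved pool is tiny and the reaction fast, $c_\mathrm{free}$
relaxes almost instantly to the balance point of supply and consumption.
Eliminating it gives the quasi-steady closed form
(`quasi_steady_flux()`):

$$F = \frac{A_s C_A}{\dfrac{1}{k_O} + \dfrac{\delta}{k_\mathrm{reac} K_{SA}\, g(r)}},$$

which reproduces both limiting behaviours the chamber data show: the
diffusion-limited early phase $F \to k_O A_s C_A$ (so $C_s$ grows linearly
at rate $R_s C_A / V_s$), and complete stalling, $F \to 0$, when the dye is
exhausted. `simulate_uptake(mode = "quasi_steady")` integrates this single
state and agrees with the two-state model far inside measurement noise
whenever the pool is fast; it is the default objective inside
`fit_uptake()` because it is two orders of magnitude cheaper than a stiff
two-state solve and the fitting regimes of interest are exactly the
regimes where the reduction is valid (the dissolved-pool transient at the
default parameters lasts ~1e-8 h).

### Capacity limiting

Two variants of $g$ are provided. The default, `"smooth"`, takes
$g(r) = r$: the reaction slows in proportion to the dye remaining, giving a
smooth exponential approach to the plateau. `"hard"` takes
$g(r) = \mathbf{1}(r > 0)$: full speed until exhaustion, the
piecewise-linear idealisation of the uptake curve. At the default
parameters the two differ only in a narrow window around saturation,
because the reaction resistance stays negligible until
$r \approx \delta k_O / (k_\mathrm{reac} K_{SA}) \sim 10^{-5}$.

### Parameters, units and defaults

| symbol | meaning | default | unit |
|---|---|---|---|
| $A_s$ | exchange surface area | 2.25e-4 | m$^2$ |
| $\delta$ | sheet thickness | 5.5e-4 | m |
| $V_s$ | sampler volume ($A_s\delta$ unless overridden) | 1.2375e-7 | m$^3$ |
| $R_s$ | calibrated sampling rate | 2.53e-3 | m$^3$ h$^{-1}$ |
| $k_O$ | overall mass-transfer coefficient | $R_s/A_s$ = 11.24 | m h$^{-1}$ |
| $k_\mathrm{reac}$ | dye reaction rate constant | 100 | h$^{-1}$ |
| $K_{SA}$ | sampler–air partition constant | 10 (assumed) | — |
| $C_\mathrm{cap}$ | reacted-chlorine capacity | 1.8 | mol m$^{-3}$ |
| stoich | mol dye per mol Cl$_2$ | 2 | — |

Notes on the choices:

* **Thickness.** The physical sheet is 0.55 mm; $\delta$ defaults to
  5.5e-4 m. Where a 5 mm value circulates for this geometry we treat it as
  a typographical slip — a 1.5 cm × 1.5 cm sheet of 5 mm thickness would
  be a block, not a patch — and the value is overridable in configuration.
* **$k_O = R_s/A_s$.** In the reaction-fast linear regime the model's
  effective sampling rate is $k_O A_s$ (`sampling_rate_identity()`).
  Anchoring $k_O$ to the calibrated $R_s$ makes the kinetic model and the
  exposure equation mutually consistent by construction.
* **$K_{SA}$** is not experimentally constrained; it only enters the
  reversible back-diffusion term, to which every reaction-fast result is
  insensitive. It is never fitted by default and is surfaced in
  `fit_uptake()` results as a fixed assumption.
* **Internal units**: hours for kinetics (matching $R_s$ in m$^3$
  h$^{-1}$), minutes for CT reporting (ppbv·min); conversions happen at
  the type boundary. Mixing-ratio conversions use the ideal gas law at
  explicit `gas_conditions()` (default 298.15 K, 101325 Pa — chamber
  conditions are rarely reported, so they are an explicit argument
  everywhere rather than a hidden constant).

A consequence worth noting: with the default geometry, a fully saturated
sampler corresponds to a CT of
$60 \cdot \mathrm{ppbv}(C_\mathrm{cap} V_s / R_s) \approx 1.29\times 10^5$
ppbv·min (the `capacity_ct_ppbv_min` quantity in the acceptance script),
independent of deployment time. This number is sensitive to $V_s$ and to
the temperature–pressure assumption, so capacity statements quoted as CT
values should always carry their geometry and conditions.

## Exposure estimation chain

From one extraction measurement (initial/blank dye concentration $C_i$,
final $C_f$, solvent volume $V_E$):

$$C_s = \frac{(C_i - C_f)\, V_E}{M_w\, V_s\, \mathrm{stoich}},
\qquad
C_{v,\mathrm{TWA}} = \frac{C_s V_s}{R_s\, t},$$

with $M_w = 244.30$ g mol$^{-1}$ for *o*-dianisidine and stoich $= 2$
exposed as a parameter rather than a magic ½. `cv_twa_from_cs()` converts
to ppbv, attaches the CT value and guideline flags (OSHA PEL and AEGL-1,
both 500 ppbv with AEGL-1 applicable from 10 min to 8 h; the thresholds
live in a configurable table), and sets a saturation flag at 90% of
capacity. A saturated sampler has stopped accumulating, so its TWA is
reported as a *lower bound*, never silently dropped. Replicate aggregation
(`batch_report()`) uses the sample (n−1) standard deviation. The blank
$C_i$ is taken from the matched blank samplers of the same batch when
available, otherwise from configuration.

## PTR/SRI-MS processing

The reference instrument records Cl$_2$ as three isotopologue channels at
m/z 70/72/74; their inside-minus-outside differences are summed and
inverted through a linear calibration (slope user-supplied; intercept
defaults to 0). The channel split follows the binomial combination of the
chlorine isotopes, $(p^2,\; 2p(1-p),\; (1-p)^2)$ at $^{35}$Cl abundance
$p = 0.7577$. Negative post-calibration values are floored at zero; if
more than 10% of points need flooring a baseline-drift warning is raised.
The TWA integral is discretised by the trapezoidal rule on the irregular
timestamps — exact for constant and piecewise-linear series, which is also
what the test suite asserts.

## Synthetic chamber experiments

The generator emulates a 125 L closed-chamber protocol so that every
pipeline stage is testable without laboratory data.

* **Emission shapes are phenomenological, not speciation chemistry.**
  Liquid and stock-solution scenarios rise as
  $C(t) = C_\infty(1 - e^{-kt})$ (default plateau 1160 ppbv, rise rate
  1 h$^{-1}$). Spray scenarios scale the plateau sublinearly with the
  number of sprays ($\mathrm{amount}^{0.7}$; a configuration default
  chosen to make 1/5/10-spray plateaus ordered and sublinear, not a
  claim). Gel scenarios emit in two linear phases: the early phase
  (up to a 1.5 h lag) runs at 1/6 of the late slope, representing the
  thickener-suppressed early release; the contrast is configurable.
  Hypochlorite pH speciation is deliberately out of scope — pH is carried
  as metadata only.
* **Noise model.** Multiplicative Gaussian noise, CV-parameterised
  (default 0.05), applied to extraction differences $C_i - C_f$ and,
  independently per channel, to PTR-MS responses. Note that channel-level
  noise partially averages out in the isotopologue sum: a per-channel CV
  of 0.05 yields an effective series CV of
  $0.05\sqrt{p_{70}^2+p_{72}^2+p_{74}^2} \approx 0.034$ — the noise
  pathway concentration series actually experience.
* **Determinism.** Every draw derives its seed from the scenario seed and
  a (deployment, replicate) counter, so regeneration is bit-for-bit
  reproducible and adding replicates never perturbs earlier ones. Draws
  that would imply dye creation are floored, with a warning when more
  than 1% of draws needed it.
* **What the generator does not emulate**: chamber wall losses, aerosol
  physics of sprays, humidity/temperature dependence of the kinetics, and
  instrument baseline drift. Passing closure tests therefore demonstrates
  internal consistency of the estimation chain, not field accuracy of the
  sampler.

## Inverse problems

`fit_uptake()` minimises the sum of squared $C_s$ residuals over a chosen
subset of $(k_O, k_\mathrm{reac}, C_\mathrm{cap})$, on the log scale
(enforcing positivity), with five deterministic multi-starts (the initial
values, then cyclic ×1/3, ×3, ×1/5, ×5 perturbations); ties break by SSE
then by log-distance from the start. Estimates more than four orders of
magnitude from their initial values are flagged as boundary solutions —
the behaviour expected of, e.g., all-zero observations. $k_\mathrm{reac}$
is excluded from the default free set because a reaction-fast sampler's
trajectory carries almost no information about it.

`estimate_capacity()` declares a plateau where the terminal run of
intervals has local relative slope below 0.02 h$^{-1}$ — a tolerance that
separates the flat tail from the linear phase at the hour time scales of
chamber runs — and returns the mean level over the run, or a not-plateaued
marker rather than a number when the series is still rising.

`changepoint_check()` scans every interior two-segment split exhaustively
(via prefix-sum OLS, so the scan is $O(n)$), declares a changepoint when
the two-segment SSE improves on one segment by at least 10%, and reports
the split as the intersection of the two fitted lines. Two design points
deserve emphasis:

* The 10% improvement threshold controls false positives only on *dense*
  series. A power analysis during design showed that on sparse
  extraction-style series (7–13 points) the best-of-all-splits improvement
  on pure noise almost always exceeds 10%, while at instrument-resolution
  sampling (hundreds of points) the false-positive rate at 5% multiplicative
  noise falls below 5%. Changepoint analysis is therefore defined on
  PTR-MS-resolution series (the generator's 0.5-min grid), not on the
  handful of extraction time points.
* The line-intersection split estimate is continuous in the data and
  localises the kink more sharply than the discrete split index, whose
  error is an absolute time scale set by noise and slope contrast rather
  than by the grid.

`recovery_study()` wraps generate-then-fit over split seeds and tabulates
per-parameter bias and RMSE. With the default study design (a saturating
stock-solution scenario, twelve deployments spanning the linear rise and
the plateau, 5% extraction noise) the capacity is recovered with ~1.7%
RMSE and negligible bias over 100 repetitions — the acceptance script
recomputes exactly this.

## Numerical choices

* Two-state integration: `deSolve::lsoda`, rtol 1e-8, atol 1e-12
  mol m$^{-3}$ — the system is stiff (the dissolved-pool relaxation rate
  at defaults is ~3e8 h$^{-1}$), which is precisely why the quasi-steady
  reduction exists. Seedless and deterministic.
* Quasi-steady integration: fixed-step classical RK4 with steps of at most
  0.01 h (0.02 h inside the fitter); the single state is non-stiff and the
  O($h^4$) error is far below measurement noise.
* The test suite cross-checks the two-state solver against an independent
  explicit-Euler oracle at step 1e-4 h on randomized parameter sets drawn
  inside Euler's stability region (which at this geometry means
  $k_\mathrm{reac} \lesssim 1.5\times10^{-3}$ h$^{-1}$; a numerical
  validity constraint of the oracle, not a physical regime).
* Air series are interpolated linearly between points and held constant
  (zero-order hold) beyond their last point; simulations require the
  series to cover time zero.
* Floors: concentrations at 0; $C_s$ clamped to $[0, C_\mathrm{cap}]$ and
  made non-decreasing against solver round-off.

### Problem sizes used by the tests

The suite and the acceptance script use deliberately modest sizes chosen
as adequate for their statistical purpose: 20 randomized parameter sets
for the integrator cross-check, 100 repetitions for the recovery study,
100 gel and 200 linear replicates for the changepoint operating
characteristics, and 48-h saturation runs for plateau checks. These sizes
give Monte-Carlo standard errors comfortably below the tolerances they are
tested against.

## Known limitations

* The model is lumped: no spatially resolved diffusion inside the PDMS
  sheet, no multi-gas competition, no temperature dependence of $k_O$ or
  $K_{SA}$.
* $K_{SA}$ is an assumption (default 10). Reaction-fast results are
  insensitive to it, but reversible-regime simulations inherit its
  uncertainty.
* TWA estimates from saturated samplers are lower bounds; the pipeline
  flags but cannot correct them.
* Whether the quoted exchange area counts one or both faces of the sheet
  is not specified by the hardware description; the default treats
  2.25e-4 m$^2$ as the effective area.
* The saturating emission shapes are generator assumptions; real chamber
  concentrations may still be rising when sampling ends.
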