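---
title: "Methods: flow-through cuvette flux inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-through cuvette flux inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuvetteflux)
```

## The measurement problem

Whole-plant volatilomics platforms enclose potted plants in glass
cuvettes flushed with conditioned air at a controlled inlet flow.
Downstream analyzers — a proton-transfer-reaction time-of-flight mass
spectrometer (PTR-ToF-MS) for volatile organic compounds (VOCs) and
infra-red gas analyzers (IRGAs) for CO2 and H2O — sample the outlet of
one cuvette at a time through a valve multiplexer, typically dwelling
5 minutes per cuvette. The biological quantities of interest are rates
per unit leaf area: VOC net emission (nmol m⁻² s⁻¹), net CO2
assimilation (µmol m⁻² s⁻¹) and transpiration (mmol m⁻² s⁻¹). This
package implements the forward physics of such a system and the full
inverse pipeline from raw multiplexed logs to normalized rate tables.

## Chamber model and its assumptions

A cuvette of air volume $V$ flushed at flow $F$ with good turbulent
mixing, equal in- and outflow, and negligible wall deposition obeys

$$\frac{dc}{dt} = \frac{E(t)\,A_\mathrm{leaf}}{V}
  + \frac{F}{V}\bigl(c_\mathrm{in}(t) - c(t)\bigr),$$

with $c$ the (homogeneous) compound concentration, $E(t)$ the net
emission rate per one-sided leaf area $A_\mathrm{leaf}$. The time
constant $\tau = V/F$ controls everything: after $5\tau$ the cuvette
air is exchanged to more than 99 %, and the chamber acts as a
first-order low-pass filter that attenuates a sinusoidal emission of
angular frequency $\omega$ by $1/\sqrt{1+(\omega\tau)^2}$. At steady
state the balance inverts to the classic formula
$E = (F/A_\mathrm{leaf})(c_\mathrm{out}-c_\mathrm{in})$; away from
steady state `dynamic_emission()` restores the storage term
$V\,dc/dt$ with second-order central differences.

The well-mixed, $F_\mathrm{out}=F_\mathrm{in}$, no-deposition
assumptions are design assumptions of the hardware this models, not
options of the software; multi-compartment or wall-loss models are out
of scope.

### Numerical choices

* **Integrator.** The forward model uses an adaptive Dormand–Prince
  5(4) Runge–Kutta scheme (relative tolerance $10^{-8}$), implemented
  in the package because no ODE-solver package is assumed at run time.
  The system is scalar, linear and non-stiff at realistic $\tau$
  (minutes), so accuracy is cheap; steps never cross requested output
  times.
* **Derivative estimate.** `dynamic_emission()` uses the three-point
  central difference on possibly non-uniform grids, one-sided at the
  boundaries, with an optional moving-average smoothing window
  (default off). No smoothing is applied silently.
* **Units.** Volumes are entered in liters and flows in L min⁻¹
  (instrument conventions), converted internally to SI. Flow-to-molar
  conversions use the ideal gas law at the cuvette air temperature and
  a configurable pressure, default 96 000 Pa.

## Signal processing

Demultiplexing assigns each log record to the cuvette whose valve was
open, reconstructing switch times from the `active_cuvette` annotation
(or from nominal schedule timing when absent), and discards records
within the lag time after each switch — the gas-exchange time of the
tubing between cuvette outlet and sensor. The lag default is 30 s: the
platform literature prescribes the discard but no number, so the value
is an explicit, logged configuration parameter.

Background correction subtracts the signal of empty cuvettes flushed
with the same supply air: their demultiplexed series are pooled
(values sharing a timestamp are averaged first — with several
background cuvettes this reduces spline variance), interpolated with a
cubic spline over time, evaluated at the target series' timestamps and
subtracted. Two deliberate choices:

* **Spline end conditions.** We use Forsythe–Malcolm–Moler ("fmm")
  end conditions rather than natural ones, because the package's own
  correctness contract — exact recovery when the contaminant drift is
  polynomial of degree ≤ 3 — cannot be met by natural end conditions
  (which force zero second derivatives at the ends and are exact only
  for linear trends there). The leaf-area timeline interpolator, whose
  contract only requires exactness at knots and on straight lines,
  keeps natural end conditions.
* **Negative corrected values** are retained and counted, never
  clipped: clipping would bias upward every emission-rate average
  computed downstream.

Queries outside the background's time coverage hold the endpoint value
(no extrapolation); gaps longer than two multiplex cycles trigger a
warning.

## Gas exchange and energy balance

Net assimilation converts the inlet–outlet CO2 mixing-ratio difference
with the molar air flow $F P/(RT)$; transpiration mirrors the chamber
formula for absolute humidity. Because pot soil is normally not sealed
off, bare-soil reference cuvettes measure the soil's CO2/H2O
contribution, which is removed from the *concentrations*
(`corrected = plant_out − (soil_out − inlet)`) before any flux is
computed. The pipeline additionally subtracts the chamber storage term
($n_\mathrm{air}\,dx/dt$ for CO2, $V\,dh/dt$ for H2O, central
differences) by default; without it, diurnal rates lag the truth by
up to $\sim\omega\tau$ relative error (about 5 % at $\tau = 400$ s),
which would violate the package's 2 % recovery contract.

Psychrometric helpers use the Magnus correlation
$e_s = 610.94\,\exp(17.625\,t/(t+243.04))$ Pa ($t$ in °C), ideal-gas
absolute humidity, a two-component ideal-gas moist-air density, and
the Clausius–Clapeyron latent heat
$H_v = R T^2\, d\ln e_s/dT$ evaluated analytically from the Magnus
form (44.07 kJ mol⁻¹ at 298.15 K, within 0.2 % of the conventional
43.99 kJ mol⁻¹).

The evaporative-cooling estimate
$\Delta T = E_s A H_v / (\rho_\mathrm{air} F c_p)$ takes *all* factors
as explicit inputs. This is deliberate: published worked examples of
this balance quote specific $\rho_\mathrm{air}$ and $c_p$ values
(1.01 kg m⁻³ and 1106 J kg⁻¹ K⁻¹ at 96 kPa / 298.15 K / 80 % RH) that
standard psychrometric formulas do not reproduce (`air_density()`
gives ≈ 1.11 kg m⁻³, `moist_air_cp()` ≈ 1030 J kg⁻¹ K⁻¹). Rather than
silently disagreeing, the function reproduces any quoted example
bit-for-bit from its stated inputs, and the helpers document the
discrepancy.

## Ion m/z assignment

PTR-ToF-MS ionizes analytes by proton transfer from H₃O⁺, and — with
selective-reagent units — by electron transfer (O₂⁺), hydride or
hydroxide abstraction, or clustering (NO⁺). The module computes
theoretical product-ion m/z from pinned most-abundant-isotope masses
(¹H 1.0078250, ¹²C 12, ¹⁴N 14.0030740, ¹⁶O 15.9949146, ³²S
31.9720707 u). Two conventions are provided:

* `label` (default): offsets are neutral-atom masses
  (protonation adds the hydrogen-atom mass 1.007825 u). This is the
  convention that reproduces, at 3-decimal half-up rounding, the peak
  labels commonly printed in the applied literature — an inference
  validated against nine independent labels in the test suite.
* `physical`: additionally subtracts one electron mass per unit
  charge (protonation then adds the true proton mass 1.007276 u).

Which reaction channel a compound actually takes (branching ratios,
fragmentation) is chemistry the module does not predict; it computes
candidate masses for all allowed channels and ranks candidates within
a mass tolerance. Mode constraints are structural only (hydroxide
abstraction needs an OH to abstract, etc.).

## Leaf area

Plants are photographed against a blue background; pixels with hue in
60–180° and saturation ≥ 0.15 (HSV space) count as plant. Both
thresholds are per-species tunables — the defaults are chosen for the
synthetic fixtures and typical green foliage. Pixel counts map to
area through an ordinary-least-squares line fitted to destructively
measured calibration plants (free intercept by default, through-origin
variant available); when several images per time point exist their
counts are averaged. Leaf area between photography days is
interpolated with a natural cubic spline and extrapolation is refused.
Raster I/O uses ASCII PPM (P3), a plain-text format sufficient for the
synthetic fixtures; in-memory RGB arrays from any reader work equally.

## The synthetic-data generator: what it emulates, and what not

`generate_experiment()` simulates the full measurement chain under a
stated world that mirrors a published screening campaign: 24 cuvettes
(18 plants, 3 empty backgrounds, 3 bare-soil references), ~40 L
volume, 6 L min⁻¹ inlet flow (τ ≈ 6.7 min), 300-s valve dwell with
30-s lag, a 12/12-h photoperiod, half-sine diurnal profiles over the
light phase (VOC peak 5 nmol m⁻² s⁻¹; assimilation peak
10 µmol m⁻² s⁻¹; transpiration peak 1 mmol m⁻² s⁻¹ — mid-range values
for young cereal plants of 0.05 m² leaf area), constant soil efflux
(0.05 µmol CO2 s⁻¹, 10⁻⁵ mol H2O s⁻¹ per pot), supply air at 400 ppm
CO2 and 50 % RH (298.15 K, 96 kPa), and a slow cubic contaminant
drift on the VOC channel so the spline correction is exercised in a
regime with an exact-recovery answer. Sensor noise is i.i.d. Gaussian
per channel from a single seeded stream; a fixed seed makes the output
byte-identical.

What it does **not** emulate — and hence what a green end-to-end test
does *not* establish: instrument drift and sensitivity changes, peak
overlap and fragmentation in the mass spectra, temperature/humidity
feedback on emissions, non-ideal mixing, wall sorption, leaks, or soil
microbial dynamics. Recovery of the configured rates to within 2 %
(noiseless) demonstrates the correctness of the inversion chain, not
the fidelity of any real instrument.

## Scaling of test workloads

The test suite runs the full 24-cuvette noiseless day once; the
repeated-seed unbiasedness checks run on a reduced layout (1 plant /
1 background / 1 soil cuvette, 6 h, 30-s records) purely to bound
runtime. The generator defaults themselves are never changed for
testing.

## Known limitations

* Steady-state inversion is biased low/lagged for emissions varying
  faster than τ; use the dynamic inversion (default in the pipeline)
  and a cuvette small enough that τ is well below the fastest
  expected emission dynamics.
* The dynamic inversion amplifies high-frequency sensor noise through
  the $V\,dc/dt$ term (zero-mean, so averages stay unbiased); the
  optional smoothing window trades variance for time resolution.
* One printed exchange-time figure in the platform literature
  (8 min at 20 L min⁻¹ for a 40-L cuvette) is inconsistent with
  $5\tau = 5V/F = 10$ min; the package follows the formula.
* Ion assignment is bookkeeping: it will happily list candidates for
  channels a compound never takes in a real drift tube.
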