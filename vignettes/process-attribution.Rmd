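---
title: "Process attribution of land carbon stock changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process attribution of land carbon stock changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbattrib)
```

## The problem

Dynamic global vegetation models (DGVMs) agree reasonably well on the net
land carbon sink but disagree widely on *why* the land takes up carbon:
is vegetation storing more because productivity rose, or because carbon
residence times changed? The two mechanisms have incommensurable units
(PgC yr^-1^ versus yr), so comparing them requires expressing both as
contributions to the stock change in PgC. This package implements a
process-attribution framework that does exactly that, together with the
factorial-scenario arithmetic that splits changes between external
drivers (CO~2~ fertilisation, climate, land use), a four-factor
decomposition of multi-model spread, and a synthetic toy-model ensemble
that exercises every step with known ground truth.

## The attribution framework

Each of the two analysis pools — vegetation carbon $C_v$ and the
aggregated soil system $C_s$ (soil + litter + coarse woody debris) —
obeys a one-pool balance
$$\frac{dC}{dt} = \mathrm{INPUT} - \frac{C}{\tau},$$
with input NPP for vegetation and the vegetation-to-soil flux $f_{vs}$
for soil. Annual diagnostics are recovered from standard model output:
$$\tau_v = \frac{C_v}{\mathrm{NPP} - \Delta C_v},\qquad
  \tau_s = \frac{C_s}{R_h},\qquad
  f_{vs} = \Delta C_s + R_h.$$
Assuming $\Delta C \approx 0$ relative to the fluxes gives a
steady-state pool estimate $\hat{C} = \mathrm{input}\cdot\tau$ for any
year, and the change between a reference year (1959) and an end year
splits exactly into three terms,
$$\Delta\hat{C} = \underbrace{\Delta \mathrm{input}\cdot\tau_{ref}}_{\text{input}}
 + \underbrace{\mathrm{input}_{ref}\cdot\Delta\tau}_{\text{turnover}}
 + \underbrace{\Delta \mathrm{input}\cdot\Delta\tau}_{\text{interaction}}.$$
Because the one-pool steady-state picture misses multi-pool dynamics and
non-steady-state behaviour, $\Delta\hat{C}$ differs from the simulated
change $\Delta C$ by a correction $\delta = \Delta C - \Delta\hat{C}$,
which is distributed over the three terms in proportion to their
absolute magnitudes (`scale_to_actual()`). The adjusted terms sum to the
simulated change exactly — this identity holds to machine precision by
construction and is tested on thousands of random inputs.

When every raw term is exactly zero the proportional rule is undefined;
the correction is then assigned to the input term, an arbitrary but
documented tie-break that preserves the sum.

### Differencing convention

Stocks are reported as start-of-year values and fluxes as within-year
totals, so the stock change *during* year $t$ is the forward difference
$C(t{+}1)-C(t)$. The diagnostics pair each year's stock with that year's
fluxes using this flux-aligned change (`flux_aligned_change()`); under
it, the diagnosed $\tau_v$ of a single well-mixed pool recovers the true
turnover time exactly, which the test suite checks to 10^-9^. The
plain `annual_change()` helper (backward difference, forward fallback at
the first year) is retained for end-user differencing of arbitrary
series. Synthetic runs carry the first out-of-window stock
(`next_stocks`) so the forward difference is exact at the final year
too; for data read from CSV without that extra year, the last year falls
back to a backward difference, which is approximate there.

A turnover diagnostic whose denominator is non-positive (e.g.
$\mathrm{NPP} < \Delta C_v$ in a strong-disturbance year) is flagged
missing rather than clamped; clamping would silently bias the terms.
Attribution results at flagged endpoints are flagged, not interpolated.

### Endpoint values

The framework uses single-year diagnostics at the reference and end
years, following the defining equations literally. Because single-year
endpoints are volatile under interannual variability, an optional
trailing averaging window (`endpoint_window`, default 1 yr) can replace
each endpoint by a short mean; the sum-to-$\Delta C$ identity is
preserved because the actual change is averaged consistently.

## Driver decomposition

Each model runs four simulations: S0 (pre-industrial CO~2~ and land
use, recycled early-period climate), S1 (+transient CO~2~), S2
(+transient climate), S3 (+transient land use). Driver effects are the
telescoped differences CO~2~ = S1−S0, climate = S2−S1+S0, land use =
S3−S2, net = S3, which sum to the net run identically. The S2−S1+S0
form is implemented literally (S0 added back as the control baseline),
which is what makes the three components telescope exactly to S3.

Process terms are attributed per scenario first and telescoped after.
The alternative — attributing differenced diagnostics — would break one
of the two closure identities; telescoping the adjusted terms keeps
both: within every driver the three terms sum to that driver's stock
change, and across drivers each term sums to the net-run term. Both
closures are asserted at 10^-10^ relative across a full 18-model
ensemble.

Land-use forcing reconstructions carry an artificial transition spike
around 1960; `lulcc_spike_correction()` replaces 1959–1961 values by
the mean of 1958 and 1962. It is applied to the S3−S2 difference
series by default (the artefact lives in the land-use response);
correcting S3 itself is available via `correct_on = "net"`. The
correction touches only the three named years and is idempotent.

## Ensemble spread decomposition

The steady-state change is bilinear in four per-model factors: baseline
input, change in input, baseline turnover, change in turnover. For each
factor, $\Delta\hat{C}$ is recomputed per model with that model's own
factor value and the ensemble mean of the other three; the sample
standard deviation of the resulting values is that factor's
contribution to spread. The interaction term takes each of its two
slots from whichever factor owns it. Spread uses the $n-1$ sample
standard deviation throughout, the usual convention for ensembles of
order 18, and the one-at-a-time $\Delta\hat{C}$ values are *not*
$\delta$-adjusted — the spread is a property of the steady-state
approximation itself.

Sign agreement for stippling counts the majority sign over models;
zero changes count in the denominator but toward neither sign (a
conservative choice: an all-zero cell is reported as fully uncertain),
and cells below 80% agreement are flagged.

## The synthetic ensemble

The toy model is a surrogate for structural diversity across DGVMs, not
a reconstruction of any of them. Vegetation receives
$$\mathrm{NPP} = \mathrm{npp}_0\,[(1-f_{ag}) + f_{ag}\rho_{ag}]\,
  (1+\beta\ln(\mathrm{CO_2}/\mathrm{CO_2}_{ref}))(1+\gamma T),$$
and loses carbon at $C_v/\tau_v^{eff}$ with the effective turnover
blending natural and agricultural land, plus a clearing flux
$E_{lu} = \lambda_{lu}\max(\Delta f_{ag},0)\,C_v$ split between direct
emission ($p_{atm}$) and transfer to the soil system. Soil turnover
responds to warming as $\tau_s = \tau_{s0}\,q_{10}^{-T/10}$. An
optional litter pool sits between vegetation and soil, transferring a
fraction $\epsilon_{lit}$ of its outflux downward — this is the
configuration that reproduces *false priming*: under rising inputs the
fast litter pool grows relative to slow soil, shortening the diagnosed
aggregate turnover while every pool-level rate is constant.

Runs start from the closed-form steady state (every pool equals input
times turnover at pre-industrial forcing), which removes spin-up drift
entirely: the S0 control preserves pools to 10^-9^ relative over 160
years by construction, tested. Stepping is explicit with Δt = 1 yr,
matching annual reporting and keeping the mass balance
$\Delta C_v + \Delta C_{lit} + \Delta C_s = \mathrm{NBP}$ exact at
machine precision.

Default parameter ranges (`default_param_ranges()`, also in the
packaged YAML config) are sampled uniformly and independently per
model: $\beta \in [0.3, 0.7]$, $\gamma \in [-0.02, 0.02]$ K^-1^,
$q_{10} \in [1.5, 2.5]$, $\tau_{v,nat} \in [8, 25]$ yr,
$\tau_{s0} \in [15, 40]$ yr, $\rho_{ag} \in [0.5, 0.9]$,
$p_{atm} \in [0.4, 0.8]$, with baseline NPP in $[45, 65]$ PgC yr^-1^
bracketing the observed global magnitude. These ranges were chosen once
to produce inter-model spread of the qualitative character seen in real
archives — disagreement in the magnitude of the productivity response
and even in the sign of turnover changes — and are not calibrated to
any particular ensemble. Pool-availability flags (litter present, CWD
reported, litter folded into the soil output) are sampled with
probabilities 0.9/0.25/0.1, mirroring the heterogeneity of real
archives where a minority of models report CWD and occasionally litter
arrives inside the soil pool; CWD and litter-in-soil require a litter
pool.

Forcing is shared across models (common forcing, different structure):
exponential CO~2~ from 284 ppm at 1850 (~412 ppm by 2020), a linear
warming trend of 0.01 K yr^-1^ from 1900 with Gaussian interannual
noise of σ = 0.1 K, and a piecewise-linear agricultural fraction from
0.10 to 0.32. The noise starts at the warming onset so the
pre-industrial control climate is exactly stationary; the
recycled-climate variant repeats the first 20 years of the anomaly
series and is therefore identically zero here. This makes S0/S1 clean
steady-state controls — with noise in the control climate the
steady-state closure and exact-diagnostic properties would hold only
statistically. The land-use ramp can carry a configurable one-year
spike (default +0.02 at 1960) to exercise the spike correction.

What the generator does *not* emulate: nitrogen cycling and deposition
(folded into the CO~2~ driver by the scenario definition), fire,
permafrost, demography, sub-annual dynamics, spatial heterogeneity
within a region, and wood-product pools. Passing tests therefore show
the arithmetic and identities are right and that the framework behaves
correctly on dynamics it was designed for — they cannot show that any
real model's attribution is accurate.

## Regional aggregation

Gridded stocks (kgC m^-2^) and rates (kgC m^-2^ s^-1^) reduce to
regional totals by area weighting: PgC = Σ value·area × 10^-12^, rates
× 365.25·86400 s yr^-1^. Regions are latitude bands (≥30°N, <30°N,
global); cells are assigned by centre latitude with 30°N going north —
a deterministic tie-break. Cell areas default to the analytic band
integral on a sphere of radius 6 371 000 m. Missing cells raise an
error unless the treat-as-zero policy is chosen explicitly; silent
corruption is worse than a hard stop. North + south = global is an
identity of the construction and is tested.

## Presentation statistics

*Spline smoothing*: a penalized cubic smoothing spline (order-4
B-splines), with the penalty weight exposed; "fourth-order" is read as
basis order 4 = cubic, the common convention, and a quartic-degree
P-spline variant is provided for the alternative reading. The full
knot set is used so that small penalties interpolate and large
penalties approach the least-squares line; penalties beyond ~10^6^ are
numerically ill-conditioned and not meaningful.

*Local regression*: tricube-weighted local linear fits over the
span-nearest neighbours — deliberately the classical definition, fixed
as local *linear* (not quadratic) as the conservative default for trend
lines; the implementation is cross-checked against an independent
weighted-least-squares oracle and `stats::loess` in the tests.

*Period statistics*: simple period means and OLS trends versus year;
"acceleration" of a flux is reported as the OLS slope over the later
period (default 2001–2020), in PgC yr^-2^ or TgC yr^-2^.

*Driver-dominance composite*: per-cell channels
$|\Delta_i| / \sum_j |\Delta_j|$ with climate→red, CO~2~→green, land
use→blue, and opacity min(1, |net|/scale) — linear saturating alpha
with a configurable scale, since nothing pins down a particular
normalisation.

## Problem sizes and tolerances

The default study configuration is 18 models × 4 scenarios × 171
forcing years reported over 1958–2020 — small enough that the entire
test suite, including two full-ensemble end-to-end passes, runs in well
under a minute. Identity checks (term sums, telescoping) are asserted
at 10^-10^–10^-12^ relative; steady-state and exact-diagnostic
properties at 10^-9^; cross-implementation checks (loess, oracle
recomputation) at 10^-10^.

## Known limitations

- Attribution is two-pool (vegetation, aggregated soil system); no
  leaf/wood/root or soil-layer resolution, so compensating errors
  between component pools are invisible by design.
- The loss-of-additional-sink-capacity component of the land-use term
  is not separated.
- The toy model's land-use response is aggregate-tile blending plus an
  episodic clearing flux, not cohort tracking; it produces realistic
  input/turnover signatures but not realistic age structure.
- Persisted I/O is tidy CSV; gridded fields are handled as in-memory
  matrices with latitude/longitude coordinates.
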