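---
title: "Feedback-controlled turbidostats on a liquid handler: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-controlled turbidostats on a liquid handler: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbicell)
library(dplyr)
set.seed(1)
```

turbicell is a hardware-free reimplementation of the computational core of a
liquid-handling-robot culture platform: hundreds of microbial cultures held
in log phase in multi-well plates by a per-well feedback controller, sparse
transfer matrices that move liquid between wells to emulate metapopulation
dynamics, and an asynchronous scheduler that interleaves plate reading and
pipetting. This vignette explains the models, the tunable parameters, and
the design choices, in the package's own terms.

## The growth and dilution model

Between service visits a culture's optical density evolves as pure
exponential growth,

$$x(t) = x_0 \, e^{k t},$$

with $k$ the growth constant in 1/h (doubling time $\ln 2 / k$). A service
visit exchanges a fraction $y$ of the working volume for fresh transparent
media, which under instant uniform mixing scales the OD to

$$x' = \frac{x}{1 + y}.$$

Two conventions matter:

* **Constant volume.** The mixing picture *adds* a fraction $y$ of the
  initial volume; a real well cannot grow every cycle. `dilute()` and the
  simulator therefore realize the exchange as removing $V\,y/(1+y)$ of
  *mixed* culture and replacing it with the same volume of media. The OD
  update is algebraically identical and the working volume is constant,
  which is what `exchange_volume()` and `effective_fraction()` convert
  between.
* **Cycle order.** One cycle is measure → control → dilute → grow. The
  growth-constant estimator is derived under exactly this order (the
  previous command is assumed executed immediately after the previous
  measurement), so the simulator applies it as a fixed convention and the
  closed-loop equivalence tests pin it down. Note that for the *final* OD
  of a single full cycle the two scalar operations commute
  ($x\,e^{k\Delta t}/(1+y)$ either way); what the order fixes is the
  meaning of each recorded measurement, not the arithmetic.

There is no lag phase, stationary phase, evaporation, or temperature
dependence; OD 0 is a sterile absorbing state. Fluorescence is modeled as
proportional to OD through a per-well `expression_factor` with no
maturation kinetics, because only bulk fluorescence is of interest here.

## The controller

The per-well controller state is the triple (last measurement $x_{i-1}$,
filtered growth estimate $k^e$, last command $y_{i-1}$). Each cycle:

1. **Estimate.** Given the new measurement $x_i$ taken $\Delta t$ after the
   previous replacement,
   $$k_i = \frac{\ln\!\big[(x_i / x_{i-1})\,(y_{i-1} + 1)\big]}{\Delta t}.$$
   The dilution is undone, the growth law inverted. Raw values may be
   negative (noise, death) and are admitted as such.
2. **Filter.** $k^e_i = \max\{0,\ \alpha\, k^e_{i-1} + (1-\alpha)\, k_i\}$ —
   first-order exponential smoothing with a nonnegativity clamp, since the
   output law projects growth forward and cannot interpret negative $k$.
3. **Command.**
   $$y_i = \max\Big\{0,\ \min\big\{y^{\max},\ x_i e^{k^e_i \Delta t}/x^{\mathrm{set}} - 1\big\}\Big\},$$
   the replacement fraction that would return the projected OD to the
   setpoint, clamped to the physical limits (nonnegative; at most the
   largest volume the robot can move as a fraction of the well).

At the setpoint with a converged estimate the loop has the fixed point
$y^\ast = e^{k \Delta t} - 1$, which the tests verify both algebraically and
by iteration.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `x_set` | 0.8 | OD600 | the density the screens hold cultures at |
| `y_max` | 1 | fraction | one working volume per visit is a realistic single-tip limit |
| `dt_hours` | 0.5 | h | a five-plate service round fits comfortably in 30 min |
| `alpha` | 0.7 | — | damps 5% read noise (stationary estimator SD roughly halved twice) while still tracking a change in $k$ within a few cycles |
| `k_init` | 0 | 1/h | no dilution until growth is actually observed, so slow growers are never washed out at cold start |

`alpha` and `k_init` are implementation parameters — the transfer function
itself does not prescribe the filter or the cold-start estimate — so both
are exposed in the configuration and reported in logs rather than
hard-coded.

**Degraded reads.** A blank or failed measurement ($x \le 0$ or missing)
yields command 0 and leaves the estimate and stored measurement untouched.
This is exactly the behaviour sterile control wells need: they must never
trigger dilution.

## The stochastic simulator

`run_turbidostat()` runs the loop over every well of one or more plates,
vectorized per cycle, with two noise sources:

* **Measurement noise** — multiplicative lognormal with median equal to the
  true value and CV `od_cv` (default 0.05). Lognormal keeps reads strictly
  positive and median-preserving, the standard multiplicative instrument
  error model; the parameterization is checked by Monte Carlo (sample
  median of $10^5$ draws within 1% of the true value).
* **Mechanical noise** — the executed exchange volume is the commanded
  volume times a normal factor (mean 1, CV `vol_cv`, default 0.02,
  typical liquid-handler precision), truncated at zero.

Setting both CVs to zero reduces the simulator to the deterministic loop
*exactly*, and that trajectory is tested against an independent analytic
iteration of the transfer function at $10^{-12}$. With a fixed seed the
output is byte-identical between runs.

### Convergence and how settling is judged

A 96-well plate inoculated across OD 0.01–0.8 with plant $k = 0.7$/h
settles onto a 0.8 setpoint well inside 12 h. One subtlety: at steady state
the loop transmits essentially the full per-read noise into the true OD
(with an exact estimate, $x_{i+1} = x^{\mathrm{set}} / \varepsilon_i$ where
$\varepsilon_i$ is the read's multiplicative error), so with 5% CV a *raw*
per-cycle ±10% band test will be violated eventually by chance alone.
Plate-reader practice smooths OD traces with a rolling mean before
interpreting them, and `settling_time()` does the same: it applies the band
test to a trailing 5-cycle (2.5 h) rolling mean of the true OD by default.
Five cycles reduces the effective CV to about 2.2%, making a ±10% band a
4.5-sigma statement per point, while adding at most a couple of hours of
detection lag — negligible against the 12 h horizon. The window is a
package convention, exposed as an argument.

## Media-condition grids and landscapes

`make_condition_grid()` builds the Cartesian product of carbon, nitrogen
and phosphorus fold-changes relative to 1× M9 — by default five C levels ×
five N levels × four P levels (2- and 4-fold up and down) = 100 conditions,
300 wells in triplicate — and assigns wells deterministically in row-major
plate order. Each condition carries the deviation metric
$|\log_2 c| + |\log_2 n| + |\log_2 p|$, zero only at standard media.

`response_map()` is **synthetic by construction**: a stand-in surface used
to verify that the analysis pipeline recovers whatever surface is planted,
not a claim about E. coli metabolism. Each nutrient contributes a
Monod-type saturating multiplier $f(m) = m (1+h)/(m+h)$: $f(1) = 1$ exactly
so baseline media returns baseline values, $f$ is smooth and strictly
increasing for $h > 0$, and $h = 0$ switches a nutrient off. The defaults
($h$ = 0.05/0.05/0.15 for C/N/P growth sensitivity) make phosphorus the
dominant growth nutrient and keep the spread of growth rates within a few
tens of percent of baseline, the regime such screens operate in.

`summarize_landscape()` averages the filtered $k$ estimate and fluorescence
over the equilibrium window (default: final 12 h, matching the convergence
horizon), first within a well's trajectory, then across replicates; the
replicate spread is the reported SD, so identical triplicates give SD 0. A
noiseless 100-condition, 36 h screen recovers the planted growth surface
to better than 1% per condition. Fluorescence is reported both as totals
(the default, what plate plots show) and per-OD; an optional blank
subtraction is exposed since raw instrument counts may or may not be
blanked upstream.

## Metapopulation transfers

A `transfer_matrix()` is a sparse set of (source well, destination well,
fraction) entries; `"SINK"` (stored as `NA`) is an explicit off-plate
destination so that unbounded outflow is auditable in logs. Invariants:
no self-transfers, per-source outgoing fractions sum to ≤ 1, well-to-well
entries unique per pair.

* **Kernels.** `make_diffusion_kernel()` sends `rate/4` to each von-Neumann
  neighbour (`rate/8` Moore, behind a flag — the 4-neighbour stencil is the
  minimal diffusion model and is declared in the configuration). Bounded
  kernels keep missing edge shares (reflecting, mass-conserving);
  unbounded kernels send them to SINK.
* **Barriers.** `apply_barriers()` multiplies crossing entries by a class
  attenuation. "High" and "medium" default to 0 and 0.5 — configuration
  entries, not measured values.
* **Snapshot semantics.** All moved volumes and tracer amounts are computed
  from the pre-iteration state, so execution order cannot change what is
  moved. This matches the matrix definition of the transfer pattern and is
  what makes compilation sound: `compile_transfers()` precomputes absolute
  µL per entry, splits anything over the tip capacity into equal sub-steps,
  and `interpret_transfers()` executes the aspirate phase before the
  dispense phase (removal never changes a well's concentration, so the
  aspirated aliquots carry snapshot concentrations exactly). Equivalence of
  compile-then-interpret with the direct matrix application is tested at
  $10^{-12}$, including under random step reordering; a sequential
  in-place mode exists behind a flag for order-sensitivity studies.

Conservation (bounded matrices conserve tracer to $10^{-9}$ over 1000
random instances), linearity in tracer amounts, scaling with initial
volumes, and symmetry of point spreads under symmetric kernels are all
property-tested against independent dense-loop references.

## Deck runtime and scheduling

The scheduler models three single-occupancy resources — pipetting head,
reader, transport arm — and visits plates in fixed round-robin order
(determinism by construction). Per plate and round: move to reader, read,
move back, service (aspirate + dispense with the 96-probe head), optional
tip wash (1% bleach, water rinse, return to housing — the three-phase
template of `wash_cycle_steps()`). Reading plate $i$ overlaps pipetting of
plate $j \ne i$; with five 96-well plates the deck services 480 cultures
per full cycle and the asynchronous makespan beats the serialized one by
the reader time of all but one plate. Default durations (10 min read,
10 min service, washes folded into service) are modeling assumptions and
configurable; wall-clock realism is not a goal. Per-well liquid steps with
absolute volumes come from `compile_service_steps()` on simulator records,
whose dispensed total reconciles exactly with the simulator's exchanged
volume ledger. Step logs are JSON-lines and round-trip losslessly.

The single-plate channel model deserves a note: an 8-channel head over a
4-row 24-well plate aligns at most one channel per row, so one plate
exposes 4 usable channels (6 cycles for 24 wells) while two deck-adjacent
plates expose 8 rows and are serviced in the same 6 cycles — the doubling
is geometric, and `assign_channels()` reproduces it as an explicit
partition of wells.

## Problem sizes, determinism and limitations

The test suite and the bundled acceptance script use desk-scale runs: 96 to
480 wells, 24 to 36 simulated hours at 30-minute cycles, 100-condition
grids in one or three replicates, 1000-instance property sweeps on 12-well
plates. These complete in seconds to tens of seconds and are the sizes the
package's claims are verified at.

What passing tests show — and what they do not: the simulator demonstrates
that the *control and analysis machinery* is correct (estimator inversion,
fixed points, convergence, conservation, recovery of planted surfaces). It
does not model real metabolism, media chemistry, cross-well biological
contamination, lag or stationary phases, or hardware timing, so agreement
here says nothing about those. The synthetic response surface in
particular is a test instrument: real C/N/P landscapes must be measured,
not simulated.

```{r example, fig.width = 6, fig.height = 4}
plates <- culture_plate("P1", od0 = rep(c(0.01, 0.1, 0.2, 0.4, 0.6, 0.8),
                                        each = 16), k = 0.7)
sim <- run_turbidostat(plates, controller_config(),
                       noise_model(0.05, 0.02, seed = 42), hours = 24)
glance(sim)
summary(settling_time(sim)$settle_h)
autoplot(sim)
```
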