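---
title: "Methods: thermal monitoring of instrumented sediment columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal monitoring of instrumented sediment columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocol)
```

## The problem

A living Winogradsky column and an autoclaved control sit side by side in a
diurnally lit incubator, each carrying two embedded digital thermometers
(top and bottom sediment regions) plus external wall references and an
incubator probe. Microbial catabolism releases heat; the question is
whether that heat is resolvable as (i) a larger vertical temperature
gradient inside the living column, (ii) a persistent living-minus-control
offset, or (iii) excess heat retention when the columns are wrapped in
insulation. The signals at stake — tenths of a degree at best — sit near
the sensors' 0.0625 °C quantization step and well below their ±0.5 °C
accuracy bound, which shapes every methodological choice below.

## Heat-balance theory

The idealized upper limit treats the sediment as a closed, lossless mass:
a metabolic power density $P$ (W kg⁻¹) heats sediment of specific heat
$c_s$ (J kg⁻¹ °C⁻¹) at

$$\dot T \;=\; P / c_s \quad (^\circ\mathrm{C\,s^{-1}}),$$

reported per hour by `heating_rate()`. $P$ is the per-cell metabolic heat
rate times the cell abundance per kilogram (`power_density()`). Defaults
use the *E. coli* reference rates of 0.8 pW (aerobic) and 0.2 pW
(anaerobic) per cell and an abundance of $5.725\times10^{12}$ cells kg⁻¹ —
the value implied by the aerobic volumetric coefficient of 4.58 W kg⁻¹
that the prediction reproduces; the abundance is configurable.

Two numerical caveats are deliberate:

* The bulk heat-capacity range used by the predictions, 2880–4180
  J kg⁻¹ °C⁻¹, is an independently sourced bound and is *not* re-derived
  from the measured 62 % water content via the mass-weighted mixture rule:
  with dry-solid capacities of 910–2400 J kg⁻¹ °C⁻¹ the mixture gives
  ≈2940–3506, a narrower and differently-centred interval. Both the quoted
  range and the mixture calculator (`mixture_heat_capacity()`) are
  exposed; neither silently replaces the other.
* At the quoted range, the computed rate bounds are 3.94–5.73 °C h⁻¹
  (aerobic) and 0.99–1.43 °C h⁻¹ (anaerobic). The commonly quoted upper
  bounds of 5.6 and 1.3 °C h⁻¹ disagree with the computed values at the
  last printed digit; `theory_prediction_table()` reports computed values
  and flags the disagreement rather than reproducing unreproducible
  numbers. Only the lower bounds round to the quoted 3.9 (the anaerobic
  low rounds to 1.0, not the quoted 0.9, and is flagged too).

The gravimetric water-content estimator (`water_content_from_drying()`)
declares drying complete at the first balance reading whose change from
its predecessor is at most `convergence_delta` (default 0.01 g — the
smallest change a 0.01 g-resolution laboratory balance can register; the
source procedure says only "no further weight change").

## Log ingestion and valid days

The native dialect is semicolon-separated text with one header row and
local `YYYY-mm-dd HH:MM:SS` timestamps — the format produced by
serial-logger scripts. Timestamps are naive local clock, stored as UTC so
no daylight-saving arithmetic ever applies; the analysis is phase-of-day
based and a timezone would only add failure modes. Readings outside a
plausibility window (default −10…60 °C; the incubator operates at
22–30 °C) are dropped and counted, never imputed. A gap is reported where
consecutive timestamps are more than three nominal sampling periods apart
(default period 60 s). Merging concatenates, sorts, and keeps the first
record at duplicate timestamps, making it order-insensitive and
associative.

A calendar day is *valid* for a phase when at least `min_coverage`
(default 0.9) of the expected samples are present. The threshold is a
design choice: 1.0 would discard days with a single lost sample, while
anything below ~0.8 admits days missing whole stretches of a phase; 0.9
tolerates brief dropouts while still excluding genuine interruptions.

## Diel phases

The incubator's light program (moonlight 1.9 % from 01:00, ramp up
07:00–08:00, full power until 00:00, ramp down by 01:00) is segmented into
half-open intervals `[start, end)`:
T1 00:00–01:00 and T2 07:00–08:00 (ramping transitions, excluded),
N1 01:00–04:00, N2 04:00–07:00, D1 08:00–15:30, D2 15:30–24:00.
The half-open convention makes the partition exact (450/510/180/180/60/60
minutes); a sample at exactly 15:30 is D2. An end of "00:00" is read as
24:00 of the same day so D2 belongs wholly to its start date and
phase-days stay contiguous. The schedule is configurable for other light
programs.

## Difference statistics

Six difference series are defined by channel pairs: internal vertical
gradients (living, control), external vertical gradients from the wall
references, and living-minus-control differences at top and bottom.
Aggregation is strictly hierarchical — raw samples → per-day phase means →
across-day summaries (boxplot statistics, monthly means) — rather than
pooling raw samples, so days and months with unequal coverage remain
comparable and a single long day cannot dominate a month. Standard
deviations use the n−1 denominator (0 for singletons); quartiles use
linear interpolation between order statistics (R type 7), fixed so boxplot
statistics are deterministic. Within one log, channel pairs share rows;
pairing snaps timestamps to the nominal grid first, which guards against
logger jitter when files from separate acquisitions are merged.

## Insulation retention

For an insulation event, per phase:

* `delta_delta` (ΔΔT) = highest per-day phase mean of the difference
  series among days whose phase interval overlaps the event, minus the
  mean over the three valid phase-days immediately before the event;
* `delta_delta_steady` (ΔΔT_Steady) = mean over the first three valid
  phase-days after the event, minus the same baseline.

"Preceding three days" is implemented as three *valid phase-days* (not
72 h of samples), because every statistic in the pipeline is
phase-resolved; interrupted days are skipped, not shrunk over. Days
partially covered by an event boundary count as "during", and their means
use only the overlapped portion of the phase — mixing insulated and
uninsulated samples would dilute the maximum. A per-day-mean maximum
(rather than a raw-sample maximum) keeps ΔΔT from being noise-dominated:
with ~0.07 °C of per-sample read noise, a max over thousands of raw
samples would measure the noise tails, not retention. Both statistics are
offset-invariant and scale-equivariant, and `precision_flag()` marks each
against the 0.0625 °C quantization step (strictly above / strictly below /
exactly at threshold, reported distinctly).

## The binned distribution comparison

Continuous difference series are heavily autocorrelated, so a test on all
raw points produces meaninglessly small p-values. The procedure
implemented bins differences into 200 left-closed 0.01 °C intervals on
[−1, +1) °C, normalizes counts by the *total* sample count (out-of-range
samples stay in the denominator and are reported), and applies a
two-sided Mann–Whitney U test to the two 200-element frequency vectors.
This is reproduced exactly as specified, but it is statistically
unconventional: treating bins as observations tests whether the two
vectors' *frequency magnitudes* differ, not whether the underlying samples
do. Two distributions of identical shape shifted in location have nearly
identical sorted frequency vectors and will not be distinguished, whereas
a concentration difference (narrow vs broad) will be. For this reason
`mwu_raw()` — the conventional test on raw samples, exact for ≤ 20 untied
observations per side, tie-corrected normal approximation with continuity
correction otherwise — is provided as a clearly labeled diagnostic, and
the test suite checks both behaviours instead of hiding the divergence.
No reinterpretation of either procedure's p-values is attempted.

## The simulator

The synthetic generator exists so the full pipeline is testable without
the deposited dataset. Each column is a two-node lumped-capacitance
network (matching the two embedded probes; finer spatial resolution would
be unobservable):

$$C_i \frac{dT_i}{dt} = K_{\mathrm{int}}(T_j - T_i)
  + s(t)\,K_{\mathrm{ext},i}(T_{\mathrm{inc}} - T_i)
  + [K_{\mathrm{base}}(T_{\mathrm{inc}} - T_i)]_{i=\mathrm{bottom}}
  + P_i(t)$$

where $s(t)$ is the insulation scale factor (events scale only the
lateral/external coupling; the base-loss path stays intact, so night-time
heat loss through the unwrapped column base is reproducible). Default
node parameters — C = 512 J °C⁻¹ (≈0.16 kg of sediment at
c_s = 3200 J kg⁻¹ °C⁻¹ per node), K_ext = 0.15, K_int = 0.1,
K_base = 0.05 W °C⁻¹ — give node time constants of ~35–60 min, long
enough to reproduce the observed lag of the columns behind incubator
transitions while keeping a 7-day simulation fast.

The incubator trace is a first-order response (τ = 30 min) to
`base + amplitude × light fraction` (defaults 22.2 + 7.5·f °C, spanning
the 22–30 °C operating band), plus white noise, clipped to the band.
Optional disturbance spikes (laboratory-light switching) affect only the
external reference channels.

Sensor channels are node temperatures plus a fixed per-channel offset,
Gaussian noise (default SD 0.05 °C, about one quantization step — typical
for this sensor family and enough to dither the quantizer), quantized to
0.0625 °C; the incubator reference uses a separate higher-resolution
device and is not quantized. Technical interruptions delete whole records.

Integration is fixed-step explicit Euler with an enforced stability bound
(step ≤ 0.1 × the smallest C/K time constant; violations are errors that
suggest a smaller step). Euler makes the energy bookkeeping exact by
construction — per step, $C\,\Delta T$ equals the recorded flux times the
step — which the tests verify to 0.1 %. Step-response accuracy against
the analytic single-node exponential is held under 0.5 % of the step size
at a 30 s step. All randomness derives from a single integer seed; the
seed is saved and restored around the caller's RNG state, so identical
configurations give bit-identical logs without perturbing the session.

### The default scenario, and what it does and does not emulate

`scenario_default()` places a light-modulated source on the living
column's top node — phototrophy-coupled aerobic activity in the oxygen-
rich upper sediment — and a small constant source (default 0.01 W) on the
bottom node. The top-node power is back-solved from the steady-state
network solution so that the living column's internal gradient exceeds
the control's by a configurable target, default 0.25 °C, under full
illumination: far below the idealized adiabatic limits (real sediment
heat production fluctuates with growth stage and loses heat continuously),
but comfortably above the per-day noise floor so a week of simulated data
yields an unambiguous detection. Default per-channel offsets are zero:
the scenario's purpose is to exercise detection of a known injected
source, and a zero-offset default makes the null scenario (sources
zeroed) genuinely null. Real sensors carry offsets up to ±0.5 °C, and
offset confounding — a central caveat for the real experiment — can be
studied by configuring `sensor_model(offsets = ...)`.

The generator emulates: the diurnal 22–30 °C forcing, sediment thermal
lag, localized light-modulated heat injection, per-sensor offsets,
Gaussian read noise, 0.0625 °C quantization, logging gaps, external
reference channels with ambient disturbance spikes, and insulation as a
conductance reduction. It does **not** emulate: spatially continuous heat
conduction, microbial population dynamics or community shifts (sources
are fixed power profiles), evaporation and water-level changes,
sensor drift, or incubator door-opening transients. Passing tests on
synthetic data therefore demonstrate that the *pipeline* recovers known
injected signals under realistic instrument noise — not that any
particular real dataset contains such signals.

## Problem sizes and determinism

The test suite and the acceptance script run simulations of 1–7 days at
60 s sampling (≈1 440–10 080 records per day set), sizes chosen because
every statistic of interest (per-day phase means, their across-day
spread, retention windows) stabilizes within a week of simulated data
while the full suite stays fast. Pipeline tables are written with fixed
formatting so identical inputs give byte-identical outputs; the run
manifest records the configuration and a content fingerprint.

## Known limitations

* The living-vs-control contrasts assume the two columns share incubator
  forcing exactly; in reality vertical gradients inside the incubator and
  sensor placement asymmetries contribute systematic offsets that only
  external references and differential calibration can bound.
* Retention statistics require three valid phase-days on each side of an
  event; short logs or gap-riddled windows fail loudly rather than
  degrade silently.
* The binned Mann–Whitney procedure answers a narrower question than a
  raw-sample test (see above); both are reported, and conclusions should
  rest on the estimator hierarchy (per-day phase means) rather than on
  either omnibus p-value alone.
* Measured long-term values from the original six-month deposited dataset
  are not reproduced here; ingesting that dataset through
  `read_temp_log()`/`run_pipeline()` is supported as an optional
  replication workflow.
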