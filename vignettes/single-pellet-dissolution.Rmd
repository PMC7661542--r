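---
title: "Measuring single-pellet dissolution with a vibrating-tube buoyant-mass sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-pellet dissolution with a vibrating-tube buoyant-mass sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletmass)
```

## The measurement

Controlled-release oral drug products are often capsules filled with many
small coated pellets, and the clinically relevant quantity is how fast each
pellet releases its payload. Instead of measuring the drug concentration
accumulating in the dissolution medium, this package works with the
complementary signal: the *decrease in the buoyant mass of the solid
pellet* while it dissolves, measured by a vibrating glass tube.

A fluid-filled glass tube bent into a tuning-fork shape resonates at a
frequency set by its mass. A pellet carried through the tube by a
peristaltic pump momentarily replaces fluid of its own volume, changing
the vibrating mass by the pellet's buoyant mass

$$m_b \;=\; m\left(1 - \frac{\rho_{\mathrm{fluid}}}{\rho_{\mathrm{pellet}}}\right)
      \;=\; V\,(\rho_{\mathrm{pellet}} - \rho_{\mathrm{fluid}}),$$

where $m$ is the absolute (in vacuo) mass and $V$ the volume. We use this
standard form throughout: a pellet denser than the fluid has *positive*
buoyant mass, adds mass to the tube, and lowers the resonance frequency,
so its transits appear as *downward* frequency peaks. (The alternative
form with the density ratio inverted would assign sinking pellets negative
buoyant mass, which contradicts both the sign of the observed frequency
dips and the positive masses one wants to report; `buoyant_mass()`
implements the convention above.)

Because the tube's vibrational amplitude is zero at its mounted bases and
at the midpoint between the tines and maximal at the two tine tips, one
passage produces **two** frequency extrema — one per tip — and the average
of their two heights is the transit's measurement. The simulator models
the amplitude weighting as $w(s) = \sin^2(2\pi s)$ along the normalized
path coordinate $s$; any smooth function with nodes at $s = 0, 0.5, 1$ and
maxima at $s = 0.25, 0.75$ would be consistent with the qualitative
picture, and $\sin^2$ is the simplest differentiable choice.

Buoyant mass confounds mass change with density change. When that matters,
measuring the same pellet in two fluids of different densities separates
the two: `solve_two_fluid()` inverts $m_{b,i} = V(\rho_p - \rho_{f,i})$
for $(m, V, \rho_p)$ exactly.

## The pipeline

`run_pipeline()` (or the equivalent chain of functions) turns a raw
two-column trace into a dissolution profile:

```{r, eval = FALSE}
pump <- pump_schedule(reversal_period_s = 10, transit_duration_s = 2)
profile <- read_trace("trace.csv") |>
  lowpass(pump = pump) |>
  estimate_baseline() |>
  detect_transits(pump = pump) |>
  to_mass_series(cal) |>
  fit_dissolution_profile()
```

**Filtering.** `lowpass()` is a 4th-order Butterworth applied forward and
backward (zero phase, so extremum times do not shift). The default cutoff
is $5/\text{transit duration}$ (2.5 Hz at the 2 s default): a transit lobe
has its fundamental near $2/\text{transit duration}$, so the cutoff passes
the peak shape essentially unattenuated (the measured depth error is below
0.1%) while removing sample noise far above it. The series is mean-removed
and reflect-padded around the filter so the DC gain is exactly 1 and a
constant trace passes through unchanged.

**Baseline.** The paper-style analysis measures peak heights *relative to
baseline*, but no baseline estimator is prescribed; we use a rolling
median over `window_s` (default 3 pump reversals, 30 s) with one masking
refinement: samples deviating from the first-pass median by more than 4
robust SDs are replaced by it and the median recomputed. The median runs
on a decimated grid (the baseline varies on drift timescales, hours) and
is interpolated back to every sample.

**Transit detection.** Samples whose baseline-subtracted magnitude
exceeds `min_prominence_hz` are clustered; gaps larger than 0.75 transit
durations separate clusters (the two lobes of one transit sit half a
transit duration apart, consecutive transits a full reversal period
apart). Within a cluster the largest-magnitude sample is the first
extremum, a window of a quarter transit duration around it is masked, and
the largest remaining sample — required to be at least 10% of the primary,
so filter skirts cannot masquerade as a lobe — is its partner. The default
prominence is 5 robust SDs (median absolute deviation) of the
baseline-subtracted trace, floored at $10^{-4}$ Hz for noiseless input.
Pairs whose heights differ by more than 25% are flagged `asymmetric-pair`
but kept (the two heights are averaged unconditionally); lone extrema are
flagged `singleton-peak` and excluded from the mass series by default.

**Calibration.** `fit_density_calibration()` fits mean resonance
frequency against known fluid density by ordinary least squares; the
linear model is adequate over the narrow 1.00–1.08 g/mL span even though
the underlying resonator law is nonlinear in total mass.
`fit_point_mass_calibration()` divides the known buoyant mass of a
reference microbead by the mean of its replicate peak heights to get the
constant $K$ (g/Hz); magnitudes are used, so the result is independent of
the sign convention. `estimate_resolution()` interprets "the width of the
distribution" of replicate height measurements as the 1-sigma sample
standard deviation (a configurable multiplier is provided since FWHM or
other widths are defensible readings) and converts it through $K$; this is
the per-point mass uncertainty attached to the series.

## Dissolution profiles

A profile is piecewise linear in time with possible abrupt jumps, and the
two kinds of feature are handled separately: a 50 µg loss inside 10 s
would dominate any least-squares slope if left in.

**Jumps.** `detect_jumps()` flags consecutive-point drops of at least
`min_drop_ug` completed within `max_span_s`, merging adjacent qualifying
intervals into one event. `min_drop_ug` must exceed the largest
per-interval drop the smooth phases can produce (|rate| × sampling
interval) plus a noise margin; the automatic default is 10 point
uncertainties, floored at 5 µg. The raw drop across an event is biased by
the local dissolution trend, so after segmentation each jump is
re-estimated: the event is modelled as a linear ramp between the flanking
segments' fitted lines with the after-segment's rate running concurrently
through the ramp, the ramp endpoints chosen by least squares over the
points inside the event (a 16 × 16 grid). For the canonical 50 µg/10 s
event preceded by a −33 µg/min phase this removes a ~3 µg bias.

**Segmentation.** Changepoints are placed by binary segmentation over
per-segment linear least-squares cost, implemented on prefix sums so any
candidate split costs O(1). A split is accepted while the reduction in
total squared residual exceeds a per-changepoint penalty; the default is
BIC-style, $3\hat\sigma^2\log n$, with $\hat\sigma$ the robust SD of first
differences divided by $\sqrt 2$ and floored at $10^{-3}$ µg so noiseless
input is not over-segmented. Three extra parameters per changepoint (slope,
intercept, location) motivate the factor 3. This makes the segmentation
invariant to time shifts and to mass rescaling (penalty and gains both
scale with $\sigma^2$). Segments need at least 3 points; boundaries abut
at midpoints between neighbouring data points, except at jumps where both
flanking segments meet at the event time. No objective phase-boundary
criterion exists in the descriptive narratives this mirrors, so the
penalty is an explicit tuning knob.

**Metrics.** `compute_metrics()` reports: starting mass (median of the
first segment when it is flat, otherwise the fitted line at its start —
the median of a sloped segment would be biased by half its drop); ghost
mass (same rule on the last segment, or 0 when the last few measurements
end below the dissolved threshold); ghost fraction (100 × ghost/start);
onset (first segment or jump whose |rate| exceeds `rate_floor_ug_min`,
default 0.05 µg/min); completion (first measurement below the dissolved
threshold). The dissolved threshold defaults to the series' *detection
floor* — the smallest mass the prominence threshold can witness — plus 3
point uncertainties: a pellet whose transits have sunk below the
detection floor is operationally dissolved, and a threshold below that
floor could never be crossed by data.

**Mass balance.** For any fitted profile, start − ghost should equal the
summed |jump| magnitudes plus the rates integrated over their segments.
`mass_balance()` reports the residual and an aggregate uncertainty with
stochastic terms (start/ghost medians, segment-rate standard errors, jump
estimates) plus three deterministic discretization bounds added linearly:
the unobserved terminal mass when the pellet dissolved below threshold;
the trend ambiguity |r_before − r_after| × gap/2 across an excised jump;
and, at each interior boundary, the changepoint-placement artifact — a
kink is estimated on the data grid, so the flanking fitted lines disagree
at the boundary by |Δrate| × placement error, measured directly as the
observed line gap there (never less than the noiseless |Δrate| ×
spacing/2 bound).

## The simulator

`simulate_experiment()` is the forward model every stage is tested
against: baseline = base frequency + density offset + linear drift; one
transit per pump reversal with the pellet's path coordinate advancing
linearly across `transit_duration_s` (constant flow within a stroke);
frequency dip = responsivity × buoyant mass × $w(s)$; i.i.d. Gaussian
noise per sample. Defaults mirror the instrument configuration the
package models: 474.25 Hz base frequency, sampling every 2 ms (once per
oscillation period), flow reversal every 10 s, and a responsivity whose
reciprocal $K = 1.8\times10^{-3}$ g/Hz pairs a 0.1 Hz peak with a 180 µg
pellet. The density slope (−300 Hz per g/mL) and the transit duration
(2 s) are not printed quantities; they are plausible values for this
sensor class, and the transit dwell profile inside the tube is genuinely
unknown, so `transit_duration_s` is a free parameter.

Scheduled trajectories (`dissolution_schedule()`) are ordered
constant-rate phases plus jump events ramped linearly over their span
(span 0 = step), clipped at a floor representing the insoluble ghost.
After the last declared phase the final rate continues until the floor is
reached, then holds: a dissolution run ends at the residue, not at an
arbitrary bookkeeping boundary, and this is the semantics under which the
canonical delayed-release trajectory (170 µg start, −33 µg/min burst,
50 µg jump, −2.5 µg/min tail, 15 µg ghost) evaluates to 15 µg at 40 min.
Declare a trailing zero-rate phase to hold a level instead.

What the simulator deliberately does **not** model: pellet hydrodynamics
(dwell-time variation, off-axis passage), temperature effects on the
resonance, multi-pellet transits, non-Gaussian or correlated sensor
noise, and any feedback of dissolved material on the bulk fluid density
(the sensed volume is continuously exchanged by pumping). Passing tests
on simulated data therefore demonstrate that the *analysis* recovers the
*model's* truth; instrument-specific behaviours outside the model are not
covered, and the physical sensor's own resolution figure can only be
reproduced by constructing fixtures with a matching replicate spread.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds
(`withr::with_seed()`), so identical configuration plus seed reproduces
byte-identical artifacts. The test-suite and acceptance runs use the
study conditions the package documents: a 40-minute experiment at 2 ms
sampling (1.2 million samples, 240 transits) for the oracle-equivalence
checks; 10-minute holds at five densities for the density calibration; 50
bead transits for the point-mass constant and 200 replicate heights for
the resolution estimate; and 100 seeded replicates of the two-phase
recovery experiment (−0.18 then −1.5 µg/min, break at 30 min, 0.2 µg
noise, 10 s cadence).

## Known limitations

- Two pellets in the tube at once produce overlapping peak pairs the
  detector will mis-pair; multi-pellet disambiguation is out of scope.
- The jump refinement assumes one ramp per event between two locally
  linear phases; overlapping jumps inside one inter-segment gap are
  merged.
- The linear density calibration extrapolates (with a warning) outside
  its fitted 0.08 g/mL span; the resonator law is not linear far from it.
- Buoyant mass is blind to density-matched pellets; use
  `solve_two_fluid()` with a second fluid, or add a densifier to the
  medium.
- Streaming/real-time processing is not supported; traces are analysed in
  memory.
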