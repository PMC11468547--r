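---
title: "Modelling fibrotic encapsulation from implant electrical telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fibrotic encapsulation from implant electrical telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromark)
```

## The problem

A cochlear-implant array sits in conductive perilymph at insertion; over
weeks, fibroblasts deposit and contract an extracellular-matrix sheath
around it. Electrically, the tissue next to each contact becomes more
resistive and less capacitive, while the platinum-iridium
electrode-electrolyte interface itself changes little. `fibromark` turns
that picture into a quantitative pipeline: fit an equivalent circuit to
impedance spectra, simulate the voltage response to the implant's biphasic
pulses in closed form, and extract markers that clinical telemetry can
measure in a living patient.

## The equivalent circuit

The one-port is a constant phase element (CPE) in series with a parallel
RC block and a series resistor:

$$Z(\omega) = \frac{1}{Y (j\omega)^p} + \frac{R_1}{1 + j\omega R_1 C} + R_2$$

* `Y` (CPE-T, S·s^p) and `p` (CPE-P, unitless, in (0, 1]) describe the
  non-ideal interface capacitance; the CPE's phase is exactly $-90p$
  degrees at every frequency, and `p = 1` recovers an ideal capacitor.
* `R1` (ohm) and `C` (farad) describe the bulk tissue or tissue-engineered
  construct — the elements fibrosis moves.
* `R2` (ohm) is the access path through medium and ground; it is not
  expected to change and is fixed from the first fitted timepoint in
  longitudinal fits.

A legacy two-element model (access resistance plus a polarization RC,
`simple_circuit_impedance()`) is included as the comparison circuit; on
CPE-generated spectra its best fit always leaves a larger weighted residual,
which is the quantitative argument for the CPE circuit.

## EIS fitting

Spectra are measured from 10 Hz to 100 kHz at 10 points per decade; we
include both endpoints, giving 41 points (`eis_frequency_grid()`). Three
repeat sweeps per electrode and timepoint are averaged (arithmetic mean of
magnitude and phase per frequency) before fitting; the repeat scatter also
feeds the quality screen.

**Quality control** (`qc_screen()`) excludes a recording when any of three
rules fires: the upper quartile over frequencies of the per-frequency phase
standard deviation exceeds 4 degrees (unstable contact); the mean magnitude
at 10 Hz exceeds 50 kOhm (open circuit / broken electrode); or the mean
phase lies strictly inside (-20, 0) degrees anywhere from 10 Hz to 1 kHz
(near-resistive behaviour, e.g. an air bubble). "Upper quartile above 4
degrees" is our reading of the screening convention "the 25% highest
standard deviations above 4 degrees"; the boundary values of the phase
interval do not trigger exclusion.

**Cost.** Fits minimise the complex calc-modulus weighted residual
(`weighted_ssq()`):
$$\frac{100}{N}\sum_i \frac{(\mathrm{Re}\,Z_i-\mathrm{Re}\,\hat Z_i)^2 +
(\mathrm{Im}\,Z_i-\mathrm{Im}\,\hat Z_i)^2}{|Z_i|^2}$$
a percentage-scale quantity proportional to the mean squared fractional
error. We weight by the data modulus; weighting by the model modulus is a
switchable option (`weighting = "model"`), since modulus-weighting
conventions differ between instruments.

**Start values** follow the instrument-era recipe: `p` starts at 0.8; `Y`
is solved from the CPE formula at 10 Hz assuming the CPE carries the whole
magnitude there; both resistors start at the 100 kHz magnitude; `C` is
solved from the ideal-capacitor formula at 10 Hz. The capacitor start is
knowingly crude — at 10 Hz the CPE, not `C`, dominates, so this start
overshoots the bulk capacitance by two to three orders of magnitude.

**Optimiser.** Bounded Levenberg-Marquardt (`minpack.lm`) on
log-transformed elements (they span six orders of magnitude and must stay
positive), bounds (1e-12, 1e6) in SI units — effectively unconstrained —
with `p` additionally capped at 1; cost tolerance 1e-10; iteration cap 100.
Because a single launch from the crude capacitor start reliably lands in a
local minimum (we measured weighted residuals near 2% on noise-free data),
`fit_spectrum()` launches the minimiser from a deterministic ladder of
capacitance start decades (one decade up through five down) and keeps the
lowest-cost solution. Each launch respects the 100-iteration cap. This is
the package's stand-in for the two-stage iteration scheme of commercial
fitting software.

**Time courses** (`fit_timecourse()`): the first QC-passing timepoint is
fitted with all five elements free; `R2` is then fixed bit-for-bit at that
fitted value; each later timepoint warm-starts from the previous result.
QC-excluded timepoints become explicit gaps, never interpolations.

## Pulse transients in closed form

The biphasic charge-balanced stimulus (cathodic-leading, amplitude
$i_{amp}$, phase duration $T_0$, optional interphase gap) is a sum of
current steps. Each step contributes a shifted copy of the circuit's
analytic unit-step response

$$r(t) = \frac{t^p}{Y\,\Gamma(p+1)} + R_1\!\left(1 - e^{-t/(R_1 C)}\right) + R_2,$$

so for zero gap
$V(t) = -i_{amp}\,[\,r(t)u(t) - 2r(t-T_0)u(t-T_0) + r(t-2T_0)u(t-2T_0)\,]$,
and a positive gap contributes four shifted terms. Samples at switching
instants take the right-limit value, a convention shared by both backends.
`simulate_waveform_numeric()` is an independent oracle: it obtains $r(t)$
by Gaver-Stehfest numerical inversion (14 terms) of $Z(s)/s$ and superposes
the same steps; the two backends agree to better than $10^{-3}$ of the peak
away from switching instants, and the $p = 1$ limit matches the textbook
resistor-capacitor response to $10^{-6}$.

## Waveform preprocessing

Raw repeats (nominally 15 per electrode, pulse and timepoint) pass through,
per repeat and in this order: a causal first-order digital Butterworth
low-pass at 80 kHz; decimation by plain sample-picking (factor 20, the
filter being the anti-alias step); and subtraction of the mean of the first
500 output samples, a pre-stimulus window (80 us at the decimated 6.25 MHz
rate). Mean and standard deviation across repeats are then taken. The
filter is referenced to each trace's initial value so a constant
environmental offset passes without a start-up transient and is removed
exactly by the baseline correction.

Two numerical facts worth knowing. First, the synthetic raw rate defaults
to 125 MHz so that decimation by 20 gives 6.25 MHz, on which 500 samples
span exactly 80 us; the true acquisition rate is an explicit argument
everywhere, so nothing depends on that choice. Second, a causal first-order
filter tracks the CPE voltage ramp with a steady lag of roughly
$1/(2\pi f_c) \approx 2$ us times the local slope — about 1–2% of the peak
— in addition to its transient. Round-trip tests therefore assert agreement
at the 3% level; sub-percent agreement is not achievable with this filter
chain and claims otherwise would be testing the wrong thing. Marker
definitions are ratios or peak picks and are far less sensitive to the lag.

**Onset detection** (`detect_onset()`) finds the single two-segment split
minimising the pooled zero-mean Gaussian cost — the standard change point
in RMS level — restricted to candidate splits *before* the absolute peak
sample. Unrestricted, the split prefers the pulse-to-tail transition on
records with a long quiet tail. A detected change must exceed three times
the pre-onset standard deviation, otherwise the trace is declared flat.

## Markers

* `contact_impedance()`: max $|V|$ over the first-phase window divided by
  $i_{amp}$. For this circuit the first-phase extremum sits at the phase
  end, so "peak" and "end of phase" coincide; the peak is used because it
  is robust to noise.
* `sppr()`: the second-phase opposite-polarity extremum as a percentage of
  the first-phase peak. Magnitudes are used throughout, so the marker is
  invariant to polarity and amplitude.
* `altered_sppr()`, `patient_contact_impedance()`: the clinical variants
  computed from telemetry voltages sampled 6 us into each phase and at the
  25 us end of phase one, normalised to input current. Signed voltages are
  accepted; magnitudes are taken.
* `sppr_slope()`: ordinary least squares of SPPR against day over
  construct-on timepoints, refusing (an explicit refusal object, not zero)
  with fewer than three timepoints or no timepoint beyond day 7 — before
  the bulk-resistance inflection a slope is not a progression rate. The
  last included day is returned for pairing with EIS fits.
* `cl_to_microamps()`: $17.5 \cdot 100^{CL/255}$.
* `pearson_ci()`: Pearson r with the Fisher-z 95% interval (via
  `stats::cor.test`).

**Validity domain of the SPPR mechanism.** The mechanism — capacitive
discharge contributes less to the second phase as `C` falls, so SPPR rises
with fibrosis — holds when the bulk discharges within a phase,
$R_1 C \lesssim T_0$. Outside it (e.g. $C$ near 1 uF with $T_0 = 50$ us)
the second-order terms invert both monotonicities by a few hundredths of a
percentage point to a few points; our monotonicity tests sweep one element
at the operating point of the others and tolerate 0.05 percentage points.
All fitted in-vitro trajectories in this package's regime sit well inside
the valid domain.

## Reverse (voltage-waveform) fitting

`vw_fit()` recovers `R1` and `C` from a measured waveform with the
interface (`Y`, `p`) and `R2` fixed at their baseline-day EIS values.
Bounds are 50–5000 ohm for `R1` and 1e-13–1e-7 F for `C`; a bounded local
least-squares search (L-BFGS-B on coordinates normalised to the bounds,
analytic gradient, relative tolerance ~1e-12) is launched from every pair
of `grid_n` linearly spaced starts per element — linear spacing on the raw
scale is kept deliberately, even though `C` spans six decades, to match the
reference procedure; a log-spaced option exists. The lowest sum of squares
over the $grid\_n^2$ searches wins; solutions within 0.1% of a bound are
flagged capped. The fitting window runs from onset through the pulse plus
an equal-length decay tail. The search is fully deterministic. The CPE and
`R2` step contributions do not depend on the candidate pair and are
precomputed once per waveform, which is what makes the 900-start default
affordable; tests and the bundled study runs use `grid_n = 10` with a
spot-check that `grid_n = 30` returns the same optimum on the same
waveform.

Capping is informative, not a failure: waveforms with low peaks — early
days, bulk resistance at or below the 50-ohm floor, bulk time constant
shorter than the filter lag — genuinely do not constrain both elements, and
the capped flags are carried through the study report so downstream
comparisons can exclude them (as the correlation tables do).

## The synthetic cohort generator

`make_cohort()` is the statistical stand-in for the wet-lab study: no real
recordings ship with the package, and every pipeline claim is tested
against generated data with retained ground truth.

Per electrode, baselines are drawn uniformly from
`Y` in [1e-6, 1.6e-6] S·s^p, `p` in [0.75, 0.85], `R1` in [25, 200] ohm,
`C` in [5e-9, 3e-8] F, `R2` in [100, 200] ohm. `R1` rises and `C` falls
along logistic (sigmoid) trajectories — chosen because the study's
inflection points are reported from post-hoc tests, not a functional form —
with fold-changes of 2–6x (R1) and 2–10x (C), inflection days drawn from
[7, 9] (R1) and [4, 7] (C), and a 1.2-day time constant. The interface and
`R2` stay constant. A configurable fraction (default 20%) of electrodes
has the construct contract off at a late day, after which parameters revert
instantly to baseline (no reversal kinetics are reported to emulate).
The two fold-changes are coupled through a shared latent severity factor:
both are driven by the same contraction process, and without that coupling
the slope-versus-final-C correlation would have no defined sign, because
`C` itself barely enters SPPR when $R_1 C \ll T_0$.

Measurement noise: per EIS repeat, log-normal multiplicative magnitude
noise (2%) and Gaussian phase noise (1 degree); per waveform repeat,
additive white noise (10 mV at the raw 125 MHz rate, i.e. ~0.4% of a
typical peak after filtering and averaging 15 repeats) plus a constant
per-repeat offset (2 mV) emulating environmental pickup. Degenerate
recordings (`degenerate_recording()`) are constructed to trip exactly one
QC rule each: open circuit (R2), air bubble (R3), unstable phase (R1).

Two generator choices deserve their reasoning spelled out, because the
obvious alternatives fail quietly:

* **Baseline magnitude regime.** The QC rules jointly pin the viable
  parameter window: the 10 Hz magnitude must stay below 50 kOhm while the
  1 kHz phase must stay steeper than -20 degrees, which bounds the *final*
  $R_1 + R_2$ by roughly $0.44^{-1}|Z_{CPE}(1\,\mathrm{kHz})|$ — about
  2 kOhm in this regime. Baselines are placed so that fibrotic endpoints
  respect both rules (>95% of non-degenerate timepoints pass QC).
* **Low baseline R1, higher baseline C.** Early-day bulk resistance extends
  below the 50-ohm reverse-fit floor — that is what produces the capped
  early fits and the bimodal reverse-fit distributions the method is known
  for, and an emulation without them would validate the wrong pipeline. At
  the same time, separating `R1` from `R2` in an EIS sweep that ends at
  100 kHz requires the bulk rolloff inside the sweep
  ($R_1 C \gtrsim 1.6$ us), which a higher `C` range preserves even at low
  `R1`. These two constraints cannot both be met with a low-C, high-R1
  baseline; the chosen regime satisfies recovery (median noisy-fit errors
  ~2% for R1, ~5% for C), QC compatibility and the capping phenomenology
  simultaneously.

What the generator does *not* emulate: electrode nonlinearity and Faradaic
effects, amplifier saturation, drift within a sweep, inter-experiment
variance components, or mechanistic fibrosis biology (the trajectory shape
is phenomenological). Passing tests on this cohort therefore demonstrate
that the analysis chain is correct and well-conditioned under the study's
stated noise model — not that the biological effect sizes are predicted.

## The study driver

`run_study()` chains the whole analysis: QC and ledger, per-electrode EIS
time-course fits, waveform preprocessing, markers and normalisation to the
baseline day, SPPR slopes with refusals, reverse fits with cap flags, and a
correlation table — SPPR slope against the EIS-fitted `R1` and `C` at each
slope's final included day, and reverse-fitted against EIS-fitted elements
at matched electrode/timepoints, reported for all fits, with capped fits
excluded, and additionally (for `R1`) excluding reverse fits above 2 kOhm.
Inputs are either CSV files (schemas in `read_eis_csv()`,
`read_waveform_csv()`, `read_patient_csv()`) or a `cohort_config()` for
synthetic mode; outputs are tidy tables plus a JSON manifest
(`write_report()`). Significance machinery beyond the correlation table
(ANOVA families, post-hoc tests) is deliberately left to downstream
statistical tools — the tables are the interface. The exported functions
and this vignette are the package's operational surface; there is no shell
entry point.

Problem sizes used by the bundled validation: oracle comparisons on a
3x3x3 parameter grid at 6.25 MHz; 20 noise-free and 50 noisy EIS
recoveries; 20 out-of-bounds reverse fits at `grid_n = 10`; a 30-electrode,
6-day cohort run end to end. A full run of the suite takes a few minutes on
one core.

## Known limitations

* The CPE convention is $Z = 1/(Y(j\omega)^p)$; CPE-T values are only
  comparable across instruments under this convention.
* EIS cannot separate `R1` from `R2` when the bulk rolloff lies above the
  sweep's 100 kHz end; their sum is still well determined.
* The reverse fit fixes the interface at baseline; interface drift over a
  time course would be absorbed into `R1`/`C`.
* Triphasic and pseudo-monophasic stimuli, Kramers-Kronig validity testing
  and Warburg/inductive elements are out of scope.
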