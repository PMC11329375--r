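---
title: "Models and methods behind navloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind navloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navloop)
```

`navloop` quantifies a positive feedback loop proposed for invasive
breast carcinoma cells: persistent Na⁺ influx through the cardiac-type
voltage-gated sodium channel Na_v1.5 loads the cell with Na⁺, the
Na⁺/K⁺ ATPase (NKA) burns glycolytic ATP to export it, glycolysis
exports H⁺, and the resulting extracellular acidification in turn
enlarges the persistent Na⁺ current. The package implements each link
of that chain as a testable component: a synthetic voltage-clamp
generator, the whole-cell analysis pipeline, a stoichiometric
acidification model, a feedback simulator, the measurement-calibration
procedures, and the modified Allred immunohistochemistry scorer.
Everything is validated by recovery: synthetic data are generated from
declared ground truth and each estimator must give that truth back.

## The forward current model

The generator produces whole-cell sweep families under the two standard
gating protocols (holding −120 mV for 250 ms; 50 ms test steps from
−120 to +30 mV for activation; 250 ms prepulses followed by a 50 ms
test pulse to −10 mV for steady-state inactivation). Per command step
$V$ the current is

$$I(t) = g_{\max} C_m\, m_\infty(V)\,
  \bigl[p + (1-p)\,h(t)\bigr](V - E_{Na}) + g_{leak}(V - E_{leak})
  + \varepsilon(t),$$

with $m_\infty$ and $h_\infty$ the Boltzmann activation and
availability curves $1/(1+\exp((V_{1/2}-V)/k))$ (signed $k$: positive
for activation, negative for inactivation), $h$ relaxing exponentially
with time constant $\tau_h$ from its pre-step steady state, and $p$ the
persistent fraction of the conductance that never inactivates.
Activation is treated as instantaneous because only inactivation
kinetics matter on the 20–25 ms persistent-current timescale; the
default $\tau_h = 1.5$ ms (typical of Na_v1.5) puts the transient peak
well before that window. Emitted sweeps are amplifier-zeroed at the
holding level, as a real recording is.

Parameters the underlying experiments do not publish are declared
defaults, not inferences: the reversal potential comes from the Nernst
equation for the stated solutions (≈149 mM extracellular Na⁺ including
NaOH titration, 5 mM pipette Na⁺, 21 °C, giving +86.0 mV), membrane
capacitance defaults to 20 pF, linear leak to 1 nS, and recording noise
to Gaussian white noise with SD 0.05 pA per 50 kHz sample. The noise
default represents the *effective post-filter* baseline noise of a
low-noise whole-cell recording; it must be sub-picoampere for the
conservative half-peak-to-peak correction (below) to leave a −6 pA
persistent current measurable at all, exactly as in the recordings it
emulates.

`nav15_channel()` packages the published MDA-MB-231 gating means at
extracellular pH 7.2 and 6.2, with $g_{\max}$ and $p$ calibrated by
closed-form inversion so the noiseless forward model reproduces the
corresponding peak (−13.5 / −9.6 pA/pF) and persistent (−0.31 /
−0.71 pA/pF) current densities. Both inversions target the
amplifier-zeroed current — the quantity a measurement actually
reports — which makes the zero-noise generator/estimator round trip
exact to <10⁻³ pA/pF.

## The analysis pipeline

* **P/6 leak subtraction.** Six 1/6-amplitude leak pulses per sweep;
  the summed scaled subsweeps estimate the linear leak, which is
  subtracted. The generator delivers the leak pulses hyperpolarising
  from a −150 mV subsweep holding — the standard channel-sparing
  choice; depolarising subpulses from −120 mV would reach ≈−100 mV,
  where this channel's window current is large enough to corrupt a
  −0.31 pA/pF persistent measurement by several percent.
  `leak_subtract()` references each trace to its own pre-depolarisation
  baseline before scaling, as P/N processing does when leak pulses come
  from a separate holding level. For an ideal ohmic leak the removal is
  exact; the corrected trace carries 7× the single-sweep noise
  variance.
* **Noise correction.** Half the peak-to-peak baseline noise in the
  10 ms before depolarisation is subtracted from the inward-current
  magnitude — a deliberately conservative convention for small-current
  detection. The noise is measured on the raw (pre-P/6) baseline by
  default, since P/6 inflates baseline noise 7-fold and would
  exaggerate the correction; plain baseline-mean subtraction is
  available as `mode = "baseline"`.
* **Peak and persistent densities.** Most-negative current in the
  first 10 ms (pA/pF), and the mean over the closed 20–25 ms window
  after depolarisation (evaluated at the 0 mV step), respectively.
* **Gating curves.** The activation curve is the max-normalised
  conductance transform $G(V) = I_{peak}/(V - E_{Na})$; the
  inactivation curve is the normalised test-pulse *transient* (peak
  minus the sustained 20–25 ms level of the same test pulse), so the
  non-inactivating component — which carries no availability
  information — cancels exactly. The raw-peak measure remains available
  via `measure = "peak"`.
* **Boltzmann fitting.** Bounded Levenberg–Marquardt
  (`minpack.lm::nlsLM`) of the signed-$k$ single form, started from the
  interpolated 0.5 crossing and a quarter of the 0.25–0.75 span, with
  $|k|$ bounded to [1, 50] mV. The cohort pipeline fits with a free
  amplitude (a free-$G_{\max}$ fit): the −120…+30 mV protocol leaves
  $m_\infty(+30) = 0.986$, so a unit-amplitude fit of the
  max-normalised curve is inflated by 1.4% and its $V_{1/2}$ biased by
  ≈0.5 mV. With the free amplitude the zero-noise pipeline recovers the
  generating $V_{1/2}$ and $k$ to <0.05 mV.
* **Window current and availability.** The pointwise product
  $m_\infty h_\infty$ on a voltage grid, and per-cell
  $h_\infty(V_m)$ at the reported resting potential −18.9 mV averaged
  over cells. Published per-cell availabilities (1.9→4.9% at pH
  7.2→6.2, and 2.1→10.3% at pH 7.2→6.0) derive from per-cell fits of
  the ten largest-current cells that are not published, and are **not**
  reproducible from the cohort-mean parameters (which give ≈0.07% and
  ≈1.0%); the package therefore validates `availability_at()` against
  the direct Boltzmann formula rather than against those numbers.

## Stoichiometric prediction of channel-dependent acidification

Assuming a stable intracellular [Na⁺] — every Na⁺ ion entering through
the channel is pumped back out — the chain is: persistent current
density × capacitance → Na⁺ influx (mol/s, dividing by Faraday's
constant); ÷3 Na⁺ per ATP (NKA stoichiometry) → glycolytic ATP demand;
×1 H⁺ per glycolytic ATP (2 ATP and 2 lactate per glucose, and lactate
production coupled to ATP hydrolysis nets one H⁺ per ATP) → H⁺ export;
scaled by 3.0×10⁴ cells per well in 180 µl and divided by the medium's
buffering power to give mpH/min.

```{r ecar}
predict_ecar(-0.31, capacitance_pf = 20)
```

The buffering power is a single lumped linear coefficient (the assay
medium is bicarbonate-free, so no CO₂ chemistry is modelled); the
default 1.65×10⁻⁴ mol/L/pH is the package's reproduction constant for
the published 1.3 mpH/min prediction and is consistent with a lightly
buffered DMEM-based assay medium. The prediction sits within an order
of magnitude of the measured TTX-sensitive ECAR (9.8 ± 1.7 mpH/min),
which `order_of_magnitude_check()` formalises as max/min ≤ 10. The
Seahorse-style generator mimics the measured comparator: 6-minute
measurement cycles, six basal cycles, an injection with an exponential
artefact that returns to baseline within 15 minutes (excluded by the
estimator), and a sustained step change in treated wells; the effect
estimator takes the mean of the last six timepoints per well and
differences control − treated, with an SEM over plate repeats.

## The feedback loop

The loop is closed at the level of the persistent current density
only. pH_e follows

$$\frac{d\,\mathrm{pH}_e}{dt} = \lambda(\mathrm{pH}_{bath} -
  \mathrm{pH}_e) - \frac{g}{1000}\,\mathrm{ECAR}(\mathrm{pH}_e),$$

where ECAR is the stoichiometric chain evaluated at
`current_vs_ph(pH_e)`, a monotone map anchored exactly at
(7.2, −0.31) and (6.2, −0.71) pA/pF. Only two pH points were measured,
so the interpolation form is a declared assumption: linear in pH by
default, clamped flat outside [6.0, 7.4], with a log-[H⁺]-linear
alternative. The relaxation rate λ (default 0.01/min) and gain *g*
(default 1) have no published values; results are reported as
comparative statics — the steady-state pH is non-increasing in gain,
non-decreasing in λ, and the closed-loop/open-loop acidification ratio
(`feedback_amplification()`) is ≥1 and grows with the steepness of the
current–pH map. The fixed point is found by damped iteration with a
bisection fallback (tolerance 10⁻⁹); trajectories are integrated with
fixed-step RK4 (`deSolve`), and the terminal state agrees with the
fixed point to 10⁻⁶ across a parameter grid. One caution: the feedback
*weakens* the effective relaxation (λ_eff = λ − g·|ECAR′|/1000), so
trajectories need spans well past 1/λ to converge. Availability-based
modulation of the loop is deliberately not combined with the
current-density map: both derive from the same measured current change
and combining them would double count.

## Calibration procedures

* **pH microelectrodes.** Voltages lie on a line V = intercept +
  slope·pH (≈−58 mV/pH). Junction-potential offsets drift with each
  electrode placement and are measured every ≤12 measurements via a
  reference-bath reading at each calibration event (before, half-way,
  end); `apply_offset_schedule()` holds each block's offset
  piecewise-constant and subtracts it from that block's calibration
  points and measurements alike. The line is fitted by OLS with
  voltage as regressand (with 2–3 calibration points the direction is
  almost immaterial; both are offered) and inverted analytically. The
  zero-noise round trip recovers true pH to <0.01; at 1 mV noise the
  mean absolute error over 24 measurements stays below 0.05.
* **BCECF intracellular pH.** Two-point per-cell calibration
  (nigericin/high-K⁺ at pH 7.0 then 8.0); each cell's own line inverts
  its resting ratio — an interpolation identity, exact for any
  monotone two-point line — and the cohort value is the mean over ~40
  cells.
* **SBFI intracellular Na⁺.** Mean background per wavelength is
  subtracted before the 340/380 ratio; five-well plate means per
  repeat; the fold change is treated/vehicle per repeat. Background
  subtraction is what makes the estimator unbiased — the uncorrected
  ratio is provably compressed toward 1 — and the corrected estimator
  is invariant to any common gain on both wavelengths.

## The Allred scorer

The modified Allred score adds a 0–5 proportion bin (none; <1/100;
1/100–1/10; 1/10–1/3; 1/3–2/3; >2/3) to a 0–3 intensity score; totals
0–3 are "low", 4–8 "high". The published bin labels leave the boundary
assignment open, so the package declares one: the extreme bins are
strict (so exactly 1/100 scores 2) and each interior boundary belongs
to the bin it closes (exactly 1/10 → 2, 1/3 → 3, 2/3 → 4). The full
6×4 score table is enumerated in the tests.

## Validation cohorts: what they do and do not show

`recover_*` functions generate cohorts whose population parameters
equal the published values, run the full pipeline, and compare cohort
means with the generator truth at 2 SEM. Cohorts use 10 cells (11 for
the peak density, matching the published n), and modest inter-cell
scatter — V½ jitter SD 1 mV, 5% CV on slope factors, 10% CV on the
density targets, capacitance SD 2 pF — so that estimator behaviour,
not biological variability, dominates the cohort mean. The published
SEMs imply considerably larger biological scatter; a validation cohort
at that scatter would mostly measure sampling noise of the mean, which
is not the property under test. Consequently a passing recovery shows
the estimators are faithful to the forward model, not that the forward
model captures everything in real recordings: real data add
capacitive transients, series-resistance error, drift, 50 Hz pickup
and cell-to-cell gating heterogeneity that the generator deliberately
omits.

Numerical details worth knowing: the simulated peak is read one sample
(0.02 ms) after depolarisation, ≈1.3% smaller in magnitude than the
continuous-time peak the conductance calibration targets — negligible
against the 2-SEM bands; all sub-stream seeding discards a short
burn-in because a freshly seeded Mersenne–Twister state produces
correlated first draws across streams; and the 20–25 ms window is
closed on the sampling grid, giving 251 samples at 50 kHz.

```{r report, eval = FALSE}
# the full recovery table (seed-controlled, ~2 s)
reproduce_report(seed = 1)
```
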