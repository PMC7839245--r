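---
title: "Physiologically variable ventilation on a synthetic lung: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiologically variable ventilation on a synthetic lung: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvvent)
```

## What this package computes

Physiologically variable ventilation (PVV) replays the breath-by-breath
tidal-volume and rate variability of spontaneous breathing through a
pressure-controlled ventilator, instead of delivering identical breaths
(PCV). In emphysematous lungs, monotonous ventilation progressively
derecruits peripheral airspaces: effective elastance rises, delivered
volume falls, intrapulmonary shunt grows and oxygenation deteriorates;
sporadic large breaths are thought to reverse the closure. `pvvent`
implements the full computational chain needed to study that contrast on a
mechanical lung model, with every input available synthetically under
seeded reproducibility:

1. **Pattern derivation** — breath detection on plethysmograph-like traces,
   artifact exclusion, normalization to unit-mean pressure and period
   ratios, and ratio-preserving rescaling to target VT and rate.
2. **Ventilator simulation** — per-breath pressure-controlled waveforms
   applied to a single-compartment lung with a recruited-fraction state, a
   normocapnia rate controller and recruitment maneuvers.
3. **Forced-oscillation mechanics** — multisine forcing design, Welch
   cross-spectral impedance estimation, epoch averaging, circuit
   subtraction, and global fitting of the airway + constant-phase tissue
   model.
4. **Gas exchange** — oxygenation index, oxygen contents and the
   intrapulmonary shunt fraction Qs/Qt = (CcO2 − CaO2)/(CcO2 − CvO2).
5. **Imaging** — aerated-area quantification on fluoroscopy-like frames
   and mean linear intercept (MLI) morphometry on airspace masks.
6. **Study planning** — noncentral-t two-group sample size, dropout
   inflation, relative changes and Pearson correlation.

## The breathing-pattern model

Spontaneous breathing is synthesized as a concatenation of half-sine
deflections. Breath amplitudes and periods are lognormal — positivity with
realistic right skew — with AR(1) correlation (default 0.3) on the latent
normal scale; mild autocorrelation is a robust feature of resting
breathing. Calibration defaults are the awake COPD-rabbit statistics the
pattern is meant to emulate: mean amplitude 7.1 mL/kg with CV 12.6%, rate
22.9 /min with CV 12.9%. Movement artifacts are modelled as
uniform-amplitude broadband bursts (three times the mean breath amplitude)
with Poisson placement; the real artifacts are uncharacterized, so the
generator's version is a declared stand-in whose only job is to be
annotated, detectable and removable.

Breath detection low-passes the trace (2nd-order zero-phase Butterworth,
corner 3 Hz), subtracts a 5-s rolling-mean baseline, and finds inspiratory
peaks with a prominence of at least 25% of the median peak height.
Amplitudes are measured on the *undetrended* low-pass signal as the
excursion from the minimum between successive peaks: the rolling-mean
baseline is essential for stable peak finding but correlates with local
breath size, and measuring excursions on it inflates the detected
amplitude CV by several points. Periods are inter-peak intervals and are
never computed across an artifact-excision boundary.

A pattern is the detected breath list normalized to unit-mean pressure and
period ratios (exact to 1e-9 by a second renormalization); rescaling to
any mean VT and rate multiplies the two ratio columns and therefore
preserves every CV and every successive ratio identically. Pattern files
round-trip bit-exactly (17 significant digits, MD5-checksummed sidecar).

## The lung model and its recruitment dynamics

The forward lung is a single compartment: Paw(t) = R·V'(t) + E_eff·V(t) +
PEEP. The tissue side is the constant-phase model (damping G, elastance H,
exponent alpha = (2/pi)·atan(H/G)); the mapping to the compartment
parameters at breathing frequency f is documented as E_eff = H /
open_fraction and R = Raw + G/(2·pi·f)^alpha (the real part of the tissue
impedance at that frequency). The linear ODE is integrated with the exact
exponential update per sample, so stiff parameter combinations need no
special handling, and a square-wave drive reproduces the RC-charging
closed form VT = (ΔP/E)(1 − e^(−T·E/R)) to numerical precision.

Recruitment is a scalar open fraction in (0, 1]: closed units accept no
volume, so effective elastance is H divided by the open fraction. Closure
is exponential at `close_rate` (default 5e-4/min, losing ≈16.5% over 6 h
of monotonous 7 mL/kg breaths — inside the 15–20% design target); a breath
above `reopen_threshold` (9 mL/kg) reopens `reopen_gain` of the closed
units. The gain default (0.1) comes from a flux balance: with ≈2% of PVV
breaths qualifying at rate ≈23/min, reopening must supply ≈5e-4/min
against the closing flux near full recruitment; an order-of-magnitude
smaller gain cannot, and the variable mode would lose its recruitment
advantage entirely. This mechanism is deliberately minimal — a synthetic
stand-in for derecruitment, not a validated physiological model.

The normocapnia controller mirrors clinical practice: every 5 minutes the
forward gas model supplies an end-tidal CO2 estimate and the rate steps by
±1/min toward the 5.5–6% band, bounded to 10–60/min. Step, epoch and
bounds are pragmatic choices; only the target band is protocol-specified.

## Forced oscillations and the constant-phase fit

The default forcing carries 15 components spanning 0.5–20.75 Hz, built as
prime multiples of 0.25 Hz (primes 2, 7, …, 83). Distinct primes make the
set non-harmonic — no component is an integer multiple of another, so
nonlinear distortion of one line never lands on a neighbour — and the
0.25 Hz base puts every component on an exact bin of the 4-s analysis
windows. Phases are chosen by a seeded random search (64 candidates)
minimizing the crest factor, and the summed signal is scaled to its exact
peak-to-peak amplitude (default 2 cmH2O over 10 s).

Impedance is estimated Welch-style: 4-s Hann-tapered windows with 95%
overlap, Zrs at each design frequency as the averaged flow–pressure
cross-spectrum over the flow auto-spectrum. The cross-spectral form, with
per-frequency coherence as a quality metric, is robust to uncorrelated
noise: at 20 dB SNR the spectrum is recovered within 3% with coherence
above 0.99. Design frequencies without flow power are excluded (error if
more than a third). Three epochs per timepoint are averaged as complex
means, and the breathing-circuit calibration spectrum is subtracted
per-frequency (series convention).

The model Z(f) = Raw + i·2·pi·f·Iaw + (G − iH)/(2·pi·f)^alpha is fitted by
multi-start bounded local minimization (default 20 seeded log-uniform
starts; bounds Raw ∈ [1, 200], Iaw ∈ [0, 1], G ∈ [1, 500], H ∈ [10, 2000]
in cmH2O units) of the unweighted sum of squared complex residuals;
1/|Z|^2 weighting is available. Boundary-pinned solutions are flagged,
never silent. Noise-free spectra are recovered within 0.5% from any
admissible parameter set; with 5% relative Gaussian noise per component
and the protocol's three-epoch averaging, median parameter errors stay
below 5%. Without epoch averaging G settles at a 6–8% median error — an
identifiability property of the model at that noise level, worth knowing
when interpreting single-epoch fits.

## Gas exchange

The oxygen dissociation curve is a Hill function (P50 = 30 mmHg, n = 2.7 —
standard mammalian values appropriate to rabbit blood) chosen because it
is *exactly* invertible; the synthetic blood-gas generator and the shunt
estimator share it, so the generator/estimator round trip closes to
numerical precision rather than to curve-approximation error. The forward
model uses the alveolar-ventilation equation PaCO2 = 0.863·VCO2/VA, the
alveolar gas equation PAO2 = FiO2·(Pb − PH2O) − PaCO2/RQ, contents
1.34·Hb·SO2 + 0.003·PO2, shunt mixing of end-capillary and venous blood,
and recovers PaO2 by inverting the monotone content–tension map. Whether
end-capillary blood should be taken at alveolar tension or at full
saturation is not observable from the study's outputs; both routes are
provided, with the alveolar-gas route as default. Defaults (Hb 12 g/dL,
Pb 760, PH2O 47, RQ 0.8, VCO2 18.5 mL/min, dead space 2 mL/kg, venous PO2
40 mmHg) put a fully recruited lung at PaCO2 ≈ 41 mmHg and EtCO2 ≈ 5.7%
at the protocol's 7 mL/kg and 23/min — i.e. normocapnic by construction.
The baseline shunt (0.05) and the shunt added per closed fraction (0.7)
place the fully recruited lung near the healthy range and a 16% derecruited
lung near 16–17% shunt.

## Imaging

Fluoroscopy-like frames contain two elliptical "lung fields" in which an
exact number of pixels is dark (radiolucent = aerated); segmentation is a
recorded threshold (automatic Otsu by default) standing in for the study's
manual radiodensity segmentation, and aerated-area change is percent
change versus the H0 frame. The intensity separation (0.2 vs 0.65, noise
SD 0.04) makes threshold recovery of the ground-truth count exact in
practice; the generator does not attempt anatomical realism, overlapping
structures, or beam-hardening, so passing tests validate the counting
arithmetic, not radiological segmentation difficulty.

MLI lays evenly spaced test lines (default every 20 px) across a binary
airspace mask, measures maximal air runs, and divides total air length by
the number of *complete* air chords — chords touching the image edge are
dropped (truncation bias), as are chords touching an exclusion mask
(vessels/airways). The literature's alternative denominator (intercept
crossings) is available by flag. Stripe phantoms recover their band width
exactly; disc phantoms converge to the mean-chord value (pi/4)·d of a
circle under uniformly placed lines. Test lines parallel to a stripe
phantom produce the documented degenerate-field error, since no line
crosses an air–tissue boundary inside the mask.

## Study planning

The sample-size computation iterates the per-group n upward until the
exact noncentral-t power of the two-sided two-sample t test reaches the
target. At the planning defaults (20% detectable difference, 15%
interindividual CV, power 0.8, alpha 0.05) this yields 10 per group — the
normal approximation yields 9 and does not reproduce the plan, which is
why the t-based route is the implementation (and `stats::power.t.test`
only a cross-check in the tests). Dropout inflation is multiplicative with
round-half-up, 2×10 → 22 at 10%; the 1/(1 − rate) convention would give
23 and contradicts the plan arithmetic.

## Problem sizes, determinism and limitations

The packaged simulations are sized for a desk run: ten-minute breathing
records at 200 Hz (the estimators are rate-agnostic; the study hardware
digitized at 1 kHz), 6-h ventilation runs advanced breath-by-breath with
the closed-form volume solution (~8,000 breaths in about a second), and
Monte-Carlo studies of 50 replicates. Every stochastic step takes an
explicit seed and is bit-reproducible given (parameters, seed).

Known limitations, by design: no time-domain fractional-order (full
constant-phase) simulation — the compartment uses the documented (R, E)
mapping at the breathing frequency; no circuit compliance, leak,
humidification or spontaneous-effort modelling; no registration between
imaging timepoints; CO2 handling is the linear clearance law only; and the
derecruitment mechanism is a minimal invented dynamic whose defaults were
set once from the design targets above. The PVV-versus-PCV contrast the
simulations reproduce is therefore *directional* — higher end-run open
fraction, delivered volume and oxygenation, lower effective elastance and
shunt under PVV — not a quantitative prediction of animal physiology.
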