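---
title: "Methods: from raw traces to cardiorespiratory phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw traces to cardiorespiratory phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

respicard implements the analysis chain of a 2×2 factorial fish physiology
experiment — salinity acclimation (fresh vs sea water) crossed with surgery
(sham vs coronary ligation) — from raw intermittent-flow respirometry and
ventral-aortic blood-flow recordings down to group-level statistics. This
vignette describes the models, the parameters that matter, the numerical
decisions that were genuinely open, and what the synthetic-data oracle does
and does not establish.

## Oxygen consumption from air-saturation slopes

During each sealed measure phase of an intermittent-flow cycle, the % air
saturation in the chamber declines linearly while the fish consumes oxygen.
The mass-specific oxygen consumption rate is

$$\dot{M}_{O_2} \;=\; \left(|\alpha_a| V_n - |\alpha_b| V_t\right)
  \cdot \frac{\beta}{100} \cdot \frac{3600}{m}$$

with $\alpha_a$ the fitted saturation slope of the fish run (% s⁻¹),
$\alpha_b$ the microbial background slope measured in the empty chamber,
$V_t$ the chamber volume (l), $V_n = V_t - m$ the net volume (body mass $m$
in kg taken as litres of displaced water), and $\beta$ the oxygen
solubility at 100% air saturation (mg l⁻¹). $\beta$ comes from the
García–Gordon polynomial in temperature and salinity (≈11.29 mg l⁻¹ at
10 °C in fresh water, ≈9.14 at 33 ppt); a user-supplied constant overrides
it.

Quality control follows the standard conventions of the method:

* the first 30–60 s of each measure phase are discarded (mixing
  non-linearity); the default head exclusion is 45 s, the midpoint of that
  admissible range;
* a slope is accepted only when its $R^2$ *strictly* exceeds 0.90 — a fit at
  exactly 0.90 is rejected. Rejected cycles are retained with a reason code
  so the audit identity (cycles = accepted + rejected) always holds;
* background correction uses the end-of-series background run as a
  constant, matching the measurement protocol; a linear-ramp mode exists but
  is off by default because no within-series background information is
  available to justify it.

Cycle timestamps are the midpoints of the fitted windows, in seconds from
recording start.

## Metabolic phenotypes

**SMR** is the mean of the lowest 20% of accepted pre-chase measurements
(subset size `ceiling(0.2 n)`, guaranteeing at least one sample), after a
one-pass outlier screen that removes values outside the subset mean ± 2 s.d.
The screen is applied *within the lowest-20% subset* by default — the
alternative, screening against the full pre-chase series, is available via
`outlier_scope = "full"`; the subset interpretation was chosen because the
screen's purpose is to drop single aberrant low readings (flush failures)
rather than to re-trim the full distribution, and with typical data the two
differ only when such artefacts exist. The screen is deliberately not
iterated.

**MMR** is the single highest accepted post-chase measurement. Ties break to
the earliest timestamp so that maximum cardiac variables align with the
first physiological peak. **Aerobic scope** is MMR − SMR.

**EPOC** is the trapezoidal integral of the post-chase series above the
recovery threshold SMR × 1.10, from the chase until the threshold is first
reached. Two decisions here were open:

* *recovery time* is linearly interpolated between the last sample above
  and the first at/below the threshold — taking the first sample at face
  value would quantise recovery time upward by up to one cycle;
* recovery is *first touch*, not sustained: the first sample at or below
  the threshold ends the integration. A fish that never reaches the
  threshold within the recording is flagged `recovered = FALSE` and its
  EPOC fields are `NA`; it is excluded from EPOC summaries and counted in
  the report's audit, never imputed.

The gap between the chase and the first accepted cycle is filled by
carrying the first value back to time zero; at the default cycle lengths
this contributes ≲2% of the integral and avoids a systematic undercount.

**Activity smoothing.** Spontaneous swimming inflates recovery
measurements. The smoothing rule scans forward: when a sample exceeds the
running held value by ≥5%, it is replaced by the held value until a raw
sample returns to within 5% above it. The rule is one-sided (only upward
excursions are touched) because its target is activity spikes; downward
excursions are physiology. It never increases a sample and is idempotent —
both properties are enforced by tests over randomly generated series. In
coronary-ligated fish the first 2 h after the chase are left unsmoothed:
their early recovery is genuinely depressed by post-chase bradycardia, and
the rebound out of that dip would otherwise be clipped as if it were a
spike.

## Cardiac variables

Flow probes are bench-calibrated against gravimetrically determined flow
rates (1–70 ml min⁻¹); `calibrate_probe()` fits the least-squares linear
map from recorded to true flow and the correction is applied to every trace
before analysis.

**CO** is the calibrated mean flow over each respirometry measure window
divided by body mass; **fH** is the pulse frequency over that window,
`(n_beats − 1)/span × 60`, from peak detection; **SV = CO / fH**. Beat
counting (rather than median inter-beat interval) was chosen because it
remains meaningful when the rate changes within a window — exactly what
happens during an atrioventricular (AV) block, where dropped ventricular
beats halve the pulse frequency while each remaining ejection is unchanged.

Peak detection uses a minimum inter-peak distance of half the shortest
expected beat period (default ceiling 120 beats min⁻¹) and a height floor
of 25% of the window amplitude. These are package decisions, not values
inherited from any acquisition software; they reject dicrotic and noise
peaks while preserving the long diastolic gaps of dropped beats. Windows
with fewer than two detected beats report CO but flag fH and SV as
undefined.

**Resting** cardiac values are the means over the windows co-timed with the
SMR-defining cycles; **maximum** values come from the single window
co-timed with the MMR cycle; scope is maximum − resting and may be negative
(post-chase heart rate below resting rate is a real phenomenon in
seawater-acclimated fish). Post-exercise dynamics are read on the grid
{0, 10, 20, 30, 60, 120, 300, 600, 900} min after the chase, taking the
temporally closest sample and recording the offset used.

## Biometrics and haematology

Condition factor $100\,m/L^3$ (g, cm), splenosomatic index and relative
ventricle mass (×100 mass ratios), relative compact mass = dry compact
myocardium / dry ventricular mass × 100, and MCHC = [Hb]/Hct. Dry
ventricular mass is taken as the sum of the separately dried compact and
spongy portions — the plausible alternative (an independently dried whole
ventricle) cannot be reconstructed once the layers are separated. Hct stays
on its percentage scale, so MCHC is in g l⁻¹ per % Hct. Fish with Hct
strictly below 20% are excluded as anaemic (a fish at exactly 20.0 is
retained); every removal is logged with its rule.

## Factorial statistics

Each variable is analysed by two-way ANOVA with Type II sums of squares —
on a balanced design this equals the textbook decomposition exactly (tested
against an explicit sums-of-squares oracle to 10⁻⁹), and it behaves
consistently when variable-specific exclusions unbalance the cells, which
is why per-variable *n* is carried through the report rather than one
study-wide *n*. When a main effect is significant, the simple main effect
of that factor is tested at each level of the other factor using the pooled
residual variance, with Bonferroni adjustment of p-values and confidence
level across the number of levels tested (two levels → adjusted α = 0.025).
A transformation registry (log for resting CO and SV scope, square root for
maximum fH, square for maximum SV) stabilises variances before fitting; a
registered log/sqrt transform silently falls back to none when a variable
contains non-positive values, rather than dropping fish. Significance is
accepted at p < 0.05, strict. Repeated-measures analysis of the post-chase
time courses is delegated to standard mixed-model routines and is not
re-implemented here.

## The synthetic-study generator

Because no raw traces are published for studies of this design, the
generator is the package's oracle: it produces complete studies with known
per-fish ground truth, and every pipeline stage is tested by round trip.

The study conditions are fixed in `study_design()` and were chosen once,
from the experimental design the package models: ~0.5 kg rainbow trout at
10 °C in 10-l chambers; 6 h of pre-chase rest, a 5-min chase, ≥15 h of
recovery; fresh-sham baselines SMR 51.9 and MMR 274.3 mg O₂ h⁻¹ kg⁻¹,
resting fH 44 and maximum 60 beats min⁻¹, maximum SV 0.45 ml kg⁻¹, resting
CO 12.7 ml min⁻¹ kg⁻¹, Hb 85 g l⁻¹, Hct 28%; multiplicative group effects
per variable (salinity, surgery, interaction) matching the factorial
contrasts the design is powered for; between-fish CV 10%.

Mechanics worth knowing:

* **Recovery profile**: single-exponential decay from MMR to SMR (default
  τ = 2.5 h; ×1.6 in ligated fish, ×0.8 in sea water, CV 25%). The
  single-exponential family was chosen because it is the standard
  description of EPOC kinetics and integrates in closed form, giving exact
  oracles for the trapezoid. The ligated τ inflation makes a realistic
  fraction (roughly a third to a half) of ligated fish fail to reach
  SMR + 10% within 15 h, reproducing the non-recovery phenomenon.
* **Saturation traces** invert the ṀO₂ equation exactly, so conservation
  (oxygen removed = ∫ṀO₂ + background) holds by construction. Flush phases
  relax exponentially toward 100% (τ = 40 s). Optode noise is Gaussian,
  default s.d. 0.2% air saturation at 1 Hz.
* **Cycle schedules**: 4 min flush + 10 min measure at rest; 4 + 5 min for
  the first 3 h after the chase, then back to the long cycles. This mirrors
  the field practice of shortening cycles when consumption is highest: the
  short early cycles keep end-of-cycle saturation above the 80% floor at
  MMR, while the long cycles give the shallow resting and late-recovery
  slopes enough signal to pass the strict R² filter at this noise level.
  With a single uniform schedule one of the two constraints always fails.
* **Flow traces**: beats are laid down sequentially from the instantaneous
  heart-rate profile; each beat ejects its stroke volume as a half-sine
  pulse with zero diastolic flow. Samples store the exact mean flow of each
  sample interval, so the mean over any window equals ejected volume per
  time and CO = fH × SV is exact by construction, not approximately true at
  the sampling rate. AV block in ligated fish drops every second beat from
  2 to 30 min post-chase (2:1 ratio); the metabolic profile carries a
  matching impairment dip (depth 0.4, linear return over 30 min) so that
  respiration and perfusion tell a consistent story.
* **Ground truth** records both the profile parameters and the *observable*
  MMR — the maximum of the noiseless cycle-mean ṀO₂ over the actual measure
  windows. A cycle-averaging method cannot see the instantaneous peak: the
  first window opens after a flush and averages over several minutes of
  decay (and, in ligated fish, over the impairment dip). Parameter-recovery
  tests therefore compare the estimate against what the method could at
  best report, which is the honest oracle for the estimator; the
  instantaneous MMR is still stored for anyone studying that bias itself
  (≈2–5% at the default τ and cycle lengths).
* **Determinism**: all randomness flows from the single study seed;
  identical seeds give identical datasets.

What the generator does *not* emulate: spontaneous activity spikes during
recovery are off by default (their magnitude is not a measured quantity in
this design; the hook exists as the `activity_spikes` flag), there is no
haemodynamic pressure model, no ECG waveform synthesis, and optode noise is
white rather than drifting. Passing round-trip tests on this generator
therefore demonstrates that the estimators are faithful to their
definitions under the stated noise model — not that they are robust to
instrument drift, activity artefacts, or model misspecification in real
recordings.

## Validation problem sizes

The packaged checks use: a 32-fish study (8 per cell) at the default
recording lengths for fish-by-fish parameter recovery (SMR and MMR within
5%, window-level fH within 2%, CO ≡ fH × SV); EPOC quadrature against the
closed-form integral at 5-min sampling (within 3%); and 500 replicate
reduced studies (pre-chase respirometry only, 4 h at 20-s sampling, 6 fish
per cell, null effects) for the empirical type-I error of the
simulate-and-test loop, pooling both main effects, with an acceptance band
of 0.05 ± 0.02. The reduced replicate design keeps the full loop — trace
generation, slope fitting, R² filtering, SMR estimation, ANOVA — while
holding the suite to a few minutes.

## Known limitations

* The SMR estimator's lowest-quantile selection interacts with measurement
  noise: noisier per-cycle estimates bias SMR slightly downward (about 1–2%
  under default conditions). This is a property of the estimator class, not
  of the implementation, and cancels in group comparisons.
* Printed-report arithmetic (`percent_effect`,
  `relative_difference_ratio`) rounds to integers for parity with how such
  effects are reported; the unrounded values are available via
  `round_digits = NULL`.
* `simple_main_effects` is implemented for two-level factors, which is what
  a 2×2 design needs; it is cross-checked against emmeans in the test
  suite.
* The AV block is represented as beat dropping in the flow signal; ECG
  morphology (P-waves without QRS complexes) is out of scope.
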