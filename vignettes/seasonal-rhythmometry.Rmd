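---
title: "Methods: seasonal rhythmometry of morning clock-gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal rhythmometry of morning clock-gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`circaseason` implements an analysis pipeline for a recurring study design in
high-latitude chronobiology: a cohort wears a wrist actigraph for one week
around each solstice and equinox, gives a single 08:00 blood sample per
seasonal visit, and the morning expression of a clock gene (quantified by
qPCR against a housekeeping gene) is related to the amount and timing of
light exposure and physical activity. This vignette documents the models,
the conventions chosen where the field offers several, and what the
package's synthetic validation does and does not establish.

## Relative expression: 2^-ddCq

For each sample, `dCq = Cq_target - Cq_reference` normalizes the target to
the reference gene, `ddCq = dCq - dCq_cal` references a calibrator, and
`RE = 2^-ddCq`. Two conventions were open:

* **Calibrator.** The default is the arithmetic mean `dCq` of the
  winter-solstice samples, so seasonal profiles read as fold change versus
  the darkest season. The choice is cosmetic: every ratio `RE_i/RE_j` is
  calibrator-invariant (a tested property), and all downstream statistics
  use either ratios or a per-analysis standardization.
* **Efficiency.** No amplification-efficiency (Pfaffl) correction is
  applied; the doubling-per-cycle assumption is the stated quantification
  model. Plate effects and technical-replicate aggregation are out of scope.

Samples with non-finite Cq are flagged and excluded, never imputed.

## Cosinor rhythmometry

The rhythm model is ordinary least squares on

y(t) = M + sum_k [ beta_k cos(2 pi t / tau_k) + gamma_k sin(2 pi t / tau_k) ]

with amplitude `A_k = sqrt(beta_k^2 + gamma_k^2)` and acrophase
`phi_k = (tau_k / 2 pi) atan2(gamma_k, beta_k)` mapped into `[0, tau_k)`.
Conventions and numerical choices:

* **Acrophase sign.** Reported as the positive local clock time of the
  component maximum (helpers convert to the classical negative-degrees
  convention). The time axis is hours since the local midnight preceding the
  recording start, so a 24 h acrophase *is* a clock time. Timestamps are
  naive local clock throughout — every endpoint of interest (acrophase, M10
  onset, epoch-of-day correlation) is defined on local time, and no UTC or
  solar-time conversion is attempted (solar noon is taken as 12:00).
* **Zero-amplitude test.** `F = [(TSS - RSS)/2m] / [RSS/(n - 2m - 1)]` for
  `m` components against `F(2m, n - 2m - 1)`. A perfect fit (`RSS = 0`) is
  returned with the test flagged degenerate; a flat input (`TSS = 0`) yields
  `F = 0`, `p = 1` and no rhythm claim.
* **Confidence intervals** are delta-method intervals on `(beta_k, gamma_k)`
  rather than exact Halberg elliptical regions — simpler, and their coverage
  is verified by simulation (see below). Delta intervals for amplitudes near
  zero are unreliable; the package leaves them `NA` at `A = 0` and the
  zero-amplitude F test, not the amplitude CI, decides whether a rhythm
  exists.
* **Peak detection** evaluates the full fitted curve on a 1-minute grid over
  the day (1440 points, circular), reporting local maxima with ties broken
  toward the earliest clock minute — matching the minute-precision peak
  reporting conventional in this literature. Curves whose total range is at
  rounding level report no peaks.
* **Light transform.** Channel endpoints are fitted on raw values by
  default, treating light linearly; `log10(x + 1)` is available by argument
  because lux is heavy-tailed. Which transform underlies any given published
  light MESOR is rarely stated; results in this package always say which was
  used.
* **Missing data.** Minutes are masked, never imputed. A channel endpoint
  requires at least 80% valid minutes, otherwise it is missing with a logged
  reason. The 80% rule is this package's convention (device software rarely
  documents its own).

## Non-parametric circadian metrics

On consecutive bin means (60-minute bins by default, the classical
convention; the width is an argument):

* `IS`, inter-daily stability: variance of the 24 h average profile over the
  total variance (0 to 1; 1 for any exactly 24 h-periodic record).
* `IV`, intra-daily variability: normalized first-difference variance
  (about 0 for smooth curves, about 2 for white noise).
* `M10`/`L5`: max/min mean over cyclic 10 h / 5 h windows of the *average
  day profile* (not per-day-then-averaged), with onsets at the window start;
  windows may wrap midnight; ties resolve to the earliest start.
* `RA = (M10 - L5)/(M10 + L5)`.
* `CFI = [IS + clip((2 - IV)/2, 0, 1) + RA]/3`, the equal-weight composite
  (Ortiz-Tudela-style convention). Published uses of CFI rarely print a
  formula, and proprietary actigraphy software may differ in detail;
  cross-software numerical identity is explicitly not claimed.

Zero-variance records flag IS/IV undefined; `M10 + L5 = 0` flags RA
undefined. Bins need 80% of their minutes valid, else the bin is missing.

At finite record lengths the iid-noise reference values are not exactly the
asymptotes: for 168 hourly bins over 7 days, `E[IV] = 2N/(N-1) ~ 2.01` and
the IS ratio concentrates near 0.137 rather than 1/7 ~ 0.143. The validation
suite asserts the means within tolerances (0.05 and 0.02) that cover this
known finite-sample offset plus Monte-Carlo error.

## Windowed correlation map

The day is cut into 48 consecutive 30-minute clock epochs; each
participant-season contributes the mean channel value per epoch (pooling all
7 days; 80% coverage per epoch required). Per epoch, the Pearson correlation
between epoch means and relative expression is computed across pooled
participant-season observations, `p` from the t transform on `n - 2` df, and
Benjamini-Hochberg step-up control is applied across the 48-epoch family at
`q = 0.1`. Choices worth noting:

* **Pooling.** The default family pools all participant-season observations,
  replicating the published design; repeated observations of one participant
  across seasons are therefore not independent, and no repeated-measures
  correction is applied. Per-season maps are available and an outlier
  *flagging* helper (|externally studentized residual| > 3) is provided for
  sensitivity analyses; observations are never auto-removed.
* **Validity of p-values.** The t-based Pearson p-value assumes approximate
  normality. On heavy-tailed inputs (raw lux across participants) it is
  anti-conservative at modest n — in simulation, log-normal null data at
  n = 30 produced far more than `q` false families. The FDR property test
  therefore uses Gaussian nulls (valid p-values), and applied results on raw
  lux should be read with this caveat; rank or log-transformed sensitivity
  analyses are recommended.
* **Epochs with undefined correlations** (zero variance) are dropped from
  the FDR family, with the family size adjusted and the count logged.

The correlation profile is then summarized by a 24 h + 12 h harmonic cosinor
fit on the 48 `(midpoint, r)` pairs; its fitted local maxima (1-minute grid)
are labelled major/minor by fitted height. When the 24 h amplitude interval
covers zero, a 12 h-only refit is reported alongside — the pattern seen with
activity rather than light profiles.

## Seasonal comparisons and regression models

One-way ANOVA with Tukey HSD post hoc (studentized-range adjusted),
Shapiro-Wilk normality annotations per group and a Kruskal-Wallis companion
are delegated to the standard `stats` routines. An all-identical response
reports `F = 0` with unit post hoc p-values rather than `NaN`.

The regression layer fits OLS with **sigma-restricted coding**: continuous
predictors z-scored, two-level factors effect-coded -1/+1 and then z-scored
(so every 1-df coefficient is a standardized beta), and per-term Type-III
(partial) sums of squares by block deletion. Reported per term:

* standardized beta and its t-based CI (response z-scored by default;
  recovery simulations disable response standardization so coefficients are
  comparable to generating values);
* partial `eta^2 = SS_term/(SS_term + SS_res)`, identically
  `F df1/(F df1 + df2)`;
* observed power at the sample-estimated noncentrality `ncp = F df1`,
  `alpha = 0.05` — the convention of mainstream ANCOVA software.

`season` enters by default as a single-df ordered score
(winter < spring < summer < autumn, z-scored): published model tables of
this design print one coefficient for "Seasons", implying one df. A
categorical sum-coded alternative is an argument. Light acrophase enters as
a linear (unwrapped) covariate; this is justified only when individual light
acrophases span well under half a cycle (in the emulated design they sit
within about an hour of each other), and circular regression is explicitly
out of scope. Season subsets (e.g. omitting autumn so the two equinoxes do
not over-represent intermediate light conditions) are an argument.

## The synthetic cohort

No raw data from the motivating study design are publicly deposited, so the
package ships a generator whose defaults define the validation conditions:

* 29 participants (8 natives, 24 women), ages ~18-52, BMI ~17-40;
  recordings available for 29/22/25/21 participant-seasons
  (winter/spring/summer/autumn).
* Photoperiods 1/12/24/12 h with a raised-cosine daylight envelope centred
  near 12:00 (per-recording jitter sd 0.4 h, keeping individual light
  acrophases within about an hour), seasonal peak illuminance
  500/5000/10000/5000 lux times a per-recording behavioural scale
  (log-normal, sd 0.4), multiplicative minute noise (log-normal, sd 0.5,
  mean one), zero light during sleep; blue light is 1% of white per lux.
* Activity: per-participant 24 h cosine (MESOR 230 +- 40 PIM, amplitude
  180 +- 30, acrophase 15:00 +- 1 h) gated to 5% during the seasonal sleep
  window, plus half-normal minute noise (sd 60). Wrist temperature: 33 degC
  MESOR, 1 degC amplitude, antiphase to activity, Gaussian noise sd 0.3.
* Expression: `log2 RE = 3 + b_season + 0.35 native + 0.4 z(light MESOR) +
  0.3 z(light acrophase) + 0.25 z(activity MESOR) + N(0, 0.55)`, with
  seasonal shifts 0/0.35/1.0/0.75 (winter minimum, summer maximum). Cq
  pairs are emitted so the 2^-ddCq stage recovers the generated expression
  exactly up to the calibrator convention.

Ground truth per recording is the exact cosinor projection of the noise-free
expected day curve, which is what a 24 h cosinor estimates in expectation.
Each participant-season has its own RNG substream derived from the master
seed, so subsetting the cohort never perturbs other recordings, and
identical configuration plus seed reproduces the cohort bit-identically.

**What the generator does not emulate** — and hence what passing tests do
not establish about field data: day-to-day behavioural variation (activity
noise is white, so generated IS is near its periodic ceiling of 1, far above
the 0.4-0.8 typical of real actigraphy), weather and cloud cover, solar-time
offsets from legal clock time, non-24 h free-running periods, realistic
sleep behaviour (sleep is a hard gate, not a scored process — proprietary
sleep-staging outputs such as WASO or efficiency are out of scope
entirely), melatonin phase, and any within-participant correlation of
expression across seasons beyond what the shared traits induce.

Effect sizes were chosen once to reproduce the qualitative structure of the
motivating design (summer maximum, winter minimum, natives above newcomers,
light amount the strongest adjusted predictor) rather than any printed
F-statistics, which depend on undeposited raw data. One visible consequence:
the *unadjusted* native-vs-newcomer contrast is underpowered at the chosen
0.35 log2 shift because seasonal and light-driven variance dominates; the
covariate-adjusted models are the appropriate comparison.

## Validation problem sizes

The test suite validates at sizes chosen to keep the full run in the order
of a minute or two while leaving Monte-Carlo error well inside the asserted
tolerances: CI coverage and zero-amplitude calibration use 500 and 1000
replicates of 168 hourly points; the iid IS/IV checks use 1000 replicates;
BH is checked against a brute-force step-up oracle on 200 random 48-value
families; end-to-end recovery uses 500 synthetic cohorts for both the
correlation-map peak location (n = 60 epoch-level cohorts, coupling window
16:00-20:00) and the regression-coefficient recovery (full 97-row cohorts).
Exact claims (round trips, ddCq identities, noiseless recovery) are asserted
at 1e-6 to 1e-12; statistical claims at binomial or Monte-Carlo bands.

## Known limitations

* Cross-observation models only: no mixed-effects handling of repeated
  participant-seasons, matching the emulated design but understating
  uncertainty where within-participant correlation is strong.
* Pearson-based epoch correlations inherit the normality caveat above.
* Delta-method CIs undercover for amplitudes near zero (use the F test).
* The CFI and M10/L5 conventions match the published formulas where given
  and common practice elsewhere; numerical identity with proprietary
  actigraphy software is not claimed.
* Acrophase covariates are linear, not circular; do not reuse the models on
  designs where light timing spans more than a few hours.
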