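# circaseason

Seasonal circadian rhythmometry of morning clock-gene expression and wrist
actigraphy.

At high Arctic latitudes the photoperiod swings from roughly one hour of
daylight at the winter solstice to continuous daylight at the summer
solstice. Cohort studies of this environment pair a week of minute-level
wrist actigraphy (activity counts, white and blue light, wrist temperature)
in each season with a single 08:00 blood sample per seasonal visit, and ask
how the morning expression of a clock gene — quantified by qPCR relative to
a housekeeping gene — tracks the amount and timing of light exposure and
physical activity. `circaseason` implements that analysis as a tested R
package plus a sequence of analysis scripts, and ships a synthetic-cohort
generator with full ground truth so every stage can be validated by
parameter recovery.

## What it computes

* **Relative expression**: `RE = 2^-ddCq`, with
  `dCq = Cq_target - Cq_reference` and a configurable calibrator (default:
  mean winter-solstice `dCq`, so values read as fold change vs the darkest
  season). All RE ratios are calibrator-invariant.
* **Cosinor rhythmometry**: OLS on
  `y(t) = M + sum_k [beta_k cos(2 pi t/tau_k) + gamma_k sin(2 pi t/tau_k)]`,
  reporting MESOR `M`, per-component amplitude
  `A_k = sqrt(beta_k^2 + gamma_k^2)` and acrophase
  `phi_k = (tau_k/2 pi) atan2(gamma_k, beta_k)` as a clock time, the
  zero-amplitude test `F = [(TSS-RSS)/2m]/[RSS/(n-2m-1)]`, delta-method CIs,
  and fitted-curve peaks on a 1-minute grid.
* **Non-parametric circadian metrics**: inter-daily stability (IS),
  intra-daily variability (IV), M10/L5 with onsets on the average day
  profile, relative amplitude `RA = (M10-L5)/(M10+L5)`, and the circadian
  function index `CFI = [IS + clip((2-IV)/2, 0, 1) + RA]/3`.
* **Windowed correlation map**: Pearson correlation between expression and
  the channel mean in each of 48 consecutive 30-min clock epochs across
  participants, Benjamini-Hochberg FDR control at `q = 0.1`, and a
  24 h + 12 h harmonic model of the correlation profile with major/minor
  peak labelling.
* **Inference**: seasonal one-way ANOVA with Tukey HSD, Shapiro-Wilk and
  Kruskal-Wallis companions, and sigma-restricted general linear models
  reporting standardized beta with 95% CI, Type-III F, p, partial
  `eta^2 = F df1/(F df1 + df2)` and observed power at `ncp = F df1`.

## Worked example

```r
library(circaseason)

cohort <- simulate_cohort(generator_config(), seed = 1, recordings = TRUE)
rec <- cohort$recordings[["P01/winter"]]
rec
#> <actigraphy_series> P01 / winter
#>   start 2023-12-18 00:00, 10080 minutes (7.0 days), 100.0% valid
#>   channels: pim, lux, blue, wrist_temp

actigraphy_endpoints(rec, "pim")
#> <cosinor_fit> n = 10080, MESOR = 260.3 (SE 0.536)
#>   tau = 24 h: A = 285.1 (SE 0.758), acrophase = 15:53
#>   peaks of fitted curve: 15:53
#>   zero-amplitude test: F(2, 10077) = 7.075e+04, p = 0

nonparam_metrics(rec, "pim")
#> <nonparam_metrics> IS = 1.000, IV = 0.126, RA = 0.978, CFI = 0.972
#>   M10 = 467.9 (onset 11:00), L5 = 5.168 (onset 02:00), 168 bins
```

This participant's winter activity rhythm has a rhythm-adjusted mean
(MESOR) of 260 PIM counts, a 24 h amplitude of 285 and peaks at 15:53; the
most active 10 h window starts at 11:00 and the rhythm is highly
consolidated (RA near 1). Quantifying expression and comparing solstices:

```r
re <- delta_delta_cq(cohort$expression)   # fold change vs winter mean
2^(mean(log2(re$relative_expression[re$season == "summer"])) -
   mean(log2(re$relative_expression[re$season == "winter"])))
#> [1] 5.23
```

i.e. a 5.2-fold higher geometric-mean morning expression at the summer
solstice than at the winter solstice in this synthetic cohort.

## The analysis workflow

The numbered scripts under `analysis/` run the full study pipeline on the
synthetic cohort, writing tables and a figure under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort + minute-level CSVs
Rscript analysis/02_quantify_expression.R  # 2^-ddCq vs winter calibrator
Rscript analysis/03_rhythm_endpoints.R     # cosinor + non-parametric metrics
Rscript analysis/04_correlation_map.R      # 48-epoch map, FDR, harmonic peaks
Rscript analysis/05_regression_models.R    # ANOVA/Tukey + 3 GLM tables
```

Stage 4 locates the clock-time windows where light exposure predicts
expression (a minor morning and a major evening peak of the fitted harmonic
profile); stage 5 prints Table-1-style models in which light MESOR, light
phase and activity MESOR emerge as the leading standardized predictors.

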