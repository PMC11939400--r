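# Synthetic Arctic cohort generator.
#
# Emulates the study design the analysis assumes: ~66 N photoperiods (1 h of
# daylight at the winter solstice through 24 h at the summer solstice),
# minute-resolution wrist actigraphy with circadian structure and sleep
# gating, and a single 08:00 expression sample per participant-season whose
# log2 level is linearly coupled to light and activity rhythm parameters,
# season and population, with known coefficients (ground truth) so that the
# whole pipeline can be validated by parameter recovery.

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a 29-participant Arctic cohort (8 natives, 24 women)
#' observed over four seasonal weeks with partially missing seasons
#' (29/22/25/21 recordings in winter/spring/summer/autumn). Daylight is a
#' raised-cosine envelope of width `photoperiod_h` centred near 12:00 local
#' (solar noon), scaled to a seasonal peak illuminance and a per-recording
#' behavioural scale factor, with multiplicative log-normal minute noise and
#' zero light during sleep. Activity is a 24 h cosine gated to near zero
#' during sleep plus half-normal noise; wrist temperature is a 24 h cosine in
#' antiphase to activity plus Gaussian noise. Expression follows
#' `log2(RE) = b0 + b_season + b_native*native + b_light_mesor*z(light MESOR)
#' + b_light_phase*z(light acrophase) + b_activity_mesor*z(activity MESOR)
#' + e` with `e ~ N(0, resid_sd)`, standardizing each predictor across the
#' generated cohort; Cq pairs are then built so the 2^-ddCq stage recovers
#' the generated relative expression exactly up to the calibrator convention.
#'
#' @param n_participants cohort size.
#' @param n_native number of participants indigenous to the high Arctic.
#' @param n_female number of women.
#' @param season_n named integer vector; recordings available per season.
#' @param photoperiod_h named numeric vector; daylight duration (h) per
#'   season, each in \code{[0, 24]}.
#' @param peak_lux seasonal peak of the daylight envelope (lux).
#' @param light_scale_sd between-recording log-normal sd of the behavioural
#'   light scale (log scale); models indoor/outdoor habits.
#' @param light_noise_sd minute-level multiplicative log-normal sd (log
#'   scale) of the light channels.
#' @param light_phase_sd_h between-recording sd (h) of the daylight-envelope
#'   centre around 12:00; kept small so individual light acrophases stay
#'   within about an hour of each other.
#' @param blue_fraction blue irradiance (uW/cm^2) per lux of white light.
#' @param pim_mesor_mean,pim_mesor_sd between-participant distribution of the
#'   activity MESOR (PIM counts).
#' @param pim_amplitude_mean,pim_amplitude_sd 24 h activity amplitude.
#' @param pim_acrophase_mean_h,pim_acrophase_sd_h activity acrophase (clock h).
#' @param pim_noise_sd half-normal minute noise sd of activity.
#' @param sleep_start_h,sleep_end_h per-season sleep window (clock h; start
#'   may exceed 24 for post-midnight onsets; equal start and end disables
#'   sleep gating).
#' @param sleep_activity_factor multiplicative activity gate during sleep.
#' @param wt_mesor,wt_amplitude,wt_noise_sd wrist temperature model (deg C).
#' @param b0 baseline log2 relative expression.
#' @param b_season per-season log2 shifts (winter reference 0; summer max).
#' @param b_native log2 shift for natives.
#' @param b_light_mesor,b_light_phase,b_activity_mesor coupling coefficients
#'   on standardized rhythm parameters (log2 scale).
#' @param resid_sd residual sd of log2 expression.
#' @param cq_ref_mean,cq_ref_sd reference-gene Cq distribution.
#' @param calibration_const constant linking target and reference Cq:
#'   `cq_target = cq_reference + (calibration_const - log2 RE)`.
#' @param n_days recording length in days.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 29L,
    n_native = 8L,
    n_female = 24L,
    season_n = c(winter = 29L, spring = 22L, summer = 25L, autumn = 21L),
    photoperiod_h = c(winter = 1, spring = 12, summer = 24, autumn = 12),
    peak_lux = c(winter = 500, spring = 5000, summer = 10000, autumn = 5000),
    light_scale_sd = 0.4,
    light_noise_sd = 0.5,
    light_phase_sd_h = 0.4,
    blue_fraction = 0.01,
    pim_mesor_mean = 230, pim_mesor_sd = 40,
    pim_amplitude_mean = 180, pim_amplitude_sd = 30,
    pim_acrophase_mean_h = 15, pim_acrophase_sd_h = 1,
    pim_noise_sd = 60,
    sleep_start_h = c(winter = 23.0, spring = 23.5, summer = 24.0, autumn = 23.5),
    sleep_end_h = c(winter = 7.5, spring = 7.0, summer = 6.5, autumn = 7.0),
    sleep_activity_factor = 0.05,
    wt_mesor = 33, wt_amplitude = 1, wt_noise_sd = 0.3,
    b0 = 3,
    b_season = c(winter = 0, spring = 0.35, summer = 1.0, autumn = 0.75),
    b_native = 0.35,
    b_light_mesor = 0.4,
    b_light_phase = 0.3,
    b_activity_mesor = 0.25,
    resid_sd = 0.55,
    cq_ref_mean = 20, cq_ref_sd = 0.5,
    calibration_const = 8,
    n_days = 7L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_participants >= 1, cfg$n_native <= cfg$n_participants,
    cfg$n_female <= cfg$n_participants,
    all(SEASONS %in% names(cfg$season_n)),
    all(cfg$season_n >= 0), all(cfg$season_n <= cfg$n_participants),
    all(SEASONS %in% names(cfg$photoperiod_h)),
    all(cfg$photoperiod_h >= 0), all(cfg$photoperiod_h <= 24),
    all(cfg$peak_lux >= 0),
    cfg$light_scale_sd >= 0, cfg$light_noise_sd >= 0,
    cfg$light_phase_sd_h >= 0, cfg$pim_noise_sd >= 0,
    cfg$wt_noise_sd >= 0, cfg$resid_sd >= 0, cfg$cq_ref_sd >= 0,
    cfg$n_days >= 1
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Raised-cosine daylight envelope
#'
#' Smooth window of width `photoperiod` hours centred at `center`, with unit
#' peak and zero outside the window (circular in clock time). With a 24 h
#' photoperiod the envelope is positive at every clock hour, as during the
#' polar day. The 24 h mean of the envelope is `photoperiod/48`, strictly
#' increasing in the photoperiod.
#'
#' @param hours clock times (h).
#' @param photoperiod daylight duration (h), in \code{[0, 24]}.
#' @param center envelope centre (clock h), default solar noon.
#' @return numeric vector of envelope values in \code{[0, 1]}.
#' @export
daylight_envelope <- function(hours, photoperiod, center = 12) {
  if (photoperiod < 0 || photoperiod > 24)
    stop("photoperiod must be in [0, 24]")
  if (photoperiod == 0) return(numeric(length(hours)) * 0)
  d <- ((hours - center + 12) %% 24) - 12
  ifelse(abs(d) <= photoperiod / 2,
         0.5 * (1 + cos(2 * pi * d / photoperiod)), 0)
}

# Circular clock-window membership; start == end means an empty window.
in_clock_window <- function(hours, start, end) {
  s <- start %% 24; e <- end %% 24
  h <- hours %% 24
  if (isTRUE(all.equal(s, e))) return(rep(FALSE, length(hours)))
  if (s < e) h >= s & h < e else h >= s | h < e
}

# Deterministic 31-bit substream seed per (participant, season, purpose),
# so that subsetting the cohort never perturbs other recordings.
derive_seed <- function(master, i, s, k = 0L) {
  x <- (abs(as.numeric(master)) %% 1e6) * 1999 +
    i * 7907 + s * 131 + k * 17 + 1
  as.integer(x %% 2147483647)
}

# Least-squares projection of a uniformly sampled full-period curve onto
# {1, cos, sin} at a given period: exact cosinor parameters of the curve.
fourier_params <- function(y, hours, period = 24) {
  w <- 2 * pi * hours / period
  m <- mean(y)
  b <- 2 * mean(y * cos(w))
  g <- 2 * mean(y * sin(w))
  list(mesor = m, amplitude = sqrt(b^2 + g^2),
       acrophase = (period / (2 * pi) * atan2(g, b)) %% period)
}

# Noise-free expected minute curves over one day (1440-point grid) for one
# participant-season; the Fourier projection of these curves is the ground
# truth a 24 h cosinor estimates in expectation.
truth_day_curves <- function(cfg, row) {
  h <- (0:1439) / 60
  env <- daylight_envelope(h, cfg$photoperiod_h[[row$season]],
                           row$light_center)
  asleep <- in_clock_window(h, row$sleep_start, row$sleep_end)
  light <- cfg$peak_lux[[row$season]] * row$light_scale * env
  light[asleep] <- 0
  act <- pmax(0, row$pim_mesor +
                row$pim_amplitude * cos(2 * pi * (h - row$pim_acrophase) / 24))
  act[asleep] <- act[asleep] * cfg$sleep_activity_factor
  list(hours = h, light = light, activity = act, asleep = asleep)
}

#' Generate the cohort's ground truth
#'
#' Draws participant traits (age, sex, BMI, population, habitual activity
#' rhythm), per-season availability, and per-recording light behaviour, then
#' computes each recording's true channel rhythm parameters as the exact
#' cosinor projection of the noise-free expected day curve.
#'
#' @param config a [generator_config()].
#' @param seed master integer seed.
#' @return list with `meta` (participant metadata) and `truth` (one row per
#'   available participant-season with true light/activity MESOR, amplitude
#'   and acrophase, sleep window and substream seed).
#' @export
simulate_truth <- function(config = generator_config(), seed = 1L) {
  cfg <- config
  n <- cfg$n_participants
  ids <- sprintf("P%02d", seq_len(n))

  set.seed(derive_seed(seed, 0L, 0L))
  native <- seq_len(n) %in% sample.int(n, cfg$n_native)
  female <- seq_len(n) %in% sample.int(n, cfg$n_female)
  age <- round(pmin(52, pmax(18, stats::rnorm(n, 39, 9))), 1)
  bmi <- round(pmin(40, pmax(17, stats::rnorm(n, 25.5, 3.5))), 1)
  pim_mesor <- stats::rnorm(n, cfg$pim_mesor_mean, cfg$pim_mesor_sd)
  pim_amplitude <- pmax(10, stats::rnorm(n, cfg$pim_amplitude_mean,
                                         cfg$pim_amplitude_sd))
  pim_acrophase <- (stats::rnorm(n, cfg$pim_acrophase_mean_h,
                                 cfg$pim_acrophase_sd_h)) %% 24
  # amplitude never exceeds the mesor so the noise-free cosine stays >= 0
  pim_amplitude <- pmin(pim_amplitude, 0.95 * pmax(pim_mesor, 10))

  meta <- data.frame(
    participant_id = ids,
    age = age,
    sex = ifelse(female, "F", "M"),
    bmi = bmi,
    population = ifelse(native, "native", "nonnative"),
    stringsAsFactors = FALSE
  )

  rows <- list()
  for (s_idx in seq_along(SEASONS)) {
    season <- SEASONS[s_idx]
    set.seed(derive_seed(seed, 0L, s_idx))
    avail <- sort(sample.int(n, cfg$season_n[[season]]))
    for (i in avail) {
      set.seed(derive_seed(seed, i, s_idx, 1L))
      light_scale <- stats::rlnorm(1, -cfg$light_scale_sd^2 / 2,
                                   cfg$light_scale_sd)
      light_center <- 12 + stats::rnorm(1, 0, cfg$light_phase_sd_h)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], season = season,
        native = native[i],
        pim_mesor = pim_mesor[i], pim_amplitude = pim_amplitude[i],
        pim_acrophase = pim_acrophase[i],
        light_scale = light_scale, light_center = light_center,
        sleep_start = cfg$sleep_start_h[[season]],
        sleep_end = cfg$sleep_end_h[[season]],
        rec_seed = derive_seed(seed, i, s_idx, 2L),
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, rows)

  tl <- ta <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    cur <- truth_day_curves(cfg, truth[r, ])
    tl[[r]] <- fourier_params(cur$light, cur$hours)
    ta[[r]] <- fourier_params(cur$activity, cur$hours)
  }
  truth$light_mesor_true <- vapply(tl, `[[`, 0, "mesor")
  truth$light_amplitude_true <- vapply(tl, `[[`, 0, "amplitude")
  truth$light_acrophase_true <- vapply(tl, `[[`, 0, "acrophase")
  truth$activity_mesor_true <- vapply(ta, `[[`, 0, "mesor")
  truth$activity_amplitude_true <- vapply(ta, `[[`, 0, "amplitude")
  truth$activity_acrophase_true <- vapply(ta, `[[`, 0, "acrophase")
  truth <- truth[order(truth$participant_id,
                       match(truth$season, SEASONS)), , drop = FALSE]
  rownames(truth) <- NULL
  list(meta = meta, truth = truth)
}

# Seasonal recording start dates: the Monday of the week nearest each
# solstice/equinox (local clock).
SEASON_START <- c(winter = "2023-12-18", spring = "2024-03-18",
                  summer = "2024-06-17", autumn = "2024-09-16")

#' Simulate one minute-resolution recording
#'
#' Generates the 7-day, 1-minute actigraphy record for one truth row: light
#' as the scaled daylight envelope with mean-one multiplicative log-normal
#' noise, zeroed during sleep; blue light as a fixed fraction of white light
#' with its own noise; activity as a 24 h cosine gated to near zero during
#' sleep plus half-normal noise; wrist temperature as a 24 h cosine in
#' antiphase to activity plus Gaussian noise.
#'
#' @param config a [generator_config()].
#' @param truth_row one row of `simulate_truth(...)$truth`.
#' @return An [actigraphy_series].
#' @export
simulate_recording <- function(config, truth_row) {
  cfg <- config
  row <- as.list(truth_row)
  set.seed(row$rec_seed)
  n <- cfg$n_days * 1440L
  h <- (seq_len(n) - 1L) / 60          # recordings start at local midnight
  hc <- h %% 24

  env <- daylight_envelope(hc, cfg$photoperiod_h[[row$season]],
                           row$light_center)
  asleep <- in_clock_window(hc, row$sleep_start, row$sleep_end)
  base <- cfg$peak_lux[[row$season]] * row$light_scale * env
  lnoise <- function(sd) stats::rlnorm(n, -sd^2 / 2, sd)
  lux <- base * if (cfg$light_noise_sd > 0) lnoise(cfg$light_noise_sd) else 1
  blue <- cfg$blue_fraction * base *
    if (cfg$light_noise_sd > 0) lnoise(cfg$light_noise_sd) else 1
  lux[asleep] <- 0
  blue[asleep] <- 0

  pim <- pmax(0, row$pim_mesor +
                row$pim_amplitude * cos(2 * pi * (hc - row$pim_acrophase) / 24))
  if (cfg$pim_noise_sd > 0) pim <- pim + abs(stats::rnorm(n, 0, cfg$pim_noise_sd))
  pim[asleep] <- pim[asleep] * cfg$sleep_activity_factor

  wt <- cfg$wt_mesor + cfg$wt_amplitude *
    cos(2 * pi * (hc - ((row$pim_acrophase + 12) %% 24)) / 24)
  if (cfg$wt_noise_sd > 0) wt <- wt + stats::rnorm(n, 0, cfg$wt_noise_sd)

  start <- as.POSIXct(paste(SEASON_START[[row$season]], "00:00:00"),
                      tz = "UTC")
  actigraphy_series(row$participant_id, row$season, start,
                    data.frame(pim = pim, lux = lux, blue = blue,
                               wrist_temp = wt),
                    mask = rep(TRUE, n))
}

z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Simulate the expression samples
#'
#' Computes each participant-season's true log2 relative expression from the
#' configured linear model on standardized true rhythm parameters, then emits
#' a Cq pair per sample: `cq_reference ~ N(mean, sd)` and
#' `cq_target = cq_reference + (calibration_const - log2 RE)`, so the
#' 2^-ddCq stage recovers the generated expression exactly up to the
#' calibrator convention.
#'
#' @param config a [generator_config()].
#' @param truth truth table from [simulate_truth()].
#' @param seed master integer seed.
#' @return list with `expression` (Cq table ready for [delta_delta_cq()]) and
#'   `truth` (input truth with the log2 linear-predictor decomposition
#'   appended).
#' @export
simulate_expression <- function(config, truth, seed = 1L) {
  cfg <- config
  if (nrow(truth) == 0L) stop("empty truth table")
  set.seed(derive_seed(seed, 0L, 9L))
  lp <- data.frame(
    b0 = rep(cfg$b0, nrow(truth)),
    season = unname(cfg$b_season[truth$season]),
    native = cfg$b_native * as.numeric(truth$native),
    light_mesor = cfg$b_light_mesor * z_score(truth$light_mesor_true),
    light_phase = cfg$b_light_phase * z_score(truth$light_acrophase_true),
    activity_mesor = cfg$b_activity_mesor * z_score(truth$activity_mesor_true)
  )
  eps <- stats::rnorm(nrow(truth), 0, cfg$resid_sd)
  log2_re <- rowSums(lp) + eps
  cq_ref <- stats::rnorm(nrow(truth), cfg$cq_ref_mean, cfg$cq_ref_sd)
  expression <- data.frame(
    participant_id = truth$participant_id,
    season = truth$season,
    cq_target = cq_ref + (cfg$calibration_const - log2_re),
    cq_reference = cq_ref,
    sample_time = "08:00",
    stringsAsFactors = FALSE
  )
  truth$log2_re_true <- log2_re
  truth$lp_light_mesor <- lp$light_mesor
  truth$lp_light_phase <- lp$light_phase
  truth$lp_activity_mesor <- lp$activity_mesor
  list(expression = expression, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_truth()], [simulate_expression()]
#' and optionally [simulate_recording()] for every available
#' participant-season.
#'
#' @param config a [generator_config()].
#' @param seed master integer seed.
#' @param recordings if `TRUE`, also generate the minute-level actigraphy
#'   records (a named list keyed `participant/season`).
#' @return list with `config`, `meta`, `truth`, `expression` and optionally
#'   `recordings`.
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1L,
                            recordings = FALSE) {
  st <- simulate_truth(config, seed)
  se <- simulate_expression(config, st$truth, seed)
  out <- list(config = config, meta = st$meta, truth = se$truth,
              expression = se$expression)
  if (recordings) {
    recs <- lapply(seq_len(nrow(se$truth)), function(r)
      simulate_recording(config, se$truth[r, ]))
    names(recs) <- paste(se$truth$participant_id, se$truth$season, sep = "/")
    out$recordings <- recs
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Emits `metadata.csv`, `expression.csv`, `truth.csv` and, when recordings
#' are present, one `acti_<participant>_<season>.csv` per recording.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$expression, file.path(dir, "expression.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$recordings)) {
    for (rec in cohort$recordings) {
      write_actigraphy(rec, file.path(dir, sprintf(
        "acti_%s_%s.csv", rec$participant_id, rec$season)))
    }
  }
  invisible(dir)
}

#' Simulate epoch-level cohorts with window-coupled expression
#'
#' Fast generator for validating the windowed correlation map: each
#' participant gets a 48-epoch daylight profile (raised-cosine envelope times
#' a personal scale and epoch-level log-normal noise) whose epochs inside a
#' chosen clock window receive an additional personal boost; expression is
#' then coupled to the standardized mean light inside that window. The
#' correlation map's fitted major peak should fall inside the coupling
#' window.
#'
#' @param n participants.
#' @param coupling_window numeric length-2 clock window (h), default
#'   16:00-20:00 (afternoon light).
#' @param seed integer seed.
#' @param width epoch width in minutes.
#' @param photoperiod,peak envelope parameters.
#' @param indoor baseline indoor illuminance (lux) present around the clock,
#'   so no epoch is identically dark across participants (as in real
#'   recordings, where evening light comes from indoor sources).
#' @param scale_sd,boost_sd,epoch_noise_sd log-scale sds of the personal
#'   daylight scale, the in-window personal boost, and epoch noise.
#' @param b,resid_sd coupling strength on the standardized log window light
#'   and residual sd (log2 expression scale).
#' @return list with `profiles` (n x epochs matrix), `expression` (relative
#'   expression vector), `mid_h` epoch midpoints and `window`.
#' @export
simulate_coupled_cohort <- function(n = 60, coupling_window = c(16, 20),
                                    seed = 1L, width = 30,
                                    photoperiod = 16, peak = 5000,
                                    indoor = 100,
                                    scale_sd = 0.4, boost_sd = 0.5,
                                    epoch_noise_sd = 0.3,
                                    b = 0.8, resid_sd = 0.5) {
  set.seed(derive_seed(seed, 0L, 5L))
  n_ep <- 1440 %/% width
  mid <- (seq_len(n_ep) - 0.5) * width / 60
  env <- daylight_envelope(mid, photoperiod) * peak + indoor
  inwin <- mid >= coupling_window[1] & mid < coupling_window[2]
  scale_i <- stats::rlnorm(n, 0, scale_sd)
  boost_i <- stats::rlnorm(n, 0, boost_sd)
  noise <- matrix(stats::rlnorm(n * n_ep, -epoch_noise_sd^2 / 2,
                                epoch_noise_sd), n, n_ep)
  profiles <- outer(scale_i, env) * noise
  profiles[, inwin] <- profiles[, inwin] * boost_i
  win_mean <- rowMeans(profiles[, inwin, drop = FALSE])
  log2_re <- b * z_score(log(win_mean)) + stats::rnorm(n, 0, resid_sd)
  list(profiles = profiles, expression = 2^log2_re, mid_h = mid,
       window = coupling_window)
}
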