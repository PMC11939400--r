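test_that("identical config and seed reproduce the cohort bit-identically", {
  c1 <- simulate_cohort(generator_config(), seed = 7)
  c2 <- simulate_cohort(generator_config(), seed = 7)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$expression, c2$expression)
  r1 <- simulate_recording(c1$config, c1$truth[5, ])
  r2 <- simulate_recording(c2$config, c2$truth[5, ])
  expect_identical(r1$channels, r2$channels)
})

test_that("per-recording RNG substreams are unaffected by cohort subsetting", {
  cfg <- generator_config()
  full <- simulate_truth(cfg, seed = 7)$truth
  sub <- simulate_truth(generator_config(season_n = c(
    winter = 29, spring = 0, summer = 0, autumn = 0)), seed = 7)$truth
  key <- paste(sub$participant_id, sub$season)
  rows <- match(key, paste(full$participant_id, full$season))
  for (i in c(1, 10, 29)) {
    a <- simulate_recording(cfg, full[rows[i], ])
    b <- simulate_recording(cfg, sub[i, ])
    expect_identical(a$channels, b$channels)
  }
})

test_that("the daylight envelope mean strictly increases with photoperiod", {
  h <- (0:1439) / 60
  means <- vapply(c(1, 6, 12, 18, 24),
                  function(w) mean(daylight_envelope(h, w)), 0)
  expect_true(all(diff(means) > 0))
  expect_error(daylight_envelope(h, 25), "photoperiod")
  expect_error(daylight_envelope(h, -1), "photoperiod")
})

test_that("winter light is confined to the 1 h daylight envelope", {
  cfg <- generator_config()
  st <- simulate_truth(cfg, seed = 2)
  row <- st$truth[st$truth$season == "winter", ][1, ]
  rec <- simulate_recording(cfg, row)
  h <- ((seq_len(length(rec)) - 1) / 60) %% 24
  outside <- circaseason:::in_clock_window(h, row$light_center + 0.5,
                                           row$light_center - 0.5)
  peak <- cfg$peak_lux[["winter"]] * row$light_scale
  expect_gte(mean(rec$channels$lux[outside] < 0.01 * peak), 0.95)
})

test_that("noiseless generation recovers the configured activity rhythm exactly", {
  cfg <- noiseless_config(photoperiod_h = c(winter = 24, spring = 24,
                                            summer = 24, autumn = 24))
  st <- simulate_truth(cfg, seed = 5)
  row <- st$truth[st$truth$season == "summer", ][1, ]
  rec <- simulate_recording(cfg, row)

  # with no sleep window, light equals the envelope everywhere
  h <- ((seq_len(length(rec)) - 1) / 60) %% 24
  env <- cfg$peak_lux[["summer"]] * row$light_scale *
    daylight_envelope(h, 24, row$light_center)
  expect_equal(rec$channels$lux, env, tolerance = 1e-12)

  fit <- actigraphy_endpoints(rec, "pim")
  expect_equal(fit$mesor, cfg$pim_mesor_mean, tolerance = 1e-6)
  expect_equal(fit$components$amplitude, cfg$pim_amplitude_mean,
               tolerance = 1e-6)
  expect_lt(circ_diff(fit$components$acrophase, cfg$pim_acrophase_mean_h),
            1e-6)
  # and the stored ground truth agrees with the configuration
  expect_equal(row$activity_mesor_true, cfg$pim_mesor_mean, tolerance = 1e-9)
  expect_equal(row$activity_amplitude_true, cfg$pim_amplitude_mean,
               tolerance = 1e-9)
})

test_that("generated recordings satisfy the series invariants", {
  ch <- simulate_cohort(generator_config(), seed = 11, recordings = FALSE)
  for (r in c(1, 40, 97)) {
    rec <- simulate_recording(ch$config, ch$truth[r, ])
    expect_s3_class(rec, "actigraphy_series")
    expect_equal(length(rec), 10080L)
    expect_true(all(rec$mask))
    expect_true(all(rec$channels$pim >= 0))
    expect_true(all(rec$channels$lux >= 0))
    expect_true(all(rec$channels$blue >= 0))
  }
})

test_that("seed-42 channel means match the frozen golden summary", {
  st <- simulate_truth(generator_config(), seed = 42)
  rec <- simulate_recording(generator_config(), st$truth[1, ])
  expect_identical(paste(st$truth$participant_id[1], st$truth$season[1]),
                   "P01 winter")
  expect_equal(mean(rec$channels$pim), 197.843468, tolerance = 1e-8)
  expect_equal(mean(rec$channels$lux), 6.912029702, tolerance = 1e-8)
  expect_equal(mean(rec$channels$blue), 0.07399304057, tolerance = 1e-8)
  expect_equal(mean(rec$channels$wrist_temp), 32.99762629, tolerance = 1e-8)
})

test_that("null expression model yields RE = 1 for every sample", {
  cfg <- noiseless_config(b_season = c(winter = 0, spring = 0, summer = 0,
                                       autumn = 0),
                          b_native = 0, b_light_mesor = 0, b_light_phase = 0,
                          b_activity_mesor = 0, b0 = 0.7)
  ch <- simulate_cohort(cfg, seed = 1)
  re <- delta_delta_cq(ch$expression)
  expect_equal(re$relative_expression, rep(1, nrow(re)), tolerance = 1e-12)
})

test_that("a forced summer-winter contrast of 1 log2 unit gives a ratio of 2", {
  cfg <- noiseless_config(b_season = c(winter = 0, spring = 0, summer = 1,
                                       autumn = 0),
                          b_native = 0, b_light_mesor = 0, b_light_phase = 0,
                          b_activity_mesor = 0)
  ch <- simulate_cohort(cfg, seed = 1)
  re <- delta_delta_cq(ch$expression)
  s <- re$relative_expression[re$season == "summer"]
  w <- re$relative_expression[re$season == "winter"]
  expect_equal(unique(round(s, 12)), 2)
  expect_equal(unique(round(w, 12)), 1)
})

test_that("the expression truth decomposes into its linear predictor", {
  ch <- simulate_cohort(generator_config(resid_sd = 0), seed = 9)
  cfg <- ch$config
  lp <- cfg$b0 + cfg$b_season[ch$truth$season] +
    cfg$b_native * ch$truth$native +
    ch$truth$lp_light_mesor + ch$truth$lp_light_phase +
    ch$truth$lp_activity_mesor
  expect_equal(ch$truth$log2_re_true, unname(lp), tolerance = 1e-12)
  # Cq pairs encode the truth: dCq = calibration constant - log2 RE
  expect_equal(ch$expression$cq_target - ch$expression$cq_reference,
               cfg$calibration_const - ch$truth$log2_re_true,
               tolerance = 1e-12)
})
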