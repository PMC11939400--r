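# Small builders used across the test files.

# Wrap channel vectors into a recording starting at local midnight.
make_series <- function(pim = NULL, lux = NULL, blue = NULL, wt = NULL,
                        n_days = 7, season = "winter",
                        start = "2024-01-01 00:00:00", mask = NULL,
                        id = "T01") {
  n <- n_days * 1440L
  ch <- list()
  grab <- function(x) if (is.null(x)) NULL else rep_len(x, n)
  ch$pim <- grab(pim); ch$lux <- grab(lux); ch$blue <- grab(blue)
  ch$wrist_temp <- grab(wt)
  ch <- ch[!vapply(ch, is.null, TRUE)]
  actigraphy_series(id, season, as.POSIXct(start, tz = "UTC"),
                    as.data.frame(ch), mask = mask)
}

# Minute clock hours for n_days starting at midnight.
day_hours <- function(n_days = 7) ((seq_len(n_days * 1440L) - 1L) / 60) %% 24

# Generator with all noise removed and sleep gating disabled: every channel
# is its noise-free expected curve.
noiseless_config <- function(...) {
  generator_config(
    light_scale_sd = 0, light_noise_sd = 0, light_phase_sd_h = 0,
    pim_mesor_sd = 0, pim_amplitude_sd = 0, pim_acrophase_sd_h = 0,
    pim_noise_sd = 0,
    sleep_start_h = c(winter = 0, spring = 0, summer = 0, autumn = 0),
    sleep_end_h = c(winter = 0, spring = 0, summer = 0, autumn = 0),
    wt_noise_sd = 0, resid_sd = 0, cq_ref_sd = 0,
    ...
  )
}

# Independent brute-force Benjamini-Hochberg step-up: exhaustive threshold
# search over the sorted p-values.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * q)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Direct-summation IS/IV oracle (explicit loops, no vectorized shortcuts).
npcra_oracle <- function(x, p) {
  N <- length(x)
  xbar <- mean(x)
  denom <- 0
  for (i in seq_len(N)) denom <- denom + (x[i] - xbar)^2
  prof <- numeric(p)
  for (h in seq_len(p)) {
    idx <- seq(h, N, by = p)
    prof[h] <- mean(x[idx])
  }
  num_is <- 0
  for (h in seq_len(p)) num_is <- num_is + (prof[h] - xbar)^2
  num_iv <- 0
  for (i in 2:N) num_iv <- num_iv + (x[i] - x[i - 1])^2
  list(IS = N * num_is / (p * denom),
       IV = N * num_iv / ((N - 1) * denom),
       prof = prof)
}

# Circular absolute difference in hours, modulo a period.
circ_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
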