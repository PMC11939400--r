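# Cosinor rhythmometry.
#
# y(t) = M + sum_k [ beta_k cos(2 pi t / tau_k) + gamma_k sin(2 pi t / tau_k) ]
# fitted by ordinary least squares; per component, amplitude
# A_k = sqrt(beta_k^2 + gamma_k^2) and acrophase phi_k = the clock time of
# that component's maximum in [0, tau_k). The zero-amplitude test compares
# the full fit to the flat model via F = [(TSS-RSS)/2m] / [RSS/(n-2m-1)].

#' Fit a single- or multi-component cosinor model
#'
#' @param t sampling times in hours. For clock-referenced data pass hours
#'   since local midnight so acrophases read directly as clock times.
#' @param y observed values (same length as `t`); non-finite pairs dropped.
#' @param periods component periods in hours (distinct, positive), e.g.
#'   `24` or `c(24, 12)`.
#' @param ci_level confidence level for the MESOR, amplitude and acrophase
#'   intervals (delta method on the linearized coefficients).
#'
#' @return An object of class `cosinor_fit`: `mesor`, `components` (data
#'   frame with period, amplitude, acrophase, standard errors and CI bounds),
#'   `peak_times` (clock times of local maxima of the full fitted curve on a
#'   1-minute grid over \code{[0, 24)}), `rss`, `n`, the zero-amplitude `F`,
#'   its `p` value and `df`, and a `degenerate` flag for perfect fits.
#' @export
fit_cosinor <- function(t, y, periods = 24, ci_level = 0.95) {
  stopifnot(length(t) == length(y), length(periods) >= 1)
  periods <- as.numeric(periods)
  if (any(periods <= 0) || anyDuplicated(periods))
    stop("periods must be distinct and positive")
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  m <- length(periods)
  n <- length(y)
  if (n < 2 * m + 2)
    stop("need at least ", 2 * m + 2, " valid points, got ", n)

  X <- cbind(1, do.call(cbind, lapply(periods, function(tau) {
    w <- 2 * pi * t / tau
    cbind(cos(w), sin(w))
  })))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient cosinor design (check that times vary and periods ",
         "are resolvable)")
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df2 <- n - 2 * m - 1

  degenerate <- (rss <= .Machine$double.eps^0.75 * max(tss, 1))
  if (tss <= 0) {             # flat input: no rhythm, no test
    F_stat <- 0; p <- 1; degenerate <- TRUE
  } else if (degenerate) {
    F_stat <- Inf; p <- 0
  } else {
    F_stat <- ((tss - rss) / (2 * m)) / (rss / df2)
    p <- stats::pf(F_stat, 2 * m, df2, lower.tail = FALSE)
  }

  sigma2 <- if (df2 > 0) rss / df2 else NA_real_
  V <- tryCatch(sigma2 * chol2inv(qr.R(qrX)), error = function(e) NULL)
  tcrit <- if (df2 > 0) stats::qt(1 - (1 - ci_level) / 2, df2) else NA_real_

  comp <- data.frame(period = periods, amplitude = NA_real_,
                     acrophase = NA_real_, beta = NA_real_, gamma = NA_real_,
                     se_amplitude = NA_real_, se_acrophase = NA_real_,
                     amplitude_lo = NA_real_, amplitude_hi = NA_real_,
                     acrophase_lo = NA_real_, acrophase_hi = NA_real_)
  for (k in seq_len(m)) {
    b <- coef[2 * k]; g <- coef[2 * k + 1]
    A <- sqrt(b^2 + g^2)
    tau <- periods[k]
    phi <- (tau / (2 * pi) * atan2(g, b)) %% tau
    comp$beta[k] <- b; comp$gamma[k] <- g
    comp$amplitude[k] <- A; comp$acrophase[k] <- phi
    if (!is.null(V) && A > 0 && is.finite(sigma2)) {
      Vk <- V[(2 * k):(2 * k + 1), (2 * k):(2 * k + 1)]
      gA <- c(b, g) / A
      se_A <- sqrt(drop(gA %*% Vk %*% gA))
      gP <- c(-g, b) / A^2 * (tau / (2 * pi))
      se_P <- sqrt(drop(gP %*% Vk %*% gP))
      comp$se_amplitude[k] <- se_A
      comp$se_acrophase[k] <- se_P
      comp$amplitude_lo[k] <- A - tcrit * se_A
      comp$amplitude_hi[k] <- A + tcrit * se_A
      comp$acrophase_lo[k] <- phi - tcrit * se_P
      comp$acrophase_hi[k] <- phi + tcrit * se_P
    }
  }
  se_mesor <- if (!is.null(V) && is.finite(sigma2)) sqrt(V[1, 1]) else NA_real_

  fit <- structure(list(
    mesor = unname(coef[1]),
    se_mesor = se_mesor,
    mesor_lo = unname(coef[1]) - tcrit * se_mesor,
    mesor_hi = unname(coef[1]) + tcrit * se_mesor,
    components = comp,
    rss = rss, tss = tss, n = n, df1 = 2 * m, df2 = df2,
    F = F_stat, p = p, degenerate = degenerate,
    sigma = if (is.finite(sigma2)) sqrt(sigma2) else NA_real_,
    ci_level = ci_level
  ), class = "cosinor_fit")
  fit$peak_times <- cosinor_peaks(fit)
  fit
}

#' Evaluate a fitted cosinor curve
#'
#' @param fit a [fit_cosinor()] result.
#' @param t times in hours.
#' @return fitted values at `t`.
#' @export
predict_cosinor <- function(fit, t) {
  y <- rep(fit$mesor, length(t))
  for (k in seq_len(nrow(fit$components))) {
    tau <- fit$components$period[k]
    w <- 2 * pi * t / tau
    y <- y + fit$components$beta[k] * cos(w) + fit$components$gamma[k] * sin(w)
  }
  y
}

# Local maxima of the fitted curve on a dense 1-minute clock grid over
# [0, 24), treated circularly; plateaus yield their earliest minute. A
# numerically flat curve (amplitudes at rounding level) has no peaks.
cosinor_peaks <- function(fit, grid_min = 1) {
  g <- seq(0, 24 - grid_min / 60, by = grid_min / 60)
  f <- predict_cosinor(fit, g)
  if (diff(range(f)) <= 1e-10 * max(1, abs(fit$mesor)))
    return(numeric(0))
  nf <- length(f)
  prev <- f[c(nf, seq_len(nf - 1))]
  nxt <- f[c(seq_len(nf)[-1], 1)]
  peaks <- which(f > prev & f >= nxt)
  sort(g[peaks])
}

#' Convert acrophase between clock time and classical negative degrees
#'
#' Chronobiology software often reports acrophase as a negative angle
#' (0 to -360 degrees from local midnight). This package reports the positive
#' clock time of the component maximum; these helpers convert between the
#' two conventions.
#'
#' @param clock_h acrophase as clock hours in \code{[0, tau)}.
#' @param degrees acrophase in negative degrees \code{(-360, 0]}.
#' @param period component period in hours.
#' @return the acrophase in the other convention.
#' @export
acrophase_to_degrees <- function(clock_h, period = 24) {
  -(clock_h %% period) / period * 360
}

#' @rdname acrophase_to_degrees
#' @export
acrophase_from_degrees <- function(degrees, period = 24) {
  ((-degrees) %% 360) / 360 * period
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> n = %d, MESOR = %.4g (SE %.3g)\n",
              x$n, x$mesor, x$se_mesor))
  for (k in seq_len(nrow(x$components)))
    cat(sprintf("  tau = %g h: A = %.4g (SE %.3g), acrophase = %s\n",
                x$components$period[k], x$components$amplitude[k],
                x$components$se_amplitude[k],
                format_clock(x$components$acrophase[k])))
  if (length(x$peak_times))
    cat("  peaks of fitted curve:",
        paste(format_clock(x$peak_times), collapse = ", "), "\n")
  cat(sprintf("  zero-amplitude test: F(%d, %d) = %.4g, p = %.3g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Format clock hours as HH:MM
#'
#' @param h clock hours.
#' @return character vector like `"19:31"`.
#' @export
format_clock <- function(h) {
  h <- h %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60) %% 60)
}

#' Cosinor endpoints of one actigraphy channel
#'
#' Applies [fit_cosinor()] to the valid minutes of a recording channel, on a
#' clock-referenced time axis so acrophases are local clock times. Requires
#' at least 80% valid minutes; otherwise returns `NULL` with a warning (the
#' endpoint is missing for that recording).
#'
#' @param series an [actigraphy_series].
#' @param channel one of `"pim"`, `"lux"`, `"blue"`, `"wrist_temp"`.
#' @param periods component periods in hours (default single 24 h component).
#' @param light_transform `"raw"` (default) or `"log10"`; with `"log10"` the
#'   light channels are transformed by `log10(x + 1)` before fitting, an
#'   option for the heavy-tailed lux distribution.
#' @return a `cosinor_fit`, or `NULL` when coverage is insufficient.
#' @export
actigraphy_endpoints <- function(series, channel, periods = 24,
                                 light_transform = c("raw", "log10")) {
  stopifnot(inherits(series, "actigraphy_series"))
  light_transform <- match.arg(light_transform)
  if (!channel %in% names(series$channels))
    stop("no channel '", channel, "' in recording")
  cov <- mean(series$mask)
  if (cov < 0.8) {
    warning(sprintf("recording %s/%s: only %.1f%% valid minutes (< 80%%), %s endpoint missing",
                    series$participant_id, series$season, 100 * cov, channel),
            call. = FALSE)
    return(NULL)
  }
  t <- elapsed_hours(series)[series$mask]
  y <- series$channels[[channel]][series$mask]
  if (light_transform == "log10" && channel %in% c("lux", "blue"))
    y <- log10(y + 1)
  fit <- fit_cosinor(t, y, periods)
  fit$channel <- channel
  fit$participant_id <- series$participant_id
  fit$season <- series$season
  fit
}
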