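# Clock-time windowed correlation mapping: per 30-min epoch of the day,
# the cross-participant Pearson correlation between a wearable channel's
# epoch mean and morning expression, with Benjamini-Hochberg FDR control
# over the epoch family and a 24 h + 12 h harmonic model of the correlation
# profile to locate its peaks.

#' Clock-time epoch means of a recording channel
#'
#' Averages the valid minutes of each consecutive clock-time epoch (pooling
#' all recorded days), e.g. 48 means for 30-minute epochs. An epoch needs at
#' least 80% of its recorded minutes valid, otherwise it is `NA`.
#'
#' @param series an [actigraphy_series].
#' @param channel channel name.
#' @param width epoch width in minutes; must divide 1440.
#' @return numeric vector of length `1440/width` with attribute `mid_h`
#'   (epoch midpoints, clock hours).
#' @export
epoch_profile <- function(series, channel, width = 30) {
  stopifnot(inherits(series, "actigraphy_series"))
  if (1440 %% width != 0) stop("epoch width must divide 1440")
  if (!channel %in% names(series$channels))
    stop("no channel '", channel, "' in recording")
  n_ep <- 1440L %/% width
  cm <- round(clock_hours(series) * 60) %% 1440
  ep <- (cm %/% width) + 1L
  v <- series$channels[[channel]]
  valid <- series$mask & is.finite(v)
  tot <- tabulate(ep, nbins = n_ep)
  nv <- tabulate(ep[valid], nbins = n_ep)
  sums <- vapply(seq_len(n_ep), function(e) sum(v[valid & ep == e]), 0)
  out <- ifelse(tot > 0 & nv >= 0.8 * tot, sums / pmax(nv, 1), NA_real_)
  attr(out, "mid_h") <- (seq_len(n_ep) - 0.5) * width / 60
  out
}

#' Windowed correlation map between a channel and expression
#'
#' For each clock-time epoch, the Pearson correlation across pooled
#' participant-season observations between the epoch mean of the channel and
#' relative expression; two-sided p from the t transform on n - 2 df;
#' Benjamini-Hochberg step-up control at level `q` over the epoch family
#' (epochs with undefined correlations are dropped from the family).
#'
#' @param profiles matrix of epoch profiles, one row per participant-season
#'   observation (as from [epoch_profile()]).
#' @param expression numeric vector of relative expression, aligned with the
#'   rows of `profiles`.
#' @param q FDR level (default 0.1).
#' @param pooling `"all_seasons"` pools every observation into one family;
#'   `"per_season"` computes one map per season (requires `season`).
#' @param season optional season labels per row, for `per_season` pooling.
#' @param mid_h epoch midpoints (clock h); defaults to uniform epochs.
#' @param channel optional channel name stored for labelling.
#' @return data frame of class `correlation_map` with one row per epoch:
#'   `epoch`, `start_h`, `end_h`, `mid_h`, `n`, `r`, `p`, `p_adj`,
#'   `significant`; or a named list of such maps for `per_season` pooling.
#' @export
correlation_map <- function(profiles, expression, q = 0.1,
                            pooling = c("all_seasons", "per_season"),
                            season = NULL, mid_h = NULL, channel = NULL) {
  pooling <- match.arg(pooling)
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(expression))
  if (pooling == "per_season") {
    if (is.null(season)) stop("per_season pooling needs `season`")
    return(lapply(split(seq_along(expression), season), function(i)
      correlation_map(profiles[i, , drop = FALSE], expression[i], q = q,
                      mid_h = mid_h, channel = channel)))
  }
  n_ep <- ncol(profiles)
  if (is.null(mid_h)) mid_h <- (seq_len(n_ep) - 0.5) * 24 / n_ep
  width_h <- 24 / n_ep

  r <- p <- rep(NA_real_, n_ep)
  n_pairs <- integer(n_ep)
  for (e in seq_len(n_ep)) {
    ok <- is.finite(profiles[, e]) & is.finite(expression)
    n_pairs[e] <- sum(ok)
    if (n_pairs[e] < 3) next
    xe <- profiles[ok, e]; ye <- expression[ok]
    if (stats::sd(xe) == 0 || stats::sd(ye) == 0) next
    r[e] <- stats::cor(xe, ye)
    tt <- r[e] * sqrt((n_pairs[e] - 2) / max(1 - r[e]^2, 0))
    p[e] <- 2 * stats::pt(abs(tt), n_pairs[e] - 2, lower.tail = FALSE)
  }
  fam <- which(is.finite(p))
  if (length(fam) < n_ep)
    message(n_ep - length(fam),
            " epoch(s) with undefined correlation dropped from the FDR family")
  p_adj <- rep(NA_real_, n_ep)
  p_adj[fam] <- stats::p.adjust(p[fam], method = "BH")
  out <- data.frame(
    epoch = seq_len(n_ep),
    start_h = mid_h - width_h / 2,
    end_h = mid_h + width_h / 2,
    mid_h = mid_h,
    n = n_pairs, r = r, p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj <= q
  )
  attr(out, "q") <- q
  attr(out, "channel") <- channel
  class(out) <- c("correlation_map", "data.frame")
  out
}

#' Harmonic model of a correlation profile
#'
#' Fits a multi-component cosinor (default 24 h + 12 h harmonics) to the
#' epoch correlations and reports the local maxima of the fitted curve on a
#' 1-minute grid, labelled major/minor by fitted height. When the 24 h
#' component's amplitude interval covers zero, a 12 h-only refit is reported
#' alongside (mirroring profiles where only the half-daily harmonic is
#' supported).
#'
#' @param map a [correlation_map()].
#' @param periods harmonic periods in hours.
#' @return list of class `harmonic_peak_model`: `fit` (the `cosinor_fit`),
#'   `peaks` (data frame of clock time, fitted r, label), `F`, `p`,
#'   `degenerate`, and optionally `refit` (the reduced model).
#' @export
fit_peak_model <- function(map, periods = c(24, 12)) {
  ok <- is.finite(map$r)
  if (sum(ok) < 2 * length(periods) + 2)
    stop("too few epochs with defined correlations")
  fit <- fit_cosinor(map$mid_h[ok], map$r[ok], periods)
  peaks <- data.frame(time_h = numeric(), fitted_r = numeric(),
                      label = character())
  # peaks are reported whenever the fitted curve has structure (tss > 0);
  # a perfect noise-free fit is degenerate for F/p but its peaks are real
  if (fit$tss > 0 && length(fit$peak_times)) {
    fr <- predict_cosinor(fit, fit$peak_times)
    o <- order(fr, decreasing = TRUE)
    peaks <- data.frame(
      time_h = fit$peak_times[o],
      fitted_r = fr[o],
      label = c("major", rep("minor", length(o) - 1L))[seq_along(o)],
      stringsAsFactors = FALSE
    )
  }
  out <- list(fit = fit, peaks = peaks, F = fit$F, p = fit$p,
              degenerate = fit$degenerate, periods = periods)
  if (24 %in% periods && length(periods) > 1) {
    k24 <- which(fit$components$period == 24)
    lo <- fit$components$amplitude_lo[k24]
    if (is.finite(lo) && lo <= 0) {
      red <- setdiff(periods, 24)
      out$refit <- fit_peak_model(map, periods = red)
    }
  }
  class(out) <- "harmonic_peak_model"
  out
}

#' @export
print.harmonic_peak_model <- function(x, ...) {
  cat(sprintf("<harmonic_peak_model> periods %s h: F(%d, %d) = %.3f, p = %.3g\n",
              paste(x$periods, collapse = "+"), x$fit$df1, x$fit$df2,
              x$F, x$p))
  if (nrow(x$peaks))
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf("  %s peak at %s (fitted r = %.3f)\n", x$peaks$label[i],
                  format_clock(x$peaks$time_h[i]), x$peaks$fitted_r[i]))
  else cat("  no peaks claimed\n")
  if (!is.null(x$refit))
    cat("  24 h amplitude not supported; reduced model:",
        paste(x$refit$periods, collapse = "+"), "h, F =",
        format(x$refit$F, digits = 4), "\n")
  invisible(x)
}

#' Plot a correlation map
#'
#' Bar chart of the epoch correlations across the day, with significant
#' epochs (after FDR control) shaded, the significance threshold in r units
#' drawn as a horizontal line, and the fitted harmonic curve overlaid when a
#' peak model is supplied.
#'
#' @param x a [correlation_map()].
#' @param model optional [fit_peak_model()] result to overlay.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.correlation_map <- function(x, model = NULL, ...) {
  cols <- ifelse(x$significant, "orange", "grey70")
  ylim <- range(0, x$r, na.rm = TRUE) * 1.15
  bp <- graphics::barplot(x$r, names.arg = format_clock(x$start_h),
                          col = cols, border = NA, las = 2,
                          ylim = ylim, ylab = "Pearson r",
                          xlab = "clock time epoch", ...)
  if (any(x$significant, na.rm = TRUE)) {
    thr <- min(abs(x$r[x$significant]), na.rm = TRUE)
    graphics::abline(h = thr, col = "grey40", lty = 2)
  }
  if (!is.null(model)) {
    g <- seq(0, 24, by = 1 / 60)
    sc <- stats::approx(x$mid_h, bp, xout = g, rule = 2)$y
    graphics::lines(sc, predict_cosinor(model$fit, g), col = "blue", lwd = 2)
  }
  invisible(bp)
}

#' Flag regression outliers by studentized residuals
#'
#' Helper for sensitivity analyses of single-epoch correlations: fits
#' `y ~ x` and returns the indices whose absolute externally studentized
#' residual exceeds the threshold. Observations are never removed
#' automatically.
#'
#' @param x,y numeric vectors.
#' @param threshold absolute studentized-residual cutoff (default 3).
#' @return integer indices of flagged observations.
#' @export
studentized_outliers <- function(x, y, threshold = 3) {
  ok <- is.finite(x) & is.finite(y)
  fit <- stats::lm(y[ok] ~ x[ok])
  rs <- stats::rstudent(fit)
  which(ok)[abs(rs) > threshold]
}
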