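# Non-parametric circadian rhythm analysis (Van Someren-style metrics).
#
# On binned means x_i (N non-missing bins, p bins per day, clock-bin means
# xbar_h, grand mean xbar):
#   IS = [N * sum_h (xbar_h - xbar)^2] / [p * sum_i (x_i - xbar)^2]
#   IV = [N * sum_{i}(x_i - x_{i-1})^2] / [(N - 1) * sum_i (x_i - xbar)^2]
# M10/L5 are the max/min cyclic 10 h / 5 h moving-window means of the
# average day profile, with onsets at the window starts, RA =
# (M10 - L5)/(M10 + L5), and the circadian function index
# CFI = [IS + clip((2 - IV)/2, 0, 1) + RA] / 3 (equal-weight composite).

#' Non-parametric circadian metrics of a recording channel
#'
#' Computes inter-daily stability (IS), intra-daily variability (IV), the
#' most-active 10 h (M10) and least-active 5 h (L5) levels and onsets on the
#' average day profile, relative amplitude (RA) and the circadian function
#' index (CFI).
#'
#' @param x an [actigraphy_series], or an already-binned numeric vector of
#'   consecutive bin means.
#' @param ... passed to methods.
#' @return list of class `nonparam_metrics` with fields `IS`, `IV`, `M10`,
#'   `M10_onset`, `L5`, `L5_onset`, `RA`, `CFI`, `n_bins`, `bins_per_day`
#'   and `flags` (character notes about undefined metrics).
#' @export
nonparam_metrics <- function(x, ...) UseMethod("nonparam_metrics")

#' @rdname nonparam_metrics
#' @param channel channel name for the series method.
#' @param bin_min bin width in minutes (must divide 1440 and 300).
#' @export
nonparam_metrics.actigraphy_series <- function(x, channel = "pim",
                                               bin_min = 60, ...) {
  if (!channel %in% names(x$channels))
    stop("no channel '", channel, "' in recording")
  if (mean(x$mask) < 0.8)
    stop(sprintf("recording %s/%s below 80%% coverage", x$participant_id,
                 x$season))
  n <- length(x)
  if (n < 2 * 1440) stop("record must span at least 2 full days")
  if (1440 %% bin_min != 0) stop("bin width must divide 1440")
  v <- x$channels[[channel]]
  v[!x$mask] <- NA_real_
  # Bins are aligned to clock time so bin 1 of each day is the same clock
  # window; recordings start at a whole minute of the day.
  start_min <- round(as.numeric(difftime(
    x$start, trunc(x$start, "days"), units = "mins")))
  if (start_min %% bin_min != 0)
    stop("recording start must be aligned to the bin grid")
  n_bins <- n %/% bin_min
  v <- v[seq_len(n_bins * bin_min)]
  bm <- matrix(v, nrow = bin_min)
  cnt <- colSums(!is.na(bm))
  means <- ifelse(cnt >= 0.8 * bin_min, colMeans(bm, na.rm = TRUE), NA_real_)
  first_bin <- start_min %/% bin_min          # 0-based clock bin of bin 1
  npcra_core(means, p = 1440L %/% bin_min, bin_min = bin_min,
             first_bin = first_bin)
}

#' @rdname nonparam_metrics
#' @param bins_per_day number of bins per 24 h for the numeric method.
#' @param first_bin 0-based clock position of the first bin.
#' @export
nonparam_metrics.numeric <- function(x, bins_per_day = 24, first_bin = 0, ...) {
  npcra_core(as.numeric(x), p = as.integer(bins_per_day),
             bin_min = 1440 / bins_per_day, first_bin = first_bin)
}

npcra_core <- function(x, p, bin_min, first_bin = 0) {
  N_all <- length(x)
  if (N_all < 2 * p) stop("need at least 2 full days of bins")
  if (1440 %% bin_min != 0) stop("bin width must divide 1440")
  flags <- character()

  clockbin <- (first_bin + seq_len(N_all) - 1L) %% p  # 0-based clock bin
  ok <- is.finite(x)
  N <- sum(ok)
  xbar <- mean(x[ok])
  denom <- sum((x[ok] - xbar)^2)

  prof <- vapply(0:(p - 1L), function(h) {
    v <- x[ok & clockbin == h]
    if (length(v)) mean(v) else NA_real_
  }, 0)

  if (denom == 0) {
    IS <- IV <- NA_real_
    flags <- c(flags, "zero variance: IS and IV undefined")
  } else {
    IS <- N * sum((prof[is.finite(prof)] - xbar)^2) / (p * denom)
    adj <- which(ok[-1] & ok[-N_all])          # consecutive non-missing pairs
    d2 <- (x[adj + 1L] - x[adj])^2
    IV <- N * sum(d2) / ((N - 1) * denom)
  }

  wlen <- function(hours) {
    w <- hours * 60 / bin_min
    if (w != round(w)) stop("window of ", hours, " h not a whole number of bins")
    as.integer(w)
  }
  win_means <- function(w) {
    vapply(0:(p - 1L), function(s)
      mean(prof[((s + 0:(w - 1L)) %% p) + 1L]), 0)
  }
  m10w <- win_means(wlen(10))
  l5w <- win_means(wlen(5))
  if (all(is.na(m10w)) || all(is.na(l5w)))
    stop("day profile too incomplete for M10/L5 windows")
  i10 <- which.max(m10w)                        # earliest on ties
  i5 <- which.min(l5w)
  M10 <- m10w[i10]; L5 <- l5w[i5]
  M10_onset <- (i10 - 1L) * bin_min / 60
  L5_onset <- (i5 - 1L) * bin_min / 60

  if (!is.finite(M10 + L5) || M10 + L5 == 0) {
    RA <- NA_real_
    flags <- c(flags, "M10 + L5 = 0: RA undefined")
  } else RA <- (M10 - L5) / (M10 + L5)

  CFI <- if (is.finite(IS) && is.finite(IV) && is.finite(RA))
    (IS + min(max((2 - IV) / 2, 0), 1) + RA) / 3 else NA_real_

  structure(list(IS = IS, IV = IV, M10 = M10, M10_onset = M10_onset,
                 L5 = L5, L5_onset = L5_onset, RA = RA, CFI = CFI,
                 n_bins = N, bins_per_day = p, flags = flags),
            class = "nonparam_metrics")
}

#' @export
print.nonparam_metrics <- function(x, ...) {
  cat(sprintf(
    "<nonparam_metrics> IS = %.3f, IV = %.3f, RA = %.3f, CFI = %.3f\n",
    x$IS, x$IV, x$RA, x$CFI))
  cat(sprintf("  M10 = %.4g (onset %s), L5 = %.4g (onset %s), %d bins\n",
              x$M10, format_clock(x$M10_onset), x$L5,
              format_clock(x$L5_onset), x$n_bins))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
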