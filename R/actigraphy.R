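#' @keywords internal
"_PACKAGE"

#' Season levels used throughout the package
#'
#' Seasons are sampled at the solstices and equinoxes and ordered by the
#' annual light cycle: winter solstice, spring equinox, summer solstice,
#' autumn equinox.
#'
#' @export
SEASONS <- c("winter", "spring", "summer", "autumn")

# Recognised channel names and the CSV column each maps to.
CHANNELS <- c(pim = "pim", lux = "lux", blue = "blue_uw_cm2",
              wrist_temp = "wrist_temp_c")

NOMINAL_MINUTES <- 7L * 1440L

#' Construct a minute-resolution actigraphy recording
#'
#' An `actigraphy_series` holds one participant-season wrist recording:
#' per-minute motor activity (PIM counts), white-light illuminance (lux),
#' blue-light irradiance (uW/cm^2) and wrist skin temperature (degrees C),
#' on a uniform 1-minute grid, plus a per-minute validity mask.
#'
#' @param participant_id character scalar.
#' @param season one of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @param start POSIXct start of the recording (naive local clock; the
#'   package never converts time zones because every endpoint - acrophase,
#'   M10 onset, epoch-of-day correlation - is defined on local clock time).
#' @param channels data frame with any of the columns `pim`, `lux`, `blue`,
#'   `wrist_temp`; all columns must have equal length.
#' @param mask logical vector of per-minute validity; defaults to minutes
#'   where every channel is finite.
#'
#' @return An object of class `actigraphy_series`.
#' @export
actigraphy_series <- function(participant_id, season, start, channels,
                              mask = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  season <- match.arg(season, SEASONS)
  start <- as.POSIXct(start, tz = "UTC")
  stopifnot(length(start) == 1L, !is.na(start))
  channels <- as.data.frame(channels)
  known <- intersect(names(CHANNELS), names(channels))
  if (length(known) == 0L)
    stop("`channels` must contain at least one of: ",
         paste(names(CHANNELS), collapse = ", "))
  channels <- channels[known]
  n <- nrow(channels)
  if (n == 0L) stop("empty recording")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(channels, is.finite))
  }
  stopifnot(is.logical(mask), length(mask) == n)
  mask[is.na(mask)] <- FALSE
  for (ch in intersect(c("pim", "lux", "blue"), known)) {
    bad <- mask & (!is.finite(channels[[ch]]) | channels[[ch]] < 0)
    if (any(bad))
      stop("channel '", ch, "' has negative or non-finite values on ",
           sum(bad), " valid minutes")
  }
  structure(
    list(participant_id = participant_id, season = season, start = start,
         channels = channels, mask = mask),
    class = "actigraphy_series",
    full_week = (n == NOMINAL_MINUTES)
  )
}

#' @export
length.actigraphy_series <- function(x) nrow(x$channels)

#' @export
print.actigraphy_series <- function(x, ...) {
  cat(sprintf("<actigraphy_series> %s / %s\n", x$participant_id, x$season))
  cat(sprintf("  start %s, %d minutes (%.1f days), %.1f%% valid\n",
              format(x$start, "%Y-%m-%d %H:%M"), length(x),
              length(x) / 1440, 100 * mean(x$mask)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# Hours elapsed since the midnight preceding the first sample. Taking this
# as the cosinor time axis makes a 24 h acrophase directly a clock time.
elapsed_hours <- function(series) {
  start_h <- as.numeric(difftime(series$start, trunc(series$start, "days"),
                                 units = "hours"))
  start_h + (seq_len(length(series)) - 1L) / 60
}

# Clock time of day in hours, in [0, 24).
clock_hours <- function(series) elapsed_hours(series) %% 24

parse_timestamps <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop("unparseable timestamps, e.g. '", x[which(is.na(ts))[1]], "'")
  ts
}

#' Read a minute-level actigraphy CSV
#'
#' Reads a comma-separated export with an ISO-8601 `timestamp` column and at
#' least one channel column. Rows are sorted by time; minutes missing from
#' the file are inserted on a uniform 1-minute grid with the validity mask
#' cleared, so downstream coverage rules see them as invalid rather than
#' absent. Non-numeric or negative channel values invalidate that minute
#' with a warning. Duplicated timestamps and empty files are hard errors.
#'
#' @param path CSV file path.
#' @param participant_id,season recording identity; if `NULL`, taken from
#'   optional `participant_id`/`season` columns in the file.
#' @param col_map named character vector mapping internal channel names
#'   (`pim`, `lux`, `blue`, `wrist_temp`) and `timestamp` to the file's
#'   column names, for device exports with other headers.
#'
#' @return An [actigraphy_series].
#' @export
read_actigraphy <- function(path, participant_id = NULL, season = NULL,
                            col_map = NULL) {
  cmap <- c(timestamp = "timestamp", CHANNELS)
  if (!is.null(col_map)) cmap[names(col_map)] <- col_map
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty actigraphy file: ", path)
  if (!cmap[["timestamp"]] %in% names(raw))
    stop("no timestamp column '", cmap[["timestamp"]], "' in ", path)
  ts <- parse_timestamps(raw[[cmap[["timestamp"]]]])
  if (anyDuplicated(ts)) stop("duplicate timestamps in ", path)
  o <- order(ts)
  ts <- ts[o]
  raw <- raw[o, , drop = FALSE]

  present <- names(CHANNELS)[cmap[names(CHANNELS)] %in% names(raw)]
  if (length(present) == 0L) stop("no recognised channel columns in ", path)

  grid <- seq(ts[1], ts[length(ts)], by = 60)
  idx <- match(as.numeric(ts), as.numeric(grid))
  if (anyNA(idx)) stop("timestamps are not aligned to a 1-minute grid in ", path)

  n <- length(grid)
  channels <- as.data.frame(
    lapply(present, function(ch) {
      col <- rep(NA_character_, n)
      col[idx] <- raw[[cmap[[ch]]]]
      col[!nzchar(col) | is.na(col)] <- NA_character_
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad))
        warning(sum(bad), " non-numeric value(s) in channel '", ch,
                "' masked invalid", call. = FALSE)
      num
    }),
    col.names = present
  )
  mask <- Reduce(`&`, lapply(channels, is.finite))
  for (ch in intersect(c("pim", "lux", "blue"), present)) {
    neg <- mask & channels[[ch]] < 0
    if (any(neg)) {
      warning(sum(neg), " negative value(s) in channel '", ch,
              "' masked invalid", call. = FALSE)
      mask <- mask & !neg
      channels[[ch]][neg] <- NA_real_
    }
  }
  if (is.null(participant_id))
    participant_id <- if ("participant_id" %in% names(raw))
      raw$participant_id[1] else basename(path)
  if (is.null(season))
    season <- if ("season" %in% names(raw)) raw$season[1] else
      stop("season not given and not in file")
  out <- actigraphy_series(participant_id, season, grid[1], channels, mask)
  if (!attr(out, "full_week"))
    message("recording ", participant_id, "/", season, " has ", n,
            " minutes (nominal ", NOMINAL_MINUTES, ")")
  out
}

#' Write an actigraphy recording to CSV
#'
#' The inverse of [read_actigraphy()]. Values are written with 17 significant
#' digits so finite values round-trip bit-identically; invalid minutes are
#' written with empty channel fields and read back as masked.
#'
#' @param series an [actigraphy_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_actigraphy <- function(series, path) {
  n <- length(series)
  ts <- format(series$start + 60 * (seq_len(n) - 1L), "%Y-%m-%dT%H:%M:%S")
  out <- data.frame(timestamp = ts, stringsAsFactors = FALSE)
  for (ch in names(series$channels)) {
    v <- series$channels[[ch]]
    s <- ifelse(series$mask & is.finite(v), sprintf("%.17g", v), "")
    out[[CHANNELS[[ch]]]] <- s
  }
  out$participant_id <- series$participant_id
  out$season <- series$season
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
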