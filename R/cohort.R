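#' Read a qPCR expression table
#'
#' Expects columns `participant_id`, `season`, `cq_target`, `cq_reference`
#' and optionally `relative_expression` and `sample_time`. Cq values are the
#' quantification cycles of the target gene and of the reference
#' (housekeeping) gene for the single morning sample of that
#' participant-season.
#'
#' @param path CSV file path.
#' @return data frame of expression samples.
#' @export
read_expression <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "season", "cq_target", "cq_reference")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("expression table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !x$season %in% SEASONS
  if (any(bad)) stop("unknown season label(s): ",
                     paste(unique(x$season[bad]), collapse = ", "))
  if (!"sample_time" %in% names(x)) x$sample_time <- "08:00"
  x$participant_id <- as.character(x$participant_id)
  x
}

#' Read a participant metadata table
#'
#' Expects columns `participant_id`, `age` (years), `sex` (`F`/`M`),
#' `bmi` (kg/m^2) and `population` (`native`/`nonnative`).
#'
#' @param path CSV file path.
#' @return data frame of participant metadata.
#' @export
read_metadata <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "sex", "bmi", "population")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("metadata table lacks column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(x$age > 0), all(x$bmi > 0),
            all(x$sex %in% c("F", "M")),
            all(x$population %in% c("native", "nonnative")))
  x$participant_id <- as.character(x$participant_id)
  x
}

check_unique_keys <- function(df, keys, what) {
  dup <- duplicated(df[keys])
  if (any(dup))
    stop("conflicting duplicate rows in ", what, " for key(s): ",
         paste(do.call(paste, c(df[dup, keys, drop = FALSE], sep = "/")),
               collapse = ", "))
}

#' Assemble the participant-season analysis table
#'
#' Outer-joins expression samples and per-recording derived metrics on
#' (`participant_id`, `season`), then attaches participant metadata. One row
#' per distinct participant-season present in any input; cells absent from an
#' input are explicitly `NA`, never dropped, so the partially missing
#' seasonal availability typical of field cohorts stays visible.
#'
#' @param expr expression data frame (see [read_expression()]); may be `NULL`.
#' @param meta metadata data frame (see [read_metadata()]).
#' @param metrics optional data frame of derived per-recording metrics keyed
#'   by `participant_id` and `season` (cosinor endpoints, non-parametric
#'   endpoints, ...).
#' @return data frame of class `cohort_table`, sorted by participant and
#'   season.
#' @export
assemble_cohort <- function(expr, meta, metrics = NULL) {
  stopifnot(is.data.frame(meta))
  keys <- c("participant_id", "season")
  check_unique_keys(meta, "participant_id", "metadata")
  tab <- NULL
  for (part in list(expr = expr, metrics = metrics)) {
    if (is.null(part)) next
    stopifnot(all(keys %in% names(part)))
    part$participant_id <- as.character(part$participant_id)
    check_unique_keys(part, keys, "input")
    tab <- if (is.null(tab)) part else merge(tab, part, by = keys, all = TRUE)
  }
  if (is.null(tab)) stop("need at least one of `expr`, `metrics`")
  orphan <- setdiff(tab$participant_id, meta$participant_id)
  if (length(orphan))
    stop("participant(s) without metadata: ", paste(orphan, collapse = ", "))
  tab <- merge(tab, meta, by = "participant_id", all.x = TRUE)
  tab <- tab[order(tab$participant_id,
                   match(tab$season, SEASONS)), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
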