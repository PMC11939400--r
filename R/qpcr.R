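#' Calibrator specification for 2^-ddCq quantification
#'
#' Either a single explicit sample or the mean delta-Cq of a group (default:
#' the winter-solstice samples, so relative expression reads as fold change
#' versus the darkest season). All downstream statistics are invariant to
#' this choice because every ratio RE_i/RE_j is calibrator-free.
#'
#' @param mode `"group_mean"` or `"explicit_sample"`.
#' @param group season label used when `mode = "group_mean"`.
#' @param sample_id `"participant_id/season"` key used when
#'   `mode = "explicit_sample"`.
#' @return list of class `calibrator_spec`.
#' @export
calibrator_spec <- function(mode = c("group_mean", "explicit_sample"),
                            group = "winter", sample_id = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit_sample" && is.null(sample_id))
    stop("explicit_sample mode needs `sample_id`")
  if (mode == "group_mean" && !group %in% SEASONS)
    stop("unknown calibrator group: ", group)
  structure(list(mode = mode, group = group, sample_id = sample_id),
            class = "calibrator_spec")
}

#' Relative expression by the 2^-ddCq method
#'
#' For each sample, `dCq = cq_target - cq_reference` (target gene normalized
#' to the reference/housekeeping gene), `ddCq = dCq - dCq_cal`, and
#' `RE = 2^-ddCq`, where `dCq_cal` is the calibrator sample's dCq or the
#' arithmetic mean dCq of the calibrator group. No amplification-efficiency
#' correction is applied (doubling per cycle assumed).
#'
#' Samples with non-finite Cq are flagged (`qc_pass = FALSE`), excluded from
#' the calibrator mean and left with `NA` expression, with a warning.
#'
#' @param samples expression data frame with `participant_id`, `season`,
#'   `cq_target`, `cq_reference` (see [read_expression()]).
#' @param calibrator a [calibrator_spec()].
#' @return `samples` with `delta_cq`, `delta_delta_cq`,
#'   `relative_expression` and `qc_pass` columns added.
#' @export
delta_delta_cq <- function(samples, calibrator = calibrator_spec()) {
  stopifnot(is.data.frame(samples),
            all(c("participant_id", "season", "cq_target",
                  "cq_reference") %in% names(samples)))
  ok <- is.finite(samples$cq_target) & is.finite(samples$cq_reference)
  if (any(!ok))
    warning(sum(!ok), " sample(s) with non-finite Cq excluded", call. = FALSE)
  dcq <- ifelse(ok, samples$cq_target - samples$cq_reference, NA_real_)

  if (calibrator$mode == "group_mean") {
    cal <- ok & samples$season == calibrator$group
    if (!any(cal)) stop("empty calibrator group: ", calibrator$group)
    dcq_cal <- mean(dcq[cal])
  } else {
    key <- paste(samples$participant_id, samples$season, sep = "/")
    hit <- which(key == calibrator$sample_id & ok)
    if (length(hit) != 1L)
      stop("calibrator sample not resolvable: ", calibrator$sample_id)
    dcq_cal <- dcq[hit]
  }

  samples$delta_cq <- dcq
  samples$delta_delta_cq <- dcq - dcq_cal
  samples$relative_expression <- 2^(-samples$delta_delta_cq)
  samples$qc_pass <- ok
  samples
}
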