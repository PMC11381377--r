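#' Blink feature of an EOG epoch
#'
#' The peak (maximum absolute amplitude) of a 2-s EOG trace. Blinks are
#' biphasic and the electrode polarity is montage-dependent, so the
#' absolute value is taken.
#'
#' @param trace numeric vector (512 samples at 256 Hz).
#' @return Peak amplitude in microvolts.
#' @export
blink_feature <- function(trace) {
  if (length(trace) == 0) stop("empty EOG trace")
  max(abs(trace))
}

#' Calibrate the blink-detection threshold
#'
#' From the peak features of the blinking trials of an EOG run, outliers
#' are pruned relative to the median -- features strictly above twice the
#' median or strictly below half of it are removed -- and the threshold is
#' the arithmetic mean of the survivors. Boundary features (exactly at
#' `2*median` or `median/2`) survive.
#'
#' @param features numeric vector of blink peak amplitudes (microvolts).
#' @return A list of class `blink_calibration` with `raw_features`,
#'   `retained_features`, `threshold`.
#' @examples
#' calibrate_threshold(c(10, 90, 100, 110, 500))$threshold  # 100
#' @export
calibrate_threshold <- function(features) {
  if (length(features) == 0) stop("no blink features supplied")
  med <- stats::median(features)
  keep <- features >= med / 2 & features <= 2 * med
  if (!any(keep)) stop("all blink features pruned as outliers")
  structure(list(raw_features = features,
                 retained_features = features[keep],
                 threshold = mean(features[keep])),
            class = "blink_calibration")
}

#' Has the subject marked this trial as dissatisfied?
#'
#' TRUE iff the peak amplitude of the confirmation-phase EOG strictly
#' exceeds the calibrated blink threshold.
#'
#' @param confirmation_eog numeric vector, the 2-s confirmation trace.
#' @param calibration a [calibrate_threshold()] result.
#' @return Logical flag.
#' @export
is_dissatisfied <- function(confirmation_eog, calibration) {
  if (!inherits(calibration, "blink_calibration"))
    stop("missing or invalid blink calibration")
  blink_feature(confirmation_eog) > calibration$threshold
}

#' Calibrate from a (simulated or recorded) EOG run
#'
#' Convenience wrapper: extracts peak features of the blinking-labeled
#' trials only and calibrates the threshold from them.
#'
#' @param eog_run list of records with elements `trace` and `blink`.
#' @return A `blink_calibration`.
#' @export
calibrate_eog_run <- function(eog_run) {
  blinks <- Filter(function(tr) isTRUE(tr$blink), eog_run)
  if (length(blinks) == 0) stop("EOG run contains no blinking trials")
  calibrate_threshold(vapply(blinks, function(tr) blink_feature(tr$trace), 0))
}

#' Remove dissatisfied trials from a run
#'
#' Drops every trial whose confirmation EOG peak exceeds the blink
#' threshold; surviving trials keep their labels untouched.
#'
#' @param run list of [raw_trial()] objects.
#' @param calibration a `blink_calibration`.
#' @return List with `trials` (the survivors), `flagged` (indices of the
#'   removed trials).
#' @export
gate_run <- function(run, calibration) {
  flagged <- which(vapply(run, function(tr)
    is_dissatisfied(tr$eog, calibration), logical(1)))
  list(trials = if (length(flagged)) run[-flagged] else run,
       flagged = flagged)
}
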