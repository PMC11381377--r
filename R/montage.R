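#' Sensorimotor electrode montage
#'
#' The fixed 21-electrode layout over the sensorimotor cortex used
#' throughout the toolkit, plus the prefrontal EOG channel. Electrodes are
#' arranged in three rows (FC, C, CP) of seven positions each and split
#' into a left group (`J1`), a right group (`J2`) and the midline. Every
#' trial matrix in this package has its columns in the order of
#' `all_labels`; modules resolve electrode indices through the montage,
#' never by hard-coded position.
#'
#' @return An object of class `mi_montage`: a list with elements
#'   `all_labels` (21 electrode names, canonical column order),
#'   `left_group` (9 names), `right_group` (9 names), `midline` (3 names),
#'   `eog_label` (`"Fp2"`), and `coords`, a data.frame of planar 10-20
#'   projection coordinates (`label`, `x`, `y`; x positive towards the
#'   right ear, y positive towards the nasion) for topographic export.
#' @examples
#' m <- standard_montage()
#' m$left_group
#' @export
standard_montage <- function() {
  all_labels <- c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
                  "C5",  "C3",  "C1",  "Cz",  "C2",  "C4",  "C6",
                  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
  left_group  <- c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1")
  right_group <- c("FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6")
  midline     <- c("FCz", "Cz", "CPz")

  xs <- c("5" = -0.6, "3" = -0.4, "1" = -0.2, "z" = 0,
          "2" = 0.2, "4" = 0.4, "6" = 0.6)
  ys <- c(FC = 0.2, C = 0, CP = -0.2)
  row_of <- sub("[z0-9]+$", "", all_labels)
  col_of <- sub("^(FC|CP|C)", "", all_labels)
  coords <- data.frame(
    label = c(all_labels, "Fp2"),
    x = c(unname(xs[col_of]), 0.25),
    y = c(unname(ys[row_of]), 0.9),
    stringsAsFactors = FALSE
  )

  structure(
    list(all_labels = all_labels,
         left_group = left_group,
         right_group = right_group,
         midline = midline,
         eog_label = "Fp2",
         coords = coords),
    class = "mi_montage"
  )
}

#' @export
print.mi_montage <- function(x, ...) {
  cat("Sensorimotor MI montage: 21 EEG electrodes + EOG (", x$eog_label,
      ")\n", sep = "")
  cat("  left group (J1): ", paste(x$left_group, collapse = " "), "\n")
  cat("  right group (J2):", paste(x$right_group, collapse = " "), "\n")
  cat("  midline:         ", paste(x$midline, collapse = " "), "\n")
  invisible(x)
}

#' Column indices of a montage group
#'
#' @param montage An `mi_montage`.
#' @param group One of `"left"`, `"right"`, `"midline"`, `"all"`.
#' @return Integer indices into the canonical column order.
#' @export
montage_indices <- function(montage, group = c("left", "right", "midline", "all")) {
  group <- match.arg(group)
  labs <- switch(group,
                 left = montage$left_group,
                 right = montage$right_group,
                 midline = montage$midline,
                 all = montage$all_labels)
  match(labs, montage$all_labels)
}

#' Human-readable class name
#'
#' Class labels follow the convention 1 = right-hand MI, 2 = left-hand MI.
#'
#' @param label Class label, 1 or 2.
#' @return `"right-hand"` or `"left-hand"`.
#' @export
class_name <- function(label) {
  if (length(label) != 1L || !label %in% c(1, 2))
    stop("invalid class label: must be 1 (right-hand) or 2 (left-hand)")
  if (label == 1) "right-hand" else "left-hand"
}

#' Trial timing constants
#'
#' Timing of one calibration/testing trial: 2 s preparation (not
#' recorded), 4 s motor imagery at 256 Hz, 2 s confirmation window for the
#' EOG channel. The training epoch spans 0.5--2.5 s after cue onset;
#' feedback topographies average over three nested segments all starting
#' at 0.5 s. Times are 0-based seconds from MI-cue onset; sample windows
#' are half-open `[start, end)`, so (0.5, 2.5) at 256 Hz covers exactly
#' 512 samples.
#'
#' @return A list of class `mi_timing` with fields `sampling_rate`,
#'   `preparation_s`, `mi_s`, `confirmation_s`, `training_window_s`,
#'   `feedback_segments_s` (list of 3 start/end pairs), `eog_task_s`.
#' @export
timing_scheme <- function() {
  structure(
    list(sampling_rate = 256,
         preparation_s = 2,
         mi_s = 4,
         confirmation_s = 2,
         training_window_s = c(0.5, 2.5),
         feedback_segments_s = list(c(0.5, 1.5), c(0.5, 2.5), c(0.5, 3.5)),
         eog_task_s = 2),
    class = "mi_timing"
  )
}

#' Construct a raw MI trial
#'
#' @param mi_samples 1024 x 21 numeric matrix (4 s at 256 Hz, microvolts),
#'   columns in montage order.
#' @param confirmation_eog length-512 numeric vector (2 s EOG trace).
#' @param label class label (1 right-hand, 2 left-hand).
#' @param trial_id,run_id opaque identifiers.
#' @return A list of class `raw_trial`.
#' @export
raw_trial <- function(mi_samples, confirmation_eog, label,
                      trial_id = NA_character_, run_id = NA_character_) {
  mi_samples <- as.matrix(mi_samples)
  if (nrow(mi_samples) != 1024L || ncol(mi_samples) != 21L)
    stop("mi_samples must be a 1024 x 21 matrix")
  if (length(confirmation_eog) != 512L)
    stop("confirmation_eog must have 512 samples")
  if (!label %in% c(1, 2)) stop("invalid class label")
  structure(list(mi = mi_samples, eog = as.numeric(confirmation_eog),
                 label = as.integer(label),
                 trial_id = trial_id, run_id = run_id),
            class = "raw_trial")
}

#' Construct an epoched MI trial
#'
#' @param samples 512 x 21 numeric matrix (0.5--2.5 s window, microvolts).
#' @param label class label.
#' @param satisfied logical; FALSE when the subject marked the trial
#'   dissatisfied by blinking.
#' @param trial_id,run_id opaque identifiers.
#' @return A list of class `epoched_trial`.
#' @export
epoched_trial <- function(samples, label, satisfied = TRUE,
                          trial_id = NA_character_, run_id = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) != 512L || ncol(samples) != 21L)
    stop("epoched samples must be a 512 x 21 matrix")
  if (!label %in% c(1, 2)) stop("invalid class label")
  structure(list(samples = samples, label = as.integer(label),
                 satisfied = isTRUE(satisfied),
                 trial_id = trial_id, run_id = run_id),
            class = "epoched_trial")
}
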