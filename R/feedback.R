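#' Envelope transform of a 4-s MI trial
#'
#' Turns a (band-pass filtered) 1024 x 21 trial into baseline-subtracted
#' envelope deviations, the quantity the per-trial topographies average:
#'
#' 1. re-reference each sample -- by default the local (common) average
#'    over the 21 sensorimotor electrodes; a nearest-neighbour surface
#'    Laplacian over the 3 x 7 electrode grid is available, or no
#'    re-referencing at all;
#' 2. band-pass to the rhythm band (default 8--30 Hz, mu + beta) and take
#'    the analytic-signal magnitude as the envelope;
#' 3. subtract, per channel, the mean envelope over the full 4-s window.
#'
#' The 4-s MI window is the only recorded interval (the preparation phase
#' is not acquired), so the full-window mean is the baseline; ERD then
#' shows as negative deviations and ERS as positive ones within the
#' window.
#'
#' @param mi_samples 1024 x 21 numeric matrix, already 0.1--30 Hz
#'   filtered.
#' @param reference_mode `"car"` (common average, default),
#'   `"laplacian"`, or `"none"`.
#' @param band_hz length-2 numeric, envelope rhythm band in Hz.
#' @param montage an [standard_montage()] (used for Laplacian
#'   neighbourhoods).
#' @return A 1024 x 21 matrix of envelope deviations (class
#'   `envelope_trial`); per-channel means are 0 by construction.
#' @export
envelope_transform <- function(mi_samples,
                               reference_mode = c("car", "laplacian", "none"),
                               band_hz = c(8, 30),
                               montage = standard_montage()) {
  reference_mode <- match.arg(reference_mode)
  x <- as.matrix(mi_samples)
  if (nrow(x) != 1024L || ncol(x) != 21L)
    stop("expected a 1024 x 21 MI window")
  if (!all(is.finite(x))) stop("non-finite samples")

  x <- switch(reference_mode,
              car = x - rowMeans(x),
              laplacian = x - neighbour_means(x, montage),
              none = x)

  sos <- butter_sos(4, band_hz / 128, "pass")
  xb <- sos_filter_zerophase(sos, x)
  env <- apply(xb, 2, function(col) Mod(analytic_signal(col)))
  env <- sweep(env, 2, colMeans(env))
  structure(env, class = c("envelope_trial", class(env)))
}

# Analytic signal via the frequency domain (positive frequencies doubled).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Mean over grid neighbours (up/down/left/right in the 3 x 7 layout).
neighbour_means <- function(x, montage) {
  labs <- montage$all_labels
  grid <- matrix(labs, nrow = 3, byrow = TRUE)  # rows FC, C, CP
  out <- x
  for (r in 1:3) for (cc in 1:7) {
    nb <- character(0)
    if (r > 1) nb <- c(nb, grid[r - 1, cc])
    if (r < 3) nb <- c(nb, grid[r + 1, cc])
    if (cc > 1) nb <- c(nb, grid[r, cc - 1])
    if (cc < 7) nb <- c(nb, grid[r, cc + 1])
    out[, match(grid[r, cc], labs)] <-
      rowMeans(x[, match(nb, labs), drop = FALSE])
  }
  out
}

#' Segment-average topographies
#'
#' Averages the envelope deviations over the three nested feedback
#' segments (0.5, 1.5), (0.5, 2.5), (0.5, 3.5) s: `R[k, j]` is the mean
#' over segment `k` at electrode `j` (segment lengths 256, 512, 768
#' samples, all starting at sample 129).
#'
#' @param env an [envelope_transform()] result (1024 x 21).
#' @param timing a [timing_scheme()].
#' @return A 3 x 21 matrix of class `topo_summary`.
#' @export
segment_averages <- function(env, timing = timing_scheme()) {
  env <- unclass(env)
  fs <- timing$sampling_rate
  R <- t(vapply(timing$feedback_segments_s, function(seg) {
    i0 <- floor(seg[1] * fs) + 1L
    i1 <- floor(seg[2] * fs)
    colMeans(env[i0:i1, , drop = FALSE])
  }, numeric(ncol(env))))
  structure(R, class = c("topo_summary", class(R)))
}

#' Select the representative topographic map
#'
#' Counts correctly activated electrodes in each of the three segment
#' topographies and picks the best one. For a left-hand trial a left
#' electrode is correct when its average deviation is positive (ERS) and
#' a right electrode when negative (ERD); for a right-hand trial the
#' signs swap sides. A segment with correct activity on both hemispheres
#' scores `Nl + Nr` and permanently outranks single-hemisphere segments
#' (a flag latches); a segment correct on the expected ERS hemisphere
#' only scores that single count while no two-hemisphere segment has been
#' seen. Ties keep the earliest segment (strict improvement required);
#' if nothing scores, the middle map (K = 2) is the default.
#'
#' @param topo a [segment_averages()] result (3 x 21).
#' @param label class label (1 right-hand, 2 left-hand).
#' @param montage an [standard_montage()].
#' @return List with `K` (selected segment, 1..3), `counts` (3 x 2 matrix
#'   of `Nl`, `Nr` per segment), `best_metric`.
#' @export
select_topomap <- function(topo, label, montage = standard_montage()) {
  if (!label %in% c(1, 2)) stop("invalid class label")
  R <- unclass(topo)
  li <- montage_indices(montage, "left")
  ri <- montage_indices(montage, "right")
  best <- 0
  flag <- FALSE
  K <- NA_integer_
  counts <- matrix(0L, 3, 2, dimnames = list(NULL, c("Nl", "Nr")))
  for (k in 1:3) {
    if (label == 2) {  # left-hand: ERS left (+), ERD right (-)
      Nl <- sum(R[k, li] > 0)
      Nr <- sum(R[k, ri] < 0)
    } else {           # right-hand: ERD left (-), ERS right (+)
      Nl <- sum(R[k, li] < 0)
      Nr <- sum(R[k, ri] > 0)
    }
    counts[k, ] <- c(Nl, Nr)
    metric <- 0
    if (Nl > 0 && Nr > 0) {
      metric <- Nl + Nr
      flag <- TRUE
    } else if (!flag) {
      # single-hemisphere fallback: the ERS side count, only while no
      # two-hemisphere map has been seen
      single <- if (label == 2) Nl else Nr
      if (single > 0) metric <- single
    }
    if (metric > best) {
      best <- metric
      K <- k
    }
  }
  if (best == 0) K <- 2L
  list(K = K, counts = counts, best_metric = best)
}

#' Topographic values of the selected map
#'
#' Hemispheric ERD/ERS scores of a 21-electrode topography under the two
#' class hypotheses. `topoval_right` (class 1) sums, over left electrodes
#' with negative deviation, the ratio to the most negative left value,
#' plus, over right electrodes with positive deviation, the ratio to the
#' largest right value; `topoval_left` mirrors it. Every ratio lies in
#' (0, 1], so each value lies in [0, 18]; a hemisphere with no electrode
#' of the required sign contributes 0, and midline electrodes never
#' contribute.
#'
#' @param Rk numeric vector of 21 segment-average deviations.
#' @param montage an [standard_montage()].
#' @return List with `topoval_right` (class-1 hypothesis) and
#'   `topoval_left` (class-2 hypothesis).
#' @export
topo_values <- function(Rk, montage = standard_montage()) {
  li <- montage_indices(montage, "left")
  ri <- montage_indices(montage, "right")
  L <- Rk[li]
  R <- Rk[ri]
  ratio_sum <- function(v, want_pos) {
    v <- if (want_pos) v[v > 0] else v[v < 0]
    if (length(v) == 0) return(0)
    ext <- if (want_pos) max(v) else min(v)
    sum(v / ext)
  }
  list(
    topoval_right = ratio_sum(L, FALSE) + ratio_sum(R, TRUE),
    topoval_left  = ratio_sum(L, TRUE) + ratio_sum(R, FALSE)
  )
}

#' Qualitative verdict for one trial
#'
#' `'good'` when the topographic value of the true class attains the
#' maximum of the two (ties count as good, the maximum being attained by
#' the true class), `'fight'` otherwise.
#'
#' @param topoval a [topo_values()] result.
#' @param label class label.
#' @return `"good"` or `"fight"`.
#' @export
evaluate_trial <- function(topoval, label) {
  if (!label %in% c(1, 2)) stop("invalid class label")
  own <- if (label == 1) topoval$topoval_right else topoval$topoval_left
  if (own >= max(topoval$topoval_right, topoval$topoval_left)) "good"
  else "fight"
}

#' Full prompt-feedback computation for one trial
#'
#' Filter, envelope-transform, pick the representative segment map,
#' score it, and produce the verdict -- everything the on-screen feedback
#' of one calibration trial requires.
#'
#' @param trial a [raw_trial()].
#' @param spec a [filter_spec()].
#' @param reference_mode,band_hz passed to [envelope_transform()].
#' @param montage an [standard_montage()].
#' @return A list of class `feedback_outcome`: `K`, `counts`,
#'   `topoval_right`, `topoval_left`, `verdict`, `map` (the 21 deviations
#'   of the selected segment, plot-ready), `label`.
#' @export
trial_feedback <- function(trial, spec = filter_spec(),
                           reference_mode = "car", band_hz = c(8, 30),
                           montage = standard_montage()) {
  filt <- filter_trial(trial$mi, spec)
  env <- envelope_transform(filt, reference_mode, band_hz, montage)
  topo <- segment_averages(env)
  sel <- select_topomap(topo, trial$label, montage)
  tv <- topo_values(unclass(topo)[sel$K, ], montage)
  structure(list(K = sel$K, counts = sel$counts,
                 topoval_right = tv$topoval_right,
                 topoval_left = tv$topoval_left,
                 verdict = evaluate_trial(tv, trial$label),
                 map = stats::setNames(unclass(topo)[sel$K, ],
                                       montage$all_labels),
                 label = trial$label),
            class = "feedback_outcome")
}
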