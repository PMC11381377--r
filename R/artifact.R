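#' Per-trial, per-channel variances
#'
#' Unbiased (N-1) variance of each channel of each epoched trial.
#'
#' @param trials list of [epoched_trial()] objects.
#' @return N x 21 matrix of variances (microvolts squared).
#' @export
trial_variances <- function(trials) {
  t(vapply(trials, function(tr) apply(tr$samples, 2, stats::var),
           numeric(ncol(trials[[1]]$samples))))
}

#' Low-variance channel screen
#'
#' Drops channel `j` when strictly more than 10% of trials have variance
#' strictly below 0.5 microvolts squared there (a flat channel carries no
#' signal and would distort the pooled variance threshold). Computed once
#' on the post-gating set, before the iterative rejection loop.
#'
#' @param variances N x C matrix from [trial_variances()].
#' @param small_var variance floor (default 0.5).
#' @param max_fraction tolerated fraction of small-variance trials
#'   (default 0.1, strict).
#' @return Integer indices of the retained channels.
#' @export
channel_screen <- function(variances, small_var = 0.5, max_fraction = 0.1) {
  frac <- colMeans(variances < small_var)
  which(frac <= max_fraction)
}

#' Iteratively remove trials with excessive variance
#'
#' The pooled retained-channel variances `Var` of the remaining trials
#' set a threshold `P90(Var) + 3 * (P90(Var) - P10(Var))` (percentiles by
#' the linear-interpolation order-statistic convention, R's default type
#' 7); every trial whose maximum retained-channel variance strictly
#' exceeds it is removed, and the loop repeats until an iteration removes
#' nothing. A trial is doomed by a single excessive channel. The screen of
#' [channel_screen()] only restricts which channels feed the threshold;
#' all channels stay in the returned trials.
#'
#' @param trials list of [epoched_trial()] objects (at least 2).
#' @param small_var,max_fraction passed to [channel_screen()].
#' @return A list of class `variance_screen`: `trials` (survivors),
#'   `removed` (indices into the input, in removal order),
#'   `retained_channels`, `threshold_history`, `n_final`.
#' @export
reject_high_variance <- function(trials, small_var = 0.5,
                                 max_fraction = 0.1) {
  if (length(trials) < 2) stop("need at least 2 trials")
  V <- trial_variances(trials)
  keep_ch <- channel_screen(V, small_var, max_fraction)
  if (length(keep_ch) == 0) stop("every channel screened out")
  alive <- seq_along(trials)
  removed <- integer(0)
  thresholds <- numeric(0)
  repeat {
    Var <- as.numeric(V[alive, keep_ch])
    q <- stats::quantile(Var, c(0.9, 0.1), names = FALSE, type = 7)
    thr <- q[1] + 3 * (q[1] - q[2])
    thresholds <- c(thresholds, thr)
    worst <- apply(V[alive, keep_ch, drop = FALSE], 1, max)
    kick <- alive[worst > thr]
    if (length(kick) == 0) break
    removed <- c(removed, kick)
    alive <- setdiff(alive, kick)
    if (length(alive) == 0)
      stop("variance rejection removed every trial (degenerate input)")
  }
  structure(list(trials = trials[alive], removed = removed,
                 retained_channels = keep_ch,
                 threshold_history = thresholds,
                 n_final = length(alive)),
            class = "variance_screen")
}
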