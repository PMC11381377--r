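#' Temporal filter specification
#'
#' Band-pass plus power-line notch applied identically to calibration and
#' testing trials: 0.1--30 Hz Butterworth of order 8 and a 48--52 Hz
#' band-stop of the same order. Filters are factored into second-order
#' sections for numerical stability (the 0.1 Hz edge places poles very
#' close to the unit circle, where the expanded transfer-function form
#' loses precision).
#'
#' Two application modes are provided. `"zero-phase"` (the offline
#' default) applies the squared magnitude response on the even periodic
#' extension of the trial, i.e. the exact limit of forward-backward
#' filtering without the start-up transient of the recursive form -- on a
#' 4 s trial the 0.1 Hz pole's transient (time constant of several
#' seconds) would otherwise never decay inside the window. `"causal"`
#' runs the recursive sections forward only, as a real-time system would.
#'
#' @param bandpass_hz length-2 numeric, band-pass edges in Hz.
#' @param bandpass_order total band-pass order (pole count; must be a
#'   multiple of 4 so the design splits into second-order sections).
#' @param notch_hz length-2 numeric, band-stop edges in Hz.
#' @param phase_mode `"zero-phase"` or `"causal"`.
#' @param sampling_rate samples per second.
#' @return A list of class `filter_spec` carrying the parameters and the
#'   designed second-order sections (`sos_band`, `sos_notch`).
#' @export
filter_spec <- function(bandpass_hz = c(0.1, 30), bandpass_order = 8,
                        notch_hz = c(48, 52),
                        phase_mode = c("zero-phase", "causal"),
                        sampling_rate = 256) {
  phase_mode <- match.arg(phase_mode)
  nyq <- sampling_rate / 2
  if (!(bandpass_hz[1] > 0 && bandpass_hz[1] < bandpass_hz[2] &&
        bandpass_hz[2] < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist")
  if (bandpass_order %% 4 != 0) stop("bandpass_order must be a multiple of 4")
  np <- bandpass_order / 2  # prototype order: a band transform doubles it
  sos_band  <- butter_sos(np, bandpass_hz / nyq, "pass")
  sos_notch <- butter_sos(np, notch_hz / nyq, "stop")
  structure(list(bandpass_hz = bandpass_hz, bandpass_order = bandpass_order,
                 notch_hz = notch_hz, phase_mode = phase_mode,
                 sampling_rate = sampling_rate,
                 sos_band = sos_band, sos_notch = sos_notch),
            class = "filter_spec")
}

# Butterworth design in second-order sections.  The zero/pole/gain form
# from signal::butter is converted by pairing conjugate pole pairs
# (closest to the unit circle first) with their nearest zero pair.
butter_sos <- function(n, W, type) {
  zpg <- signal::as.Zpg(signal::butter(n, W, type = type))
  zpg2sos(zpg$zero, zpg$pole, zpg$gain)
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

conj_pairs <- function(v, tol = 1e-8) {
  cplx <- v[abs(Im(v)) > tol]
  re <- sort(Re(v[abs(Im(v)) <= tol]))
  pairs <- lapply(cplx[Im(cplx) > 0], function(p) c(p, Conj(p)))
  n2 <- 2L * (length(re) %/% 2L)
  if (n2 >= 2L)
    for (i in seq(1L, n2, by = 2L))
      pairs[[length(pairs) + 1L]] <- complex(real = re[i:(i + 1L)])
  if (length(re) %% 2L == 1L)
    pairs[[length(pairs) + 1L]] <- complex(real = re[length(re)])
  pairs
}

zpg2sos <- function(z, p, g) {
  zp <- conj_pairs(z)
  pp <- conj_pairs(p)
  while (length(zp) < length(pp))
    zp[[length(zp) + 1L]] <- complex(real = numeric(0))
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), 0))]
  used <- rep(FALSE, length(zp))
  sos <- vector("list", length(pp))
  for (i in seq_along(pp)) {
    d <- vapply(seq_along(zp), function(j) {
      if (used[j]) return(Inf)
      if (length(zp[[j]]) == 0L) return(.Machine$double.xmax)
      min(Mod(zp[[j]] - pp[[i]][1]))
    }, 0)
    j <- which.min(d)
    used[j] <- TRUE
    b <- Re(poly_from_roots(zp[[j]]))
    a <- Re(poly_from_roots(pp[[i]]))
    sos[[i]] <- list(b = c(b, rep(0, 3 - length(b))),
                     a = c(a, rep(0, 3 - length(a))))
  }
  gs <- abs(g)^(1 / length(sos))
  for (i in seq_along(sos)) sos[[i]]$b <- sos[[i]]$b * gs
  sos[[1]]$b <- sos[[1]]$b * sign(Re(g))
  sos
}

sos_freq_resp <- function(sos, w) {
  H <- rep(1 + 0i, length(w))
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  for (s in sos)
    H <- H * (s$b[1] + s$b[2] * e1 + s$b[3] * e2) /
             (s$a[1] + s$a[2] * e1 + s$a[3] * e2)
  H
}

# Causal single pass through the cascade, each section initialised at its
# steady state for a constant input equal to the first sample (suppresses
# the step transient a zero initial state would inject).
sos_filter_causal <- function(sos, x) {
  for (s in sos) {
    H0 <- sum(s$b) / sum(s$a)
    x <- as.numeric(signal::filter(s$b, s$a, x,
                                   init = rep(H0 * x[1], 2),
                                   init.x = rep(x[1], 2)))
  }
  x
}

# Zero-phase filtering of the columns of a matrix: multiply the DFT of
# the even periodic extension by |H(w)|^2.  The even extension is
# continuous at both circular boundaries, so no discontinuity leaks
# through the (long-tailed) zero-phase impulse response.
sos_filter_zerophase <- function(sos, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  xx <- rbind(x, x[n:1, , drop = FALSE])
  H2 <- Mod(sos_freq_resp(sos, 2 * pi * (0:(2 * n - 1)) / (2 * n)))^2
  y <- Re(stats::mvfft(stats::mvfft(xx) * H2, inverse = TRUE) / (2 * n))
  y[seq_len(n), , drop = FALSE]
}

#' Band-pass and notch filter a trial
#'
#' Applies the band-pass and then the band-stop of `spec` to every column
#' of `samples`. Columns are channels; any channel count is accepted so
#' the same routine filters EEG matrices and single EOG traces.
#'
#' @param samples numeric matrix (samples x channels) or vector.
#' @param spec a [filter_spec()].
#' @return Filtered matrix of the same shape (a vector input comes back
#'   as a vector).
#' @export
filter_trial <- function(samples, spec = filter_spec()) {
  was_vec <- is.null(dim(samples))
  x <- as.matrix(samples)
  if (!all(is.finite(x))) stop("non-finite samples")
  if (nrow(x) < 3L * spec$bandpass_order)
    stop("input too short for stable filtering")
  if (spec$phase_mode == "zero-phase") {
    y <- sos_filter_zerophase(spec$sos_band, x)
    y <- sos_filter_zerophase(spec$sos_notch, y)
  } else {
    y <- apply(x, 2, function(col)
      sos_filter_causal(spec$sos_notch, sos_filter_causal(spec$sos_band, col)))
  }
  if (was_vec) as.numeric(y) else y
}

#' Extract the training epoch from a 4-s MI window
#'
#' Half-open window `[start, end)` in seconds from cue onset; at 256 Hz
#' the default (0.5, 2.5) yields rows 129..640, a 512 x 21 matrix.
#'
#' @param mi_samples matrix with 1024 rows (4 s at 256 Hz).
#' @param window_s length-2 numeric, seconds from cue onset.
#' @param sampling_rate samples per second.
#' @return The extracted sub-matrix.
#' @export
extract_epoch <- function(mi_samples, window_s = c(0.5, 2.5),
                          sampling_rate = 256) {
  mi_samples <- as.matrix(mi_samples)
  dur <- nrow(mi_samples) / sampling_rate
  if (window_s[1] < 0 || window_s[2] > dur || window_s[1] >= window_s[2])
    stop("epoch window outside the trial: [", window_s[1], ", ",
         window_s[2], ") vs 0..", dur, " s")
  i0 <- floor(window_s[1] * sampling_rate) + 1L
  i1 <- floor(window_s[2] * sampling_rate)
  mi_samples[i0:i1, , drop = FALSE]
}
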