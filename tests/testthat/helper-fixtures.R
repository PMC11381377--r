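# Shared helpers for building small deterministic inputs.

# epoched trial with exact per-channel sample variances
trial_with_variances <- function(vars, n = 512L, seed = 1L) {
  m <- vapply(seq_along(vars), function(j) {
    x <- withr_seed_rnorm(n, seed + j)
    (x - mean(x)) / stats::sd(x) * sqrt(vars[j])
  }, numeric(n))
  structure(list(samples = m, label = 1L, satisfied = TRUE),
            class = "epoched_trial")
}

withr_seed_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n)
}

# random SPD matrix
random_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}

# band power (Hz) of one channel via the periodogram -- an FFT route
# independent of the package's filtering code
bandpower_fft <- function(x, lo, hi, fs = 256) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(X[f >= lo & f <= hi & f <= fs / 2])
}

# literal declarative restatement of the representative-map rule: among
# segments correct on both hemispheres take the earliest maximiser of
# Nl+Nr; if none, among ERS-side-only segments seen before the first
# two-hemisphere segment take the earliest maximiser; else default to 2.
oracle_select_topomap <- function(R, label, montage = standard_montage()) {
  li <- montage_indices(montage, "left")
  ri <- montage_indices(montage, "right")
  Nl <- Nr <- integer(3)
  for (k in 1:3) {
    if (label == 2) {
      Nl[k] <- sum(R[k, li] > 0); Nr[k] <- sum(R[k, ri] < 0)
    } else {
      Nl[k] <- sum(R[k, li] < 0); Nr[k] <- sum(R[k, ri] > 0)
    }
  }
  both <- which(Nl > 0 & Nr > 0)
  ers <- if (label == 2) Nl else Nr
  first_both <- if (length(both)) min(both) else 4L
  single <- which(ers > 0 & seq_len(3) < first_both &
                    !(Nl > 0 & Nr > 0))
  cand_val <- rep(0L, 3)
  cand_val[both] <- (Nl + Nr)[both]
  cand_val[single] <- ers[single]
  if (all(cand_val == 0)) return(2L)
  which.max(cand_val)  # earliest maximiser
}
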