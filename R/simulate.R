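#' Configuration for the synthetic session generator
#'
#' The generator emulates the statistical structure the training paradigm
#' relies on: an ongoing ~10 Hz mu oscillation over the sensorimotor
#' groups whose envelope, from about 0.5 s after cue onset, is reduced
#' multiplicatively on the hemisphere contralateral to the imagined hand
#' (ERD) and raised on the ipsilateral one (ERS); unmodulated mu on the
#' midline; white Gaussian background noise everywhere; occasional
#' high-variance artifact trials; and EOG confirmation traces with or
#' without a large biphasic blink deflection.
#'
#' @param effect_size fractional envelope change in (0, 1): contralateral
#'   mu envelope is scaled by `1 - effect_size`, ipsilateral by
#'   `1 + effect_size` during the MI window.
#' @param mu_freq_hz mu oscillation frequency.
#' @param mu_amp baseline mu amplitude (microvolts).
#' @param noise_sd background EEG noise standard deviation (microvolts).
#' @param noise_type `"white"` (default) or `"pink"` (1/f, stresses the
#'   filters).
#' @param eog_noise_sd EOG channel noise standard deviation (microvolts).
#' @param blink_amp blink deflection peak amplitude (microvolts); must be
#'   far above `eog_noise_sd` for the threshold calibration to make sense.
#' @param cal_blink_gain amplitude factor for the deliberate blinks a
#'   subject uses to mark a distracted calibration trial (blinking *at*
#'   the system, subjects blink hard, so these reliably exceed the
#'   threshold calibrated from ordinary blinks).
#' @param p_artifact probability a calibration/testing trial carries
#'   injected high-variance noise.
#' @param artifact_factor variance of an artifact-affected channel
#'   relative to a clean channel's nominal variance (artifacts hit a
#'   random 3--6 of the 21 channels).
#' @param p_blink probability a calibration trial's confirmation window
#'   contains a deliberate blink.
#' @param trials_per_run,n_cal_runs,n_test_runs session layout: 20-trial
#'   calibration runs (10 per class), 10-trial testing runs (5 per class).
#' @param seed integer seed; every trial derives its own reproducible
#'   stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(effect_size = 0.4, mu_freq_hz = 10, mu_amp = 6,
                       noise_sd = 4, noise_type = c("white", "pink"),
                       eog_noise_sd = 10, blink_amp = 300,
                       cal_blink_gain = 1.5,
                       p_artifact = 0.05, artifact_factor = 20,
                       p_blink = 0.1,
                       trials_per_run = 20, n_cal_runs = 6, n_test_runs = 4,
                       seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(effect_size >= 0, effect_size < 1,
            mu_amp > 0, noise_sd > 0, blink_amp > 0,
            p_artifact >= 0, p_artifact <= 1,
            p_blink >= 0, p_blink <= 1,
            trials_per_run %% 2 == 0)
  structure(list(effect_size = effect_size, mu_freq_hz = mu_freq_hz,
                 mu_amp = mu_amp, noise_sd = noise_sd,
                 noise_type = noise_type,
                 eog_noise_sd = eog_noise_sd, blink_amp = blink_amp,
                 cal_blink_gain = cal_blink_gain,
                 p_artifact = p_artifact, artifact_factor = artifact_factor,
                 p_blink = p_blink, trials_per_run = trials_per_run,
                 n_cal_runs = n_cal_runs, n_test_runs = n_test_runs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-trial substream seed (< 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

sim_noise <- function(n, sd, type = "white") {
  if (type == "white") return(stats::rnorm(n, sd = sd))
  # pink: shape white noise to 1/sqrt(f) magnitude, rescale to sd
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y * sd / stats::sd(y)
}

#' Simulate one raw MI trial
#'
#' @param label class label: 1 right-hand (ERD over the left group), 2
#'   left-hand (ERD over the right group).
#' @param config a [sim_config()].
#' @param seed integer seed for this trial's stream.
#' @param artifact logical; inject high-variance noise.
#' @param blink logical; put a deliberate blink in the confirmation EOG.
#' @param montage an [standard_montage()].
#' @return A [raw_trial()].
#' @export
simulate_mi_trial <- function(label, config = sim_config(),
                              seed = config$seed,
                              artifact = FALSE, blink = FALSE,
                              montage = standard_montage()) {
  if (!label %in% c(1, 2)) stop("invalid class label")
  with_seed(seed, {
    fs <- 256
    n <- 1024L
    tt <- (0:(n - 1)) / fs
    # ERD/ERS develops ~0.5 s after cue onset (reaction latency), with a
    # 0.2 s smooth ramp
    ramp <- pmin(pmax((tt - 0.5) / 0.2, 0), 1)
    e <- config$effect_size
    li <- montage_indices(montage, "left")
    ri <- montage_indices(montage, "right")
    gain <- matrix(1, n, 21)
    if (label == 1) {            # right-hand: ERD left, ERS right
      gain[, li] <- 1 - e * ramp
      gain[, ri] <- 1 + e * ramp
    } else {                     # left-hand: ERS left, ERD right
      gain[, li] <- 1 + e * ramp
      gain[, ri] <- 1 - e * ramp
    }
    phases <- stats::runif(21, 0, 2 * pi)
    mu <- config$mu_amp * gain *
      sin(outer(2 * pi * config$mu_freq_hz * tt, phases, `+`))
    noise <- matrix(sim_noise(n * 21, config$noise_sd, config$noise_type),
                    n, 21)
    x <- mu + noise
    if (artifact) {
      # artifacts (electrode pops, muscle bursts) are channel-localized:
      # a few channels get artifact_factor times the nominal variance
      nominal_var <- config$noise_sd^2 + config$mu_amp^2 / 2
      extra_sd <- sqrt((config$artifact_factor - 1) * nominal_var)
      ch <- sample(21L, sample(3:6, 1))
      x[, ch] <- x[, ch] +
        matrix(stats::rnorm(n * length(ch), sd = extra_sd), n, length(ch))
    }
    colnames(x) <- montage$all_labels
    eog <- simulate_eog_trace(blink, config, seed = derive_seed(seed, 999),
                              deliberate = TRUE)
    raw_trial(x, eog, label)
  })
}

#' Simulate a 2-s EOG trace
#'
#' A blink is a biphasic deflection (positive lobe followed by a smaller
#' negative rebound) riding on Gaussian noise; without a blink the trace
#' is noise only.
#'
#' @param blink logical.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param deliberate logical; deliberate calibration blinks are scaled by
#'   `config$cal_blink_gain`, ordinary EOG-run blinks by a uniform
#'   1.0--1.3 amplitude factor (natural blink-to-blink variability).
#' @return Numeric vector of 512 samples (microvolts).
#' @export
simulate_eog_trace <- function(blink, config = sim_config(),
                               seed = config$seed, deliberate = FALSE) {
  with_seed(seed, {
    n <- 512L
    tt <- (0:(n - 1)) / 256
    x <- stats::rnorm(n, sd = config$eog_noise_sd)
    if (blink) {
      t0 <- stats::runif(1, 0.6, 1.2)
      amp <- if (deliberate) config$blink_amp * config$cal_blink_gain *
               stats::runif(1, 0.9, 1.1)
             else config$blink_amp * stats::runif(1, 1, 1.3)
      shape <- exp(-((tt - t0) / 0.08)^2) -
        0.4 * exp(-((tt - t0 - 0.18) / 0.1)^2)
      x <- x + amp * shape / max(abs(shape))
    }
    x
  })
}

#' Simulate a full session
#'
#' One EOG run (20 trials, half blinking), `n_cal_runs` calibration runs
#' with balanced classes, and `n_test_runs` testing runs of 5 trials per
#' class. Blink and artifact injections are Bernoulli per trial with the
#' configured probabilities; the ground truth of every injection is
#' recorded.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_session` with elements `eog_run` (list of
#'   `trace`/`blink` records), `calibration_runs`, `testing_runs` (lists
#'   of lists of [raw_trial()]), `ground_truth` (data.frame), `config`.
#' @export
simulate_session <- function(config = sim_config()) {
  montage <- standard_montage()
  idx <- 0L
  nxt <- function() {
    idx <<- idx + 1L
    derive_seed(config$seed, idx)
  }

  eog_flags <- with_seed(derive_seed(config$seed, 0L),
                         sample(rep(c(TRUE, FALSE), 10)))
  eog_run <- lapply(seq_along(eog_flags), function(i)
    list(trace = simulate_eog_trace(eog_flags[i], config, seed = nxt()),
         blink = eog_flags[i]))

  gt <- list()
  make_run <- function(kind, run, n_per_class) {
    labels <- with_seed(nxt(), sample(rep(c(1L, 2L), n_per_class)))
    lapply(seq_along(labels), function(i) {
      s <- nxt()
      flags <- with_seed(derive_seed(s, 1L),
                         stats::runif(2))
      blink <- kind == "calibration" && flags[1] < config$p_blink
      artifact <- flags[2] < config$p_artifact
      tr <- simulate_mi_trial(labels[i], config, seed = s,
                              artifact = artifact, blink = blink,
                              montage = montage)
      tr$trial_id <- sprintf("%s%02d-t%02d", substr(kind, 1, 3), run, i)
      tr$run_id <- sprintf("%s%02d", substr(kind, 1, 3), run)
      gt[[length(gt) + 1L]] <<- data.frame(
        kind = kind, run = run, trial = i, label = labels[i],
        blink = blink, artifact = artifact, seed = s,
        trial_id = tr$trial_id, stringsAsFactors = FALSE)
      tr
    })
  }

  calibration_runs <- lapply(seq_len(config$n_cal_runs), function(r)
    make_run("calibration", r, config$trials_per_run / 2))
  testing_runs <- lapply(seq_len(config$n_test_runs), function(r)
    make_run("testing", r, 5L))

  structure(list(eog_run = eog_run,
                 calibration_runs = calibration_runs,
                 testing_runs = testing_runs,
                 ground_truth = do.call(rbind, gt),
                 config = config),
            class = "sim_session")
}
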