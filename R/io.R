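# On-disk session format: one delimited numeric matrix per trial plus a
# JSON manifest.  Plain text, diff-able, and lossless: values are written
# with 17 significant digits, which round-trips IEEE doubles exactly.

write_matrix_csv <- function(X, path) {
  ch <- apply(as.matrix(X), 2, formatC, format = "g", digits = 17)
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1,
                                     dimnames = list(NULL, colnames(X)))
  data.table::fwrite(data.table::as.data.table(ch), path, quote = FALSE)
}

#' Write a set of trials to disk
#'
#' Each trial's MI matrix (and confirmation EOG, if present) goes into a
#' CSV under `dir`; a JSON manifest records file names, labels, flags,
#' the montage ordering, sampling rate, and an arbitrary config echo so
#' the run can be re-processed bit-identically.
#'
#' @param trials list of [raw_trial()] or [epoched_trial()] objects.
#' @param dir output directory (created if missing).
#' @param kind run kind recorded in the manifest (`"calibration"`,
#'   `"testing"`, `"eog"`, ...).
#' @param config_echo list serialized verbatim into the manifest.
#' @return Path of the manifest file, invisibly.
#' @export
write_trials <- function(trials, dir, kind = "calibration",
                         config_echo = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  montage <- standard_montage()
  entries <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    stem <- sprintf("trial_%03d", i)
    X <- if (inherits(tr, "raw_trial")) tr$mi else tr$samples
    write_matrix_csv(X, file.path(dir, paste0(stem, "_eeg.csv")))
    ent <- list(eeg = paste0(stem, "_eeg.csv"),
                label = tr$label,
                n_samples = nrow(X),
                trial_id = tr$trial_id, run_id = tr$run_id)
    if (inherits(tr, "raw_trial")) {
      write_matrix_csv(matrix(tr$eog, ncol = 1,
                              dimnames = list(NULL, "eog")),
                       file.path(dir, paste0(stem, "_eog.csv")))
      ent$eog <- paste0(stem, "_eog.csv")
    }
    if (inherits(tr, "epoched_trial")) ent$satisfied <- tr$satisfied
    ent
  })
  manifest <- list(format = "mitrainr-run/1",
                   kind = kind,
                   sampling_rate = 256,
                   montage = montage$all_labels,
                   eog_label = montage$eog_label,
                   config = config_echo,
                   trials = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read trials back from a manifest
#'
#' Inverse of [write_trials()]; matrices, labels and flags round-trip
#' losslessly. Channel columns are mapped onto the montage by name, so a
#' permuted on-disk column order is re-ordered canonically.
#'
#' @param manifest path to a `manifest.json`.
#' @return List of trials (`raw_trial` when an EOG trace is present,
#'   `epoched_trial` for 512-row matrices, otherwise a bare list).
#' @export
read_trials <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  dir <- dirname(manifest)
  montage <- standard_montage()
  lapply(m$trials, function(ent) {
    f <- file.path(dir, ent$eeg)
    if (!file.exists(f)) stop("missing trial file: ", f)
    X <- as.matrix(data.table::fread(f))
    if (!is.null(colnames(X)) && all(montage$all_labels %in% colnames(X)))
      X <- X[, montage$all_labels, drop = FALSE]
    else if (ncol(X) == 21L)
      colnames(X) <- montage$all_labels
    if (!is.null(ent$eog)) {
      fe <- file.path(dir, ent$eog)
      if (!file.exists(fe)) stop("missing trial file: ", fe)
      eog <- data.table::fread(fe)$eog
      raw_trial(X, eog, ent$label,
                trial_id = ent$trial_id %||% NA_character_,
                run_id = ent$run_id %||% NA_character_)
    } else if (nrow(X) == 512L) {
      epoched_trial(X, ent$label, ent$satisfied %||% TRUE,
                    trial_id = ent$trial_id %||% NA_character_,
                    run_id = ent$run_id %||% NA_character_)
    } else {
      list(samples = X, label = ent$label)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole training-and-testing pipeline on a session
#'
#' Orchestrates the full protocol on a (simulated or loaded) session:
#' EOG threshold calibration, per-trial feedback verdicts (trial-feedback
#' sessions), blink gating, filtering and epoching, variance-based
#' artifact rejection, decoder fits on the first three and on all six
#' calibration runs, decoding of the four testing runs (first two with
#' the 3-run decoder, last two with the 6-run one), and per-run feature
#' evaluations.
#'
#' @param session a [simulate_session()] result (or an equivalent list).
#' @param spec a [filter_spec()].
#' @param feedback logical; compute per-trial feedback outcomes.
#' @param cv logical; include the 10 x 10-fold cross-validated accuracy
#'   of the 6-run training set.
#' @param cv_seed seed for the cross-validation shuffles.
#' @return A list of class `session_report` with elements `calibration`
#'   (per-run log: flagged, removed, kept, verdicts), `threshold`,
#'   `bundle3`, `bundle6`, `testing` (per-run decode accuracy and
#'   commands), `run_evals`, and optionally `cv`.
#' @export
run_pipeline <- function(session, spec = filter_spec(), feedback = TRUE,
                         cv = FALSE, cv_seed = 1L) {
  calib <- calibrate_eog_run(session$eog_run)

  prep_run <- function(run, run_idx) {
    gated <- gate_run(run, calib)
    epoched <- lapply(gated$trials, function(tr)
      epoched_trial(extract_epoch(filter_trial(tr$mi, spec), c(0.5, 2.5)),
                    tr$label, trial_id = tr$trial_id, run_id = tr$run_id))
    screened <- reject_high_variance(epoched)
    verdicts <- if (feedback)
      vapply(run, function(tr) trial_feedback(tr, spec)$verdict, "")
    else NULL
    list(trials = screened$trials,
         flagged = gated$flagged,
         removed_ids = vapply(epoched[screened$removed], `[[`, "",
                              "trial_id"),
         n_remove_dis = length(epoched),
         n_final = screened$n_final,
         verdicts = verdicts)
  }

  cal <- lapply(seq_along(session$calibration_runs), function(r)
    prep_run(session$calibration_runs[[r]], r))
  cal_trials <- lapply(cal, `[[`, "trials")

  bundle3 <- fit_decoder(cal_trials[1:3])
  bundle6 <- fit_decoder(cal_trials)

  testing <- lapply(seq_along(session$testing_runs), function(r) {
    bundle <- if (r <= 2) bundle3 else bundle6
    run <- session$testing_runs[[r]]
    dec <- lapply(run, decode_trial, bundle = bundle, spec = spec)
    pred <- vapply(dec, `[[`, 0L, "class")
    truth <- vapply(run, `[[`, 0L, "label")
    list(run = r, bundle = if (r <= 2) "3-run" else "6-run",
         commands = vapply(dec, `[[`, "", "command"),
         predicted = pred, truth = truth,
         accuracy = mean(pred == truth))
  })

  run_evals <- lapply(seq_along(cal_trials), function(r) {
    run <- cal_trials[[r]]
    covs <- lapply(run, trial_covariance)
    A <- spd_invsqrt(riemannian_mean(covs))
    feats <- t(vapply(run, function(tr)
      csp_features(tr$samples %*% A, bundle6$csp), numeric(6)))
    run_evaluation(feats, vapply(run, `[[`, 0L, "label"))
  })

  out <- list(calibration = cal,
              threshold = calib$threshold,
              bundle3 = bundle3, bundle6 = bundle6,
              testing = testing,
              run_evals = run_evals)
  if (cv) out$cv <- cv_accuracy(cal_trials, seed = cv_seed)
  structure(out, class = "session_report")
}

#' Serialize a decoder bundle to JSON
#'
#' Matrices are stored row-major with their dimensions, so the bundle is
#' portable and diff-able. [read_bundle()] restores an object usable by
#' [decode_trial()].
#'
#' @param bundle a [fit_decoder()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  mat <- function(M) list(dim = dim(M), data = as.numeric(t(M)))
  obj <- list(format = "mitrainr-bundle/1",
              run_means = lapply(bundle$run_means, mat),
              global_mean = mat(bundle$global_mean),
              projection = mat(bundle$csp$projection),
              filters = mat(bundle$csp$filters),
              eigenvalues = bundle$csp$eigenvalues,
              m_per_side = bundle$csp$m_per_side,
              lda_weight = bundle$lda$weight,
              lda_bias = bundle$lda$bias,
              labels = bundle$labels,
              features = mat(bundle$features))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @param path path to a bundle JSON file.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  unmat <- function(m) matrix(m$data, nrow = m$dim[1], byrow = TRUE)
  csp <- structure(list(projection = unmat(obj$projection),
                        filters = unmat(obj$filters),
                        eigenvalues = obj$eigenvalues,
                        m_per_side = obj$m_per_side),
                   class = "csp_model")
  structure(list(run_means = lapply(obj$run_means, unmat),
                 global_mean = unmat(obj$global_mean),
                 csp = csp,
                 lda = structure(list(weight = obj$lda_weight,
                                      bias = obj$lda_bias),
                                 class = "lda_model"),
                 features = unmat(obj$features),
                 labels = obj$labels),
            class = "decoder_bundle")
}
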