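#' Fit CSP spatial filters
#'
#' Common spatial patterns for the two-class problem: with class-average
#' covariances `P1`, `P2` (arithmetic means over each class's aligned
#' trial covariances), the projection matrix solves the generalized
#' eigenproblem `P1 w = lambda P2 w`, rows sorted by descending
#' eigenvalue; the spatial filters are the first and last `m_per_side`
#' rows. Each filter is scaled so `w' (P1 + P2) w = 1` (the Rayleigh
#' quotient leaves scale free; this makes log-variance features
#' comparable across refits) and its largest-magnitude coefficient is
#' made positive (eigenvector sign is arbitrary but exported filter
#' topographies must be reproducible).
#'
#' @param covs list of per-trial (aligned) covariance matrices.
#' @param labels integer vector of class labels (1/2), one per trial.
#' @param m_per_side filters kept per end (default 3, so 6 filters).
#' @return A list of class `csp_model`: `projection` (C x C, rows =
#'   filters, descending eigenvalue), `filters` (2*m x C), `eigenvalues`,
#'   `m_per_side`, `class_covs`.
#' @export
csp_fit <- function(covs, labels, m_per_side = 3) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(1L, 2L))) stop("labels must be 1 or 2")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (length(covs) != length(labels)) stop("covs/labels length mismatch")
  C <- ncol(covs[[1]])
  if (C < 2 * m_per_side) stop("not enough channels for m_per_side")
  P1 <- Reduce(`+`, covs[labels == 1L]) / sum(labels == 1L)
  P2 <- Reduce(`+`, covs[labels == 2L]) / sum(labels == 2L)

  # whiten by the composite covariance, then an ordinary symmetric
  # eigenproblem; unit-norm eigenvectors give w'(P1+P2)w = 1 for free
  Wh <- spd_invsqrt(P1 + P2)
  S <- Wh %*% P1 %*% Wh
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)  # descending by default
  Wp <- t(Wh %*% e$vectors)                     # rows are filters
  # generalized eigenvalues of P1 w = lambda P2 w: mu/(1-mu)
  lambda <- e$values / (1 - e$values)
  flip <- apply(Wp, 1, function(w) sign(w[which.max(abs(w))]))
  Wp <- Wp * flip
  sel <- c(seq_len(m_per_side), (C - m_per_side + 1):C)
  structure(list(projection = Wp, filters = Wp[sel, , drop = FALSE],
                 eigenvalues = lambda, m_per_side = m_per_side,
                 class_covs = list(P1, P2)),
            class = "csp_model")
}

#' Log-variance CSP features of one trial
#'
#' @param samples aligned epoch samples (rows = time).
#' @param csp a [csp_fit()] model (or a filters matrix, rows = filters).
#' @return Numeric feature vector, one log-variance per filter.
#' @export
csp_features <- function(samples, csp) {
  W <- if (inherits(csp, "csp_model")) csp$filters else as.matrix(csp)
  proj <- as.matrix(samples) %*% t(W)
  v <- apply(proj, 2, stats::var)
  if (any(v <= 0)) stop("zero-variance projection")
  log(v)
}

#' Fit the LDA hyperplane
#'
#' Two-class linear discriminant with the unweighted average of the two
#' class covariance matrices: `w = ((cov(F1) + cov(F2)) / 2)^{-1}
#' (mean(F1) - mean(F2))` and `b = -(mean(F1) + mean(F2)) . w / 2`.
#' Predicted class is 1 when `w . F + b > 0`, 2 when negative; an exact 0
#' maps to class 1 (the sign convention leaves 0 undefined, so a tie rule
#' is fixed here).
#'
#' @param features N x d numeric matrix.
#' @param labels integer class labels (1/2), one per row.
#' @param ridge relative ridge added to the pooled covariance if it is
#'   numerically singular.
#' @return A list of class `lda_model` with `weight`, `bias`.
#' @export
lda_fit <- function(features, labels, ridge = 1e-8) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (any(table(factor(labels, levels = c(1L, 2L))) < 2))
    stop("need at least 2 samples per class")
  F1 <- features[labels == 1L, , drop = FALSE]
  F2 <- features[labels == 2L, , drop = FALSE]
  S <- (stats::cov(F1) + stats::cov(F2)) / 2
  S <- S + diag(ridge * mean(diag(S)), ncol(S))
  w <- solve(S, colMeans(F1) - colMeans(F2))
  b <- -0.5 * sum((colMeans(F1) + colMeans(F2)) * w)
  structure(list(weight = as.numeric(w), bias = b), class = "lda_model")
}

#' Decision values and classes of an LDA model
#'
#' @param model an [lda_fit()] result.
#' @param features matrix (or vector) of feature rows.
#' @return List with `decision` (numeric) and `class` (1 where decision
#'   >= 0, else 2).
#' @export
lda_predict <- function(model, features) {
  f <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  d <- as.numeric(f %*% model$weight + model$bias)
  list(decision = d, class = ifelse(d >= 0, 1L, 2L))
}

#' Train the full decoder from calibration runs
#'
#' The training pipeline after gating and artifact rejection: per
#' calibration run, trial covariances are computed and the run is
#' re-centred by its own Riemannian mean (Riemannian alignment, label
#' free); the aligned trials of all runs are pooled for CSP and the LDA
#' is fit on their log-variance features. For the testing phase the
#' decoder also stores the single Karcher mean of *all* training trials'
#' raw covariances, which is what aligns incoming testing trials.
#'
#' @param runs list of runs, each a list of [epoched_trial()] objects.
#' @param m_per_side CSP filters per end.
#' @param ridge covariance ridge.
#' @return A list of class `decoder_bundle`: `run_means`, `global_mean`,
#'   `csp`, `lda`, `features` (training features), `labels`.
#' @export
fit_decoder <- function(runs, m_per_side = 3, ridge = 1e-8) {
  runs <- Filter(length, runs)
  if (length(runs) == 0) stop("no training trials")
  aligned <- list()
  labels <- integer(0)
  run_means <- vector("list", length(runs))
  all_raw_covs <- list()
  for (r in seq_along(runs)) {
    covs <- lapply(runs[[r]], trial_covariance, ridge = ridge)
    all_raw_covs <- c(all_raw_covs, covs)
    MR <- riemannian_mean(covs)
    run_means[[r]] <- MR
    A <- spd_invsqrt(MR)
    aligned <- c(aligned, lapply(runs[[r]], function(tr) tr$samples %*% A))
    labels <- c(labels, vapply(runs[[r]], `[[`, 0L, "label"))
  }
  acovs <- lapply(aligned, trial_covariance, ridge = ridge)
  csp <- csp_fit(acovs, labels, m_per_side)
  feats <- t(vapply(aligned, csp_features, numeric(2 * m_per_side),
                    csp = csp))
  lda <- lda_fit(feats, labels, ridge)
  structure(list(run_means = run_means,
                 global_mean = riemannian_mean(all_raw_covs),
                 csp = csp, lda = lda,
                 features = feats, labels = labels),
            class = "decoder_bundle")
}

#' Decode one testing trial
#'
#' Real-time processing of a 4-s testing trial: band-pass and notch
#' filter, extract the 0.5--2.5 s epoch, align with the stored
#' all-training-trials Riemannian mean, project onto the CSP filters and
#' apply the LDA sign. Class 1 drives the snake right, class 2 left.
#'
#' @param trial a [raw_trial()] (or bare 1024 x 21 matrix).
#' @param bundle a [fit_decoder()] result.
#' @param spec a [filter_spec()]; use `phase_mode = "causal"` for a
#'   faithful real-time simulation.
#' @return List with `command` (`"right"`/`"left"`), `class`, `decision`,
#'   `features`.
#' @export
decode_trial <- function(trial, bundle, spec = filter_spec()) {
  if (!inherits(bundle, "decoder_bundle")) stop("untrained decoder bundle")
  X <- if (inherits(trial, "raw_trial")) trial$mi else as.matrix(trial)
  ep <- extract_epoch(filter_trial(X, spec), c(0.5, 2.5),
                      spec$sampling_rate)
  Xa <- align_trial(ep, bundle$global_mean)
  f <- csp_features(Xa, bundle$csp)
  pred <- lda_predict(bundle$lda, f)
  list(command = if (pred$class == 1L) "right" else "left",
       class = pred$class, decision = pred$decision, features = f)
}
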