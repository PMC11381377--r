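#' Within- and between-class scatter matrices
#'
#' `Sw = sum_c Fc (I - 1/Nc) Fc'` (features as columns, centring matrix
#' per class) and `Sb = sum_c Nc (mean_c - mean)(mean_c - mean)'` with
#' the grand mean over all features.
#'
#' @param features N x d matrix of feature rows.
#' @param labels integer class labels (1/2).
#' @return List with `Sw`, `Sb` (d x d each).
#' @export
scatter_matrices <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!all(c(1L, 2L) %in% labels)) stop("both classes must be non-empty")
  d <- ncol(features)
  gm <- colMeans(features)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (c in c(1L, 2L)) {
    Fc <- t(features[labels == c, , drop = FALSE])  # d x Nc
    Nc <- ncol(Fc)
    Cn <- diag(Nc) - matrix(1 / Nc, Nc, Nc)
    Sw <- Sw + Fc %*% Cn %*% t(Fc)
    dm <- rowMeans(Fc) - gm
    Sb <- Sb + Nc * tcrossprod(dm)
  }
  list(Sw = Sw, Sb = Sb)
}

#' Class distance of a feature distribution
#'
#' Ratio of the norms of the between- and within-class scatter matrices.
#' The norm is the entrywise sum of absolute values by default; the
#' induced 1-norm (maximum absolute column sum) and the trace are
#' available since the normalization is a convention, not a result.
#'
#' @param Sw,Sb scatter matrices from [scatter_matrices()].
#' @param norm_mode `"entrywise"`, `"induced"`, or `"trace"`.
#' @return The class distance (scalar, >= 0).
#' @export
class_distance <- function(Sw, Sb, norm_mode = c("entrywise", "induced",
                                                 "trace")) {
  norm_mode <- match.arg(norm_mode)
  nf <- switch(norm_mode,
               entrywise = function(M) sum(abs(M)),
               induced = function(M) max(colSums(abs(M))),
               trace = function(M) sum(diag(M)))
  dw <- nf(Sw)
  if (dw == 0) stop("within-class scatter is zero (degenerate input)")
  nf(Sb) / dw
}

#' Evaluate one calibration run's feature distribution
#'
#' Scatter matrices, class distance, and the 2-D projection (first and
#' last CSP feature) shown to the subject after a trial-feedback
#' calibration run.
#'
#' @param features N x d CSP feature matrix of the run's trials.
#' @param labels class labels.
#' @param norm_mode passed to [class_distance()].
#' @return A list of class `run_eval`: `Sw`, `Sb`, `cd`, `projection`
#'   (data.frame `f_first`, `f_last`, `label`).
#' @export
run_evaluation <- function(features, labels,
                           norm_mode = "entrywise") {
  features <- as.matrix(features)
  sc <- scatter_matrices(features, labels)
  structure(list(Sw = sc$Sw, Sb = sc$Sb,
                 cd = class_distance(sc$Sw, sc$Sb, norm_mode),
                 projection = data.frame(
                   f_first = features[, 1],
                   f_last = features[, ncol(features)],
                   label = as.integer(labels))),
            class = "run_eval")
}

#' Repeated stratified k-fold cross-validated accuracy
#'
#' Offline accuracy of the CSP+LDA decoder, 10 x 10-fold by default.
#' Riemannian alignment is applied per run beforehand (it uses no labels,
#' so no information leaks); CSP and LDA are refit inside every fold on
#' the training portion only. Folds are stratified by class and reshuffled
#' each repetition.
#'
#' @param runs list of runs, each a list of [epoched_trial()] objects.
#' @param reps,folds repetitions and folds.
#' @param seed integer seed controlling the fold shuffles.
#' @param m_per_side,ridge decoder hyperparameters.
#' @return A list of class `cv_report`: `accuracy` (mean over all folds),
#'   `sd`, `fold_accuracy` (reps x folds matrix), `n_trials`.
#' @export
cv_accuracy <- function(runs, reps = 10, folds = 10, seed = 1L,
                        m_per_side = 3, ridge = 1e-8) {
  runs <- Filter(length, runs)
  aligned <- list()
  labels <- integer(0)
  for (run in runs) {
    covs <- lapply(run, trial_covariance, ridge = ridge)
    A <- spd_invsqrt(riemannian_mean(covs))
    aligned <- c(aligned, lapply(run, function(tr) tr$samples %*% A))
    labels <- c(labels, vapply(run, `[[`, 0L, "label"))
  }
  n <- length(aligned)
  if (min(table(factor(labels, levels = 1:2))) < folds)
    stop("need at least `folds` trials per class")
  acovs <- lapply(aligned, trial_covariance, ridge = ridge)

  acc <- matrix(NA_real_, reps, folds)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      fold_of <- integer(n)
      for (c in 1:2) {
        idx <- sample(which(labels == c))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      for (k in seq_len(folds)) {
        tr_i <- which(fold_of != k)
        te_i <- which(fold_of == k)
        csp <- csp_fit(acovs[tr_i], labels[tr_i], m_per_side)
        ftr <- t(vapply(aligned[tr_i], csp_features,
                        numeric(2 * m_per_side), csp = csp))
        fte <- t(vapply(aligned[te_i], csp_features,
                        numeric(2 * m_per_side), csp = csp))
        model <- lda_fit(ftr, labels[tr_i], ridge)
        acc[r, k] <- mean(lda_predict(model, fte)$class == labels[te_i])
      }
    }
  })
  structure(list(accuracy = mean(acc), sd = stats::sd(as.numeric(acc)),
                 fold_accuracy = acc, n_trials = n),
            class = "cv_report")
}

#' Paired two-tailed t-test
#'
#' @param x,y paired numeric vectors.
#' @return List with `t`, `df` (N - 1), `p` (two-tailed).
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of length >= 2")
  if (stats::sd(x - y) == 0)
    stop("differences have zero variance (degenerate input)")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
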