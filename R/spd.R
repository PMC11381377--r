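# Symmetric-eigendecomposition matrix functions on SPD matrices.

sym_fun <- function(M, f) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_sqrt    <- function(M) sym_fun(M, sqrt)
spd_invsqrt <- function(M) sym_fun(M, function(v) 1 / sqrt(v))
spd_log     <- function(M) sym_fun(M, log)
spd_exp     <- function(M) sym_fun(M, exp)

check_spd <- function(M, tol = 1e-8) {
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop("matrix is not symmetric")
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("matrix is not positive definite")
  invisible(M)
}

#' Regularized covariance matrix of a trial
#'
#' Sample covariance of the (column-centred) epoch, `t(X) X / (N - 1)`,
#' plus a small ridge proportional to the mean diagonal so the result is
#' positive definite even with linearly dependent channels.
#'
#' @param trial an [epoched_trial()] or a samples matrix.
#' @param ridge relative ridge (default 1e-8 of the mean diagonal).
#' @return A 21 x 21 symmetric positive-definite matrix.
#' @export
trial_covariance <- function(trial, ridge = 1e-8) {
  X <- if (inherits(trial, "epoched_trial")) trial$samples else as.matrix(trial)
  if (!all(is.finite(X))) stop("non-finite samples")
  Xc <- sweep(X, 2, colMeans(X))
  P <- crossprod(Xc) / (nrow(X) - 1)
  P + diag(ridge * mean(diag(P)), ncol(P))
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' The mean under the affine-invariant metric, computed by the standard
#' fixed-point iteration
#' `M <- M^{1/2} exp(mean_i log(M^{-1/2} P_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean, stopping when the Frobenius norm
#' of the tangent-space mean drops below `tol`.
#'
#' @param mats list of SPD matrices.
#' @param tol convergence tolerance on the tangent-mean norm.
#' @param max_iter iteration cap; on hitting it the last iterate is
#'   returned with a warning and `converged = FALSE` attribute.
#' @return The SPD mean matrix, with attribute `converged`.
#' @export
riemannian_mean <- function(mats, tol = 1e-9, max_iter = 50) {
  if (length(mats) == 0) stop("no matrices supplied")
  for (P in mats) check_spd(P)
  if (length(mats) == 1) {
    M <- mats[[1]]
    attr(M, "converged") <- TRUE
    return(M)
  }
  M <- Reduce(`+`, mats) / length(mats)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mih <- spd_invsqrt(M)
    Mh <- spd_sqrt(M)
    Tm <- Reduce(`+`, lapply(mats, function(P)
      spd_log(Mih %*% P %*% Mih))) / length(mats)
    if (sqrt(sum(Tm^2)) < tol) {
      converged <- TRUE
      break
    }
    M <- Mh %*% spd_exp(Tm) %*% Mh
    M <- (M + t(M)) / 2
  }
  if (!converged)
    warning("Riemannian mean did not reach tol within max_iter iterations")
  attr(M, "converged") <- converged
  M
}

#' Align a trial by a Riemannian mean
#'
#' Right-multiplies the samples by the symmetric inverse square root of
#' the mean covariance, re-centring the run so the Karcher mean of the
#' aligned covariances is (approximately) the identity.
#'
#' @param samples samples matrix (rows = time).
#' @param mean_cov SPD mean covariance with matching dimension.
#' @return The aligned samples matrix.
#' @export
align_trial <- function(samples, mean_cov) {
  samples <- as.matrix(samples)
  if (ncol(samples) != ncol(mean_cov))
    stop("channel count does not match the mean covariance")
  check_spd(mean_cov)
  samples %*% spd_invsqrt(mean_cov)
}
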