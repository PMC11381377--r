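test_that("trial covariance is a ridged sample covariance", {
  set.seed(14)
  X <- matrix(rnorm(512 * 21), 512, 21)
  P <- trial_covariance(X)
  expect_equal(P, t(P))
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  # bilinearity in scale
  expect_equal(trial_covariance(3 * X), 9 * trial_covariance(X),
               tolerance = 1e-10)
  # long white noise approaches sigma^2 I
  Y <- matrix(rnorm(1e5 * 4, sd = 2), ncol = 4)
  expect_equal(trial_covariance(Y), diag(4, 4), tolerance = 0.15)
  # a duplicated channel is rank-deficient without the ridge, PD with it
  Z <- cbind(X[, 1:3], X[, 3])
  expect_gt(min(eigen(trial_covariance(Z), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(trial_covariance(matrix(Inf, 512, 2)), "non-finite")
})

test_that("Karcher mean: fixed points and the commuting closed form", {
  P <- random_spd(4, seed = 3)
  expect_equal(riemannian_mean(list(P)), P, ignore_attr = TRUE)
  I3 <- diag(3)
  expect_equal(riemannian_mean(list(I3, I3, I3)), I3,
               ignore_attr = TRUE, tolerance = 1e-9)
  M <- riemannian_mean(list(diag(c(1, 4)), diag(c(4, 1))))
  expect_equal(M, diag(c(2, 2)), ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(riemannian_mean(list(matrix(c(1, 2, 3, 4), 2))),
               "symmetric")
})

test_that("Karcher mean is congruence-equivariant", {
  set.seed(23)
  for (i in 1:5) {
    mats <- lapply(1:5, function(j) random_spd(3))
    A <- matrix(rnorm(9), 3)
    lhs <- riemannian_mean(lapply(mats, function(P) t(A) %*% P %*% A))
    rhs <- t(A) %*% riemannian_mean(mats) %*% A
    expect_equal(lhs, rhs, ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("alignment whitens a run towards identity mean", {
  X <- matrix(rnorm(512 * 5), 512, 5)
  expect_equal(align_trial(X, diag(5)), X)
  # shared-covariance run: aligned covariances near identity
  set.seed(77)
  A <- matrix(rnorm(25), 5)
  trials <- lapply(1:12, function(i) matrix(rnorm(2048 * 5), 2048, 5) %*% A)
  # ridge 0: the congruence identity cov(XB) = B' cov(X) B is then exact
  covs <- lapply(trials, trial_covariance, ridge = 0)
  M <- riemannian_mean(covs)
  acovs <- lapply(trials, function(X)
    trial_covariance(align_trial(X, M), ridge = 0))
  expect_equal(riemannian_mean(acovs), diag(5),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(align_trial(X, diag(4)), "channel count")
})

test_that("CSP solves the 2x2 case and degenerates gracefully", {
  P1 <- diag(c(4, 1))
  P2 <- diag(c(1, 4))
  covs <- list(P1, P1, P2, P2)
  csp <- csp_fit(covs, c(1, 1, 2, 2), m_per_side = 1)
  expect_equal(csp$eigenvalues, c(4, 0.25), tolerance = 1e-8)
  w1 <- csp$filters[1, ]
  w2 <- csp$filters[2, ]
  expect_gt(abs(w1[1]), 1e-3); expect_lt(abs(w1[2]), 1e-10)
  expect_gt(abs(w2[2]), 1e-3); expect_lt(abs(w2[1]), 1e-10)
  # normalization w'(P1+P2)w = 1 and positive leading coefficient
  expect_equal(drop(w1 %*% (P1 + P2) %*% w1), 1)
  expect_gt(w1[which.max(abs(w1))], 0)

  same <- csp_fit(list(P1, P1), c(1, 2), m_per_side = 1)
  expect_equal(same$eigenvalues, c(1, 1), tolerance = 1e-8)
  expect_error(csp_fit(list(P1, P1), c(1, 1)), "both classes")
})

test_that("the top CSP filter maximizes the Rayleigh quotient", {
  set.seed(37)
  P1 <- random_spd(21)
  P2 <- random_spd(21)
  csp <- csp_fit(list(P1, P2), c(1, 2))
  w <- csp$projection[1, ]
  rq <- function(v) drop(v %*% P1 %*% v) / drop(v %*% P2 %*% v)
  best_random <- max(apply(matrix(rnorm(21 * 1000), ncol = 21), 1, rq))
  expect_gte(rq(w), best_random)
})

test_that("swapping class labels reverses the filter order up to sign", {
  set.seed(44)
  covs <- lapply(1:10, function(i) random_spd(8))
  labs <- rep(c(1, 2), 5)
  a <- csp_fit(covs, labs, m_per_side = 2)
  b <- csp_fit(covs, 3 - labs, m_per_side = 2)
  for (k in 1:4) {
    wa <- a$filters[k, ]
    wb <- b$filters[5 - k, ]
    expect_equal(abs(sum(wa * wb)) / sqrt(sum(wa^2) * sum(wb^2)), 1,
                 tolerance = 1e-6)
  }
})

test_that("log-variance features scale and centre as expected", {
  set.seed(9)
  X <- matrix(rnorm(512 * 4), 512, 4)
  W <- diag(4)
  f <- csp_features(X, W)
  expect_equal(f, log(apply(X, 2, var)))
  expect_equal(csp_features(5 * X, W), f + 2 * log(5), tolerance = 1e-10)
  # unit-variance projection gives a zero feature
  Xunit <- X[, 1, drop = FALSE] / sd(X[, 1])
  expect_equal(csp_features(Xunit, matrix(1, 1, 1))[1], 0, tolerance = 1e-12)
})

test_that("LDA matches the symmetric closed form and hand example", {
  F1 <- rbind(c(1, 0), c(1, 2), c(1, -2))
  F1 <- sweep(F1, 2, colMeans(F1)) + matrix(c(1, 0), 3, 2, byrow = TRUE)
  F2 <- -F1
  m <- lda_fit(rbind(F1, F2), c(1, 1, 1, 2, 2, 2))
  expect_equal(m$weight[1] > 0, TRUE)
  expect_equal(m$bias, 0, tolerance = 1e-12)
  expect_equal(m$weight[2], 0, tolerance = 1e-12)
  expect_identical(lda_predict(m, c(0.5, 0))$class, 1L)

  # worked 2-D set with a null second dimension handled by the ridge
  f <- rbind(c(2, 0), c(4, 0), c(-2, 0), c(-4, 0))
  m2 <- lda_fit(f, c(1, 1, 2, 2))
  expect_equal(m2$weight[1], 3, tolerance = 1e-5)
  expect_equal(m2$bias, 0, tolerance = 1e-10)
  expect_identical(lda_predict(m2, f)$class, c(1L, 1L, 2L, 2L))

  # translating every feature leaves decisions unchanged
  shift <- matrix(c(10, -7), 4, 2, byrow = TRUE)
  m3 <- lda_fit(f + shift, c(1, 1, 2, 2))
  expect_equal(m3$weight, m2$weight, tolerance = 1e-8)
  expect_equal(lda_predict(m3, f + shift)$decision,
               lda_predict(m2, f)$decision, tolerance = 1e-8)
  # decision value exactly zero maps to class 1
  expect_identical(lda_predict(m2, c(0, 0))$class, 1L)
  expect_error(lda_fit(f, c(1, 1, 1, 2)), "2 samples")
})

test_that("a small separable session decodes far above chance", {
  cfg <- sim_config(effect_size = 0.7, seed = 12L, p_blink = 0,
                    p_artifact = 0, n_cal_runs = 2, n_test_runs = 1)
  s <- simulate_session(cfg)
  spec <- filter_spec()
  runs <- lapply(s$calibration_runs, function(run)
    lapply(run, function(tr)
      epoched_trial(extract_epoch(filter_trial(tr$mi, spec)), tr$label)))
  bundle <- fit_decoder(runs)
  preds <- vapply(s$testing_runs[[1]], function(tr)
    decode_trial(tr, bundle, spec)$class, 0L)
  truth <- vapply(s$testing_runs[[1]], `[[`, 0L, "label")
  expect_gte(mean(preds == truth), 0.8)
  cmds <- vapply(s$testing_runs[[1]], function(tr)
    decode_trial(tr, bundle, spec)$command, "")
  expect_identical(cmds, ifelse(preds == 1L, "right", "left"))
  expect_error(decode_trial(s$testing_runs[[1]][[1]], list()), "bundle")
})
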