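mont <- standard_montage()

test_that("envelope transform recovers amplitude-modulated mu steps", {
  tt <- seq(0, 4 - 1 / 256, by = 1 / 256)
  amp <- ifelse(tt < 2, 2, 1)
  X <- matrix(0, 1024, 21)
  X[, 9] <- amp * sin(2 * pi * 10 * tt)   # C3
  env <- envelope_transform(X, reference_mode = "none")
  R <- segment_averages(env)
  # baseline is the full-window mean envelope (1.5): segment 1 sits on
  # the high plateau, segment 3 averages the two plateaus evenly
  expect_equal(unclass(R)[1, 9], 0.5, tolerance = 0.05)
  expect_equal(unclass(R)[3, 9], 0, tolerance = 0.05)
  expect_lt(max(abs(colMeans(unclass(env)))), 1e-9)
})

test_that("segment averages equal brute-force re-summation", {
  set.seed(21)
  env <- structure(matrix(rnorm(1024 * 21), 1024, 21),
                   class = c("envelope_trial", "matrix"))
  R <- unclass(segment_averages(env))
  lens <- c(256, 512, 768)
  for (k in 1:3) for (j in c(1, 10, 21)) {
    acc <- 0
    for (t in 129:(128 + lens[k])) acc <- acc + unclass(env)[t, j]
    expect_equal(R[k, j], acc / lens[k])
  }
  const <- structure(matrix(1, 1024, 21), class = "envelope_trial")
  expect_true(all(unclass(segment_averages(const)) == 1))
  zero <- structure(matrix(0, 1024, 21), class = "envelope_trial")
  expect_true(all(unclass(segment_averages(zero)) == 0))
})

test_that("map selection follows the hand-traced priority rule", {
  li <- montage_indices(mont, "left")
  ri <- montage_indices(mont, "right")
  mk <- function(counts) {
    # counts: 3 x 2 matrix of (Nl, Nr) targets for a left-hand trial
    R <- matrix(-1e-3, 3, 21)          # default: all wrong sign
    R[, montage_indices(mont, "midline")] <- 0
    for (k in 1:3) {
      R[k, li] <- -1e-3
      R[k, ri] <- 1e-3
      if (counts[k, 1] > 0) R[k, li[seq_len(counts[k, 1])]] <- 1
      if (counts[k, 2] > 0) R[k, ri[seq_len(counts[k, 2])]] <- -1
    }
    R
  }
  # single-hemisphere 3, then both-hemisphere 6, then stale-flag 5-count
  sel <- select_topomap(mk(rbind(c(3, 0), c(2, 4), c(5, 0))), 2, mont)
  expect_equal(sel$K, 2)
  expect_equal(sel$best_metric, 6)
  # an early strong single-hemisphere segment can beat a later weak pair
  sel2 <- select_topomap(mk(rbind(c(8, 0), c(1, 1), c(0, 0))), 2, mont)
  expect_equal(sel2$K, 1)
  expect_equal(sel2$best_metric, 8)
  # nothing correct: default to the middle map
  zero <- matrix(0, 3, 21)
  expect_equal(select_topomap(zero, 1, mont)$K, 2)
  expect_equal(select_topomap(zero, 1, mont)$best_metric, 0)
  # right-hand trial perfect only in segment 3
  R <- matrix(0, 3, 21)
  R[3, li] <- -1
  R[3, ri] <- 1
  sel3 <- select_topomap(R, 1, mont)
  expect_equal(sel3$K, 3)
  expect_equal(sel3$best_metric, 18)
  expect_error(select_topomap(zero, 7, mont), "label")
})

test_that("map selection agrees with the declarative oracle", {
  set.seed(99)
  for (i in 1:1000) {
    R <- matrix(rnorm(63, sd = 1), 3, 21)
    if (i %% 3 == 0) R[R > 0.5] <- 0       # inject ties/zeros
    lab <- sample(1:2, 1)
    expect_identical(select_topomap(R, lab, mont)$K,
                     as.integer(oracle_select_topomap(R, lab, mont)))
  }
})

test_that("topographic values match hand evaluation and bounds", {
  li <- montage_indices(mont, "left")
  ri <- montage_indices(mont, "right")
  Rk <- numeric(21)
  Rk[li] <- c(2, 1, 0, 0, 0, 0, 0, 0, -1)
  Rk[ri] <- c(-3, 0, 0, 0, 0, 0, 0, 0.5, 0.5)
  tv <- topo_values(Rk, mont)
  expect_equal(tv$topoval_right, 3)    # (-1/-1) + (0.5+0.5)/0.5
  expect_equal(tv$topoval_left, 2.5)   # (2+1)/2 + (-3/-3)

  tv0 <- topo_values(numeric(21), mont)
  expect_equal(tv0$topoval_right, 0)
  expect_equal(tv0$topoval_left, 0)

  Rk2 <- numeric(21)
  Rk2[li] <- -2
  Rk2[ri] <- 2
  tv2 <- topo_values(Rk2, mont)
  expect_equal(tv2$topoval_right, 18)
  expect_equal(tv2$topoval_left, 0)

  set.seed(31)
  for (i in 1:1000) {
    tv <- topo_values(rnorm(21), mont)
    expect_gte(tv$topoval_right, 0); expect_lte(tv$topoval_right, 18)
    expect_gte(tv$topoval_left, 0);  expect_lte(tv$topoval_left, 18)
  }
})

test_that("negating all lateral electrodes swaps the two hypotheses", {
  li <- montage_indices(mont, "left")
  ri <- montage_indices(mont, "right")
  set.seed(12)
  for (i in 1:100) {
    Rk <- rnorm(21)
    flipped <- Rk
    flipped[c(li, ri)] <- -flipped[c(li, ri)]
    a <- topo_values(Rk, mont)
    b <- topo_values(flipped, mont)
    expect_equal(a$topoval_right, b$topoval_left)
    expect_equal(a$topoval_left, b$topoval_right)
    # count roles swap between the class hypotheses too
    R3 <- matrix(Rk, 3, 21, byrow = TRUE)
    F3 <- matrix(flipped, 3, 21, byrow = TRUE)
    expect_identical(select_topomap(R3, 1, mont)$counts,
                     select_topomap(F3, 2, mont)$counts)
  }
})

test_that("the verdict rewards the true class, ties included", {
  expect_identical(evaluate_trial(list(topoval_right = 3,
                                       topoval_left = 2.5), 2), "fight")
  expect_identical(evaluate_trial(list(topoval_right = 3,
                                       topoval_left = 2.5), 1), "good")
  expect_identical(evaluate_trial(list(topoval_right = 0,
                                       topoval_left = 0), 1), "good")
  expect_identical(evaluate_trial(list(topoval_right = 10,
                                       topoval_left = 1), 1), "good")
  expect_error(evaluate_trial(list(topoval_right = 1, topoval_left = 1), 9),
               "label")
})

test_that("a strongly lateralized trial earns a 'good' verdict", {
  cfg <- sim_config(effect_size = 0.7, noise_sd = 1, seed = 6L)
  tr <- simulate_mi_trial(2, cfg, seed = 606L)
  fb <- trial_feedback(tr)
  expect_identical(fb$verdict, "good")
  expect_true(fb$K %in% 1:3)
  expect_length(fb$map, 21)
  expect_gt(fb$topoval_left, fb$topoval_right)
})
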