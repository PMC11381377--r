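test_that("scatter matrices match hand algebra and the covariance identity", {
  f <- rbind(c(1, 0), c(3, 0), c(-1, 0), c(-3, 0))
  lab <- c(1, 1, 2, 2)
  sc <- scatter_matrices(f, lab)
  expect_equal(sc$Sw, rbind(c(4, 0), c(0, 0)))
  expect_equal(sc$Sb, rbind(c(16, 0), c(0, 0)))
  expect_equal(class_distance(sc$Sw, sc$Sb), 4)

  # Sw equals sum_c Nc * biased class covariance (centring identity)
  set.seed(19)
  f2 <- matrix(rnorm(60), 20, 3)
  lab2 <- rep(c(1, 2), 10)
  sc2 <- scatter_matrices(f2, lab2)
  oracle <- Reduce(`+`, lapply(1:2, function(c) {
    Fc <- f2[lab2 == c, ]
    nrow(Fc) * cov(Fc) * (nrow(Fc) - 1) / nrow(Fc)
  }))
  expect_equal(sc2$Sw, oracle, tolerance = 1e-10)
  expect_error(scatter_matrices(f2, rep(1, 20)), "both classes")
})

test_that("class distance is scale-invariant and degenerates safely", {
  set.seed(29)
  f <- matrix(rnorm(40), 20, 2)
  f[1:10, 1] <- f[1:10, 1] + 2
  lab <- rep(c(1, 2), each = 10)
  sc <- scatter_matrices(f, lab)
  cd <- class_distance(sc$Sw, sc$Sb)
  sc5 <- scatter_matrices(5 * f, lab)
  expect_equal(class_distance(sc5$Sw, sc5$Sb), cd, tolerance = 1e-12)
  for (mode in c("entrywise", "induced", "trace"))
    expect_gte(class_distance(sc$Sw, sc$Sb, mode), 0)
  # coincident class means
  g <- rbind(c(1, 1), c(-1, -1), c(1, 1), c(-1, -1))
  scg <- scatter_matrices(g, c(1, 1, 2, 2))
  expect_equal(class_distance(scg$Sw, scg$Sb), 0)
  expect_error(class_distance(matrix(0, 2, 2), diag(2)), "degenerate")
})

test_that("run evaluation separates real labels from shuffled ones", {
  set.seed(59)
  n <- 20
  f <- matrix(rnorm(n * 6, sd = 0.5), n, 6)
  lab <- rep(c(1, 2), each = n / 2)
  f[lab == 1, 1] <- f[lab == 1, 1] + 2
  f[lab == 2, 6] <- f[lab == 2, 6] + 2
  ev <- run_evaluation(f, lab)
  expect_s3_class(ev, "run_eval")
  expect_identical(dim(ev$Sw), c(6L, 6L))
  expect_equal(nrow(ev$projection), n)
  expect_identical(ev$projection$f_first, f[, 1])
  exceed <- mean(replicate(100, {
    evs <- run_evaluation(f, sample(lab))
    ev$cd > evs$cd
  }))
  expect_gte(exceed, 0.95)
  expect_error(run_evaluation(f[c(1, 11), ], c(1, 2)), "degenerate")
})

test_that("cross-validated accuracy is deterministic and learns structure", {
  cfg <- sim_config(effect_size = 0.7, seed = 25L, p_blink = 0,
                    p_artifact = 0, n_cal_runs = 2, n_test_runs = 1)
  s <- simulate_session(cfg)
  spec <- filter_spec()
  runs <- lapply(s$calibration_runs, function(run)
    lapply(run, function(tr)
      epoched_trial(extract_epoch(filter_trial(tr$mi, spec)), tr$label)))
  cv1 <- cv_accuracy(runs, reps = 2, folds = 5, seed = 3L)
  cv2 <- cv_accuracy(runs, reps = 2, folds = 5, seed = 3L)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_gte(cv1$accuracy, 0.9)
  expect_equal(cv1$n_trials, 40)
  expect_error(cv_accuracy(runs, folds = 25), "folds")
})

test_that("paired t and Pearson wrap the classical statistics", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.9, 3.3, 3.8, 5.1)
  tt <- paired_ttest(x, y)
  expect_equal(tt$df, 4)
  expect_equal(tt$t, -0.647, tolerance = 0.01)
  expect_equal(tt$p, 0.55, tolerance = 0.02)
  rev_tt <- paired_ttest(y, x)
  expect_equal(rev_tt$t, -tt$t)
  expect_equal(rev_tt$p, tt$p)
  expect_error(paired_ttest(x, x), "zero variance")

  pc <- pearson_cor(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  expect_equal(pc$n, 5)
  expect_error(pearson_cor(rep(1, 5), x), "constant")
  set.seed(71)
  big <- pearson_cor(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
})

test_that("published summary tables are recovered from per-subject values", {
  rep <- reproduce_tables()
  expect_equal(rep$cd_means$non_feedback[["all"]], 0.79)
  expect_equal(rep$cd_means$trial_feedback[["all"]], 0.76)
  expect_equal(rep$cd_means$non_feedback[["trained"]], 0.84)
  expect_equal(rep$cd_means$non_feedback[["untrained"]], 0.74)
  expect_equal(rep$cd_means$trial_feedback[["trained"]], 0.87)
  expect_equal(rep$cd_means$trial_feedback[["untrained"]], 0.64)
  expect_equal(rep$cd_p, 0.7520)
  expect_equal(rep$qn_means$calibration$non_feedback[["all"]], 2.94)
  expect_equal(rep$qn_means$calibration$trial_feedback[["all"]], 2.80)
  expect_equal(rep$qn_means$testing$non_feedback[["all"]], 3.07)
  expect_equal(rep$qn_means$testing$trial_feedback[["all"]], 2.88)
  expect_equal(rep$qn_cal_p, 0.1540)
  expect_equal(rep$qn_test_p, 0.0894)
  expect_equal(rep$benchmark_pct, 26.25)
  expect_equal(unname(rep$stage_means["first_two"]), 56)
  expect_equal(unname(rep$stage_means["last_two"]), 57)
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(2.5, 0), 3)      # base round() would give 2
  expect_equal(round_half_up(-2.5, 0), -3)    # half away from zero
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.4, 0), 2)
})
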