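# Hand-built rate tensor for decoder unit tests.
make_rates <- function(values, trial_ids = seq_len(dim(values)[2]),
                       times = seq_len(dim(values)[3]) * 50) {
  structure(list(values = values, neuron_ids = seq_len(dim(values)[1]),
                 trial_ids = trial_ids, bin_centres_ms = times,
                 window_ms = 100, step_ms = 50,
                 alignment_event = "fixation_on", normalised = TRUE),
            class = "wm_rates")
}

test_that("pseudotrial counts spread uniformly over conditions", {
  # 1500 over 8 conditions -> counts in {187, 188}, total 1500
  set.seed(2)
  vals <- array(rnorm(5 * 32 * 2), c(5, 32, 2))
  labels <- rep(1:8, each = 4)
  ps <- build_pseudotrials(make_rates(vals), labels, half = 1:32,
                           n_pseudo = 1500, seed = 1)
  counts <- table(ps$labels)
  expect_true(all(counts %in% c(187, 188)))
  expect_equal(sum(counts), 1500)
  expect_equal(dim(ps$values), c(1500, 5, 2))

  # degenerate sampling: 1 neuron, 1 trial per condition
  v1 <- array(seq_len(8), c(1, 8, 1))
  ps1 <- build_pseudotrials(make_rates(v1), 1:8, half = 1:8, n_pseudo = 24,
                            seed = 1)
  expect_true(all(ps1$values[cbind(seq_len(24), 1, 1)] == ps1$labels))

  ps2a <- build_pseudotrials(make_rates(vals), labels, 1:32, 100, seed = 9)
  ps2b <- build_pseudotrials(make_rates(vals), labels, 1:32, 100, seed = 9)
  expect_identical(ps2a, ps2b)

  expect_error(build_pseudotrials(make_rates(vals), labels, half = 1:4,
                                  n_pseudo = 10, seed = 1),
               "no trials")
})

test_that("PCA + pooled-covariance LDA behaves like the reference models", {
  set.seed(31)
  # linearly separable, noise-free test = train -> accuracy 1
  mu <- matrix(rnorm(8 * 6, sd = 4), 8, 6)
  lab <- rep(1:8, each = 30)
  X <- mu[lab, ] + matrix(rnorm(240 * 6, sd = 0.1), 240, 6)
  acc <- denoise_and_classify(X, lab, X, lab)
  expect_equal(as.numeric(acc), 1)

  # shuffled labels, 8 classes: accuracy near 12.5%
  accs <- vapply(1:40, function(i) {
    as.numeric(denoise_and_classify(X, sample(lab), X[sample(240, 80), ],
                                    sample(lab, 80)))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.125), 0.02)

  # 2-class Gaussian with known Bayes rate Phi(d/2) (unit noise)
  delta <- 1.2
  n <- 4000
  y <- rep(1:2, each = n / 2)
  tr <- matrix(rnorm(n * 4), n, 4)
  tr[y == 2, 1] <- tr[y == 2, 1] + delta
  te <- matrix(rnorm(n * 4), n, 4)
  te[y == 2, 1] <- te[y == 2, 1] + delta
  acc2 <- as.numeric(denoise_and_classify(tr, y, te, y, var_kept = 1))
  bayes <- pnorm(delta / 2)
  se <- sqrt(bayes * (1 - bayes) / n)
  expect_lt(abs(acc2 - bayes), 3 * se + 0.01)
})

test_that("the in-package discriminant matches MASS::lda predictions", {
  skip_if_not_installed("MASS")
  set.seed(5)
  lab <- rep(1:5, each = 40)
  mu <- matrix(rnorm(5 * 7), 5, 7)
  X <- mu[lab, ] + matrix(rnorm(200 * 7), 200, 7)
  Xt <- mu[rep(1:5, each = 10), ] + matrix(rnorm(50 * 7), 50, 7)
  model <- wmpopdyn:::pooled_lda(X, lab)
  mine <- wmpopdyn:::pooled_lda_predict(model, Xt)
  ref <- as.character(predict(MASS::lda(X, grouping = lab), Xt)$class)
  expect_gt(mean(mine == ref), 0.97)
})

test_that("decoding timecourse is reproducible and calibrated", {
  g <- untuned_session()
  d1 <- decode_timecourse(g$session, "space8", "SR", times = c(1800, 2200),
                          n_perm = 2, n_train = 160, n_test = 48, seed = 4)
  d2 <- decode_timecourse(g$session, "space8", "SR", times = c(1800, 2200),
                          n_perm = 2, n_train = 160, n_test = 48, seed = 4)
  expect_identical(d1$accuracy, d2$accuracy)
  expect_equal(dim(d1$accuracy), c(2, 2))
  expect_equal(d1$chance, 0.125)

  dr <- decode_timecourse(g$session, "reward", "SR", times = 2200,
                          n_perm = 5, n_train = 160, n_test = 50, seed = 4)
  expect_equal(dr$chance, 0.2)

  # error-trial testing demands the four-location collapsing
  expect_error(decode_timecourse(g$session, "space8", test_on = "error"),
               "space4")
})

test_that("strong sustained tuning decodes far above chance", {
  g <- sustained_session()
  d <- decode_timecourse(g$session, "space8", "SR",
                         times = c(1250, 2000, 2400), n_perm = 8,
                         n_train = 240, n_test = 96, seed = 6)
  expect_true(all(colMeans(d$accuracy) > 3 * d$chance))
  expect_true(all(d$significant))
  td <- tidy(d)
  expect_equal(nrow(td), 3)
  expect_true(all(td$lo <= td$accuracy & td$accuracy <= td$hi))
})

test_that("epoch bootstrap comparison matches its overlap oracle", {
  mk <- function(m) {
    structure(list(accuracy = m, times = c(100, 300),
                   chance = 0.125, significant = c(TRUE, TRUE),
                   feature = "space8", task_type = "SR",
                   test_on = "correct", n_perm = nrow(m),
                   neurons = 1:5),
              class = "wm_decode")
  }
  ep <- tibble::tibble(epoch = "e1", lo_ms = 0, hi_ms = 500)

  set.seed(8)
  a <- matrix(rnorm(1000, 0.5, 0.01), ncol = 2, nrow = 1000)
  # identical distributions -> p about 0.5
  b <- matrix(rnorm(1000, 0.5, 0.01), ncol = 2, nrow = 1000)
  r1 <- epoch_bootstrap_compare(mk(a), mk(b), epochs = ep, seed = 2)
  expect_lt(abs(r1$p - 0.5), 0.05)

  # disjoint distributions -> p = 0 before correction
  r2 <- epoch_bootstrap_compare(mk(a), mk(a - 1), epochs = ep, seed = 2)
  expect_equal(r2$p, 0)
  expect_equal(r2$higher, "a")

  # N(0.5, 0.01) vs N(0.48, 0.01): overlap = Phi(-0.02 / (0.01 sqrt 2))
  b3 <- matrix(rnorm(1000, 0.48, 0.01), ncol = 2, nrow = 1000)
  r3 <- epoch_bootstrap_compare(mk(a), mk(b3), epochs = ep, seed = 2)
  oracle <- pnorm(-0.02 / (0.01 * sqrt(2)))
  expect_lt(abs(r3$p - oracle), 3 * sqrt(oracle * (1 - oracle) / 1000) + 0.01)

  expect_error(
    epoch_bootstrap_compare(mk(a), mk(rbind(b, b))), "permutation counts")
})

test_that("cross-temporal surfaces agree with matched-time decoding", {
  g <- sustained_session()
  xt <- cross_temporal_decode(g$session, "space8", "SR",
                              train_times = c(1900, 2300),
                              test_times = c(1900, 2300),
                              n_perm = 6, n_train = 240, n_test = 96,
                              seed = 11)
  d <- decode_timecourse(g$session, "space8", "SR",
                         times = c(1900, 2300), n_perm = 6, n_train = 240,
                         n_test = 96, seed = 11)
  diag_acc <- vapply(1:2, function(i) mean(xt$accuracy[, i, i]), numeric(1))
  expect_true(all(abs(diag_acc - colMeans(d$accuracy)) < 0.1))
  # sustained code generalises: off-diagonal close to diagonal
  off <- mean(xt$accuracy[, 1, 2])
  expect_gt(off, 0.7 * mean(diag_acc))
})

test_that("slope test recovers exact linear declines", {
  # synthetic surface: accuracy declines linearly in test time
  test_times <- seq(2000, 3950, by = 50)
  train_times <- seq(2050, 2450, by = 50)
  slope_true <- -2e-4
  curve <- 0.9 + slope_true * (test_times - 2000)
  acc <- array(rep(rep(curve, each = length(train_times)), 3),
               c(3, length(train_times), length(test_times)))
  # transposition care: fill explicitly
  for (p in 1:3) for (i in seq_along(train_times)) {
    acc[p, i, ] <- curve
  }
  xt <- structure(list(accuracy = acc, train_times = train_times,
                       test_times = test_times, chance = 0.125,
                       feature = "space8", task_type = "SR", n_perm = 3,
                       neurons = 1:4),
                  class = "wm_xt")
  res <- decline_slope_test(xt)
  expect_equal(res$gradient, rep(slope_true, 3), tolerance = 1e-9)
  expect_true(all(res$lo <= slope_true + 1e-12 &
                    slope_true <= res$hi + 1e-12))

  # constant surface: CI contains 0
  for (p in 1:3) acc[p, , ] <- 0.5
  xt0 <- xt
  xt0$accuracy <- acc
  res0 <- decline_slope_test(xt0)
  expect_true(all(!res0$significant))

  # identical epochs compare as not significant, centred difference
  ep <- epoch_pair_compare(xt0, "T1", "T1")
  expect_false(ep$significant)
  expect_equal(ep$mean_same - ep$mean_cross, 0)

  expect_error(decline_slope_test(xt0, windows = "nope"), "unknown window")
})
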