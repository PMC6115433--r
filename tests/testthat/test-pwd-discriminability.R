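make_rates2 <- function(values, trial_ids = seq_len(dim(values)[2])) {
  structure(list(values = values, neuron_ids = seq_len(dim(values)[1]),
                 trial_ids = trial_ids,
                 bin_centres_ms = seq_len(dim(values)[3]) * 10,
                 window_ms = 200, step_ms = 10,
                 alignment_event = "fixation_on", normalised = FALSE),
            class = "wm_rates")
}

test_that("PWD combinatorics follow C(c, 2)", {
  set.seed(1)
  for (spec in list(c(8, 28), c(5, 10), c(2, 1))) {
    nc <- spec[1]
    vals <- array(rnorm(4 * nc * 3 * 2), c(4, nc * 3, 2))
    labels <- rep(seq_len(nc), each = 3)
    pwd <- condition_pwds(make_rates2(vals), labels, seq_len(nc * 3))
    expect_equal(dim(pwd$values)[1], spec[2])
  }
  # 2 conditions: the single PWD equals mean(c1) - mean(c2)
  vals <- array(rnorm(3 * 6 * 1), c(3, 6, 1))
  labels <- rep(1:2, each = 3)
  pwd <- condition_pwds(make_rates2(vals), labels, 1:6)
  expect_equal(pwd$values[1, , 1],
               rowMeans(vals[, 1:3, 1]) - rowMeans(vals[, 4:6, 1]))
})

test_that("discriminability matches self, sign-flip and the oracle", {
  set.seed(2)
  train <- matrix(rnorm(28 * 10), 28, 10)
  expect_gt(discriminability(train, train), 0.999)
  expect_lt(discriminability(train, -train), -0.999)

  # 3 neurons x 3 conditions toy vs brute force (and vs a hand-set case)
  set.seed(3)
  for (i in 1:5) {
    tr_v <- array(rnorm(4 * 9 * 2), c(4, 9, 2))
    te_v <- array(rnorm(4 * 9 * 2), c(4, 9, 2))
    labels <- rep(1:3, each = 3)
    p1 <- condition_pwds(make_rates2(tr_v), labels, 1:9)
    p2 <- condition_pwds(make_rates2(te_v), labels, 1:9)
    mine <- discriminability(p1$values[, , 1], p2$values[, , 1])
    ref <- oracle_discriminability(tr_v[, , 1], te_v[, , 1], labels, labels)
    expect_equal(mine, ref, tolerance = 1e-12)
    # matrix fast path agrees with the scalar path
    rmat <- wmpopdyn:::pwd_corr_matrix(
      wmpopdyn:::pwd_standardise(p1$values),
      wmpopdyn:::pwd_standardise(p2$values))
    # the fast path shrinks |r| multiplicatively before atanh where the
    # scalar path clamps; they agree to ~1e-9, far inside estimator noise
    expect_equal(rmat[1, 1], mine, tolerance = 1e-9)
  }

  # hand-computable pair correlations {1, 0.5, 0.5}: the perfect pair is
  # clamped to 1 - 1e-12 before atanh and dominates the Fisher mean
  n <- 16
  z1 <- scale(rnorm(n))[, 1]
  w <- scale(stats::resid(stats::lm(rnorm(n) ~ z1)))[, 1]
  b_half <- 0.5 * z1 + sqrt(1 - 0.25) * w        # cor(z1, b_half) = 0.5
  train3 <- rbind(z1, z1, z1)
  test3 <- rbind(z1, b_half, b_half)
  expect_equal(cor(z1, b_half), 0.5, tolerance = 1e-12)
  got <- discriminability(train3, test3)
  expect_equal(got, tanh((atanh(1 - 1e-12) + 2 * atanh(0.5)) / 3),
               tolerance = 1e-9)

  expect_error(discriminability(train[, 1:2], train[, 1:2]), "3 neurons")
})

test_that("PWDs cancel additive offsets and respect common permutations", {
  set.seed(4)
  vals <- array(rnorm(6 * 16 * 2), c(6, 16, 2))
  labels <- rep(1:4, times = 4)       # each half sees every condition
  r0 <- make_rates2(vals)
  p1 <- condition_pwds(r0, labels, 1:8)
  p2 <- condition_pwds(r0, labels, 9:16)
  base <- discriminability(p1$values[, , 1], p2$values[, , 1])

  # per-neuron additive offsets leave PWDs unchanged
  off <- rnorm(6, sd = 10)
  r_off <- make_rates2(sweep(vals, 1, off, "+"))
  p1o <- condition_pwds(r_off, labels, 1:8)
  expect_equal(p1o$values, p1$values, tolerance = 1e-12)

  # common neuron permutation applied to both halves
  perm <- c(3, 1, 6, 2, 5, 4)
  d_perm <- discriminability(p1$values[, perm, 1], p2$values[, perm, 1])
  expect_equal(d_perm, base, tolerance = 1e-12)
})

test_that("cross-temporal surfaces capture reversal vs stability", {
  times <- seq(1000, 2500, by = 100)
  g <- reversal_session()
  dr <- crosstemporal_discriminability(g$session, "space8",
                                       task_type = "SR", times = times,
                                       seed = 3)
  cue <- times >= 1050 & times < 1450
  dly <- times >= 1650 & times < 2450
  expect_lt(mean(dr$r[cue, dly]), 0)
  expect_gt(mean(dr$r[dly, dly]), 0.4)

  gs <- sustained_session()
  ds <- crosstemporal_discriminability(gs$session, "space8",
                                       task_type = "SR", times = times,
                                       seed = 3)
  expect_gt(mean(ds$r[cue, dly]), 0.2)

  # symmetrised surface is exactly symmetric
  dsym <- crosstemporal_discriminability(gs$session, "space8",
                                         task_type = "SR", times = times,
                                         symmetrise = TRUE, seed = 3)
  expect_equal(dsym$r, t(dsym$r), tolerance = 1e-12)
})

test_that("task-type discriminability reflects task-type information", {
  # untuned neurons respond identically on SR and RS trials: null r
  g <- untuned_session()
  tt0 <- task_type_discriminability(g$session, times = seq(1500, 2500, 100),
                                    seed = 2)
  expect_lt(mean(abs(tt0$r)), 0.45)

  # tuned neurons distinguish the tasks through their cue-order dynamics
  # even without an explicit task-type term
  gs <- sustained_session()
  tts <- task_type_discriminability(gs$session,
                                    times = seq(1500, 2500, 100), seed = 2)
  expect_gt(mean(tts$r), 0.3)

  cfg <- synth_config(n_neurons = 25, trials_per_cond = 1, frac_untuned = 0,
                      frac_transient = 0, frac_reversal = 0,
                      frac_switch = 0, error_frac = 0,
                      tasktype_depth_hz = 6, seed = 106)
  gt <- generate_session(cfg)
  tt1 <- task_type_discriminability(gt$session,
                                    times = seq(1500, 2500, 100), seed = 2)
  expect_gt(mean(tt1$r), 0.7)
})

test_that("cluster machinery finds blocks and nothing in zero maps", {
  # all-zero statistic map -> no candidates
  mask <- matrix(FALSE, 20, 20)
  expect_length(wmpopdyn:::connected_sizes(mask), 0)

  # two disjoint blocks under 4-connectivity
  mask[2:5, 2:5] <- TRUE
  mask[10:12, 10:14] <- TRUE
  sizes <- sort(wmpopdyn:::connected_sizes(mask), decreasing = TRUE)
  expect_equal(sizes, c(16, 15))

  # diagonal touching pixels are NOT connected (4- not 8-connectivity)
  m2 <- matrix(FALSE, 4, 4)
  m2[1, 1] <- m2[2, 2] <- TRUE
  expect_equal(sort(wmpopdyn:::connected_sizes(m2)), c(1, 1))

  # window grid prevents bridging across 500 ms boundaries
  m3 <- matrix(TRUE, 4, 4)
  win <- c(0, 0, 1, 1)
  sizes3 <- wmpopdyn:::cluster_sizes_in_grid(m3, win, win)
  expect_equal(sort(sizes3), rep(4, 4))
})

test_that("vs-chance cluster test flags an injected coherent block", {
  set.seed(9)
  n_neu <- 40
  n_pairs <- 28
  tt <- 30                               # 10 ms grid: 300 ms, one window
  # null PWDs: independent noise in train and test
  tr_arr <- array(rnorm(n_pairs * n_neu * tt), c(n_pairs, n_neu, tt))
  te_arr <- array(rnorm(n_pairs * n_neu * tt), c(n_pairs, n_neu, tt))
  # inject shared structure over a 20 x 20 block of timepoints
  shared <- matrix(rnorm(n_pairs * n_neu), n_pairs, n_neu)
  for (t1 in 11:30) {
    tr_arr[, , t1] <- tr_arr[, , t1] + 2 * shared
    te_arr[, , t1] <- te_arr[, , t1] + 2 * shared
  }
  mat <- structure(list(
    r = wmpopdyn:::pwd_corr_matrix(wmpopdyn:::pwd_standardise(tr_arr),
                                   wmpopdyn:::pwd_standardise(te_arr)),
    times = seq(10, by = 10, length.out = tt), feature = "space8",
    train = "half1", test = "half2", task_type = "SR", symmetrised = FALSE,
    n_neurons = n_neu, std_train = wmpopdyn:::pwd_standardise(tr_arr),
    std_test = wmpopdyn:::pwd_standardise(te_arr)),
    class = "wm_discrim")
  ct <- cluster_test_vs_chance(mat, n_perm = 150, seed = 5)
  top <- ct$clusters[1, ]
  expect_gte(top$size, 300)              # the injected 20 x 20 block
  expect_lt(top$p, 0.05)
  expect_equal(top$sign, 1)
})

test_that("between-groups statistic is antisymmetric and detects groups", {
  g <- cached("mixed_dynamics", function() {
    generate_session(synth_config(
      n_neurons = 40, trials_per_cond = 2, frac_untuned = 0,
      frac_transient = 0.5, frac_reversal = 0, frac_switch = 0,
      error_frac = 0, seed = 71))
  })
  s <- g$session
  tr <- s$trials
  correct <- tr$trial_id[tr$task_type == "SR" & tr$outcome == "correct"]
  lab <- tr$location8[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = 2)
  rates <- estimate_rates(s, step_ms = 50, window_ms = 200, t_min = 1500,
                          t_max = 2500, trials = correct)
  labs <- tr$location8[match(rates$trial_ids, tr$trial_id)]
  p1 <- condition_pwds(rates, labs, sp$train)
  p2 <- condition_pwds(rates, labs, sp$test)
  groups <- ifelse(g$ground_truth$type == "sustained", "A", "B")

  ct <- cluster_test_between_groups(p1, p2, groups, n_perm = 150,
                                    times = rates$bin_centres_ms, seed = 3)
  # sustained neurons carry the delay code: significant cluster, z > 0
  expect_gt(nrow(ct$clusters), 0)
  expect_lt(ct$clusters$p[1], 0.05)
  expect_gt(mean(ct$z), 0)

  ct_swap <- cluster_test_between_groups(p1, p2,
                                         ifelse(groups == "A", "B", "A"),
                                         n_perm = 2,
                                         times = rates$bin_centres_ms,
                                         seed = 3)
  expect_equal(ct_swap$z, -ct$z, tolerance = 1e-12)

  expect_error(cluster_test_between_groups(p1, p2, rep("A", 40)),
               "2 levels")
})
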