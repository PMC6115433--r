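test_that("raw vs demeaned correlation dissociates baseline from tuning", {
  g <- reversal_session()
  times <- seq(1000, 2500, by = 150)
  raw <- across_time_condition_correlation(g$session, features = "space8",
                                           task_type = "SR", times = times,
                                           demean = FALSE, seed = 5)
  dem <- across_time_condition_correlation(g$session, features = "space8",
                                           task_type = "SR", times = times,
                                           demean = TRUE, seed = 5)
  cue <- times >= 1050 & times < 1450
  dly <- times >= 1650 & times < 2450
  # demeaning exposes the tuning reversal: negative cue <-> delay, while
  # the raw correlation is pulled up by shared baselines
  expect_lt(mean(dem$r[cue, dly]), 0)
  expect_gt(mean(raw$r[cue, dly]), mean(dem$r[cue, dly]) + 0.1)
  # within-delay tuning is stable
  expect_gt(mean(dem$r[dly, dly]), 0.2)

  # heterogeneous baselines with no tuning: raw correlation positive at
  # all pixels, baseline-driven
  g0 <- untuned_session()
  raw0 <- across_time_condition_correlation(g0$session,
                                            features = "space8",
                                            task_type = "SR",
                                            times = times, demean = FALSE,
                                            seed = 5)
  expect_gt(mean(raw0$r), 0.3)
  expect_gt(min(raw0$r), 0)
})

test_that("untuned populations decorrelate once demeaned", {
  g <- untuned_session()
  times <- seq(1200, 2400, by = 200)
  dem <- across_time_condition_correlation(g$session, features = "space8",
                                           task_type = "SR", times = times,
                                           demean = TRUE, seed = 5)
  off <- dem$r[row(dem$r) != col(dem$r)]
  expect_lt(abs(mean(off)), 0.1)
})

test_that("subspaces have orthonormal axes and closed-form solutions", {
  g <- sustained_session()
  s <- g$session
  tr <- s$trials
  correct <- tr$trial_id[tr$task_type == "SR" & tr$outcome == "correct"]
  lab <- tr$location8[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = 7)
  times <- seq(200, 4600, by = 200)
  m <- define_subspace(s, "space8", "delay1", task_type = "SR",
                       half = sp$train, times = times)
  expect_equal(crossprod(m$axes), diag(7), tolerance = 1e-10)
  expect_false(m$degenerate)
  expect_error(define_subspace(s, "space8", "delay1", task_type = "SR",
                               half = sp$train, times = times, k = 8),
               "smaller")

  # conditions differing along one neuron only: first axis is its indicator
  cm <- matrix(0, 8, 5)
  cm[, 3] <- c(4, -1, 2, 0, 1, -3, 2, -5)
  cm_dm <- sweep(cm, 2, colMeans(cm))
  sv <- svd(cm_dm)
  expect_equal(abs(sv$v[, 1]), c(0, 0, 1, 0, 0), tolerance = 1e-12)
})

test_that("stimulus variance obeys its trace identities", {
  g <- sustained_session()
  s <- g$session
  tr <- s$trials
  correct <- tr$trial_id[tr$task_type == "SR" & tr$outcome == "correct"]
  lab <- tr$location8[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = 7)
  times <- seq(1000, 2600, by = 200)
  m <- define_subspace(s, "space8", "delay1", task_type = "SR",
                       half = sp$train, times = times)
  d1 <- times >= 1500 & times < 2500

  # the full-span identity: k = c - 1 per-timepoint axes evaluated on their
  # own training means capture all stimulus variance exactly
  m_dyn <- define_subspace(s, "space8", "dynamic", task_type = "SR",
                           half = sp$train, times = times)
  sv_self <- stimulus_variance(m_dyn, s, sp$train)
  expect_equal(sv_self$sv_normalised[d1], rep(1, sum(d1)), tolerance = 1e-9)

  # rotation of the axes within their span leaves sv_raw untouched
  sv_test <- stimulus_variance(m, s, sp$test)
  set.seed(99)
  rot <- qr.Q(qr(matrix(rnorm(49), 7, 7)))
  m_rot <- m
  m_rot$axes <- m$axes %*% rot
  sv_rot <- stimulus_variance(m_rot, s, sp$test)
  expect_equal(sv_rot$sv_raw, sv_test$sv_raw, tolerance = 1e-10)

  # a subspace orthogonal to the per-timepoint condition space captures
  # none of that timepoint's stimulus variance
  m_orth <- m_dyn
  m_orth$axes <- lapply(m_dyn$axes, function(ax) {
    q <- qr.Q(qr(cbind(ax, matrix(rnorm(nrow(ax) * 7), nrow(ax)))))
    q[, 8:14]
  })
  sv_orth <- stimulus_variance(m_orth, s, sp$train)
  expect_true(all(sv_orth$sv_normalised[d1] < 1e-9))
})

test_that("projected trajectories reproduce training configurations", {
  g <- reversal_session()
  s <- g$session
  tr <- s$trials
  correct <- tr$trial_id[tr$task_type == "SR" & tr$outcome == "correct"]
  lab <- tr$location8[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = 7)
  times <- seq(1000, 2600, by = 200)
  m <- define_subspace(s, "space8", "delay1", task_type = "SR",
                       half = sp$train, times = times)

  pr <- project_trajectories(m, s, sp$test)
  expect_setequal(unique(pr$axis), 1:2)
  expect_equal(nrow(pr), 8 * length(times) * 2)

  # reversal: axis-1 condition ordering anti-correlates cue vs delay
  a1 <- pr[pr$axis == 1, ]
  cue_t <- times[times >= 1050 & times < 1450]
  dly_t <- times[times >= 1650 & times < 2450]
  cm <- tapply(a1$coordinate[a1$time_ms %in% cue_t],
               a1$condition[a1$time_ms %in% cue_t], mean)
  dm <- tapply(a1$coordinate[a1$time_ms %in% dly_t],
               a1$condition[a1$time_ms %in% dly_t], mean)
  expect_lt(cor(cm, dm, method = "spearman"), 0)

  expect_error(project_trajectories(
    define_subspace(s, "space8", "dynamic", task_type = "SR",
                    half = sp$train, times = times), s, sp$test),
    "fixed-epoch")
})

test_that("dynamic subspace dominates fixed subspaces up to noise", {
  g <- reversal_session()
  s <- g$session
  tr <- s$trials
  correct <- tr$trial_id[tr$task_type == "SR" & tr$outcome == "correct"]
  lab <- tr$location8[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = 7)
  times <- seq(1000, 2600, by = 200)
  m_dyn <- define_subspace(s, "space8", "dynamic", task_type = "SR",
                           half = sp$train, times = times)
  m_fix <- define_subspace(s, "space8", "delay1", task_type = "SR",
                           half = sp$train, times = times)
  sv_dyn <- stimulus_variance(m_dyn, s, sp$test)
  sv_fix <- stimulus_variance(m_fix, s, sp$test)
  expect_gt(mean(sv_dyn$sv_normalised - sv_fix$sv_normalised, na.rm = TRUE),
            -0.05)
  # during the cue the dynamic subspace captures far more than the
  # delay-defined one (little consistency between cue and delay patterns)
  cue <- times >= 1050 & times < 1450
  expect_gt(mean(sv_dyn$sv_normalised[cue]),
            mean(sv_fix$sv_normalised[cue]) + 0.2)
})
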