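# Pseudopopulation accuracy-based decoding: pseudotrial construction,
# per-timepoint PCA denoising + pooled-covariance linear-discriminant
# classification, permutation distributions, epoch bootstrap comparisons,
# cross-temporal surfaces, error-trial testing, and decline (slope) tests.

DECODE_FEATURES <- c("space8", "space4", "reward", "task_type")

# Condition label per trial for a decoded feature.
feature_labels <- function(trials, feature) {
  switch(feature,
         space8 = trials$location8,
         space4 = trials$location4,
         reward = trials$reward_level,
         task_type = trials$task_type,
         stop("unknown feature: ", feature))
}

#' The ten consecutive 500 ms analysis epochs from fixation onset
#'
#' @return Tibble with `epoch`, `lo_ms`, `hi_ms` (half-open windows).
#' @export
task_epochs <- function() {
  tibble::tibble(
    epoch = c("fix1", "fix2", "cue1", "delay1a", "delay1b", "cue2",
              "delay2a", "delay2b", "go1", "go2"),
    lo_ms = seq(0, 4500, by = 500),
    hi_ms = seq(500, 5000, by = 500)
  )
}

# The three windows of the reward-cue disruption analyses. The reward cue is
# cue2 on SR-trials and cue1 on RS-trials.
disruption_windows <- function(task_type = "SR") {
  reward_cue_on <- if (task_type == "SR") {
    TASK_SCHEDULE[["cue2_on"]]
  } else {
    TASK_SCHEDULE[["cue1_on"]]
  }
  tibble::tibble(
    window = c("T1", "post_reward", "T2"),
    lo_ms = c(2000, reward_cue_on + 250, 3500),
    hi_ms = c(2500, reward_cue_on + 750, 4000)
  )
}

#' Build a pseudotrial set from one half of the trials
#'
#' Pseudotrials approximate simultaneous population recordings from pooled
#' single-neuron sessions: for every pseudotrial of a condition, one trial of
#' that condition is drawn independently (with replacement) per neuron. The
#' `n_pseudo` pseudotrials are spread uniformly over conditions (counts
#' differ by at most one, remainder assigned to the first conditions in
#' sorted label order).
#'
#' @param rates A z-scored `wm_rates`.
#' @param labels Condition label per trial of `rates` (aligned with
#'   `rates$trial_ids`).
#' @param half Trial ids forming this half.
#' @param n_pseudo Total number of pseudotrials (1500 train / 100 test in the
#'   reference pipeline).
#' @param seed Seed for the draws.
#' @return A `wm_pseudo`: `values` array (pseudotrials x neurons x
#'   timepoints) and `labels`.
#' @export
build_pseudotrials <- function(rates, labels, half, n_pseudo, seed = 1L) {
  stopifnot(inherits(rates, "wm_rates"))
  idx_half <- match(half, rates$trial_ids)
  if (anyNA(idx_half)) stop("half contains trial ids absent from rates")
  lab_half <- labels[idx_half]
  conds <- sort(unique(labels))
  missing <- setdiff(conds, lab_half)
  if (length(missing) > 0) {
    stop("condition with no trials in this half: ", missing[1])
  }
  n_cond <- length(conds)
  per <- rep(n_pseudo %/% n_cond, n_cond)
  rem <- n_pseudo %% n_cond
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1

  d <- dim(rates$values)
  n_neu <- d[1]
  n_time <- d[3]
  values <- array(NA_real_, c(n_pseudo, n_neu, n_time))
  out_labels <- rep(conds, per)
  rng <- local_rng(seed)
  row0 <- 0L
  for (ci in seq_len(n_cond)) {
    tr_c <- idx_half[lab_half == conds[ci]]
    m <- per[ci]
    draw <- matrix(tr_c[rng$sample(seq_along(tr_c), m * n_neu,
                                   replace = TRUE)], nrow = m)
    for (nn in seq_len(n_neu)) {
      values[row0 + seq_len(m), nn, ] <- rates$values[nn, draw[, nn], ]
    }
    row0 <- row0 + m
  }
  structure(list(values = values, labels = out_labels,
                 bin_centres_ms = rates$bin_centres_ms,
                 neuron_ids = rates$neuron_ids),
            class = "wm_pseudo")
}

# Pooled-covariance Gaussian linear discriminant (the model behind MATLAB's
# `classify`). Adds a 1e-6 * mean-diagonal ridge only when the pooled
# covariance is numerically singular; the fallback is recorded in the result.
pooled_lda <- function(train, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  k <- ncol(train)
  g <- length(classes)
  n <- nrow(train)
  M <- matrix(0, g, k)
  S <- matrix(0, k, k)
  counts <- integer(g)
  for (ci in seq_len(g)) {
    Xc <- train[labels == classes[ci], , drop = FALSE]
    counts[ci] <- nrow(Xc)
    M[ci, ] <- colMeans(Xc)
    Xd <- sweep(Xc, 2, M[ci, ])
    S <- S + crossprod(Xd)
  }
  S <- S / (n - g)
  ridged <- FALSE
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    S <- S + diag(1e-6 * mean(diag(S)) + 1e-12, k)
    Sinv <- chol2inv(chol(S))
    ridged <- TRUE
  }
  W <- M %*% Sinv                       # g x k
  const <- -0.5 * rowSums(W * M) + log(counts / n)
  list(W = W, const = const, classes = classes, ridged = ridged)
}

pooled_lda_predict <- function(model, x) {
  scores <- x %*% t(model$W)
  scores <- sweep(scores, 2, model$const, "+")
  model$classes[max.col(scores, ties.method = "first")]
}

#' PCA-denoise a training matrix and classify a test matrix
#'
#' Principal components are fitted on the training matrix only; both sets are
#' projected onto the minimal number of leading axes explaining `var_kept` of
#' the training variance (retained component scores, not reconstructed data,
#' so the pooled covariance of the discriminant stays well-conditioned), then
#' a pooled-covariance linear discriminant is fitted on the training scores
#' and applied to the test scores.
#'
#' @param train Numeric matrix, pseudotrials x neurons, at the training time.
#' @param train_labels Condition labels of `train` rows.
#' @param test Matrix at the test time (same neurons).
#' @param test_labels Labels of `test` rows; if supplied the fraction correct
#'   is returned, otherwise the predicted labels.
#' @param var_kept Fraction of training variance to retain (default 0.90).
#' @return Accuracy (or predictions when `test_labels` is `NULL`), with the
#'   number of retained components in attribute `k`.
#' @export
denoise_and_classify <- function(train, train_labels, test,
                                 test_labels = NULL, var_kept = 0.90) {
  if (length(unique(train_labels)) < 2) {
    stop("training set must contain at least 2 classes")
  }
  ctr <- colMeans(train)
  Xc <- sweep(train, 2, ctr)
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- which(cumsum(ev) / sum(ev) >= var_kept - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  str <- Xc %*% V
  ste <- sweep(test, 2, ctr) %*% V
  model <- pooled_lda(str, train_labels)
  pred <- pooled_lda_predict(model, ste)
  out <- if (is.null(test_labels)) {
    pred
  } else {
    mean(pred == as.character(test_labels))
  }
  attr(out, "k") <- k
  attr(out, "ridged") <- model$ridged
  out
}

# Assemble the z-scored rates needed by the decoding pipelines.
decode_rates <- function(session, times, neurons, trial_ids,
                         step_ms = 50, window_ms = 100) {
  rates <- estimate_rates(session, step_ms = step_ms, window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = trial_ids, neurons = neurons)
  keep <- rates$bin_centres_ms %in% times
  rates$values <- rates$values[, , keep, drop = FALSE]
  rates$bin_centres_ms <- rates$bin_centres_ms[keep]
  base <- baseline_stats(session, trials =
                           intersect(trial_ids,
                                     session$trials$trial_id[
                                       session$trials$outcome == "correct"]))
  base <- base[match(neurons, base$neuron_id), ]
  baseline_zscore(rates, base)
}

#' Timecourse of pseudopopulation decoding accuracy
#'
#' The full accuracy-decoding pipeline: per permutation, correct trials of
#' the chosen task type are re-split into stratified halves, the training
#' half is reorganised into `n_train` pseudotrials and the test half (or the
#' error trials) into `n_test` pseudotrials, and a PCA-denoised
#' linear-discriminant classifier is fitted and scored at every timepoint.
#' A timepoint is significant when the 2.5th percentile of the accuracy
#' distribution exceeds chance.
#'
#' @param session A `wm_session`.
#' @param feature One of `"space8"`, `"space4"`, `"reward"`, `"task_type"`.
#' @param task_type `"SR"` or `"RS"`; ignored for `feature = "task_type"`,
#'   which uses all correct trials.
#' @param neurons Population neuron ids (default: all).
#' @param times Bin centres (ms); default 50 ms grid over the trial.
#' @param n_perm Number of permutations of the whole procedure.
#' @param n_train,n_test Pseudotrial counts (reference: 1500 / 100).
#' @param var_kept PCA variance retained.
#' @param test_on `"correct"` or `"error"`; error-trial testing requires
#'   `feature = "space4"`.
#' @param seed Master seed.
#' @return A `wm_decode`: accuracy matrix (`n_perm` x timepoints), per-time
#'   significance, chance level and metadata.
#' @export
decode_timecourse <- function(session, feature, task_type = "SR",
                              neurons = NULL,
                              times = seq(50, 4800, by = 50),
                              n_perm = 100, n_train = 1500, n_test = 100,
                              var_kept = 0.90,
                              test_on = c("correct", "error"), seed = 1L) {
  feature <- match.arg(feature, DECODE_FEATURES)
  test_on <- match.arg(test_on)
  if (test_on == "error" && feature != "space4") {
    stop("error-trial testing uses the four-location collapsing",
         " (feature = 'space4')")
  }
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  if (length(neurons) == 0) stop("empty population")

  tr <- session$trials
  in_task <- if (feature == "task_type") rep(TRUE, nrow(tr)) else
    tr$task_type == task_type
  correct_ids <- tr$trial_id[in_task & tr$outcome == "correct"]
  error_ids <- tr$trial_id[in_task & tr$outcome == "error"]
  pool_ids <- if (test_on == "error") c(correct_ids, error_ids) else
    correct_ids
  rates <- decode_rates(session, times, neurons, pool_ids)
  labels_all <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                               feature)
  correct_lab <- labels_all[match(correct_ids, rates$trial_ids)]
  chance <- 1 / length(unique(labels_all))

  acc <- matrix(NA_real_, n_perm, length(times))
  for (p in seq_len(n_perm)) {
    sp <- split_half(correct_ids, correct_lab,
                     seed = substream_seed(seed, 2 * p))
    train <- build_pseudotrials(rates, labels_all, sp$train, n_train,
                                seed = substream_seed(seed, 2 * p + 1))
    test_half <- if (test_on == "error") error_ids else sp$test
    test <- build_pseudotrials(rates, labels_all, test_half, n_test,
                               seed = substream_seed(seed, 2 * p + 1) + 1L)
    for (ti in seq_along(times)) {
      acc[p, ti] <- denoise_and_classify(train$values[, , ti],
                                         train$labels,
                                         test$values[, , ti],
                                         test$labels, var_kept)
    }
  }
  lo <- apply(acc, 2, stats::quantile, probs = 0.025)
  structure(list(accuracy = acc, times = times, chance = chance,
                 significant = lo > chance, feature = feature,
                 task_type = task_type, test_on = test_on,
                 n_perm = n_perm, neurons = neurons),
            class = "wm_decode")
}

#' @export
print.wm_decode <- function(x, ...) {
  cat("<wm_decode> ", x$feature, " on ", x$task_type, "-trials (test on ",
      x$test_on, "): ", x$n_perm, " permutations x ", length(x$times),
      " timepoints; chance ", signif(100 * x$chance, 3), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.wm_decode <- function(x, ...) {
  tibble::tibble(
    time_ms = x$times,
    accuracy = colMeans(x$accuracy),
    lo = apply(x$accuracy, 2, stats::quantile, probs = 0.025),
    hi = apply(x$accuracy, 2, stats::quantile, probs = 0.975),
    significant = x$significant
  )
}

#' @export
glance.wm_decode <- function(x, ...) {
  tibble::tibble(feature = x$feature, task_type = x$task_type,
                 n_perm = x$n_perm, chance = x$chance,
                 mean_accuracy = mean(x$accuracy),
                 frac_significant = mean(x$significant))
}

#' @export
autoplot.wm_decode <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed",
                        colour = "magenta") +
    ggplot2::labs(x = "time from fixation onset (ms)",
                  y = "classifier accuracy",
                  title = paste0(object$feature, ", ", object$task_type,
                                 "-trials"))
}

#' Bootstrap comparison of two decoding results across ten 500 ms epochs
#'
#' Within each permutation, accuracy is averaged over each of the ten
#' consecutive 500 ms epochs from fixation onset. Per epoch, the population
#' with the higher mean is identified and the p-value is the average, over
#' `n_reshuffle` random re-pairings of the permutations, of the fraction of
#' pairs in which the lower-mean population exceeds the higher-mean one;
#' Bonferroni correction multiplies by the number of epochs.
#'
#' @param res_a,res_b Two `wm_decode` objects with equal permutation counts.
#' @param epochs Epoch table (default [task_epochs()]).
#' @param n_reshuffle Number of random re-pairings.
#' @param seed Seed for the re-pairings.
#' @return Tibble: epoch, means, which is higher, `p`, `p_bonferroni`.
#' @export
epoch_bootstrap_compare <- function(res_a, res_b, epochs = task_epochs(),
                                    n_reshuffle = 1000, seed = 1L) {
  stopifnot(inherits(res_a, "wm_decode"), inherits(res_b, "wm_decode"))
  if (res_a$n_perm != res_b$n_perm) {
    stop("permutation counts differ between the two results")
  }
  if (!identical(res_a$times, res_b$times)) {
    stop("mismatched time grids")
  }
  rng <- local_rng(seed)
  n <- res_a$n_perm
  purrr::map_dfr(seq_len(nrow(epochs)), function(e) {
    inw <- res_a$times >= epochs$lo_ms[e] & res_a$times < epochs$hi_ms[e]
    if (!any(inw)) {
      return(tibble::tibble(epoch = epochs$epoch[e], mean_a = NA_real_,
                            mean_b = NA_real_, higher = NA_character_,
                            p = NA_real_, p_bonferroni = NA_real_))
    }
    a <- rowMeans(res_a$accuracy[, inw, drop = FALSE])
    b <- rowMeans(res_b$accuracy[, inw, drop = FALSE])
    if (mean(a) >= mean(b)) {
      hi <- a; lo <- b; who <- "a"
    } else {
      hi <- b; lo <- a; who <- "b"
    }
    exceed <- vapply(seq_len(n_reshuffle), function(i) {
      mean(lo[rng$sample(seq_len(n))] > hi)
    }, numeric(1))
    p <- mean(exceed)
    tibble::tibble(epoch = epochs$epoch[e], mean_a = mean(a),
                   mean_b = mean(b), higher = who, p = p,
                   p_bonferroni = pmin(1, p * nrow(epochs)))
  })
}

#' Cross-temporal decoding surface
#'
#' For every permutation, a classifier trained at each training timepoint is
#' tested at every test timepoint, yielding a train x test accuracy surface.
#'
#' @inheritParams decode_timecourse
#' @param train_times,test_times Bin centres for the two axes (default: the
#'   `times` grid for both).
#' @return A `wm_xt`: accuracy array (`n_perm` x train x test) plus
#'   metadata.
#' @export
cross_temporal_decode <- function(session, feature, task_type = "SR",
                                  neurons = NULL,
                                  train_times = seq(50, 4800, by = 50),
                                  test_times = train_times,
                                  n_perm = 100, n_train = 1500,
                                  n_test = 100, var_kept = 0.90,
                                  seed = 1L) {
  feature <- match.arg(feature, DECODE_FEATURES)
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  in_task <- if (feature == "task_type") rep(TRUE, nrow(tr)) else
    tr$task_type == task_type
  correct_ids <- tr$trial_id[in_task & tr$outcome == "correct"]
  all_times <- sort(unique(c(train_times, test_times)))
  rates <- decode_rates(session, all_times, neurons, correct_ids)
  labels_all <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                               feature)
  chance <- 1 / length(unique(labels_all))
  tr_idx <- match(train_times, all_times)
  te_idx <- match(test_times, all_times)

  acc <- array(NA_real_, c(n_perm, length(train_times), length(test_times)))
  for (p in seq_len(n_perm)) {
    sp <- split_half(correct_ids, labels_all,
                     seed = substream_seed(seed, 2 * p))
    train <- build_pseudotrials(rates, labels_all, sp$train, n_train,
                                seed = substream_seed(seed, 2 * p + 1))
    test <- build_pseudotrials(rates, labels_all, sp$test, n_test,
                               seed = substream_seed(seed, 2 * p + 1) + 1L)
    for (i in seq_along(tr_idx)) {
      Xtr <- train$values[, , tr_idx[i]]
      ctr <- colMeans(Xtr)
      Xc <- sweep(Xtr, 2, ctr)
      eg <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      k <- which(cumsum(ev) / sum(ev) >= var_kept - 1e-12)[1]
      V <- eg$vectors[, seq_len(k), drop = FALSE]
      model <- pooled_lda(Xc %*% V, train$labels)
      for (j in seq_along(te_idx)) {
        ste <- sweep(test$values[, , te_idx[j]], 2, ctr) %*% V
        pred <- pooled_lda_predict(model, ste)
        acc[p, i, j] <- mean(pred == as.character(test$labels))
      }
    }
  }
  structure(list(accuracy = acc, train_times = train_times,
                 test_times = test_times, chance = chance,
                 feature = feature, task_type = task_type, n_perm = n_perm,
                 neurons = neurons),
            class = "wm_xt")
}

#' @export
print.wm_xt <- function(x, ...) {
  cat("<wm_xt> ", x$feature, " on ", x$task_type, "-trials: ", x$n_perm,
      " permutations, ", length(x$train_times), " x ", length(x$test_times),
      " surface; chance ", signif(100 * x$chance, 3), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.wm_xt <- function(x, ...) {
  m <- apply(x$accuracy, c(2, 3), mean)
  tibble::tibble(
    train_ms = rep(x$train_times, times = length(x$test_times)),
    test_ms = rep(x$test_times, each = length(x$train_times)),
    accuracy = as.vector(m)
  )
}

#' @export
autoplot.wm_xt <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$train_ms, y = .data$test_ms,
                                  fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "training time (ms)", y = "test time (ms)",
                  fill = "accuracy")
}

# Mean accuracy of T1-trained classifiers inside a (train window, test
# window) block, per permutation.
xt_block_means <- function(xt, train_win, test_win) {
  tr_in <- xt$train_times >= train_win[1] & xt$train_times < train_win[2]
  te_in <- xt$test_times >= test_win[1] & xt$test_times < test_win[2]
  if (!any(tr_in) || !any(te_in)) stop("window outside the decoded grid")
  apply(xt$accuracy[, tr_in, te_in, drop = FALSE], 1, mean)
}

#' Compare cross-temporal generalisation between two epochs
#'
#' Compares the accuracy of classifiers trained in one window and tested in
#' the same window against those trained there and tested in a second window
#' (e.g. T1T1 vs T1T2). Per permutation, accuracy is averaged within each
#' block; the paired difference distribution is significant when its 95th
#' percentile range (2.5th-97.5th) excludes zero.
#'
#' @param xt A `wm_xt`.
#' @param train_window Window name from [disruption_windows()] (or a numeric
#'   `c(lo, hi)`).
#' @param test_window Second window, same conventions.
#' @param task_type Task type for the named-window lookup.
#' @return One-row tibble with the block means, difference quantiles, and a
#'   significance flag.
#' @export
epoch_pair_compare <- function(xt, train_window = "T1", test_window = "T2",
                               task_type = xt$task_type) {
  wins <- disruption_windows(task_type)
  as_win <- function(w) {
    if (is.character(w)) {
      row <- wins[wins$window == w, ]
      if (nrow(row) == 0) stop("unknown epoch label: ", w)
      c(row$lo_ms, row$hi_ms)
    } else {
      w
    }
  }
  tw <- as_win(train_window)
  aw <- tw
  bw <- as_win(test_window)
  same <- xt_block_means(xt, tw, aw)
  cross <- xt_block_means(xt, tw, bw)
  d <- same - cross
  qs <- stats::quantile(d, c(0.025, 0.975))
  tibble::tibble(
    train_window = if (is.character(train_window)) train_window else "custom",
    test_window = if (is.character(test_window)) test_window else "custom",
    mean_same = mean(same), mean_cross = mean(cross),
    diff_lo = qs[[1]], diff_hi = qs[[2]],
    significant = qs[[1]] > 0 | qs[[2]] < 0
  )
}

#' Slope test for a decline of generalisation after the reward cue
#'
#' For classifiers trained in T1 (the final 500 ms of delay-one), the
#' accuracy timecourse (averaged over the T1-trained classifiers) is fitted
#' with a straight line within each analysis window, separately per
#' permutation. A window shows a significant change when the 95th percentile
#' range of the line gradients excludes zero.
#'
#' @param xt A `wm_xt` whose train axis covers T1 and whose test axis covers
#'   the requested windows.
#' @param windows Window names (default the three of
#'   [disruption_windows()]).
#' @param task_type Task type for the window lookup.
#' @return Tibble: window, mean gradient (accuracy per ms), 95% range,
#'   significance.
#' @export
decline_slope_test <- function(xt, windows = c("T1", "post_reward", "T2"),
                               task_type = xt$task_type) {
  wins <- disruption_windows(task_type)
  t1 <- wins[wins$window == "T1", ]
  tr_in <- xt$train_times >= t1$lo_ms & xt$train_times < t1$hi_ms
  if (!any(tr_in)) stop("train axis does not cover T1")
  # n_perm x test_times curve of T1-trained accuracy
  curve <- apply(xt$accuracy[, tr_in, , drop = FALSE], c(1, 3), mean)
  purrr::map_dfr(windows, function(w) {
    row <- wins[wins$window == w, ]
    if (nrow(row) == 0) stop("unknown window: ", w)
    te_in <- xt$test_times >= row$lo_ms & xt$test_times < row$hi_ms
    if (sum(te_in) < 2) stop("window '", w, "' covers fewer than 2 bins")
    tt <- xt$test_times[te_in]
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    slopes <- as.vector(curve[, te_in, drop = FALSE] %*% tc) / denom
    qs <- stats::quantile(slopes, c(0.025, 0.975))
    tibble::tibble(window = w, gradient = mean(slopes),
                   lo = qs[[1]], hi = qs[[2]],
                   significant = qs[[1]] > 0 | qs[[2]] < 0)
  })
}
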