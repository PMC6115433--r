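# Sliding per-neuron selectivity tests (rank-based), 1-D cluster permutation
# correction, ten-epoch selectivity/switching profiles, and two-way ANOVA
# mixed-selectivity classification. The Kruskal-Wallis statistic is computed
# in-package from ranks (chi-square approximation with tie correction)
# because ranks are invariant under label shuffles, which makes the
# permutation nulls cheap; stats::kruskal.test is the oracle in the tests.

# Kruskal-Wallis H (tie-corrected) and p for every column of a value matrix,
# given a group indicator matrix. Ranks and tie corrections are precomputed
# so permutations only change the indicator.
kw_precompute <- function(Y) {
  N <- nrow(Y)
  R <- apply(Y, 2, rank)
  tie_c <- apply(Y, 2, function(y) {
    t <- table(y)
    1 - sum(t^3 - t) / (N^3 - N)
  })
  list(R = R, tie_c = tie_c, N = N)
}

kw_stat <- function(pre, groups) {
  G <- stats::model.matrix(~ 0 + factor(groups))
  n_j <- colSums(G)
  S <- crossprod(G, pre$R)                       # groups x bins
  H <- 12 / (pre$N * (pre$N + 1)) * colSums(S^2 / n_j) - 3 * (pre$N + 1)
  H <- H / pre$tie_c
  df <- length(n_j) - 1
  p <- stats::pchisq(H, df = df, lower.tail = FALSE)
  # constant column across trials: no information, statistic 0 and p = 1
  flat <- !is.finite(H)
  H[flat] <- 0
  p[flat] <- 1
  list(statistic = H, p = p)
}

# Per-trial rate matrix (trials x bins) of one neuron.
neuron_rate_matrix <- function(session, neuron_id, trial_ids, times,
                               window_ms = 200) {
  rates <- estimate_rates(session, step_ms = times[2] - times[1],
                          window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = trial_ids, neurons = neuron_id)
  keep <- rates$bin_centres_ms %in% times
  m <- rates$values[1, , keep, drop = TRUE]
  matrix(m, nrow = length(trial_ids),
         dimnames = list(NULL, times[times %in% rates$bin_centres_ms[keep]]))
}

#' Sliding rank-based selectivity timecourse of one neuron
#'
#' A Kruskal-Wallis test across the feature's condition groups is run on the
#' per-trial rates at every bin (10 ms steps, 200 ms window by default).
#' Bins where all trials have identical values return statistic 0 and p = 1.
#'
#' @param session A `wm_session`.
#' @param neuron_id Neuron.
#' @param feature `"space8"`, `"space4"` or `"reward"`.
#' @param task_type Task type analysed.
#' @param times Bin centres (ms).
#' @param window_ms Rate window.
#' @return A `wm_selectivity` tibble: `time_ms`, `statistic`, `p`, with the
#'   inputs attached for the cluster permutation test.
#' @export
sliding_selectivity <- function(session, neuron_id, feature = "space8",
                                task_type = "SR",
                                times = seq(100, 4800, by = 10),
                                window_ms = 200) {
  tr <- session$trials
  ids <- tr$trial_id[tr$task_type == task_type & tr$outcome == "correct"]
  labels <- feature_labels(tr[match(ids, tr$trial_id), ], feature)
  if (min(table(labels)) < 2) stop("every condition needs at least 2 trials")
  Y <- neuron_rate_matrix(session, neuron_id, ids, times, window_ms)
  pre <- kw_precompute(Y)
  res <- kw_stat(pre, labels)
  out <- tibble::tibble(time_ms = times, statistic = res$statistic,
                        p = res$p)
  attr(out, "pre") <- pre
  attr(out, "labels") <- labels
  attr(out, "neuron_id") <- neuron_id
  attr(out, "feature") <- feature
  class(out) <- c("wm_selectivity", class(out))
  out
}

# Run lengths of TRUE within non-overlapping 500 ms windows (runs cannot
# bridge window boundaries); returns a tibble of runs or just lengths.
runs_in_windows <- function(sig, times) {
  win <- floor(times / 500)
  brk <- c(TRUE, diff(win) != 0)
  grp <- cumsum(brk)
  lens <- integer(0)
  starts <- integer(0)
  for (g in unique(grp)) {
    s <- sig[grp == g]
    r <- rle(s)
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1
      lens <- c(lens, r$lengths[r$values])
      starts <- c(starts, which(grp == g)[begs[r$values]])
    }
  }
  list(lengths = lens, starts = starts)
}

#' 1-D cluster permutation test of a selectivity timecourse
#'
#' Consecutive bins with uncorrected p below the forming threshold within
#' each non-overlapping 500 ms window are candidate clusters. The null
#' distribution of the maximum run length is built by shuffling the feature
#' labels across trials and recomputing the sliding test; a cluster is
#' significant when its length exceeds the 95th percentile of the null.
#'
#' @param tc A `wm_selectivity` from [sliding_selectivity()].
#' @param n_perm Number of label shuffles (a warning is recorded below 100).
#' @param alpha_form Cluster-forming threshold (default 0.05).
#' @param seed Seed.
#' @return A `wm_cluster_test` with cluster start times attached.
#' @export
cluster_test_1d <- function(tc, n_perm = 1000, alpha_form = 0.05,
                            seed = 1L) {
  stopifnot(inherits(tc, "wm_selectivity"))
  pre <- attr(tc, "pre")
  labels <- attr(tc, "labels")
  obs <- runs_in_windows(tc$p < alpha_form, tc$time_ms)
  rng <- local_rng(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    p_i <- kw_stat(pre, labels[rng$sample(seq_along(labels))])$p
    r <- runs_in_windows(p_i < alpha_form, tc$time_ms)
    if (length(r$lengths) == 0) 0L else max(r$lengths)
  }, integer(1))
  thr <- stats::quantile(null_max, 0.95)
  clusters <- if (length(obs$lengths) == 0) {
    tibble::tibble(start_ms = numeric(0), size = integer(0), p = numeric(0),
                   significant = logical(0))
  } else {
    ord <- order(obs$lengths, decreasing = TRUE)
    tibble::tibble(
      start_ms = tc$time_ms[obs$starts][ord],
      size = obs$lengths[ord],
      p = vapply(obs$lengths[ord], function(s) {
        (1 + sum(null_max >= s)) / (1 + n_perm)
      }, numeric(1)),
      significant = obs$lengths[ord] > thr
    )
  }
  structure(list(clusters = clusters, null_max = null_max,
                 alpha_form = alpha_form, tail = "one", n_perm = n_perm,
                 low_perm_warning = n_perm < 100),
            class = "wm_cluster_test")
}

#' Ten-epoch selectivity table and switching profile
#'
#' Splits the trial into ten consecutive 500 ms epochs from fixation onset
#' and runs a Kruskal-Wallis test on epoch-mean rates per neuron for both
#' spatial location and reward level. The switching profile follows the
#' neurons selective for the first-presented cue's feature during the
#' cue-one epoch and tracks, in every epoch, the fraction exclusively
#' space-selective, exclusively reward-selective, both, or neither.
#'
#' @param session A `wm_session`.
#' @param task_type Task type (`"SR"`: the first cue is spatial).
#' @param neurons Neuron ids (default all).
#' @param alpha Selectivity threshold (default 0.05).
#' @return List with `table` (neuron x epoch p-values and category) and
#'   `profile` (per-epoch category fractions of the first-cue-selective
#'   subset).
#' @export
epoch_selectivity <- function(session, task_type = "SR", neurons = NULL,
                              alpha = 0.05) {
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  ids <- tr$trial_id[tr$task_type == task_type & tr$outcome == "correct"]
  labs_s <- feature_labels(tr[match(ids, tr$trial_id), ], "space8")
  labs_r <- feature_labels(tr[match(ids, tr$trial_id), ], "reward")
  eps <- task_epochs()
  centres <- (eps$lo_ms + eps$hi_ms) / 2

  tab <- purrr::map_dfr(neurons, function(nid) {
    rates <- estimate_rates(session, step_ms = 500, window_ms = 500,
                            t_min = centres[1], t_max = centres[10],
                            trials = ids, neurons = nid)
    Y <- matrix(rates$values[1, , ], nrow = length(ids))
    pre <- kw_precompute(Y)
    ps <- kw_stat(pre, labs_s)$p
    pr <- kw_stat(pre, labs_r)$p
    tibble::tibble(neuron_id = nid, epoch = eps$epoch,
                   p_space = ps, p_reward = pr)
  })
  tab$category <- dplyr::case_when(
    tab$p_space < alpha & tab$p_reward < alpha ~ "both",
    tab$p_space < alpha ~ "space_only",
    tab$p_reward < alpha ~ "reward_only",
    TRUE ~ "neither"
  )

  first_feature <- if (task_type == "SR") "space" else "reward"
  cue1 <- tab[tab$epoch == "cue1", ]
  sel_ids <- if (first_feature == "space") {
    cue1$neuron_id[cue1$p_space < alpha]
  } else {
    cue1$neuron_id[cue1$p_reward < alpha]
  }
  sub <- tab[tab$neuron_id %in% sel_ids, ]
  profile <- purrr::map_dfr(eps$epoch, function(e) {
    se <- sub[sub$epoch == e, ]
    n <- max(nrow(se), 1L)
    tibble::tibble(
      epoch = e,
      n_selected = nrow(se),
      frac_space_only = sum(se$category == "space_only") / n,
      frac_reward_only = sum(se$category == "reward_only") / n,
      frac_both = sum(se$category == "both") / n,
      frac_neither = sum(se$category == "neither") / n
    )
  })
  list(table = tab, profile = profile,
       first_cue_selective = sel_ids, first_feature = first_feature)
}

# Type-II two-way F statistics for every column of Y, given factors A and B.
# Projection (QR) matrices are precomputed once; vectorised over bins.
two_way_F <- function(Y, A, B) {
  A <- factor(A)
  B <- factor(B)
  qa <- qr.Q(qr(stats::model.matrix(~A)))
  qb <- qr.Q(qr(stats::model.matrix(~B)))
  qab <- qr.Q(qr(stats::model.matrix(~ A + B)))
  qfull <- qr.Q(qr(stats::model.matrix(~ A * B)))
  rss <- function(Q) colSums((Y - Q %*% crossprod(Q, Y))^2)
  rss_a <- rss(qa)
  rss_b <- rss(qb)
  rss_ab <- rss(qab)
  rss_full <- rss(qfull)
  df_a <- nlevels(A) - 1
  df_b <- nlevels(B) - 1
  df_int <- ncol(qfull) - ncol(qab)
  df_res <- nrow(Y) - ncol(qfull)
  mse <- rss_full / df_res
  safe_F <- function(ss, df) {
    f <- (ss / df) / mse
    f[!is.finite(f) | f < 0] <- 0
    f
  }
  F_a <- safe_F(rss_b - rss_ab, df_a)
  F_b <- safe_F(rss_a - rss_ab, df_b)
  F_int <- safe_F(rss_ab - rss_full, df_int)
  tibble::tibble(
    F_space = F_a, F_reward = F_b, F_interaction = F_int,
    p_space = stats::pf(F_a, df_a, df_res, lower.tail = FALSE),
    p_reward = stats::pf(F_b, df_b, df_res, lower.tail = FALSE),
    p_interaction = stats::pf(F_int, df_int, df_res, lower.tail = FALSE)
  )
}

#' Two-way ANOVA mixed-selectivity classification of one neuron
#'
#' Fits a two-way fixed-effects ANOVA (spatial location group x reward
#' level, type-II sums of squares) on epoch-mean rates and classifies the
#' neuron: `space` / `reward` (one significant main effect, no interaction),
#' `linear_mixed` (both main effects, no interaction), `nonlinear_mixed`
#' (both main effects plus interaction), `non_selective` (nothing), else
#' `unclassified`.
#'
#' @param session A `wm_session`.
#' @param neuron_id Neuron.
#' @param task_type Task type.
#' @param window Epoch window `c(lo, hi)` ms; default the second-cue period.
#' @param alpha Significance threshold (default 0.05).
#' @return One-row tibble with F statistics, p-values and `class`.
#' @export
anova_classify <- function(session, neuron_id, task_type = "SR",
                           window = c(2500, 3000), alpha = 0.05) {
  tr <- session$trials
  ids <- tr$trial_id[tr$task_type == task_type & tr$outcome == "correct"]
  sel <- tr[match(ids, tr$trial_id), ]
  if (min(table(sel$location8, sel$reward_level)) < 1) {
    stop("empty cell in the space x reward design")
  }
  centre <- mean(window)
  rates <- estimate_rates(session, step_ms = diff(window),
                          window_ms = diff(window),
                          t_min = centre, t_max = centre,
                          trials = ids, neurons = neuron_id)
  y <- matrix(rates$values[1, , 1], ncol = 1)
  res <- two_way_F(y, sel$location8, sel$reward_level)
  cls <- classify_anova_row(res, alpha)
  dplyr::bind_cols(tibble::tibble(neuron_id = neuron_id), res,
                   tibble::tibble(class = cls))
}

classify_anova_row <- function(res, alpha = 0.05) {
  s <- res$p_space < alpha
  r <- res$p_reward < alpha
  i <- res$p_interaction < alpha
  dplyr::case_when(
    s & r & i ~ "nonlinear_mixed",
    s & r & !i ~ "linear_mixed",
    s & !r & !i ~ "space",
    !s & r & !i ~ "reward",
    !s & !r & !i ~ "non_selective",
    TRUE ~ "unclassified"
  )
}

#' Sliding two-way ANOVA F-statistic maps for a population
#'
#' @param session A `wm_session`.
#' @param neurons Neuron ids (default all).
#' @param task_type Task type.
#' @param times Bin centres (ms).
#' @param window_ms Rate window.
#' @return Tibble: `neuron_id`, `time_ms`, F statistics and p-values per
#'   factor and interaction.
#' @export
sliding_anova <- function(session, neurons = NULL, task_type = "SR",
                          times = seq(100, 4800, by = 10),
                          window_ms = 200) {
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  ids <- tr$trial_id[tr$task_type == task_type & tr$outcome == "correct"]
  sel <- tr[match(ids, tr$trial_id), ]
  purrr::map_dfr(neurons, function(nid) {
    Y <- neuron_rate_matrix(session, nid, ids, times, window_ms)
    res <- two_way_F(Y, sel$location8, sel$reward_level)
    dplyr::bind_cols(tibble::tibble(neuron_id = nid, time_ms = times), res)
  })
}

#' Rank correlation between spatial and reward selectivity strengths
#'
#' At each bin, the across-neuron Spearman correlation between the spatial
#' and reward F-statistics is computed; a positive correlation at the time
#' of the second cue indicates that the same neurons carry both effects
#' (linear mixed selectivity). A single whole-epoch correlation over the
#' second-cue period complements the sliding version.
#'
#' @param f_map Output of [sliding_anova()] (needs `neuron_id`, `time_ms`,
#'   `F_space`, `F_reward`).
#' @param cue2_window Window `c(lo, hi)` for the single-epoch correlation.
#' @param session,task_type Session and task type used for the single-epoch
#'   ANOVA (whole-window spike counts); omit `session` to skip it.
#' @param neurons Neuron ids for the single-epoch ANOVA.
#' @return List with `timecourse` (tibble `time_ms`, `rho`, `n_neurons`) and
#'   `cue2` (single-epoch Spearman r, or `NULL`).
#' @export
sliding_F_correlation <- function(f_map, cue2_window = c(2500, 3000),
                                  session = NULL, task_type = "SR",
                                  neurons = NULL) {
  n_neu <- length(unique(f_map$neuron_id))
  if (n_neu < 4) stop("at least 4 neurons are required")
  tcs <- f_map |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(
      rho = stats::cor(.data$F_space, .data$F_reward, method = "spearman"),
      n_neurons = dplyr::n(), .groups = "drop")
  cue2 <- NULL
  if (!is.null(session)) {
    if (is.null(neurons)) neurons <- unique(f_map$neuron_id)
    av <- purrr::map_dfr(neurons, function(nid) {
      anova_classify(session, nid, task_type, window = cue2_window)
    })
    cue2 <- list(
      r = stats::cor(av$F_space, av$F_reward, method = "spearman"),
      table = av
    )
  }
  list(timecourse = tcs, cue2 = cue2)
}
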