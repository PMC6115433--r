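# Correlation-based decoder on pairwise condition differences (PWDs).
# Correlating PWDs across neurons between independent data halves measures
# tuning similarity; negative values indicate tuning reversal, which an
# accuracy-based classifier can only show weakly below chance. Includes both
# cluster-based permutation tests (vs chance, and between groups).

#' Pairwise condition differences of trial-averaged firing
#'
#' For each neuron and timepoint, firing rate is averaged across the trials
#' of each condition in the chosen half; all unordered condition pairs are
#' differenced with the canonical orientation (lower condition index minus
#' higher). 8 conditions yield 28 PWDs, 5 yield 10, 2 yield 1.
#'
#' @param rates A `wm_rates` (raw Hz; additive per-neuron offsets cancel
#'   within PWDs).
#' @param labels Condition label per trial of `rates`.
#' @param half Trial ids forming this half.
#' @return A `wm_pwd`: array `values` (pairs x neurons x timepoints), the
#'   pair table, times and neuron ids.
#' @export
condition_pwds <- function(rates, labels, half) {
  stopifnot(inherits(rates, "wm_rates"))
  idx <- match(half, rates$trial_ids)
  if (anyNA(idx)) stop("half contains trial ids absent from rates")
  lab <- labels[idx]
  conds <- sort(unique(labels))
  missing <- setdiff(conds, lab)
  if (length(missing) > 0) stop("condition missing from half: ", missing[1])
  d <- dim(rates$values)
  n_cond <- length(conds)
  # condition means: cond x neurons x time
  cm <- array(NA_real_, c(n_cond, d[1], d[3]))
  for (ci in seq_len(n_cond)) {
    sel <- idx[lab == conds[ci]]
    sub <- rates$values[, sel, , drop = FALSE]
    cm[ci, , ] <- apply(sub, c(1, 3), function(v) mean(v, na.rm = TRUE))
  }
  pairs <- utils::combn(n_cond, 2)
  values <- cm[pairs[1, ], , , drop = FALSE] -
    cm[pairs[2, ], , , drop = FALSE]
  structure(list(values = values,
                 pairs = tibble::tibble(cond_a = conds[pairs[1, ]],
                                        cond_b = conds[pairs[2, ]]),
                 bin_centres_ms = rates$bin_centres_ms,
                 neuron_ids = rates$neuron_ids),
            class = "wm_pwd")
}

#' @export
print.wm_pwd <- function(x, ...) {
  cat("<wm_pwd> ", nrow(x$pairs), " condition pairs x ",
      length(x$neuron_ids), " neurons x ", length(x$bin_centres_ms),
      " timepoints\n", sep = "")
  invisible(x)
}

# Clamp correlations away from +-1 before Fisher transforming.
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Fisher-averaged PWD correlation between two sets at one timepoint pair
#'
#' Each PWD is correlated (Pearson, across neurons) between the training and
#' test sets; coefficients are averaged via Fisher's z-transformation. Pairs
#' with zero variance in either set are dropped; if all pairs drop, `NA` is
#' returned.
#'
#' @param train,test Numeric matrices, pairs x neurons (a `wm_pwd` slice at
#'   one timepoint).
#' @return A single correlation coefficient.
#' @export
discriminability <- function(train, test) {
  stopifnot(nrow(train) == nrow(test), ncol(train) == ncol(test))
  if (ncol(train) < 3) stop("at least 3 neurons are required")
  z <- vapply(seq_len(nrow(train)), function(p) {
    a <- train[p, ]
    b <- test[p, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    fisher_z(stats::cor(a, b))
  }, numeric(1))
  if (all(is.na(z))) return(NA_real_)
  tanh(mean(z, na.rm = TRUE))
}

# Standardise a pairs x neurons x time PWD array across neurons so that
# crossprod of time-slices gives Pearson correlations directly. Columns with
# zero variance become NA. Vectorised over (pair, time) columns -- this sits
# inside the permutation nulls.
pwd_standardise <- function(arr) {
  d <- dim(arr)
  m <- aperm(arr, c(2, 1, 3))              # neurons x pairs x time
  dim(m) <- c(d[2], d[1] * d[3])
  mc <- m - rep(.colMeans(m, d[2], ncol(m)), each = d[2])
  ss <- sqrt(.colSums(mc^2, d[2], ncol(mc)))
  ss[ss == 0] <- NA_real_
  mc <- mc / rep(ss, each = d[2])
  dim(mc) <- c(d[2], d[1], d[3])
  aperm(mc, c(2, 1, 3))
}

# Fisher-averaged correlation matrix (train times x test times) from two
# standardised PWD arrays; optional neuron permutation per pair of the test
# array (the vs-chance null). The mild shrink before atanh replaces interval
# clamping: it only matters at |r| = 1 (self-correlation), where it yields a
# large finite z instead of Inf.
pwd_corr_matrix <- function(std_train, std_test, perm = NULL) {
  d <- dim(std_train)
  n_pairs <- d[1]
  nt <- d[3]
  nt2 <- dim(std_test)[3]
  rall <- array(NA_real_, c(nt, nt2, n_pairs))
  for (p in seq_len(n_pairs)) {
    A <- matrix(std_train[p, , ], d[2], nt)
    B <- matrix(std_test[p, , ], d[2], nt2)
    if (!is.null(perm)) B <- B[perm[[p]], , drop = FALSE]
    rall[, , p] <- crossprod(A, B)
  }
  z <- atanh(rall * (1 - 1e-12))
  ok <- is.finite(z)
  z[!ok] <- 0
  zcnt <- rowSums(ok, dims = 2)
  zcnt[zcnt == 0] <- NA_real_
  tanh(rowSums(z, dims = 2) / zcnt)
}

#' Cross-temporal PWD discriminability surface
#'
#' Computes the Fisher-averaged PWD correlation between a training and a test
#' data source at every timepoint pair. Sources are either the two stratified
#' halves of one task type's correct trials (within-task) or the two task
#' types (cross-task generalisation: train on SR, test on RS). When
#' `symmetrise = TRUE` (within-task, square grids) the matrix is averaged
#' across the diagonal via Fisher's z so it reflects both
#' training-to-test and test-to-training projections.
#'
#' @param session A `wm_session`.
#' @param feature `"space8"`, `"space4"` or `"reward"`.
#' @param neurons Population neuron ids (default all).
#' @param train,test `"half1"`/`"half2"` (split halves of `task_type`'s
#'   correct trials) or `"SR"`/`"RS"` (cross-task).
#' @param task_type Task type for the within-task configuration.
#' @param times Bin centres (ms); default 10 ms grid.
#' @param window_ms Rate window (default 200 ms).
#' @param symmetrise Average across the diagonal.
#' @param seed Seed for the split half.
#' @return A `wm_discrim`: matrix `r` (train x test times), the standardised
#'   PWD arrays (kept for the cluster-test nulls), and metadata.
#' @export
crosstemporal_discriminability <- function(session, feature = "space8",
                                           neurons = NULL,
                                           train = "half1", test = "half2",
                                           task_type = "SR",
                                           times = seq(100, 4800, by = 10),
                                           window_ms = 200,
                                           symmetrise = FALSE, seed = 1L) {
  feature <- match.arg(feature, c("space8", "space4", "reward"))
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  if (length(neurons) < 3) stop("at least 3 neurons are required")
  tr <- session$trials
  sources <- c(train, test)
  if (all(sources %in% c("SR", "RS"))) {
    if (train == test) stop("train and test must use disjoint trials")
    ids <- lapply(sources, function(tt) {
      tr$trial_id[tr$task_type == tt & tr$outcome == "correct"]
    })
  } else if (all(sources %in% c("half1", "half2"))) {
    if (train == test) stop("train and test must use disjoint trials")
    correct <- tr$trial_id[tr$task_type == task_type &
                             tr$outcome == "correct"]
    lab <- feature_labels(tr[match(correct, tr$trial_id), ], feature)
    sp <- split_half(correct, lab, seed = seed)
    ids <- list(half1 = sp$train, half2 = sp$test)[sources]
  } else {
    stop("train/test must both be halves or both be task types")
  }

  all_ids <- unlist(ids, use.names = FALSE)
  rates <- estimate_rates(session, step_ms = 10, window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = all_ids, neurons = neurons)
  keep <- rates$bin_centres_ms %in% times
  rates$values <- rates$values[, , keep, drop = FALSE]
  rates$bin_centres_ms <- rates$bin_centres_ms[keep]
  labels <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                           feature)

  pwd_train <- condition_pwds(rates, labels, ids[[1]])
  pwd_test <- condition_pwds(rates, labels, ids[[2]])
  std_train <- pwd_standardise(pwd_train$values)
  std_test <- pwd_standardise(pwd_test$values)
  r <- pwd_corr_matrix(std_train, std_test)
  if (symmetrise) {
    if (!identical(dim(r)[1], dim(r)[2])) {
      stop("symmetrisation needs a square time grid")
    }
    z <- fisher_z(r)
    r <- tanh((z + t(z)) / 2)
  }
  structure(list(r = r, times = times, feature = feature,
                 train = train, test = test, task_type = task_type,
                 symmetrised = symmetrise,
                 n_neurons = length(neurons),
                 std_train = std_train, std_test = std_test),
            class = "wm_discrim")
}

#' @export
print.wm_discrim <- function(x, ...) {
  cat("<wm_discrim> ", x$feature, ", train ", x$train, " -> test ", x$test,
      ", ", nrow(x$r), " x ", ncol(x$r), " surface over ", x$n_neurons,
      " neurons", if (x$symmetrised) ", symmetrised", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.wm_discrim <- function(x, ...) {
  tibble::tibble(
    train_ms = rep(x$times, times = ncol(x$r)),
    test_ms = rep(x$times, each = nrow(x$r)),
    r = as.vector(x$r)
  )
}

#' @export
autoplot.wm_discrim <- function(object, ...) {
  d <- tidy(object)
  lim <- max(abs(d$r), na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$train_ms, y = .data$test_ms,
                                  fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick",
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "training time (ms)", y = "test time (ms)",
                  fill = "discriminability")
}

#' Task-type (SR vs RS) discriminability timecourse
#'
#' All correct trials are split into halves stratified by task type; within
#' each half the single PWD (SR mean minus RS mean, per neuron) is computed
#' and correlated across neurons between the halves at each matched
#' timepoint.
#'
#' @param session A `wm_session`.
#' @param neurons Population neuron ids.
#' @param times Bin centres (ms).
#' @param window_ms Rate window.
#' @param seed Split seed.
#' @return Tibble: `time_ms`, `r`.
#' @export
task_type_discriminability <- function(session, neurons = NULL,
                                       times = seq(100, 4800, by = 10),
                                       window_ms = 200, seed = 1L) {
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  correct <- tr$trial_id[tr$outcome == "correct"]
  lab <- tr$task_type[match(correct, tr$trial_id)]
  sp <- split_half(correct, lab, seed = seed)
  rates <- estimate_rates(session, step_ms = 10, window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = correct, neurons = neurons)
  keep <- rates$bin_centres_ms %in% times
  rates$values <- rates$values[, , keep, drop = FALSE]
  rates$bin_centres_ms <- rates$bin_centres_ms[keep]
  labels <- tr$task_type[match(rates$trial_ids, tr$trial_id)]
  pwd1 <- condition_pwds(rates, labels, sp$train)
  pwd2 <- condition_pwds(rates, labels, sp$test)
  r <- vapply(seq_along(times), function(ti) {
    a <- pwd1$values[1, , ti]
    b <- pwd2$values[1, , ti]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  tibble::tibble(time_ms = times, r = r)
}

# --- cluster machinery -----------------------------------------------------

# Connected-component labels of a logical matrix under 4-connectivity, by
# iterative label propagation (fast for the sparse masks the nulls produce).
connected_labels <- function(mask) {
  ids <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (!any(mask)) return(ids)
  ids[mask] <- seq_len(sum(mask))
  repeat {
    nb <- ids
    nr <- nrow(ids)
    nc <- ncol(ids)
    if (nr > 1) {
      nb[-1, ] <- pmin(nb[-1, ], ids[-nr, ], na.rm = TRUE)
      nb[-nr, ] <- pmin(nb[-nr, ], ids[-1, ], na.rm = TRUE)
    }
    if (nc > 1) {
      nb[, -1] <- pmin(nb[, -1], ids[, -nc], na.rm = TRUE)
      nb[, -nc] <- pmin(nb[, -nc], ids[, -1], na.rm = TRUE)
    }
    nb[!mask] <- NA_real_
    if (identical(nb, ids)) break
    ids <- nb
  }
  ids
}

connected_sizes <- function(mask) {
  ids <- connected_labels(mask)
  if (!any(mask)) return(integer(0))
  as.integer(table(ids[mask]))
}

# Cluster sizes within the non-overlapping window grid (windows cannot be
# bridged), split by the sign of the statistic when `sign_mat` is given.
# With `details = TRUE`, also returns each cluster's sign and pixel-index
# bounding box (used for the observed clusters; nulls only need sizes).
cluster_sizes_in_grid <- function(mask, win_row, win_col, sign_mat = NULL,
                                  details = FALSE) {
  sizes <- integer(0)
  det <- list()
  for (wr in unique(win_row)) {
    for (wc in unique(win_col)) {
      ri <- which(win_row == wr)
      ci <- which(win_col == wc)
      sub <- mask[ri, ci, drop = FALSE]
      if (!any(sub)) next
      parts <- if (is.null(sign_mat)) {
        list(pos = sub)
      } else {
        sg <- sign_mat[ri, ci, drop = FALSE]
        list(pos = sub & sg > 0, neg = sub & sg < 0)
      }
      for (nm in names(parts)) {
        m <- parts[[nm]]
        if (!any(m)) next
        ids <- connected_labels(m)
        for (lab in unique(ids[m])) {
          px <- which(ids == lab, arr.ind = TRUE)
          sizes <- c(sizes, nrow(px))
          if (details) {
            det[[length(det) + 1]] <- tibble::tibble(
              size = nrow(px),
              sign = if (nm == "neg") -1 else 1,
              row_min = ri[min(px[, 1])], row_max = ri[max(px[, 1])],
              col_min = ci[min(px[, 2])], col_max = ci[max(px[, 2])])
          }
        }
      }
    }
  }
  if (details) {
    if (length(det) == 0) {
      return(tibble::tibble(size = integer(0), sign = numeric(0),
                            row_min = integer(0), row_max = integer(0),
                            col_min = integer(0), col_max = integer(0)))
    }
    return(dplyr::bind_rows(det))
  }
  sizes
}

# p-value of a correlation under the t-distribution null, df = n - 2.
corr_pvalue <- function(r, n, tail = c("two", "greater")) {
  tail <- match.arg(tail)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  if (tail == "two") {
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
}

#' Cluster-based permutation test of a discriminability surface vs chance
#'
#' Pixels with an uncorrected correlation p below the cluster-forming
#' threshold (two-tailed, df = neurons - 2) are candidate-cluster members;
#' neighbouring pixels (4-connectivity, same sign) within each non-overlapping
#' 500 x 500 ms window form candidate clusters. The null distribution of the
#' maximum cluster size is built by shuffling the order of neurons
#' independently within each PWD of the test set and recomputing the surface.
#' Cluster p-values use the `(1 + exceedances) / (1 + n_perm)` convention.
#'
#' @param mat A `wm_discrim` from [crosstemporal_discriminability()].
#' @param n_perm Number of permutations (a warning is recorded below 100).
#' @param alpha_form Cluster-forming threshold (default 0.01 two-tailed).
#' @param seed Seed.
#' @return A `wm_cluster_test`: cluster table, null distribution, and
#'   settings.
#' @export
cluster_test_vs_chance <- function(mat, n_perm = 1000, alpha_form = 0.01,
                                   seed = 1L) {
  stopifnot(inherits(mat, "wm_discrim"))
  n <- mat$n_neurons
  warning_low <- n_perm < 100
  win_row <- floor(mat$times[seq_len(nrow(mat$r))] / 500)
  win_col <- floor(mat$times[seq_len(ncol(mat$r))] / 500)

  p_pix <- corr_pvalue(mat$r, n)
  mask <- !is.na(p_pix) & p_pix < alpha_form
  obs <- cluster_sizes_in_grid(mask, win_row, win_col, mat$r,
                               details = TRUE)

  n_pairs <- dim(mat$std_test)[1]
  rng <- local_rng(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    perm <- rng$run(function() {
      lapply(seq_len(n_pairs), function(p) sample.int(n))
    })
    r_p <- pwd_corr_matrix(mat$std_train, mat$std_test, perm = perm)
    if (mat$symmetrised) {
      z <- fisher_z(r_p)
      r_p <- tanh((z + t(z)) / 2)
    }
    p_p <- corr_pvalue(r_p, n)
    m_p <- !is.na(p_p) & p_p < alpha_form
    s <- cluster_sizes_in_grid(m_p, win_row, win_col, r_p)
    if (length(s) == 0) 0L else max(s)
  }, integer(1))

  obs <- obs[order(obs$size, decreasing = TRUE), ]
  obs$p <- vapply(obs$size, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  obs$train_from_ms <- mat$times[obs$row_min]
  obs$train_to_ms <- mat$times[obs$row_max]
  obs$test_from_ms <- mat$times[obs$col_min]
  obs$test_to_ms <- mat$times[obs$col_max]
  structure(list(clusters = obs, null_max = null_max,
                 alpha_form = alpha_form, tail = "two",
                 n_perm = n_perm, low_perm_warning = warning_low),
            class = "wm_cluster_test")
}

#' @export
print.wm_cluster_test <- function(x, ...) {
  cat("<wm_cluster_test> ", nrow(x$clusters), " candidate cluster(s), ",
      x$n_perm, " permutations (", x$tail, "-tailed, forming p < ",
      x$alpha_form, ")\n", sep = "")
  if (nrow(x$clusters) > 0) {
    print(utils::head(x$clusters, 5))
  }
  if (x$low_perm_warning) cat("  note: n_perm < 100\n")
  invisible(x)
}

#' Cluster-based comparison of discriminability between two neuron groups
#'
#' Computes, at every pixel, the two-correlation Fisher-z statistic
#' `z = (atanh rA - atanh rB) / sqrt(1/(nA-3) + 1/(nB-3))` between the
#' surfaces of two subpopulations (e.g. high- vs low-tau). Candidate clusters
#' form where the one-tailed p (group A above group B) is below the forming
#' threshold, within the 10 x 10 grid of non-overlapping 500 ms windows. The
#' null permutes the neuron-to-group assignment and recomputes both surfaces.
#'
#' @param train_pwds,test_pwds `wm_pwd` objects over the *combined*
#'   population (same neurons in both).
#' @param groups Factor/character vector over the combined neurons with two
#'   levels; the first level is group A.
#' @param n_perm Permutations (the reference analysis uses 10,000; reduced
#'   counts are recorded in the result).
#' @param alpha_form Cluster-forming threshold (default 0.05, one-tailed).
#' @param times Bin centres of the PWD arrays (defaults to those stored).
#' @param seed Seed.
#' @return A `wm_cluster_test` with the observed statistic map attached.
#' @export
cluster_test_between_groups <- function(train_pwds, test_pwds, groups,
                                        n_perm = 1000, alpha_form = 0.05,
                                        times = NULL, seed = 1L) {
  stopifnot(inherits(train_pwds, "wm_pwd"), inherits(test_pwds, "wm_pwd"))
  groups <- as.character(groups)
  lev <- sort(unique(groups))       # first sorted level is group A
  if (length(lev) != 2) stop("groups must have exactly 2 levels")
  nA <- sum(groups == lev[1])
  nB <- sum(groups == lev[2])
  if (nA < 4 || nB < 4) stop("each group needs at least 4 neurons")
  if (is.null(times)) times <- train_pwds$bin_centres_ms
  win_row <- floor(times / 500)
  win_col <- win_row

  zstat_for <- function(assign) {
    a <- assign == lev[1]
    rA <- pwd_corr_matrix(pwd_standardise(train_pwds$values[, a, ,
                                                            drop = FALSE]),
                          pwd_standardise(test_pwds$values[, a, ,
                                                           drop = FALSE]))
    rB <- pwd_corr_matrix(pwd_standardise(train_pwds$values[, !a, ,
                                                            drop = FALSE]),
                          pwd_standardise(test_pwds$values[, !a, ,
                                                           drop = FALSE]))
    (fisher_z(rA) - fisher_z(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  }

  z_obs <- zstat_for(groups)
  p_obs <- stats::pnorm(z_obs, lower.tail = FALSE)
  mask <- !is.na(p_obs) & p_obs < alpha_form
  obs <- cluster_sizes_in_grid(mask, win_row, win_col, details = TRUE)

  rng <- local_rng(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    z_p <- zstat_for(groups[rng$sample(seq_along(groups))])
    p_p <- stats::pnorm(z_p, lower.tail = FALSE)
    m_p <- !is.na(p_p) & p_p < alpha_form
    s <- cluster_sizes_in_grid(m_p, win_row, win_col)
    if (length(s) == 0) 0L else max(s)
  }, integer(1))

  obs <- obs[order(obs$size, decreasing = TRUE), ]
  obs$p <- vapply(obs$size, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  obs$train_from_ms <- times[obs$row_min]
  obs$train_to_ms <- times[obs$row_max]
  obs$test_from_ms <- times[obs$col_min]
  obs$test_to_ms <- times[obs$col_max]
  structure(list(clusters = obs, null_max = null_max,
                 alpha_form = alpha_form, tail = "one",
                 n_perm = n_perm, low_perm_warning = n_perm < 100,
                 z = z_obs),
            class = "wm_cluster_test")
}
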