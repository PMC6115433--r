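# Across-trial within-condition correlation (raw and demeaned) and the state
# space analysis: epoch-defined principal subspaces over condition-averaged
# activity, trajectory projection, and the stimulus variance (SV) a subspace
# captures over time, SV = Tr(S_k' C_t S_k).

# Condition-mean firing per neuron per timepoint over a set of trials:
# conditions x neurons x time.
condition_mean_array <- function(rates, labels, trial_ids) {
  idx <- match(trial_ids, rates$trial_ids)
  if (anyNA(idx)) stop("trial ids absent from rates")
  lab <- labels[idx]
  conds <- sort(unique(labels))
  d <- dim(rates$values)
  cm <- array(NA_real_, c(length(conds), d[1], d[3]),
              dimnames = list(conds, NULL, NULL))
  for (ci in seq_along(conds)) {
    sel <- idx[lab == conds[ci]]
    if (length(sel) == 0) stop("condition missing from half: ", conds[ci])
    cm[ci, , ] <- apply(rates$values[, sel, , drop = FALSE], c(1, 3),
                        function(v) mean(v, na.rm = TRUE))
  }
  cm
}

# Subtract, per neuron and timepoint, the across-condition mean.
demean_conditions <- function(cm) {
  mu <- apply(cm, c(2, 3), mean)
  sweep(cm, c(2, 3), mu)
}

#' Within-condition correlation of population activity across time
#'
#' For each condition, the across-neuron vector of condition-mean firing in
#' the training half at time t is correlated with the test half's vector at
#' time t'; coefficients are Fisher-z averaged over conditions. With
#' `demean = TRUE` the per-neuron across-condition mean is removed at every
#' timepoint within each half first, isolating tuning structure: a
#' population with shared baseline modulation but sign-flipped tuning shows
#' positive raw correlation but negative demeaned correlation between cue
#' and delay.
#'
#' @param session A `wm_session`.
#' @param features Features whose condition sets are pooled (default the
#'   eight collapsed locations and five reward levels, i.e. 13 conditions).
#' @param neurons Population neuron ids.
#' @param task_type Task type analysed.
#' @param times Bin centres (ms).
#' @param window_ms Rate window.
#' @param demean Remove per-neuron across-condition means first.
#' @param seed Split-half seed.
#' @return A `wm_discrim`-like object of class `wm_timecorr` with matrix `r`.
#' @export
across_time_condition_correlation <- function(session,
                                              features = c("space8",
                                                           "reward"),
                                              neurons = NULL,
                                              task_type = "SR",
                                              times = seq(100, 4800,
                                                          by = 10),
                                              window_ms = 200,
                                              demean = FALSE, seed = 1L) {
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  correct <- tr$trial_id[tr$task_type == task_type &
                           tr$outcome == "correct"]
  strat <- interaction(tr$location8[match(correct, tr$trial_id)],
                       tr$reward_level[match(correct, tr$trial_id)],
                       drop = TRUE)
  sp <- split_half(correct, strat, seed = seed)
  rates <- estimate_rates(session, step_ms = 10, window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = correct, neurons = neurons)
  keep <- rates$bin_centres_ms %in% times
  rates$values <- rates$values[, , keep, drop = FALSE]
  rates$bin_centres_ms <- rates$bin_centres_ms[keep]

  zsum <- matrix(0, length(times), length(times))
  zcnt <- matrix(0, length(times), length(times))
  for (f in features) {
    labels <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ], f)
    cm1 <- condition_mean_array(rates, labels, sp$train)
    cm2 <- condition_mean_array(rates, labels, sp$test)
    if (demean) {
      cm1 <- demean_conditions(cm1)
      cm2 <- demean_conditions(cm2)
    }
    for (ci in seq_len(dim(cm1)[1])) {
      a <- cm1[ci, , ]            # neurons x time
      b <- cm2[ci, , ]
      a <- sweep(a, 2, colMeans(a))
      b <- sweep(b, 2, colMeans(b))
      sa <- sqrt(colSums(a^2))
      sb <- sqrt(colSums(b^2))
      sa[sa == 0] <- NA_real_
      sb[sb == 0] <- NA_real_
      r <- crossprod(sweep(a, 2, sa, "/"), sweep(b, 2, sb, "/"))
      z <- fisher_z(r)
      ok <- is.finite(z)
      z[!ok] <- 0
      zsum <- zsum + z
      zcnt <- zcnt + ok
    }
  }
  zcnt[zcnt == 0] <- NA_real_
  structure(list(r = tanh(zsum / zcnt), times = times,
                 features = features, task_type = task_type,
                 demeaned = demean, n_neurons = length(neurons)),
            class = "wm_timecorr")
}

#' @export
print.wm_timecorr <- function(x, ...) {
  cat("<wm_timecorr> ", paste(x$features, collapse = "+"), " conditions, ",
      if (x$demeaned) "demeaned, " else "raw, ",
      nrow(x$r), " x ", ncol(x$r), " surface\n", sep = "")
  invisible(x)
}

#' @export
autoplot.wm_timecorr <- function(object, ...) {
  d <- tibble::tibble(
    train_ms = rep(object$times, times = ncol(object$r)),
    test_ms = rep(object$times, each = nrow(object$r)),
    r = as.vector(object$r))
  lim <- max(abs(d$r), na.rm = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$train_ms, y = .data$test_ms,
                                  fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick",
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "train time (ms)", y = "test time (ms)", fill = "r")
}

# Named subspace epochs, ms from fixation onset (cue onset = 1000 ms).
subspace_epoch_window <- function(epoch) {
  switch(epoch,
         fixation = c(0, 1000),
         delay1 = c(1500, 2500),
         stop("unknown epoch: ", epoch))
}

#' Define a mnemonic subspace from condition-averaged training activity
#'
#' Builds the conditions x neurons matrix of training-half condition means
#' (time-averaged over the named epoch, or per-timepoint for the dynamic
#' subspace), demeans it across conditions per neuron, and extracts the
#' leading principal axes over conditions. By default one fewer axis than
#' conditions is retained (space: k = 7, reward: k = 4).
#'
#' @param session A `wm_session`.
#' @param feature `"space8"` or `"reward"`.
#' @param epoch `"fixation"` (the 1000 ms before cue onset), `"delay1"`
#'   (500-1500 ms after cue onset) or `"dynamic"` (one subspace per
#'   timepoint).
#' @param neurons Population neuron ids.
#' @param task_type Task type analysed.
#' @param half Trial ids of the training half (from [split_half()]).
#' @param k Number of axes (default: conditions - 1).
#' @param times Bin grid used for the dynamic subspace and projections.
#' @param window_ms Rate window.
#' @return A `wm_subspace`: orthonormal axes (neurons x k; a list over time
#'   for the dynamic variant), singular values, epoch, and a degeneracy
#'   flag.
#' @export
define_subspace <- function(session, feature = "space8", epoch = "delay1",
                            neurons = NULL, task_type = "SR", half,
                            k = NULL, times = seq(100, 4800, by = 50),
                            window_ms = 200) {
  feature <- match.arg(feature, c("space8", "space4", "reward"))
  if (is.null(neurons)) neurons <- session$neurons$neuron_id
  tr <- session$trials
  rates <- estimate_rates(session, step_ms = times[2] - times[1],
                          window_ms = window_ms,
                          t_min = min(times), t_max = max(times),
                          trials = half, neurons = neurons)
  labels <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                           feature)
  cm <- condition_mean_array(rates, labels, half)
  n_cond <- dim(cm)[1]
  if (is.null(k)) k <- n_cond - 1
  if (k >= n_cond) stop("k must be smaller than the number of conditions")
  dm <- demean_conditions(cm)

  pca_of <- function(M) {
    # M: conditions x neurons, already demeaned across conditions
    if (anyNA(M)) {
      return(list(axes = matrix(0, ncol(M), k),
                  singular_values = rep(0, min(dim(M))),
                  degenerate = TRUE))
    }
    sv <- svd(M)
    list(axes = sv$v[, seq_len(k), drop = FALSE],
         singular_values = sv$d,
         degenerate = sum(sv$d^2) < 1e-10)
  }

  if (epoch == "dynamic") {
    models <- lapply(seq_along(rates$bin_centres_ms), function(ti) {
      pca_of(dm[, , ti])
    })
    axes <- lapply(models, `[[`, "axes")
    svals <- lapply(models, `[[`, "singular_values")
    degen <- vapply(models, `[[`, logical(1), "degenerate")
  } else {
    win <- subspace_epoch_window(epoch)
    inw <- rates$bin_centres_ms >= win[1] & rates$bin_centres_ms < win[2]
    if (!any(inw)) stop("epoch window not covered by the time grid")
    M <- apply(dm[, , inw, drop = FALSE], c(1, 2), mean)
    m <- pca_of(M)
    axes <- m$axes
    svals <- m$singular_values
    degen <- m$degenerate
  }
  structure(list(axes = axes, singular_values = svals, k = k,
                 epoch = epoch, feature = feature, task_type = task_type,
                 neurons = neurons, times = rates$bin_centres_ms,
                 window_ms = window_ms, degenerate = degen),
            class = "wm_subspace")
}

#' @export
print.wm_subspace <- function(x, ...) {
  cat("<wm_subspace> ", x$feature, " ", x$epoch, " subspace, k = ", x$k,
      ", ", length(x$neurons), " neurons",
      if (isTRUE(any(x$degenerate))) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Project held-out condition-mean trajectories onto subspace axes
#'
#' Test-half condition means are demeaned across conditions per neuron at
#' each timepoint and projected onto the first two principal axes of the
#' subspace, giving the low-dimensional trajectory of each condition.
#'
#' @param model A fixed-epoch `wm_subspace`.
#' @param session A `wm_session`.
#' @param half Trial ids of the test half.
#' @param n_axes Number of axes to return (default 2).
#' @return Tibble: `condition`, `time_ms`, `axis`, `coordinate`.
#' @export
project_trajectories <- function(model, session, half, n_axes = 2) {
  stopifnot(inherits(model, "wm_subspace"))
  if (model$epoch == "dynamic") {
    stop("trajectory projection uses a fixed-epoch subspace")
  }
  if (isTRUE(model$degenerate)) {
    warning("projecting into a degenerate (all-zero) subspace")
  }
  tr <- session$trials
  rates <- estimate_rates(session,
                          step_ms = model$times[2] - model$times[1],
                          window_ms = model$window_ms,
                          t_min = min(model$times), t_max = max(model$times),
                          trials = half, neurons = model$neurons)
  labels <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                           model$feature)
  cm <- demean_conditions(condition_mean_array(rates, labels, half))
  conds <- sort(unique(labels))
  ax <- model$axes[, seq_len(n_axes), drop = FALSE]
  purrr::map_dfr(seq_along(model$times), function(ti) {
    proj <- cm[, , ti] %*% ax       # conditions x n_axes
    tibble::tibble(
      condition = rep(conds, times = n_axes),
      time_ms = model$times[ti],
      axis = rep(seq_len(n_axes), each = length(conds)),
      coordinate = as.vector(proj)
    )
  })
}

#' Stimulus variance captured by a subspace over time
#'
#' At each timepoint, `C_t` is the across-condition covariance of the
#' demeaned test-half condition means and the captured stimulus variance is
#' `SV = Tr(S_k' C_t S_k)`. The normalised variant divides by `Tr(C_t)`
#' (total stimulus variance at t), so a subspace spanning the full condition
#' space scores exactly 1.
#'
#' @param model A `wm_subspace` (fixed or dynamic).
#' @param session A `wm_session`.
#' @param half Trial ids of the test half.
#' @return A `wm_sv` tibble: `time_ms`, `sv_raw`, `sv_total`,
#'   `sv_normalised`, `subspace`.
#' @export
stimulus_variance <- function(model, session, half) {
  stopifnot(inherits(model, "wm_subspace"))
  tr <- session$trials
  rates <- estimate_rates(session,
                          step_ms = model$times[2] - model$times[1],
                          window_ms = model$window_ms,
                          t_min = min(model$times), t_max = max(model$times),
                          trials = half, neurons = model$neurons)
  labels <- feature_labels(tr[match(rates$trial_ids, tr$trial_id), ],
                           model$feature)
  cm <- demean_conditions(condition_mean_array(rates, labels, half))
  n_cond <- dim(cm)[1]
  out <- purrr::map_dfr(seq_along(model$times), function(ti) {
    D <- cm[, , ti]                 # conditions x neurons, demeaned
    total <- sum(D^2) / (n_cond - 1)
    if (!is.finite(total)) {
      return(tibble::tibble(time_ms = model$times[ti], sv_raw = NA_real_,
                            sv_total = NA_real_, sv_normalised = NA_real_))
    }
    ax <- if (model$epoch == "dynamic") model$axes[[ti]] else model$axes
    sv <- sum((D %*% ax)^2) / (n_cond - 1)
    tibble::tibble(time_ms = model$times[ti], sv_raw = sv,
                   sv_total = total,
                   sv_normalised = if (total > 0) sv / total else NA_real_)
  })
  out$subspace <- paste0(model$feature, ":", model$epoch)
  class(out) <- c("wm_sv", class(out))
  out
}

#' Plot stimulus-variance timecourses
#'
#' @param object A `wm_sv` (or several row-bound together).
#' @param normalised Plot the normalised variant.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wm_sv <- function(object, normalised = TRUE, ...) {
  y <- if (normalised) "sv_normalised" else "sv_raw"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms,
                                       y = .data[[y]],
                                       colour = .data$subspace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from fixation onset (ms)",
                  y = if (normalised) "stimulus variance (normalised)" else
                    "stimulus variance")
}
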