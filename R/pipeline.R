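# Orchestration: run the full analysis chain on a session with one seed and
# write every stage's output plus a hashed manifest, so a rerun with the
# same configuration reproduces the files bit for bit.

#' Moving-average smoother for display only
#'
#' Centred moving average over `span` bins (default five 10 ms bins), with
#' truncated windows at the edges. The result is flagged display-only: all
#' statistical tests in this package operate on unsmoothed data, and the
#' flag marks series that must never re-enter an analysis.
#'
#' @param series Numeric vector.
#' @param span Odd window length in bins.
#' @return Smoothed vector with attribute `display_only = TRUE`.
#' @export
smooth_for_display <- function(series, span = 5) {
  if (span %% 2 == 0) stop("span must be odd")
  h <- (span - 1) / 2
  n <- length(series)
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    mean(series[lo:hi])
  }, numeric(1))
  attr(out, "display_only") <- TRUE
  out
}

#' Run the full analysis pipeline on one session
#'
#' Stages, in dependency order: timescale fitting, median split by tau,
#' decoding timecourse, cross-temporal PWD discriminability, subspace
#' stimulus variance, and single-neuron epoch selectivity / ANOVA
#' classification. Every output table is written as CSV under `out_dir` and
#' hashed into `manifest.json`; identical configuration and seed reproduce
#' identical hashes.
#'
#' @param config Named list: either `session` (a `wm_session`) or
#'   `synth` (a [synth_config()]); `out_dir`; `seed`; optional `n_perm`
#'   (>= 2, default 20), `task_type`, `feature`, `decode_times`,
#'   `discrim_times`, `n_train`, `n_test`.
#' @return The manifest as a tibble (`file`, `md5`), invisibly; the stage
#'   results in attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  n_perm <- config$n_perm %||% 20
  if (n_perm < 2) stop("n_perm must be >= 2")
  seed <- config$seed %||% 1L
  task_type <- config$task_type %||% "SR"
  feature <- config$feature %||% "space8"
  session <- if (!is.null(config$session)) {
    config$session
  } else if (!is.null(config$synth)) {
    generate_session(config$synth)$session
  } else {
    stop("config must provide either a session or a synth config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(tbl, name) {
    f <- file.path(config$out_dir, name)
    readr::write_csv(tbl, f, progress = FALSE)
    outputs <<- c(outputs, f)
  }

  # 1. timescales + median split
  fits <- fit_timescales(session)
  emit(fits, "tau_fits.csv")
  split <- tryCatch(median_split_by_tau(fits), error = function(e) NULL)
  if (!is.null(split)) {
    emit(tibble::tibble(
      neuron_id = c(split$low_tau, split$high_tau),
      tau_group = rep(c("low", "high"),
                      c(length(split$low_tau), length(split$high_tau)))),
      "tau_split.csv")
  }

  # 2. decoding timecourse
  dec <- decode_timecourse(
    session, feature, task_type = task_type,
    times = config$decode_times %||% seq(250, 4750, by = 250),
    n_perm = n_perm, n_train = config$n_train %||% 200,
    n_test = config$n_test %||% 48, seed = seed)
  emit(tidy(dec), "decode_timecourse.csv")

  # 3. cross-temporal discriminability
  disc <- crosstemporal_discriminability(
    session, feature, task_type = task_type,
    times = config$discrim_times %||% seq(250, 4750, by = 50),
    symmetrise = TRUE, seed = seed)
  emit(tidy(disc), "discriminability.csv")

  # 4. subspace stimulus variance
  tr <- session$trials
  correct <- tr$trial_id[tr$task_type == task_type &
                           tr$outcome == "correct"]
  lab <- feature_labels(tr[match(correct, tr$trial_id), ], feature)
  sp <- split_half(correct, lab, seed = seed)
  sv <- dplyr::bind_rows(lapply(c("fixation", "delay1"), function(ep) {
    sub_times <- config$decode_times %||% seq(250, 4750, by = 250)
    m <- define_subspace(session, feature, ep, task_type = task_type,
                         half = sp$train, times = sub_times,
                         window_ms = max(200, diff(sub_times[1:2])))
    stimulus_variance(m, session, sp$test)
  }))
  emit(sv, "stimulus_variance.csv")

  # 5. single-neuron profiles
  es <- epoch_selectivity(session, task_type)
  emit(es$table, "epoch_selectivity.csv")
  emit(es$profile, "switch_profile.csv")
  av <- purrr::map_dfr(session$neurons$neuron_id, function(nid) {
    anova_classify(session, nid, task_type)
  })
  emit(av, "anova_classes.csv")

  manifest <- tibble::tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  jsonlite::write_json(
    list(seed = seed, n_perm = n_perm, task_type = task_type,
         feature = feature,
         files = stats::setNames(as.list(manifest$md5), manifest$file)),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- list(fits = fits, decode = dec,
                                    discrim = disc, sv = sv,
                                    selectivity = es, anova = av)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
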