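# Session container, file I/O, location collapsing, rate estimation, z-scoring,
# and split-half utilities. All times are milliseconds relative to fixation
# onset; analysis windows are half-open [lo, hi).

EVENT_COLS <- c("fixation_on", "cue1_on", "cue1_off", "delay1_end",
                "cue2_on", "cue2_off", "delay2_end", "go", "saccade",
                "reward_on")

REGIONS <- c("ACC", "DLPFC", "VLPFC", "OFC")

# Fixed 24 -> 8 collapsing map: the 24 targets of the 5x5 grid (centre removed,
# numbered row-wise from the top-left) partitioned into 8 contiguous angular
# sectors of 3 targets each around fixation. Rectangles merge tessellating
# sector pairs (1,2), (3,4), (5,6), (7,8).
LOC8_MAP <- c(3L, 3L, 2L, 2L, 1L, 4L, 3L, 2L, 1L, 1L, 4L, 4L,
              8L, 8L, 5L, 5L, 6L, 7L, 8L, 5L, 6L, 6L, 7L, 7L)

#' Collapse the 24 spatial targets into coarser location groups
#'
#' The task presents 24 spatial targets arranged in a 5 x 5 grid around the
#' fixation spot (centre excluded). For decoding, targets are collapsed into
#' eight triangular groups of three contiguous targets; the error-trial
#' analysis further merges tessellating triangle pairs into four rectangles of
#' six targets. The triangle membership is a fixed angular-sector partition;
#' every downstream analysis depends only on it being a fixed partition.
#'
#' @param spatial_location Integer vector in 1..24.
#' @param scheme `"eight_triangles"` or `"four_rectangles"`.
#' @return Integer vector of group ids (1..8 or 1..4).
#' @export
#' @examples
#' collapse_locations(1:24)
#' table(collapse_locations(1:24, "four_rectangles"))
collapse_locations <- function(spatial_location,
                               scheme = c("eight_triangles", "four_rectangles")) {
  scheme <- match.arg(scheme)
  bad <- !is.finite(spatial_location) | spatial_location < 1 |
    spatial_location > 24 | spatial_location != floor(spatial_location)
  if (any(bad)) {
    stop("spatial_location must be an integer in 1..24; offending value(s): ",
         paste(utils::head(spatial_location[bad], 5), collapse = ", "))
  }
  g8 <- LOC8_MAP[as.integer(spatial_location)]
  if (scheme == "eight_triangles") g8 else as.integer(ceiling(g8 / 2))
}

#' Construct a validated session object
#'
#' A session bundles a trial table, a neuron table, and a spike table. It is
#' the universal input of every analysis in the package.
#'
#' @param trials Tibble with columns `trial_id`, `task_type` ("SR"/"RS"),
#'   `spatial_location` (1..24), `reward_level` (1..5), `outcome`
#'   ("correct"/"error") and the event-time columns
#'   `fixation_on, cue1_on, cue1_off, delay1_end, cue2_on, cue2_off,
#'   delay2_end, go, saccade, reward_on` in ms relative to fixation onset.
#'   `location8`/`location4` are derived if absent.
#' @param neurons Tibble with `neuron_id` and `region`
#'   (ACC/DLPFC/VLPFC/OFC).
#' @param spikes Tibble with `neuron_id`, `trial_id`, `spike_time_ms`.
#' @param metadata Optional named list (subject id, source, generator hash...).
#' @return An object of class `wm_session`.
#' @export
wm_session <- function(trials, neurons, spikes, metadata = list()) {
  trials <- tibble::as_tibble(trials)
  neurons <- tibble::as_tibble(neurons)
  spikes <- tibble::as_tibble(spikes)

  need_tr <- c("trial_id", "task_type", "spatial_location", "reward_level",
               "outcome", EVENT_COLS)
  miss <- setdiff(need_tr, names(trials))
  if (length(miss) > 0) {
    stop("trials table is missing column(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(c("neuron_id", "region"), names(neurons))
  if (length(miss) > 0) {
    stop("neurons table is missing column(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(c("neuron_id", "trial_id", "spike_time_ms"), names(spikes))
  if (length(miss) > 0) {
    stop("spikes table is missing column(s): ", paste(miss, collapse = ", "))
  }

  if (anyDuplicated(trials$trial_id)) {
    stop("duplicate trial_id in trials table: ",
         trials$trial_id[duplicated(trials$trial_id)][1])
  }
  if (anyDuplicated(neurons$neuron_id)) {
    stop("duplicate neuron_id in neurons table: ",
         neurons$neuron_id[duplicated(neurons$neuron_id)][1])
  }
  if (!all(neurons$region %in% REGIONS)) {
    stop("unknown region: ",
         paste(setdiff(unique(neurons$region), REGIONS), collapse = ", "))
  }
  if (!all(trials$task_type %in% c("SR", "RS"))) {
    stop("task_type must be 'SR' or 'RS'")
  }
  if (!all(trials$outcome %in% c("correct", "error"))) {
    stop("outcome must be 'correct' or 'error'")
  }
  if (!all(trials$reward_level %in% 1:5)) stop("reward_level must be in 1..5")

  # event ordering: non-decreasing along the task sequence, strictly increasing
  # across non-degenerate intervals (epoch boundaries may coincide, e.g.
  # delay1_end == cue2_on)
  ev <- as.matrix(trials[, EVENT_COLS])
  d <- ev[, -1, drop = FALSE] - ev[, -ncol(ev), drop = FALSE]
  if (any(d < 0)) {
    bad <- which(rowSums(d < 0) > 0)[1]
    k <- which(d[bad, ] < 0)[1]
    stop("event times out of order in trial_id ", trials$trial_id[bad], ": ",
         EVENT_COLS[k + 1], " < ", EVENT_COLS[k])
  }

  dangling <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(dangling) > 0) {
    stop("spikes reference unknown trial_id: ", dangling[1])
  }
  dangling <- setdiff(unique(spikes$neuron_id), neurons$neuron_id)
  if (length(dangling) > 0) {
    stop("spikes reference unknown neuron_id: ", dangling[1])
  }
  if (any(spikes$spike_time_ms < 0)) {
    stop("negative spike times present (times are relative to fixation onset)")
  }

  trials$location8 <- collapse_locations(trials$spatial_location)
  trials$location4 <- collapse_locations(trials$spatial_location,
                                         "four_rectangles")
  spikes <- dplyr::arrange(spikes, .data$neuron_id, .data$trial_id,
                           .data$spike_time_ms)

  structure(list(trials = trials, neurons = neurons, spikes = spikes,
                 metadata = metadata),
            class = "wm_session")
}

#' @export
print.wm_session <- function(x, ...) {
  cat("<wm_session> ", nrow(x$neurons), " neurons, ", nrow(x$trials),
      " trials, ", nrow(x$spikes), " spikes\n", sep = "")
  cat("  regions: ",
      paste(names(table(x$neurons$region)), table(x$neurons$region),
            sep = ":", collapse = " "), "\n", sep = "")
  if (!is.null(x$metadata$source)) {
    cat("  source: ", x$metadata$source, "\n", sep = "")
  }
  invisible(x)
}

#' Read a session from a directory of CSV tables
#'
#' Expects `trials.csv`, `neurons.csv` and `spikes.csv` (UTF-8, header row) in
#' the documented dialect; see [wm_session()] for the column contracts.
#'
#' @param path Directory containing the three tables.
#' @return A validated `wm_session`.
#' @export
read_session <- function(path) {
  files <- file.path(path, c("trials.csv", "neurons.csv", "spikes.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("session file(s) not found: ", paste(missing, collapse = ", "))
  }
  trials <- readr::read_csv(files[1], show_col_types = FALSE,
                            progress = FALSE)
  neurons <- readr::read_csv(files[2], show_col_types = FALSE,
                             progress = FALSE)
  spikes <- readr::read_csv(files[3], show_col_types = FALSE,
                            progress = FALSE)
  meta_file <- file.path(path, "metadata.json")
  metadata <- if (file.exists(meta_file)) {
    jsonlite::read_json(meta_file, simplifyVector = TRUE)
  } else {
    list()
  }
  wm_session(trials, neurons, spikes, metadata)
}

#' Write a session to a directory of CSV tables
#'
#' Inverse of [read_session()]; output is bit-stable given fixed input
#' ordering.
#'
#' @param session A `wm_session`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "wm_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials
  tr <- tr[, c("trial_id", "task_type", "spatial_location", "location8",
               "location4", "reward_level", "outcome", EVENT_COLS)]
  readr::write_csv(tr, file.path(path, "trials.csv"), progress = FALSE)
  readr::write_csv(session$neurons, file.path(path, "neurons.csv"),
                   progress = FALSE)
  readr::write_csv(session$spikes, file.path(path, "spikes.csv"),
                   progress = FALSE)
  if (length(session$metadata) > 0) {
    jsonlite::write_json(session$metadata, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Estimate binned firing rates for all neurons and selected trials
#'
#' Rates are spike counts in the half-open window
#' `[centre - window/2, centre + window/2)` divided by the window length, in
#' Hz. The default grid (50 ms steps, 100 ms window) matches the accuracy
#' decoder; the discriminability analyses use 10 ms steps with a 200 ms
#' window. Bins whose window extends beyond the recorded span of a trial are
#' masked as `NA` and excluded from downstream correlations and fits.
#'
#' @param session A `wm_session`.
#' @param step_ms Spacing of bin centres.
#' @param window_ms Width of the counting window; must be >= `step_ms`.
#' @param t_min,t_max Range of bin centres, ms relative to `alignment_event`.
#' @param alignment_event Event name the bin centres are aligned to.
#' @param trials Trial ids to include (default: all).
#' @param neurons Neuron ids to include (default: all).
#' @param post_reward_ms Recorded span is assumed to end this many ms after
#'   reward onset (the generator uses the same convention).
#' @return A `wm_rates` object: array `values` (neurons x trials x bins, Hz),
#'   plus bin metadata and the trial/neuron ids.
#' @export
estimate_rates <- function(session, step_ms = 50, window_ms = 100,
                           t_min = 0, t_max = 5000,
                           alignment_event = "fixation_on",
                           trials = NULL, neurons = NULL,
                           post_reward_ms = 500) {
  stopifnot(inherits(session, "wm_session"))
  if (window_ms < step_ms) stop("window_ms must be >= step_ms")
  if (!alignment_event %in% EVENT_COLS) {
    stop("unknown alignment event: ", alignment_event)
  }
  trial_ids <- if (is.null(trials)) session$trials$trial_id else trials
  if (length(trial_ids) == 0) stop("empty trial selection")
  neuron_ids <- if (is.null(neurons)) session$neurons$neuron_id else neurons
  tr <- session$trials[match(trial_ids, session$trials$trial_id), ]
  if (anyNA(tr$trial_id)) stop("unknown trial id in selection")

  centres <- seq(t_min, t_max, by = step_ms)
  nb <- length(centres)
  half <- window_ms / 2
  align <- tr[[alignment_event]]
  span_end <- tr$reward_on + post_reward_ms

  sp <- session$spikes[session$spikes$neuron_id %in% neuron_ids &
                         session$spikes$trial_id %in% trial_ids, ]
  ni <- match(sp$neuron_id, neuron_ids)
  ti <- match(sp$trial_id, trial_ids)
  # absolute spike time -> time relative to the alignment event of its trial
  st <- sp$spike_time_ms - align[ti]

  values <- array(0, dim = c(length(neuron_ids), length(trial_ids), nb))
  # count spikes per (neuron, trial, bin); windows overlap when
  # window_ms > step_ms so each bin is counted independently
  lo <- centres - half
  for (b in seq_len(nb)) {
    inb <- st >= lo[b] & st < lo[b] + window_ms
    if (any(inb)) {
      cnt <- rowsum(rep(1, sum(inb)),
                    group = (ni[inb] - 1L) * length(trial_ids) + ti[inb])
      idx <- as.integer(rownames(cnt))
      values[cbind(((idx - 1L) %/% length(trial_ids)) + 1L,
                   ((idx - 1L) %% length(trial_ids)) + 1L,
                   b)] <- cnt[, 1]
    }
  }
  values <- values / (window_ms / 1000)

  # mask bins whose window leaves the recorded span [0, reward_on + post]
  win_lo <- outer(align, lo, "+")              # trials x bins, absolute start
  win_hi <- win_lo + window_ms
  mask <- win_lo < 0 | sweep(win_hi, 1, span_end, ">")
  if (any(mask)) {
    for (tr_i in seq_len(nrow(mask))) {
      bad <- which(mask[tr_i, ])
      if (length(bad) > 0) values[, tr_i, bad] <- NA_real_
    }
  }

  structure(list(values = values,
                 neuron_ids = neuron_ids,
                 trial_ids = trial_ids,
                 bin_centres_ms = centres,
                 window_ms = window_ms,
                 step_ms = step_ms,
                 alignment_event = alignment_event,
                 normalised = FALSE),
            class = "wm_rates")
}

#' @export
print.wm_rates <- function(x, ...) {
  cat("<wm_rates> ", dim(x$values)[1], " neurons x ", dim(x$values)[2],
      " trials x ", dim(x$values)[3], " bins",
      if (x$normalised) " (z-scored)" else " (Hz)",
      "\n  centres ", min(x$bin_centres_ms), "..", max(x$bin_centres_ms),
      " ms, step ", x$step_ms, ", window ", x$window_ms,
      ", aligned to ", x$alignment_event, "\n", sep = "")
  invisible(x)
}

#' Tidy a rate tensor into a long tibble
#'
#' @param x A `wm_rates`.
#' @param ... Unused.
#' @return Tibble with columns `neuron_id`, `trial_id`, `time_ms`, `rate`.
#' @export
tidy.wm_rates <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    neuron_id = rep(x$neuron_ids, times = d[2] * d[3]),
    trial_id = rep(rep(x$trial_ids, each = d[1]), times = d[3]),
    time_ms = rep(x$bin_centres_ms, each = d[1] * d[2]),
    rate = as.vector(x$values)
  )
}

#' Per-neuron baseline statistics from the final 300 ms of fixation
#'
#' Computes, across the selected trials, the mean and standard deviation of
#' each neuron's firing rate in the last 300 ms of the 1000 ms fixation
#' period. These normalise rates before decoding. Neurons with zero baseline
#' variability are flagged and their sd replaced by the population median sd,
#' so the pseudopopulation size never changes mid-pipeline.
#'
#' @param session A `wm_session`.
#' @param trials Trial ids to use (default: correct trials).
#' @param fixation_ms Length of the fixation period (default 1000).
#' @param baseline_ms Width of the baseline window at the end of fixation.
#' @return Tibble: `neuron_id`, `mean_hz`, `sd_hz`, `zero_sd` flag.
#' @export
baseline_stats <- function(session, trials = NULL, fixation_ms = 1000,
                           baseline_ms = 300) {
  stopifnot(inherits(session, "wm_session"))
  if (is.null(trials)) {
    trials <- session$trials$trial_id[session$trials$outcome == "correct"]
  }
  r <- estimate_rates(session, step_ms = baseline_ms, window_ms = baseline_ms,
                      t_min = fixation_ms - baseline_ms / 2,
                      t_max = fixation_ms - baseline_ms / 2,
                      trials = trials)
  v <- r$values[, , 1, drop = TRUE]
  if (is.null(dim(v))) v <- matrix(v, nrow = length(r$neuron_ids))
  m <- rowMeans(v, na.rm = TRUE)
  s <- apply(v, 1, stats::sd, na.rm = TRUE)
  zero <- !is.na(s) & s == 0
  med <- stats::median(s[!zero & s > 0], na.rm = TRUE)
  s[zero] <- med
  tibble::tibble(neuron_id = r$neuron_ids, mean_hz = m, sd_hz = s,
                 zero_sd = zero)
}

#' Z-score a rate tensor against fixation baseline statistics
#'
#' @param rates A `wm_rates` in Hz.
#' @param baseline Output of [baseline_stats()] for the same neurons.
#' @return A `wm_rates` with `normalised = TRUE`.
#' @export
baseline_zscore <- function(rates, baseline) {
  stopifnot(inherits(rates, "wm_rates"))
  idx <- match(rates$neuron_ids, baseline$neuron_id)
  if (anyNA(idx)) {
    stop("baseline is missing neuron(s): ",
         paste(utils::head(rates$neuron_ids[is.na(idx)], 5), collapse = ", "))
  }
  m <- baseline$mean_hz[idx]
  s <- baseline$sd_hz[idx]
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("baseline sd must be positive and finite for all neurons")
  }
  rates$values <- sweep(sweep(rates$values, 1, m, "-"), 1, s, "/")
  rates$normalised <- TRUE
  rates$baseline <- baseline
  rates
}

#' Invert a baseline z-scoring
#'
#' @param rates A normalised `wm_rates` produced by [baseline_zscore()].
#' @return The rates in Hz.
#' @export
baseline_unzscore <- function(rates) {
  stopifnot(inherits(rates, "wm_rates"), isTRUE(rates$normalised))
  b <- rates$baseline
  idx <- match(rates$neuron_ids, b$neuron_id)
  rates$values <- sweep(sweep(rates$values, 1, b$sd_hz[idx], "*"),
                        1, b$mean_hz[idx], "+")
  rates$normalised <- FALSE
  rates$baseline <- NULL
  rates
}

#' Split trials into stratified halves
#'
#' Splits trials into disjoint, exhaustive train/test halves with per-stratum
#' counts differing by at most one; reproducible given `seed`.
#'
#' @param trial_ids Vector of trial ids.
#' @param stratify_by Condition label per trial (same length).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (trial id vectors).
#' @export
split_half <- function(trial_ids, stratify_by, seed = 1L) {
  stopifnot(length(trial_ids) == length(stratify_by))
  tab <- table(stratify_by)
  if (any(tab < 2)) {
    stop("stratum with fewer than 2 trials: ",
         names(tab)[which(tab < 2)[1]])
  }
  rng <- local_rng(seed)
  train <- test <- vector("list", length(tab))
  strata <- split(trial_ids, stratify_by)
  for (i in seq_along(strata)) {
    ids <- strata[[i]]
    n <- length(ids)
    n_tr <- if (n %% 2 == 0) n / 2 else n %/% 2 + rng$integer(2) - 1L
    pick <- rng$sample(ids, n_tr)
    train[[i]] <- pick
    test[[i]] <- setdiff(ids, pick)
  }
  list(train = unlist(train, use.names = FALSE),
       test = unlist(test, use.names = FALSE))
}

# Small seeded RNG scope: evaluates draws under `seed` and restores the global
# RNG state on exit, so library code never perturbs the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  state <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  with_state <- function(f) {
    function(...) {
      assign(".Random.seed", state, envir = globalenv())
      on.exit({
        state <<- get(".Random.seed", envir = globalenv())
        restore()
      })
      f(...)
    }
  }
  list(
    sample = with_state(function(x, size = length(x), replace = FALSE) {
      x[sample.int(length(x), size, replace = replace)]
    }),
    integer = with_state(function(n) sample.int(n, 1L)),
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    rpois = with_state(stats::rpois),
    # run a whole block under the scoped stream with a single state swap
    # (per-call swapping is too slow for simulation inner loops)
    run = with_state(function(f) f())
  )
}

# Derive a bounded substream seed; keeps everything below 2^31 - 1.
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) + as.numeric(index) * 1000003) %%
               (.Machine$integer.max - 1)) + 1L
}
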