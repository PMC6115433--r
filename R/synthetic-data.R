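# Task-structured synthetic spike-train generator with known ground truth.
# Neurons are Ornstein-Uhlenbeck-modulated inhomogeneous Poisson processes:
# the OU latent sets the resting spike-count autocorrelation timescale, and
# additive epoch-locked tuning terms create cue/delay selectivity, cue->delay
# tuning reversal, and space->reward selectivity switching.

# Fixed task schedule, ms from fixation onset. Saccade latency is jittered
# per trial; reward follows a 150 ms target hold.
TASK_SCHEDULE <- c(fixation_on = 0, cue1_on = 1000, cue1_off = 1500,
                   delay1_end = 2500, cue2_on = 2500, cue2_off = 3000,
                   delay2_end = 4000, go = 4000)

#' Configuration for the synthetic session generator
#'
#' Defaults describe a realistic pooled prefrontal recording: log-normal
#' intrinsic timescales spanning tens of milliseconds to ~1 s, baseline rates
#' of a few Hz, and a mixture of untuned, transiently tuned, sustained,
#' reversing and feature-switching neurons.
#'
#' @param n_neurons Number of neurons.
#' @param region Region label assigned to all neurons.
#' @param trials_per_cond Trials per (task type x 24 locations x 5 rewards)
#'   design cell.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline rate (Hz).
#' @param tau_meanlog,tau_sdlog Log-normal intrinsic timescale (ms), truncated
#'   to \[20, 1000\].
#' @param latent_gain Multiplicative depth of the slow OU rate modulation.
#' @param tuning_depth_hz Peak spatial tuning depth.
#' @param reward_depth_hz Peak reward tuning depth.
#' @param tasktype_depth_hz Task-type (SR vs RS) tuning depth; 0 disables.
#' @param frac_untuned,frac_transient,frac_reversal,frac_switch Fractions of
#'   the tuned dynamics mixture; the remainder is stably sustained.
#' @param error_frac Fraction of trials recorded as errors; on error trials
#'   the spatial tuning term is driven by a corrupted (neighbouring) location
#'   group, emulating a wrong remembered location.
#' @param saccade_latency_ms,saccade_jitter_ms Go-to-saccade latency mean and
#'   half-range of its uniform jitter.
#' @param dt_ms Simulation time step; must satisfy `dt_ms <= min tau / 5`.
#' @param seed Master seed; per-neuron substreams are derived from it so
#'   adding neurons never perturbs existing ones.
#' @return A list of class `wm_synth_config`.
#' @export
synth_config <- function(n_neurons = 50, region = "VLPFC",
                         trials_per_cond = 1,
                         baseline_meanlog = log(8), baseline_sdlog = 0.4,
                         tau_meanlog = log(150), tau_sdlog = 0.8,
                         latent_gain = 0.8,
                         tuning_depth_hz = 8, reward_depth_hz = 8,
                         tasktype_depth_hz = 0,
                         frac_untuned = 0.25, frac_transient = 0.2,
                         frac_reversal = 0.15, frac_switch = 0.2,
                         error_frac = 0.1,
                         saccade_latency_ms = 250, saccade_jitter_ms = 50,
                         dt_ms = 4, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_untuned, frac_transient, frac_reversal, frac_switch)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stop("type fractions must be in [0, 1] and sum to at most 1")
  }
  if (n_neurons < 1 || trials_per_cond < 1) stop("counts must be positive")
  if (error_frac < 0 || error_frac >= 1) stop("error_frac must be in [0, 1)")
  class(cfg) <- "wm_synth_config"
  cfg
}

#' Sample a counterbalanced trial table for the task
#'
#' Every (task type x 24 locations x 5 reward levels) cell receives exactly
#' `trials_per_cond` trials; trial order is randomised, SR and RS trials are
#' intermingled. Event times follow the fixed schedule (1000 ms fixation, two
#' 500 ms cues each followed by a 1000 ms delay), with jittered go-to-saccade
#' latency.
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to the config's master seed).
#' @return Tibble of trial records, including the generator-internal
#'   `remembered_location8` column (corrupted on error trials).
#' @export
sample_task_trials <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "wm_synth_config"))
  design <- expand.grid(task_type = c("SR", "RS"),
                        spatial_location = 1:24,
                        reward_level = 1:5,
                        rep = seq_len(config$trials_per_cond),
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  rng <- local_rng(substream_seed(seed, 0))
  ord <- rng$sample(seq_len(n))
  design <- design[ord, ]

  sacc <- config$saccade_latency_ms +
    rng$runif(n, -config$saccade_jitter_ms, config$saccade_jitter_ms)
  err <- rng$runif(n) < config$error_frac
  loc8 <- collapse_locations(design$spatial_location)
  # error model: the remembered location group slips to a random neighbour
  shift <- rng$sample(c(-1L, 1L), n, replace = TRUE)
  rem8 <- ifelse(err, ((loc8 - 1L + shift) %% 8L) + 1L, loc8)

  tibble::tibble(
    trial_id = seq_len(n),
    task_type = design$task_type,
    spatial_location = design$spatial_location,
    reward_level = design$reward_level,
    outcome = ifelse(err, "error", "correct"),
    fixation_on = 0,
    cue1_on = TASK_SCHEDULE[["cue1_on"]],
    cue1_off = TASK_SCHEDULE[["cue1_off"]],
    delay1_end = TASK_SCHEDULE[["delay1_end"]],
    cue2_on = TASK_SCHEDULE[["cue2_on"]],
    cue2_off = TASK_SCHEDULE[["cue2_off"]],
    delay2_end = TASK_SCHEDULE[["delay2_end"]],
    go = TASK_SCHEDULE[["go"]],
    saccade = TASK_SCHEDULE[["go"]] + sacc,
    reward_on = TASK_SCHEDULE[["go"]] + sacc + 150,
    remembered_location8 = as.integer(rem8)
  )
}

#' Simulate a stationary unit-variance Ornstein-Uhlenbeck latent trace
#'
#' Exact AR(1) discretisation: `x[t+1] = a x[t] + sqrt(1 - a^2) e`, with
#' `a = exp(-dt/tau)`, initialised from the stationary distribution, so the
#' trace has zero mean, unit variance and autocorrelation `exp(-lag/tau)` at
#' every lag.
#'
#' @param tau_ms Timescale, > 0.
#' @param duration_ms Trace duration.
#' @param dt_ms Step; must be `<= tau_ms / 5`.
#' @param seed Optional seed (uses, and restores, a local RNG scope).
#' @param n_traces Number of independent traces (rows of the result).
#' @return Numeric matrix `n_traces x n_steps` (a vector when `n_traces = 1`).
#' @export
simulate_latent <- function(tau_ms, duration_ms, dt_ms = 4, seed = NULL,
                            n_traces = 1) {
  stopifnot(tau_ms > 0)
  if (dt_ms > tau_ms / 5) {
    stop("dt_ms must be <= tau_ms / 5 for a faithful discretisation")
  }
  n_steps <- ceiling(duration_ms / dt_ms)
  rnf <- if (is.null(seed)) stats::rnorm else local_rng(seed)$rnorm
  a <- exp(-dt_ms / tau_ms)
  b <- sqrt(1 - a^2)
  x <- matrix(0, n_traces, n_steps)
  innov <- matrix(rnf(n_traces * n_steps), n_traces)
  x[, 1] <- innov[, 1]
  for (k in 2:n_steps) x[, k] <- a * x[, k - 1] + b * innov[, k]
  if (n_traces == 1) drop(x) else x
}

# Tuning curve helpers: graded tuning with exactly +depth at the preferred
# condition. Space uses cosine tuning on the angular sector index.
space_tuning <- function(loc8, pref, depth) {
  depth * cos(2 * pi * (loc8 - pref) / 8)
}
reward_tuning <- function(level, pref, depth) {
  depth * (1 - abs(level - pref) / 2)
}

# Epoch windows (ms) for a feature's cue within a trial. The spatial cue is
# cue1 on SR-trials and cue2 on RS-trials; the reward cue is the other one.
feature_cue_window <- function(feature, task_type) {
  first <- (feature == "space" & task_type == "SR") |
    (feature == "reward" & task_type == "RS")
  lo <- ifelse(first, TASK_SCHEDULE[["cue1_on"]], TASK_SCHEDULE[["cue2_on"]])
  cbind(lo = lo, hi = lo + 500)
}

#' Deterministic rate timecourse of one neuron on one trial
#'
#' `rate(t) = max(0, baseline * (1 + gain * latent(t)) + sum of active tuning
#' terms)`. Term dynamics depend on the neuron's type: `sustained` terms are
#' active from cue onset to the go cue; `transient` terms during the cue
#' only; a `reversal` neuron expresses `-depth` (below baseline by `depth`
#' for the preferred condition) from cue offset to go, while its cue-period
#' response carries a third-weight positive copy of that pattern plus a full
#' transient component with an independent preference -- so the population's
#' cue and delay codes anti-correlate without the cue pattern lying inside
#' the delay subspace; a `switch` neuron's first-feature term is quenched at
#' the onset of the second cue, when the second feature's term activates.
#'
#' @param spec One row of the generator's neuron spec table (see
#'   [generate_session()]).
#' @param trial One row of the trial table.
#' @param latent Latent trace sampled on `t_grid` (or scalar 0).
#' @param t_grid Time grid, ms from fixation onset.
#' @return Non-negative rate vector (Hz) over `t_grid`.
#' @export
rate_profile <- function(spec, trial, latent, t_grid) {
  rate <- spec$baseline_hz * (1 + spec$latent_gain * latent)
  rate <- rep_len(rate, length(t_grid))
  go <- trial$go

  add_term <- function(rate, feature, depth_c, depth_cue_pref) {
    if (depth_c == 0 && depth_cue_pref == 0) return(rate)
    win <- feature_cue_window(feature, trial$task_type)
    cue_on <- t_grid >= win[1, "lo"] & t_grid < win[1, "hi"]
    first <- win[1, "lo"] == TASK_SCHEDULE[["cue1_on"]]
    post <- t_grid >= win[1, "hi"] & t_grid < go
    cue_add <- switch(spec$type,
                      reversal = depth_c / 3 + depth_cue_pref,
                      depth_c)
    post_add <- switch(spec$type,
                       reversal = -depth_c,
                       transient = 0,
                       depth_c)
    act <- numeric(length(t_grid))
    act[cue_on] <- cue_add
    act[post] <- post_add
    if (spec$type == "switch" && first) {
      # the first feature's code is quenched by the second cue: linear
      # ramp-down over 750 ms from second-cue onset (decline, not a step,
      # so the post-reward slope test sees a negative gradient)
      quench_at <- TASK_SCHEDULE[["cue2_on"]]
      ramp <- pmin(1, pmax(0, 1 - (t_grid - quench_at) / 750))
      act <- act * ramp
    }
    rate + act
  }

  if (spec$space_depth_hz > 0) {
    loc <- if (trial$outcome == "error" &&
               !is.null(trial$remembered_location8)) {
      trial$remembered_location8
    } else {
      collapse_locations(trial$spatial_location)
    }
    rate <- add_term(rate, "space",
                     space_tuning(loc, spec$pref_loc8, spec$space_depth_hz),
                     space_tuning(loc, spec$pref_loc8_cue,
                                  spec$space_depth_hz))
  }
  if (spec$reward_depth_hz > 0) {
    rate <- add_term(rate, "reward",
                     reward_tuning(trial$reward_level, spec$pref_reward,
                                   spec$reward_depth_hz),
                     reward_tuning(trial$reward_level, spec$pref_reward_cue,
                                   spec$reward_depth_hz))
  }
  if (spec$tasktype_depth_hz > 0) {
    d <- if (trial$task_type == spec$pref_task) {
      spec$tasktype_depth_hz
    } else {
      -spec$tasktype_depth_hz
    }
    on <- t_grid >= TASK_SCHEDULE[["cue1_on"]] & t_grid < go
    rate[on] <- rate[on] + d
  }
  pmax(rate, 0)
}

#' Sample spike times from a rate timecourse by Poisson thinning
#'
#' Inhomogeneous Poisson sampling against the maximum rate; the expected
#' spike count equals the integral of the rate.
#'
#' @param rate Non-negative rate vector (Hz) on a regular grid.
#' @param dt_ms Grid step of `rate`.
#' @param t0_ms Time of the first grid point.
#' @param seed Optional seed (scoped; the caller's RNG stream is preserved).
#' @return Sorted numeric vector of spike times (ms).
#' @export
generate_spikes <- function(rate, dt_ms, t0_ms = 0, seed = NULL) {
  if (any(rate < 0)) stop("rate must be non-negative everywhere")
  body <- function(runifn, rpoisn) {
    rmax <- max(rate)
    if (rmax == 0) return(numeric(0))
    dur_s <- length(rate) * dt_ms / 1000
    n_cand <- rpoisn(1, rmax * dur_s)
    if (n_cand == 0) return(numeric(0))
    t_cand <- t0_ms + runifn(n_cand, 0, length(rate) * dt_ms)
    idx <- pmin(floor((t_cand - t0_ms) / dt_ms) + 1, length(rate))
    keep <- runifn(n_cand) < rate[idx] / rmax
    sort(t_cand[keep])
  }
  if (is.null(seed)) {
    body(stats::runif, stats::rpois)
  } else {
    rng <- local_rng(seed)
    body(rng$runif, rng$rpois)
  }
}

# Draw the per-neuron ground-truth specification table. Every attribute of
# neuron i comes from neuron i's own substream, so adding neurons never
# perturbs existing ones; consequently the dynamics-type mixture is
# probabilistic (each neuron draws its type against the cumulative
# fractions) rather than exact-count.
generate_neuron_specs <- function(config) {
  n <- config$n_neurons
  cuts <- cumsum(c(config$frac_untuned, config$frac_transient,
                   config$frac_reversal, config$frac_switch))
  type_names <- c("untuned", "transient", "reversal", "switch", "sustained")
  rows <- lapply(seq_len(n), function(i) {
    rng <- local_rng(substream_seed(config$seed, 500000 + i))
    rng$run(function() {
      u <- stats::runif(1)
      type <- type_names[findInterval(u, cuts) + 1L]
      tibble::tibble(
        neuron_id = i,
        region = config$region,
        type = type,
        baseline_hz = exp(stats::rnorm(1, config$baseline_meanlog,
                                       config$baseline_sdlog)),
        intrinsic_tau_ms = pmin(pmax(
          exp(stats::rnorm(1, config$tau_meanlog, config$tau_sdlog)),
          20), 1000),
        latent_gain = config$latent_gain,
        space_depth_hz = if (type == "untuned") 0 else
          config$tuning_depth_hz,
        reward_depth_hz = if (type == "untuned") 0 else
          config$reward_depth_hz,
        tasktype_depth_hz = if (type == "untuned") 0 else
          config$tasktype_depth_hz,
        pref_loc8 = sample(1:8, 1),
        pref_reward = sample(1:5, 1),
        pref_loc8_cue = sample(1:8, 1),
        pref_reward_cue = sample(1:5, 1),
        pref_task = sample(c("SR", "RS"), 1)
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Generate a full synthetic session with ground truth
#'
#' Assembles trials, neuron specifications, OU latents, rate profiles and
#' thinned Poisson spike trains into a validated [wm_session()].
#' Deterministic under the master seed; per-neuron substreams guarantee that
#' adding neurons leaves existing neurons' spikes unchanged.
#'
#' @param config A [synth_config()].
#' @return List with elements `session` (a `wm_session`) and `ground_truth`
#'   (the neuron spec tibble plus the trial table's remembered locations).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "wm_synth_config"))
  trials <- sample_task_trials(config)
  specs <- generate_neuron_specs(config)
  dt <- config$dt_ms
  t_end <- max(trials$reward_on) + 500
  t_grid <- seq(0, t_end, by = dt)
  n_tr <- nrow(trials)

  trial_rows <- lapply(seq_len(n_tr), function(j) as.list(trials[j, ]))
  spike_t <- vector("list", config$n_neurons * n_tr)
  spike_n <- integer(config$n_neurons * n_tr)
  spike_tr <- integer(config$n_neurons * n_tr)
  slot <- 0L
  for (i in seq_len(config$n_neurons)) {
    sp <- as.list(specs[i, ])
    rng <- local_rng(substream_seed(config$seed, 1000 + sp$neuron_id))
    st_list <- rng$run(function() {
      a <- exp(-dt / sp$intrinsic_tau_ms)
      b <- sqrt(1 - a^2)
      lat <- matrix(0, n_tr, length(t_grid))
      lat[, 1] <- stats::rnorm(n_tr)
      for (k in 2:length(t_grid)) {
        lat[, k] <- a * lat[, k - 1] + b * stats::rnorm(n_tr)
      }
      lapply(seq_len(n_tr), function(j) {
        trl <- trial_rows[[j]]
        rate <- rate_profile(sp, trl, lat[j, ], t_grid)
        span <- t_grid <= trl$reward_on + 500
        thin_spikes(rate[span], dt, 0)
      })
    })
    for (j in seq_len(n_tr)) {
      st <- st_list[[j]]
      if (length(st) > 0) {
        slot <- slot + 1L
        spike_t[[slot]] <- st
        spike_n[slot] <- sp$neuron_id
        spike_tr[slot] <- trial_rows[[j]]$trial_id
      }
    }
  }
  spikes <- if (slot == 0) {
    tibble::tibble(neuron_id = integer(), trial_id = integer(),
                   spike_time_ms = numeric())
  } else {
    lens <- lengths(spike_t[seq_len(slot)])
    tibble::tibble(
      neuron_id = rep(spike_n[seq_len(slot)], lens),
      trial_id = rep(spike_tr[seq_len(slot)], lens),
      spike_time_ms = unlist(spike_t[seq_len(slot)], use.names = FALSE)
    )
  }

  session <- wm_session(
    trials = trials,
    neurons = specs[, c("neuron_id", "region")],
    spikes = spikes,
    metadata = list(source = "synthetic", seed = config$seed,
                    n_neurons = config$n_neurons,
                    trials_per_cond = config$trials_per_cond)
  )
  list(session = session, ground_truth = specs)
}

# Thinning sampler drawing from the ambient RNG stream (hot loop; callers
# run it inside a local_rng scope).
thin_spikes <- function(rate, dt_ms, t0_ms) {
  rmax <- max(rate)
  if (rmax == 0) return(numeric(0))
  dur_s <- length(rate) * dt_ms / 1000
  n_cand <- stats::rpois(1, rmax * dur_s)
  if (n_cand == 0) return(numeric(0))
  t_cand <- t0_ms + stats::runif(n_cand, 0, length(rate) * dt_ms)
  idx <- pmin(floor((t_cand - t0_ms) / dt_ms) + 1, length(rate))
  keep <- stats::runif(n_cand) < rate[idx] / rmax
  sort(t_cand[keep])
}

#' Simulate fixation-period-only trials for timescale calibration
#'
#' A lightweight path that generates, for one neuron, many repetitions of the
#' 1000 ms fixation period (OU-modulated Poisson, no tuning). Used to
#' calibrate generative-tau to fitted-tau recovery without simulating whole
#' trials.
#'
#' @param n_trials Number of fixation repetitions.
#' @param baseline_hz Mean rate.
#' @param tau_ms OU timescale.
#' @param latent_gain Modulation depth.
#' @param duration_ms Fixation length.
#' @param dt_ms Simulation step.
#' @param seed Seed.
#' @return List of per-trial spike time vectors (ms from fixation onset).
#' @export
simulate_fixation_trials <- function(n_trials, baseline_hz = 15,
                                     tau_ms = 200, latent_gain = 0.8,
                                     duration_ms = 1000, dt_ms = 4,
                                     seed = 1L) {
  rng <- local_rng(seed)
  rng$run(function() {
    n_steps <- ceiling(duration_ms / dt_ms)
    a <- exp(-dt_ms / tau_ms)
    b <- sqrt(1 - a^2)
    lat <- matrix(0, n_trials, n_steps)
    lat[, 1] <- stats::rnorm(n_trials)
    for (k in 2:n_steps) {
      lat[, k] <- a * lat[, k - 1] + b * stats::rnorm(n_trials)
    }
    rate <- pmax(baseline_hz * (1 + latent_gain * lat), 0)
    lapply(seq_len(n_trials), function(j) {
      thin_spikes(rate[j, ], dt_ms, 0)
    })
  })
}
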