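# Shared synthetic fixtures, built once per test run. Session generation is
# the expensive step, so the commonly reused populations are memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small mixed session: all neuron types present, errors included.
tiny_session <- function() {
  cached("tiny", function() {
    generate_session(synth_config(n_neurons = 12, trials_per_cond = 1,
                                  seed = 101))
  })
}

# No tuning at all: chance-level decoding and null calibrations.
untuned_session <- function() {
  cached("untuned", function() {
    generate_session(synth_config(
      n_neurons = 30, trials_per_cond = 1, frac_untuned = 1,
      frac_transient = 0, frac_reversal = 0, frac_switch = 0,
      error_frac = 0, seed = 102))
  })
}

# Stable sustained tuning only (space + reward), no errors.
sustained_session <- function() {
  cached("sustained", function() {
    generate_session(synth_config(
      n_neurons = 30, trials_per_cond = 2, frac_untuned = 0,
      frac_transient = 0, frac_reversal = 0, frac_switch = 0,
      error_frac = 0, seed = 103))
  })
}

# Pure reversal population (cue -> delay tuning inversion).
reversal_session <- function() {
  cached("reversal", function() {
    generate_session(synth_config(
      n_neurons = 40, trials_per_cond = 2, frac_untuned = 0,
      frac_transient = 0, frac_reversal = 1, frac_switch = 0,
      error_frac = 0, seed = 104))
  })
}

# Pure switch population (space code quenched by the reward cue on
# SR-trials, reward code takes over).
switch_session <- function() {
  cached("switch", function() {
    generate_session(synth_config(
      n_neurons = 40, trials_per_cond = 2, frac_untuned = 0,
      frac_transient = 0, frac_reversal = 0, frac_switch = 1,
      error_frac = 0, seed = 105))
  })
}

# Hand-built minimal session: 1 neuron, 2 trials, 3 spikes.
minimal_session <- function() {
  trials <- tibble::tibble(
    trial_id = 1:2, task_type = c("SR", "RS"), spatial_location = c(1L, 13L),
    reward_level = c(1L, 5L), outcome = c("correct", "correct"),
    fixation_on = 0, cue1_on = 1000, cue1_off = 1500, delay1_end = 2500,
    cue2_on = 2500, cue2_off = 3000, delay2_end = 4000, go = 4000,
    saccade = 4250, reward_on = 4400)
  neurons <- tibble::tibble(neuron_id = 1L, region = "VLPFC")
  spikes <- tibble::tibble(neuron_id = 1L, trial_id = c(1L, 1L, 2L),
                           spike_time_ms = c(100, 2000, 3500))
  wm_session(trials, neurons, spikes)
}
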