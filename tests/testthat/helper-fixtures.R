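# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

shared_patterns <- function() {
  fixture("patterns", function() stimulus_patterns(n_channels = 64, seed = 42))
}

shared_localizer <- function() {
  fixture("localizer", function()
    generate_localizer(shared_patterns(), n_trials = 280, snr = 2, seed = 43))
}

shared_state_classifiers <- function() {
  fixture("state_clf", function()
    suppressWarnings(
      train_state_classifiers(shared_localizer(), train_time = 0.2,
                              seed = 44)))
}

small_behavior <- function(n = 40, seed = 7, params = model_params()) {
  sched <- generate_trial_schedule(n, 0.28, seed = seed)
  walks <- generate_shock_walk(n, seed = seed)
  simulate_choices(params, sched, walks, seed = seed + 1)
}
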