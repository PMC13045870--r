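# Small simulated sessions shared across test files (built once).

small_two_choice_cfg <- function(max_rewards = 8L, seed = 1L,
                                 n_trials = 80L) {
  cfg <- task_preset("two_choice", seed = seed, n_trials = n_trials)
  cfg$session_end$max_rewards <- as.integer(max_rewards)
  cfg$session_end$max_duration_min <- 10
  cfg
}

small_gonogo_cfg <- function(max_rewards = 8L, seed = 1L,
                             n_trials = 200L) {
  cfg <- task_preset("gonogo", seed = seed, n_trials = n_trials)
  cfg$session_end$max_rewards <- as.integer(max_rewards)
  cfg$session_end$max_duration_min <- 10
  cfg
}

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, gen) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- gen()
  .session_cache[[key]]
}

shared_raw_session <- function() {
  cached("raw_two_choice", function()
    run_session(small_two_choice_cfg(),
                agent_policy(d_true = 2, lapse = 0.05,
                             p_lick_decision = 0.9),
                seed = 11))
}

shared_aligned_session <- function() {
  cached("aligned_two_choice",
         function() align_session(shared_raw_session()))
}

shared_classifier <- function() {
  cached("pupil_classifier", function() {
    tr <- operantr:::default_training_set(1)
    train_pupil_classifier(tr$frames, tr$labels, seed = 1)
  })
}
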