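# shared fixtures, built in code

# a parameter set with distinct, hand-checkable rates
toy_params <- function() {
  two_state_params(fast = process_params(0.9, 0.1),
                   slow = process_params(0.99, 0.01))
}

# small single-group config for cohort tests
small_config <- function(taskA = 41, n_subjects = 3, seed = 1, ...) {
  spec <- group_spec("g", n_subjects, taskA, 60)
  cohort_config(groups = list(g = spec), seed = seed, ...)
}

# minimum-jerk ideal force pair used across trace tests
mj_ideal_pair <- function() {
  vel <- minimum_jerk_velocity()
  list(vel = vel, full = ideal_force(vel, 15), half = ideal_force(vel, 7.5))
}
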