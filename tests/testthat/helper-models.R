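# toy models shared across tests

# no-exit chain: everyone stays on their dialysis modality forever
stay_put_model <- function(discount_rate = 0, horizon = 10,
                           half_cycle = FALSE) {
  knobs <- transition_knobs(0, 0, 0, 0, 0, 0)
  fix <- esrd_fixture(knobs = knobs)
  markov_model(fix$model$transitions, fix$model$costs, fix$model$utilities,
               discount_rate = discount_rate, horizon = horizon,
               half_cycle = half_cycle)
}

# only exit is death from dialysis at the given annual probability
death_only_model <- function(p_death, discount_rate = 0, horizon = 10) {
  knobs <- transition_knobs(p_death, p_death, 0, 0, 0, 0)
  fix <- esrd_fixture(knobs = knobs)
  markov_model(fix$model$transitions, fix$model$costs, fix$model$utilities,
               discount_rate = discount_rate, horizon = horizon)
}

fixed_transition_dists <- function(transitions) {
  states <- rrt_states()
  out <- lapply(states, function(s) dist_fixed(transitions[s, ]))
  stats::setNames(out, states)
}

# fully degenerate PSA spec reproducing the deterministic model
degenerate_psa_spec <- function(model, n_iterations = 10, seed = 1) {
  states <- rrt_states()
  psa_spec(
    cost_dists = lapply(stats::setNames(states, states),
                        function(s) dist_fixed(model$costs[[s]])),
    utility_dists = lapply(stats::setNames(states, states),
                           function(s) dist_fixed(model$utilities[[s]])),
    transition_dists = fixed_transition_dists(model$transitions),
    n_iterations = n_iterations, seed = seed
  )
}
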