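# shared fixtures: small deterministic genomes and task configs

# task config whose choice phase is (numerically) always offered
cfg_force_choice <- function(...) task_config(p_choice = 1 - 1e-12, ...)

# a genome with every neuron slot active (for cap tests)
full_genome <- function(seed = 1) {
  set.seed(seed)
  g <- random_genome(active_prob = 1)
  stopifnot(sum(g$neuron_active) == 16)
  g
}

# independent scalar oracle for the extended Hebbian rule, written from the
# closed form rather than the package's vectorised implementation
hebb_oracle <- function(o_j, o_i, m_i, eta, A, B, C, D) {
  tanh(m_i) * eta * (A * o_j * o_i + B * o_j + C * o_i + D)
}

# run one network step for a hand-built weight matrix with no noise
quiet_step <- function(state, input) {
  step_network(state, input, noise = FALSE)
}
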