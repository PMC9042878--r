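#' Build the phenotype network state from a genome
#'
#' Maps every genotype weight through [genotype_to_phenotype_weight()] and the
#' rule coefficients through [genotype_to_phenotype_param()] (eta unchanged),
#' masks rows/columns of inactive neurons, and initialises the unit outputs.
#' The returned state also caches the index sets used by the dynamics: which
#' rows act as standard sources, which as modulatory sources, and which
#' columns (postsynaptic neurons) receive at least one nonzero modulatory
#' connection and are therefore plastic. A neuron without such a connection
#' has modulatory sum 0 at every step, so its incoming weights can never
#' change; computing the mask once at build time is exact.
#'
#' @param g a [new_genome()] object.
#' @param init_outputs `"random"` (trial-reset convention: neuron outputs
#'   uniform in \[-1, 1\], drawn from the current RNG) or `"zero"`.
#' @param reset_mode `"genome_weights"` (default: phenotype weights expressed
#'   from the genome) or `"random_weights"` (weights drawn uniformly in
#'   \[-10, 10\], the literal reading of per-trial re-randomisation).
#' @return object of class `network_state`.
#' @export
build_phenotype <- function(g,
                            init_outputs = c("random", "zero"),
                            reset_mode = c("genome_weights", "random_weights")) {
  validate_genome(g)
  init_outputs <- match.arg(init_outputs)
  reset_mode <- match.arg(reset_mode)

  active <- g$neuron_active
  is_mod <- g$neuron_type == "modulatory" & active
  act_idx <- which(active)

  if (reset_mode == "genome_weights") {
    W <- matrix(genotype_to_phenotype_weight(g$weights), MM_N_UNITS, MM_MAX_NEURONS)
  } else {
    W <- matrix(stats::runif(MM_N_UNITS * MM_MAX_NEURONS,
                             MM_WEIGHT_PHENO_RANGE[1], MM_WEIGHT_PHENO_RANGE[2]),
                MM_N_UNITS, MM_MAX_NEURONS)
  }
  # mask connections touching inactive neurons
  W[, !active] <- 0
  W[MM_N_INPUTS + which(!active), ] <- 0

  outputs <- numeric(MM_N_UNITS)
  if (init_outputs == "random") {
    outputs[MM_N_INPUTS + act_idx] <- stats::runif(length(act_idx), -1, 1)
  }

  std_rows <- c(seq_len(MM_N_INPUTS), MM_N_INPUTS + which(active & !is_mod))
  mod_rows <- MM_N_INPUTS + which(is_mod)
  modulated <- rep(FALSE, MM_MAX_NEURONS)
  if (length(mod_rows)) {
    modulated <- active & colSums(abs(W[mod_rows, , drop = FALSE])) > 0
  }

  structure(
    list(
      weights = W,
      outputs = outputs,
      rule = phenotype_rule(g$rule),
      active = active,
      is_mod = is_mod,
      act_idx = act_idx,
      std_rows = std_rows,
      mod_rows = mod_rows,
      modulated = modulated,
      mod_cols = which(modulated),
      activation_sums = numeric(MM_MAX_NEURONS),
      modulation_sums = numeric(MM_MAX_NEURONS)
    ),
    class = "network_state"
  )
}

#' Advance the network by one synchronous step
#'
#' Reference (pure R) implementation of the dynamics. All new outputs are
#' computed from the previous step's outputs: for each active neuron `i` the
#' standard drive is \eqn{a_i = \sum_{j \in Std} w_{ji} o_j} (input units
#' count as standard sources) and the modulatory drive is
#' \eqn{m_i = \sum_{j \in Mod} w_{ji} o_j}; the new output is
#' `tanh(a_i + noise)`. Input units emit the supplied external value plus
#' Gaussian noise (sd `sigma_input`), with no squashing; other neurons receive
#' Gaussian noise (sd `sigma_neuron`) on `a_i` before the tanh. After the
#' activation pass the extended Hebbian update is applied, using the
#' just-computed outputs and the modulatory sums of this pass, to every
#' incoming connection of each modulated neuron, and the weights are clipped
#' to \[-10, 10\].
#'
#' Noise is drawn from the current RNG state; wrap calls in [with_stream()]
#' to use a dedicated noise stream.
#'
#' @param state a [build_phenotype()] state.
#' @param external_inputs numeric vector of length 7: five pattern bits,
#'   choice-phase signal, bias.
#' @param noise logical; add Gaussian noise (default TRUE).
#' @param plastic logical; apply the weight update (default TRUE).
#' @param sigma_input,sigma_neuron noise standard deviations.
#' @return the updated `network_state`.
#' @export
step_network <- function(state, external_inputs, noise = TRUE, plastic = TRUE,
                         sigma_input = 0.1, sigma_neuron = 1e-4) {
  if (length(external_inputs) != MM_N_INPUTS || any(!is.finite(external_inputs))) {
    stop("external_inputs must be 7 finite values", call. = FALSE)
  }
  o_prev <- state$outputs
  act_idx <- which(state$active)
  W <- state$weights

  in_noise <- if (noise) stats::rnorm(MM_N_INPUTS, 0, sigma_input) else numeric(MM_N_INPUTS)
  a <- as.numeric(crossprod(W[state$std_rows, act_idx, drop = FALSE],
                            o_prev[state$std_rows]))
  m <- if (length(state$mod_rows)) {
    as.numeric(crossprod(W[state$mod_rows, act_idx, drop = FALSE],
                         o_prev[state$mod_rows]))
  } else {
    numeric(length(act_idx))
  }
  n_noise <- if (noise) stats::rnorm(length(act_idx), 0, sigma_neuron) else numeric(length(act_idx))

  outputs <- numeric(MM_N_UNITS)
  outputs[seq_len(MM_N_INPUTS)] <- external_inputs + in_noise
  outputs[MM_N_INPUTS + act_idx] <- tanh(a + n_noise)

  state$outputs <- outputs
  state$activation_sums[] <- 0
  state$activation_sums[act_idx] <- a
  state$modulation_sums[] <- 0
  state$modulation_sums[act_idx] <- m

  if (plastic) {
    mod_cols <- which(state$modulated)
    if (length(mod_cols)) {
      rule <- state$rule
      pre_rows <- c(seq_len(MM_N_INPUTS), MM_N_INPUTS + act_idx)
      o_pre <- outputs[pre_rows]
      o_post <- outputs[MM_N_INPUTS + mod_cols]
      m_post <- state$modulation_sums[mod_cols]
      deltas <- matrix(0, MM_N_UNITS, MM_MAX_NEURONS)
      for (k in seq_along(mod_cols)) {
        deltas[pre_rows, mod_cols[k]] <-
          compute_hebbian_delta(o_pre, o_post[k], m_post[k], rule)
      }
      state <- apply_weight_updates(state, deltas)
    }
  }
  state
}

#' Simulate a constant-input block through the compiled kernel
#'
#' Runs `steps` synchronous network steps under a fixed external input,
#' optionally recording the full output history. This is the bulk variant of
#' [step_network()] (same dynamics, same noise-draw order) for long
#' stimulations — noise calibration, activity spectra, stress runs.
#'
#' @param state a [build_phenotype()] state.
#' @param input numeric vector of length 7.
#' @param steps number of steps.
#' @param noise,plastic,sigma_input,sigma_neuron as in [step_network()].
#' @param record logical; keep the per-step output history.
#' @return list with `state` (updated) and, when recorded, `outputs` (a
#'   23 x `steps` matrix, one column per step).
#' @export
run_network_block <- function(state, input, steps, noise = TRUE,
                              plastic = TRUE, sigma_input = 0.1,
                              sigma_neuron = 1e-4, record = FALSE) {
  if (length(input) != MM_N_INPUTS) stop("input must have 7 values", call. = FALSE)
  res <- mm_run_block(state$weights, state$outputs, as.numeric(input),
                      as.integer(steps), state$act_idx, state$std_rows,
                      state$mod_rows, state$mod_cols,
                      state$rule$eta, state$rule$A, state$rule$B,
                      state$rule$C, state$rule$D,
                      noise, sigma_input, sigma_neuron, plastic, record)
  state$weights <- res$weights
  state$outputs <- res$outputs
  state$activation_sums <- res$activation_sums
  state$modulation_sums <- res$modulation_sums
  out <- list(state = state)
  if (record) out$outputs <- res$record
  out
}

#' Apply weight changes with clipping
#'
#' Adds `deltas` to the phenotype weight matrix and clips every entry to the
#' absolute weight range \[-10, 10\]. Entries of `deltas` must already be zero
#' for connections that are not plastic (unmodulated postsynaptic neurons,
#' masked neurons).
#'
#' @param state a `network_state`.
#' @param deltas numeric 23 x 16 matrix of weight changes.
#' @return the updated state.
#' @export
apply_weight_updates <- function(state, deltas) {
  W <- state$weights + deltas
  state$weights <- matrix(pmin(pmax(W, MM_WEIGHT_PHENO_RANGE[1]), MM_WEIGHT_PHENO_RANGE[2]),
                          MM_N_UNITS, MM_MAX_NEURONS)
  state
}
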