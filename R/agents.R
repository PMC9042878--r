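# Agent protocol: an agent is an environment with a class attribute. The task
# drives any agent through the same three generics, so scripted baseline
# agents and neural-network agents are interchangeable:
#   agent_reset(agent)              -- called once at the start of every trial
#   agent_observe(agent, input, n)  -- present one 7-value input vector for n
#                                      consecutive steps; returns c(decline
#                                      output, answer output) after the last
#   agent_set_phase(agent, label)   -- phase annotation (used by tracing;
#                                      agents must not condition behaviour
#                                      on it)

#' Reset an agent at the start of a trial
#' @param agent an agent object.
#' @return the agent, invisibly.
#' @export
agent_reset <- function(agent) UseMethod("agent_reset")

#' Present an input block to an agent
#' @param agent an agent object.
#' @param input numeric vector of length 7.
#' @param reps number of consecutive steps the input is presented.
#' @return numeric length-2 vector: the decline/take output and the
#'   test-answer output after the final step.
#' @export
agent_observe <- function(agent, input, reps) UseMethod("agent_observe")

#' Annotate the current task phase (no behavioural effect)
#' @param agent an agent object.
#' @param label phase label ("study", "delay", "choice", "test").
#' @return the agent, invisibly.
#' @export
agent_set_phase <- function(agent, label) UseMethod("agent_set_phase")

#' @export
agent_set_phase.default <- function(agent, label) invisible(agent)

# ---------------------------------------------------------------------------
# Neural-network agent

#' Create a neural-network agent from a genome
#'
#' Wraps a genome as a task-playable agent. On every reset the phenotype is
#' rebuilt (weights re-expressed from the genome, or re-randomised under
#' `reset_mode = "random_weights"`) and the neuron outputs are initialised
#' uniformly in \[-1, 1\]. Observation runs the neuromodulated dynamics — by
#' default through the compiled kernel; `engine = "R"` uses the reference
#' [step_network()] implementation and additionally supports per-step trace
#' recording.
#'
#' @param genome a [new_genome()] object.
#' @param streams an [rng_streams()] object; neural noise and reset
#'   randomisation draw from its `noise` stream. If `NULL`, the current RNG
#'   is used directly.
#' @param noise logical; inject Gaussian noise (default TRUE).
#' @param sigma_input,sigma_neuron noise standard deviations (defaults 0.1
#'   and 1e-4).
#' @param reset_mode see [build_phenotype()].
#' @param engine `"cpp"` (fast kernel) or `"R"` (reference implementation).
#' @param record logical; if TRUE (forces `engine = "R"`) every step is
#'   appended to `agent$trace` for mechanism inspection.
#' @return an agent environment of class `network_agent`.
#' @export
network_agent <- function(genome, streams = NULL, noise = TRUE,
                          sigma_input = 0.1, sigma_neuron = 1e-4,
                          reset_mode = c("genome_weights", "random_weights"),
                          engine = c("cpp", "R"), record = FALSE) {
  validate_genome(genome)
  reset_mode <- match.arg(reset_mode)
  engine <- match.arg(engine)
  if (record) engine <- "R"
  a <- new.env(parent = emptyenv())
  a$genome <- genome
  a$streams <- streams
  a$noise <- noise
  a$sigma_input <- sigma_input
  a$sigma_neuron <- sigma_neuron
  a$reset_mode <- reset_mode
  a$engine <- engine
  a$record <- record
  a$trace <- list()
  a$phase <- NA_character_
  a$step_count <- 0L
  a$state <- NULL
  # phenotype template: expressed once; per-trial reset only re-randomises
  # the outputs (under "random_weights" the whole state is rebuilt per trial)
  if (reset_mode == "genome_weights") {
    a$template <- build_phenotype(genome, init_outputs = "zero",
                                  reset_mode = "genome_weights")
  }
  class(a) <- c("network_agent", "agent")
  a
}

.with_agent_noise <- function(agent, expr) {
  if (is.null(agent$streams)) expr else with_stream(agent$streams, "noise", expr)
}

#' @export
agent_reset.network_agent <- function(agent) {
  if (agent$reset_mode == "genome_weights") {
    st <- agent$template
    st$outputs[MM_N_INPUTS + st$act_idx] <-
      .with_agent_noise(agent, stats::runif(length(st$act_idx), -1, 1))
    agent$state <- st
  } else {
    agent$state <- .with_agent_noise(
      agent,
      build_phenotype(agent$genome, init_outputs = "random",
                      reset_mode = agent$reset_mode)
    )
  }
  agent$trace <- list()
  agent$step_count <- 0L
  invisible(agent)
}

#' @export
agent_set_phase.network_agent <- function(agent, label) {
  agent$phase <- label
  invisible(agent)
}

#' @export
agent_observe.network_agent <- function(agent, input, reps) {
  if (length(input) != MM_N_INPUTS) stop("input must have 7 values", call. = FALSE)
  st <- agent$state
  if (is.null(st)) stop("agent_observe called before agent_reset", call. = FALSE)
  if (agent$engine == "cpp") {
    res <- .with_agent_noise(agent, mm_run_block(
      st$weights, st$outputs, as.numeric(input), as.integer(reps),
      st$act_idx, st$std_rows, st$mod_rows, st$mod_cols,
      st$rule$eta, st$rule$A, st$rule$B, st$rule$C, st$rule$D,
      agent$noise, agent$sigma_input, agent$sigma_neuron,
      TRUE, FALSE
    ))
    st$weights <- res$weights
    st$outputs <- res$outputs
    st$activation_sums <- res$activation_sums
    st$modulation_sums <- res$modulation_sums
  } else {
    for (i in seq_len(reps)) {
      st <- .with_agent_noise(agent, step_network(
        st, input, noise = agent$noise, plastic = TRUE,
        sigma_input = agent$sigma_input, sigma_neuron = agent$sigma_neuron
      ))
      if (agent$record) {
        agent$step_count <- agent$step_count + 1L
        agent$trace[[length(agent$trace) + 1L]] <- list(
          step = agent$step_count,
          phase = agent$phase,
          inputs = as.numeric(input),
          outputs = st$outputs,
          modulation_sums = st$modulation_sums,
          weights = st$weights
        )
      }
    }
  }
  agent$state <- st
  st$outputs[MM_N_INPUTS + MM_OUTPUT_NEURONS]
}

# ---------------------------------------------------------------------------
# Scripted baseline agents

#' Scripted baseline agents with analytically known behaviour
#'
#' Policy-driven agents that honour the agent protocol but bypass the neural
#' network, used as oracles for the task environment:
#'
#' * `"always_decline"` — declines whenever the choice phase is offered and
#'   never answers in the test phase.
#' * `"always_take_random"` — always takes the test and responds positively
#'   to exactly one, uniformly chosen, of the five test presentations
#'   (forced-test accuracy is exactly 1/5).
#' * `"perfect_oracle"` — remembers the study pattern perfectly and answers
#'   it; on unsolvable trials (study stimulus all-zero) it declines.
#' * `"constant_output"` — emits `value` on both outputs at every step.
#'
#' Scripted agents identify the study phase as the first block after reset
#' and the choice phase by the choice-signal input; they never inspect the
#' phase annotation.
#'
#' @param policy policy name.
#' @param value constant output level for `"constant_output"`.
#' @param streams optional [rng_streams()]; the random answerer draws its
#'   answer position from the `task` stream (current RNG if `NULL`).
#' @return an agent environment of class `scripted_agent`.
#' @export
scripted_agent <- function(policy = c("always_decline", "always_take_random",
                                      "perfect_oracle", "constant_output"),
                           value = 0, streams = NULL) {
  policy <- match.arg(policy)
  a <- new.env(parent = emptyenv())
  a$policy <- policy
  a$value <- value
  a$streams <- streams
  a$n_blocks <- 0L
  a$test_count <- 0L
  a$stored <- NULL
  a$answer_pos <- NA_integer_
  class(a) <- c("scripted_agent", "agent")
  a
}

#' @export
agent_reset.scripted_agent <- function(agent) {
  agent$n_blocks <- 0L
  agent$test_count <- 0L
  agent$stored <- NULL
  if (agent$policy == "always_take_random") {
    agent$answer_pos <- if (is.null(agent$streams)) {
      sample.int(5L, 1L)
    } else {
      with_stream(agent$streams, "task", sample.int(5L, 1L))
    }
  }
  invisible(agent)
}

#' @export
agent_observe.scripted_agent <- function(agent, input, reps) {
  agent$n_blocks <- agent$n_blocks + 1L
  if (agent$policy == "constant_output") {
    return(c(agent$value, agent$value))
  }
  bits <- round(input[1:5])
  signal <- round(input[6])
  if (agent$n_blocks == 1L) {   # study phase is always the first block
    agent$stored <- bits
    return(c(-1, -1))
  }
  if (signal == 1) {            # choice phase
    decline <- switch(agent$policy,
      always_decline = 1,
      always_take_random = -1,
      perfect_oracle = if (all(agent$stored == 0)) 1 else -1
    )
    return(c(decline, -1))
  }
  if (any(bits == 1)) {         # test presentation
    agent$test_count <- agent$test_count + 1L
    answer <- switch(agent$policy,
      always_decline = -1,
      always_take_random = if (agent$test_count == agent$answer_pos) 1 else -1,
      perfect_oracle = if (all(bits == agent$stored)) 1 else -1
    )
    return(c(-1, answer))
  }
  c(-1, -1)                     # delay phase
}
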