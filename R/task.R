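#' Task configuration for the delayed match-to-sample environment
#'
#' All task constants, with the reference defaults: delay-shape parameter
#' `lambda = 0.7`; choice-phase constant input `cv = 0.25` delivered to each
#' pattern input; choice-phase probability 2/3 (skipped as a compulsory,
#' forced, trial otherwise); rewards 0.3 (decline, solvable), 1.0 (correct
#' match, or decline on an unsolvable trial) and 0.0 (otherwise); decision
#' threshold 1/3; inputs repeated 4 times per presentation in the choice
#' phase and 3 times in every other phase; Gaussian noise sd 0.1 on input
#' units and 1e-4 on all other neurons.
#'
#' @param lambda delay-distribution shape parameter (> 0).
#' @param cv choice-phase constant input value.
#' @param p_choice probability that the choice phase occurs.
#' @param reward_decline,reward_correct,reward_none reward levels.
#' @param threshold decision threshold for both outputs.
#' @param reps_choice,reps_other input repetition counts.
#' @param sigma_input,sigma_neuron noise standard deviations.
#' @return object of class `task_config`.
#' @export
task_config <- function(lambda = 0.7, cv = 0.25, p_choice = 2 / 3,
                        reward_decline = 0.3, reward_correct = 1.0,
                        reward_none = 0.0, threshold = 1 / 3,
                        reps_choice = 4L, reps_other = 3L,
                        sigma_input = 0.1, sigma_neuron = 1e-4) {
  if (!is.finite(lambda) || lambda <= 0) {
    stop("task config error: lambda must be > 0", call. = FALSE)
  }
  if (!is.finite(p_choice) || p_choice <= 0 || p_choice >= 1) {
    stop("task config error: p_choice must be in (0, 1)", call. = FALSE)
  }
  stopifnot(is.finite(threshold), is.finite(reward_decline),
            is.finite(reward_correct), is.finite(reward_none),
            reps_choice >= 1, reps_other >= 1)
  structure(
    list(lambda = lambda, cv = cv, p_choice = p_choice,
         reward_decline = reward_decline, reward_correct = reward_correct,
         reward_none = reward_none, threshold = threshold,
         reps_choice = as.integer(reps_choice),
         reps_other = as.integer(reps_other),
         sigma_input = sigma_input, sigma_neuron = sigma_neuron),
    class = "task_config"
  )
}

#' The five one-hot target patterns and the distractor
#'
#' @return 5 x 5 0/1 matrix; row names are the bit strings ("00001" ...
#'   "10000"), read left to right as input units 1..5.
#' @export
dmts_patterns <- function() MM_PATTERNS

MM_PATTERNS <- local({
  p <- diag(5)[5:1, , drop = FALSE]
  rownames(p) <- apply(p, 1, paste, collapse = "")
  p
})
MM_PATTERN_NAMES <- rownames(MM_PATTERNS)
MM_DISTRACTOR <- "00000"

.pattern_bits <- function(label) {
  if (label == MM_DISTRACTOR) return(rep(0, 5))
  MM_PATTERNS[label, ]
}

#' Sample the delay length
#'
#' The number of distractor presentations in the delay phase is
#' \deqn{N_{delay} = \lfloor -1 / (\lambda \ln R) \rfloor + 1}
#' with `R` uniform on (0, 1). The induced law is
#' \eqn{P(N \le k) = \exp(-1 / (\lambda k))}: heavy-tailed, with
#' \eqn{P(N = 1) = e^{-1/\lambda}} (about 0.24 at the default
#' `lambda = 0.7`). Draws come from the current RNG state.
#'
#' @param lambda shape parameter (> 0).
#' @param n number of samples.
#' @return integer vector of delays, each >= 1.
#' @export
sample_delay <- function(lambda = 0.7, n = 1L) {
  if (!is.finite(lambda) || lambda <= 0) {
    stop("task config error: lambda must be > 0", call. = FALSE)
  }
  R <- stats::runif(n)
  as.integer(floor(-1 / (lambda * log(R))) + 1)
}

#' Encode a task phase as the 7 network inputs
#'
#' Input layout: five pattern inputs, the choice-phase signal (1 during the
#' choice phase, 0 otherwise), and the bias (always 1). During the choice
#' phase every pattern input carries the constant value `cv`, which gives the
#' network a probe with which to interrogate its own memory trace.
#'
#' @param phase one of `"study"`, `"delay"`, `"choice"`, `"test"`.
#' @param pattern bit-string label (e.g. `"00001"`) or 5-bit vector;
#'   required for study/test, disallowed for delay/choice.
#' @param cfg a [task_config()].
#' @return numeric vector of length 7.
#' @export
encode_inputs <- function(phase = c("study", "delay", "choice", "test"),
                          pattern = NULL, cfg = task_config()) {
  phase <- match.arg(phase)
  if (phase %in% c("study", "test")) {
    if (is.null(pattern)) stop("pattern required for ", phase, " phase", call. = FALSE)
    bits <- if (is.character(pattern)) .pattern_bits(pattern) else as.numeric(pattern)
    if (length(bits) != 5) stop("pattern must have 5 bits", call. = FALSE)
    c(bits, 0, 1)
  } else {
    if (!is.null(pattern)) stop("no pattern in ", phase, " phase", call. = FALSE)
    if (phase == "delay") c(rep(0, 5), 0, 1) else c(rep(cfg$cv, 5), 1, 1)
  }
}

#' Decode the choice-phase output
#'
#' @param output_value the decline/take output after the choice block.
#' @param threshold decision threshold (default 1/3).
#' @return `"decline"` if the value strictly exceeds the threshold,
#'   `"take"` otherwise.
#' @export
decode_choice <- function(output_value, threshold = 1 / 3) {
  if (!is.finite(output_value)) stop("non-finite choice output", call. = FALSE)
  if (output_value > threshold) "decline" else "take"
}

#' Run one delayed match-to-sample trial
#'
#' Phase sequence: study (target presented `reps_other` times), delay (the
#' all-zero distractor presented `N_delay` times, `reps_other` steps each),
#' then with probability `p_choice` the choice phase (`reps_choice` steps;
#' decline if the decline output exceeds the threshold after the block), and
#' finally — unless the trial was declined — the test phase, in which the
#' five patterns are presented successively in random order and the first
#' whose answer output exceeds the threshold is taken as the agent's answer.
#'
#' Rewards: declining earns 0.3 on a solvable trial and 1.0 on an unsolvable
#' one (study stimulus = distractor); a correct match earns 1.0; anything
#' else earns 0.0.
#'
#' @param agent an agent (see [network_agent()], [scripted_agent()]).
#' @param cfg a [task_config()].
#' @param streams an [rng_streams()] object; task events (target, delay,
#'   choice coin, test order) draw from its `task` stream.
#' @param unsolvable logical; present the distractor in the study phase.
#' @param force_skip_choice logical; always skip the choice phase (forced
#'   trial).
#' @param fixed_delay optional integer; override delay sampling.
#' @param counterfactual logical; if the agent declines, still run the test
#'   phase and record the answer it would have given, without changing the
#'   reward.
#' @return object of class `trial_outcome`: a list with fields `target`,
#'   `delay_steps`, `choice_offered`, `declined`, `answered_pattern`,
#'   `correct`, `reward`, `unsolvable`, and (when counterfactual) `cf_answer`
#'   and `cf_correct`.
#' @export
run_trial <- function(agent, cfg = task_config(), streams,
                      unsolvable = FALSE, force_skip_choice = FALSE,
                      fixed_delay = NULL, counterfactual = FALSE) {
  pats <- MM_PATTERN_NAMES
  target <- if (unsolvable) {
    MM_DISTRACTOR
  } else {
    pats[with_stream(streams, "task", sample.int(5L, 1L))]
  }

  agent_reset(agent)

  study_in <- c(if (unsolvable) rep(0, 5) else MM_PATTERNS[target, ], 0, 1)
  agent_set_phase(agent, "study")
  agent_observe(agent, study_in, cfg$reps_other)

  n_delay <- if (is.null(fixed_delay)) {
    with_stream(streams, "task", sample_delay(cfg$lambda, 1L))
  } else {
    as.integer(fixed_delay)
  }
  agent_set_phase(agent, "delay")
  agent_observe(agent, c(rep(0, 5), 0, 1), cfg$reps_other * n_delay)

  choice_offered <- !force_skip_choice &&
    with_stream(streams, "task", stats::runif(1L)) < cfg$p_choice
  declined <- FALSE
  if (choice_offered) {
    agent_set_phase(agent, "choice")
    out <- agent_observe(agent, c(rep(cfg$cv, 5), 1, 1), cfg$reps_choice)
    declined <- out[1] > cfg$threshold
  }

  answered <- NA_character_
  if (!declined || counterfactual) {
    agent_set_phase(agent, "test")
    ord <- with_stream(streams, "task", sample.int(5L))
    for (k in ord) {
      out <- agent_observe(agent, c(MM_PATTERNS[k, ], 0, 1), cfg$reps_other)
      if (out[2] > cfg$threshold) {
        answered <- pats[k]
        break
      }
    }
  }

  correct <- !is.na(answered) && answered == target
  reward <- if (declined) {
    if (unsolvable) cfg$reward_correct else cfg$reward_decline
  } else if (correct) {
    cfg$reward_correct
  } else {
    cfg$reward_none
  }

  out <- list(
    target = target, delay_steps = n_delay, choice_offered = choice_offered,
    declined = declined,
    answered_pattern = if (declined) NA_character_ else answered,
    correct = !declined && correct,
    reward = reward, unsolvable = unsolvable
  )
  if (counterfactual && declined) {
    out$cf_answer <- answered
    out$cf_correct <- correct
  }
  structure(out, class = "trial_outcome")
}

#' Run many trials and return a tidy log
#'
#' One row per trial: target, delay, whether the choice phase was offered,
#' decline decision, answer, correctness and reward (plus counterfactual
#' columns when requested). Suitable for direct CSV export.
#'
#' @inheritParams run_trial
#' @param n number of trials.
#' @return a data.frame with `n` rows.
#' @export
run_trials <- function(agent, n, cfg = task_config(), streams,
                       unsolvable = FALSE, force_skip_choice = FALSE,
                       fixed_delay = NULL, counterfactual = FALSE) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- run_trial(agent, cfg, streams, unsolvable = unsolvable,
                    force_skip_choice = force_skip_choice,
                    fixed_delay = fixed_delay, counterfactual = counterfactual)
    rows[[i]] <- data.frame(
      target = tr$target, delay = tr$delay_steps,
      choice_offered = tr$choice_offered, declined = tr$declined,
      answer = if (is.na(tr$answered_pattern)) NA_character_ else tr$answered_pattern,
      correct = tr$correct, reward = tr$reward, unsolvable = tr$unsolvable,
      cf_answer = if (counterfactual && tr$declined && !is.null(tr$cf_answer) &&
                      !is.na(tr$cf_answer)) tr$cf_answer else NA_character_,
      cf_correct = if (counterfactual && tr$declined) isTRUE(tr$cf_correct) else NA,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
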