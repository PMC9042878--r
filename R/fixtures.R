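#' Closed-form expected fitness of scripted agents
#'
#' Exact expected total reward of a [scripted_agent()] over the evaluation
#' schedule (`tasks_per_eval` trials, `unsolvable_per_eval` of them
#' unsolvable, choice phase offered with probability `p_choice`). Used as an
#' independent oracle for [evaluate_fitness()]:
#'
#' * `always_decline`: declines whenever offered, never answers —
#'   `U p 1.0 + (T - U) p 0.3` (forced trials contribute 0).
#' * `always_take_random`: answers a uniformly random test presentation —
#'   `(T - U) / 5` (unsolvable trials can never match).
#' * `perfect_oracle`: always correct on solvable trials, declines
#'   unsolvable ones when offered — `(T - U) + U p`.
#' * `constant_output`: if `value > threshold` the agent declines when
#'   offered and otherwise answers the first test presentation
#'   (`U p + (T - U)(0.3 p + (1 - p) / 5)`); if `value <= threshold` it
#'   never declines and never answers (0).
#'
#' @param policy scripted policy name.
#' @param cfg a [ga_config()] (supplies T and U).
#' @param task_cfg a [task_config()] (supplies p_choice, rewards,
#'   threshold).
#' @param value constant output level for `"constant_output"`.
#' @return the expected fitness.
#' @export
expected_scripted_fitness <- function(policy = c("always_decline",
                                                 "always_take_random",
                                                 "perfect_oracle",
                                                 "constant_output"),
                                      cfg = ga_config(),
                                      task_cfg = task_config(),
                                      value = 0) {
  policy <- match.arg(policy)
  T_ <- cfg$tasks_per_eval
  U <- cfg$unsolvable_per_eval
  p <- task_cfg$p_choice
  r_d <- task_cfg$reward_decline
  r_c <- task_cfg$reward_correct
  switch(policy,
    always_decline = U * p * r_c + (T_ - U) * p * r_d,
    always_take_random = (T_ - U) * (1 / 5) * r_c,
    perfect_oracle = (T_ - U) * r_c + U * p * r_c,
    constant_output = {
      if (value > task_cfg$threshold) {
        # declines when offered; forced: answers the first test presentation,
        # correct with probability 1/5 on solvable trials
        U * p * r_c + (T_ - U) * (p * r_d + (1 - p) * (1 / 5) * r_c)
      } else {
        0
      }
    }
  )
}
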