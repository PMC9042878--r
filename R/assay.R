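#' Behavioral assay: forced, chosen and declined-counterfactual accuracy
#'
#' Runs the agent through the task under two protocols at each requested
#' delay: *forced* trials (choice phase skipped) and *offered* trials (choice
#' phase always presented; if the agent declines, the test phase is still run
#' counterfactually so the answer it would have given is recorded, without
#' affecting the reward). The per-trial log is aggregated by target pattern
#' and delay into forced accuracy, chosen-test accuracy, declined-test
#' counterfactual accuracy, and take/decline probabilities — the summary
#' needed to ask whether an agent's declining tracks its own memory: a
#' metamemory-positive agent shows chosen accuracy above forced accuracy and
#' declined-counterfactual accuracy below it.
#'
#' @param agent_or_genome a genome (wrapped in a [network_agent()]) or an
#'   agent object.
#' @param n_trials trials per protocol per delay.
#' @param delays integer vector of fixed delays, or `NULL` to sample delays
#'   from the task's delay law (aggregation then bins by realised delay).
#' @param cfg a [task_config()].
#' @param streams an [rng_streams()] object, or `seed` may be given instead.
#' @param seed convenience master seed used when `streams` is missing.
#' @param noise,reset_mode passed to [network_agent()] for genomes.
#' @return object of class `behavior_summary`: list with `trials` (tidy
#'   per-trial log) and `summary` (one row per delay x pattern with columns
#'   `n_forced`, `accuracy_forced`, `n_offered`, `p_take`, `p_decline`,
#'   `accuracy_chosen`, `accuracy_declined_cf`).
#' @export
run_behavior_assay <- function(agent_or_genome, n_trials = 100L,
                               delays = c(1L, 10L, 40L), cfg = task_config(),
                               streams = NULL, seed = 1L, noise = TRUE,
                               reset_mode = "genome_weights") {
  if (n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  if (is.null(streams)) streams <- rng_streams(seed)
  agent <- if (inherits(agent_or_genome, "genome")) {
    network_agent(agent_or_genome, streams = streams, noise = noise,
                  sigma_input = cfg$sigma_input, sigma_neuron = cfg$sigma_neuron,
                  reset_mode = reset_mode)
  } else {
    agent_or_genome
  }

  delay_list <- if (is.null(delays)) list(NULL) else as.list(delays)
  logs <- list()
  for (d in delay_list) {
    forced <- run_trials(agent, n_trials, cfg, streams,
                         force_skip_choice = TRUE, fixed_delay = d)
    forced$protocol <- "forced"
    offered <- run_trials(agent, n_trials, cfg2_force_choice(cfg), streams,
                          fixed_delay = d, counterfactual = TRUE)
    offered$protocol <- "offered"
    logs[[length(logs) + 1L]] <- rbind(forced, offered)
  }
  trials <- do.call(rbind, logs)

  summary <- .summarise_assay(trials)
  structure(list(trials = trials, summary = summary),
            class = "behavior_summary")
}

# offered-protocol trials must always present the choice phase; p_choice is
# pushed against its open-interval bound rather than to 1 exactly
cfg2_force_choice <- function(cfg) {
  cfg$p_choice <- 1 - 1e-12
  cfg
}

.summarise_assay <- function(trials) {
  key <- interaction(trials$delay, trials$target, drop = TRUE)
  rows <- lapply(split(trials, key), function(df) {
    f <- df[df$protocol == "forced", ]
    o <- df[df$protocol == "offered", ]
    taken <- o[!o$declined, ]
    decl <- o[o$declined, ]
    data.frame(
      delay = df$delay[1], pattern = df$target[1],
      n_forced = nrow(f),
      accuracy_forced = if (nrow(f)) mean(f$correct) else NA_real_,
      n_offered = nrow(o),
      p_take = if (nrow(o)) mean(!o$declined) else NA_real_,
      p_decline = if (nrow(o)) mean(o$declined) else NA_real_,
      accuracy_chosen = if (nrow(taken)) mean(taken$correct) else NA_real_,
      accuracy_declined_cf = if (nrow(decl)) mean(decl$cf_correct) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delay, out$pattern), ]
  rownames(out) <- NULL
  out
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary> ", nrow(x$trials), " trials\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Decline probability as a function of delay
#'
#' @param x a `behavior_summary` (or its `trials` data.frame) covering at
#'   least two delay values.
#' @param conf confidence level for the exact binomial interval.
#' @return data.frame with one row per delay: `n_offered`, `n_declined`,
#'   `p_decline`, `ci_lo`, `ci_hi`. Delays with no offered trials are
#'   reported with `NA` probabilities.
#' @export
decline_rate_by_delay <- function(x, conf = 0.95) {
  trials <- if (inherits(x, "behavior_summary")) x$trials else x
  offered <- if (!is.null(trials$protocol)) {
    trials[trials$protocol == "offered", ]
  } else {
    trials
  }
  offered <- offered[offered$choice_offered, ]
  delays <- sort(unique(trials$delay))
  if (length(delays) < 2L) {
    stop("decline_rate_by_delay needs trials at >= 2 delay values", call. = FALSE)
  }
  rows <- lapply(delays, function(d) {
    o <- offered[offered$delay == d, ]
    n <- nrow(o)
    if (n == 0L) {
      return(data.frame(delay = d, n_offered = 0L, n_declined = NA_integer_,
                        p_decline = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    }
    k <- sum(o$declined)
    ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
    data.frame(delay = d, n_offered = n, n_declined = k, p_decline = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot decline rate against delay
#'
#' @param tbl output of [decline_rate_by_delay()].
#' @return a ggplot object.
#' @export
plot_decline_by_delay <- function(tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_decline_by_delay requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(tbl, ggplot2::aes(x = delay, y = p_decline)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delay (distractor presentations)",
                  y = "P(decline)") +
    ggplot2::ylim(0, 1)
}

#' Record a full state trace of one trial
#'
#' Runs one trial with the reference (pure R) network engine, logging at
#' every network step the phase, the input vector, every unit output, every
#' modulatory sum, and a snapshot of the full weight matrix. This is the raw
#' material for mechanism-level inspection of an evolved network — e.g.
#' watching the input-to-core-modulatory-neuron weights absorb the study
#' pattern and then freeze as the opposing modulatory signals cancel.
#'
#' @param genome a [new_genome()] object.
#' @param cfg a [task_config()].
#' @param streams an [rng_streams()] object, or use `seed`.
#' @param seed convenience master seed used when `streams` is missing.
#' @param unsolvable,force_skip_choice,fixed_delay,counterfactual trial
#'   options, as in [run_trial()].
#' @param noise logical; neural noise (disable for deterministic traces).
#' @param reset_mode phenotype reset convention.
#' @return object of class `trace_record`: list with `outcome` (the
#'   [run_trial()] result) and `steps` (one record per network step).
#'   `as.data.frame()` converts it to a long tidy table (step, phase, unit,
#'   quantity, value).
#' @export
record_trace <- function(genome, cfg = task_config(), streams = NULL,
                         seed = 1L, unsolvable = FALSE,
                         force_skip_choice = FALSE, fixed_delay = NULL,
                         counterfactual = FALSE, noise = TRUE,
                         reset_mode = "genome_weights") {
  if (is.null(streams)) streams <- rng_streams(seed)
  agent <- network_agent(genome, streams = streams, noise = noise,
                         sigma_input = cfg$sigma_input,
                         sigma_neuron = cfg$sigma_neuron,
                         reset_mode = reset_mode, record = TRUE)
  outcome <- run_trial(agent, cfg, streams, unsolvable = unsolvable,
                       force_skip_choice = force_skip_choice,
                       fixed_delay = fixed_delay,
                       counterfactual = counterfactual)
  structure(list(outcome = outcome, steps = agent$trace),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat("<trace_record> ", length(x$steps), " steps; reward ",
      x$outcome$reward, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trace_record <- function(x, ...) {
  unit_names <- c(paste0("in_", 1:7), paste0("nrn_", 1:16))
  nrn_names <- unit_names[8:23]
  conn_names <- paste0(rep(unit_names, times = 16), "->",
                       rep(nrn_names, each = 23))
  units <- c(unit_names, nrn_names, conn_names)
  quantities <- c(rep("output", 23), rep("modulation_sum", 16),
                  rep("weight", length(conn_names)))
  rows <- lapply(x$steps, function(s) {
    data.frame(
      step = s$step, phase = s$phase, unit = units, quantity = quantities,
      value = c(s$outputs, s$modulation_sums, as.numeric(s$weights)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
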