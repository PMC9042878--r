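test_that("behavior assay aggregates forced/chosen/declined protocols", {
  s <- rng_streams(1)
  decl <- scripted_agent("always_decline", streams = s)
  res <- run_behavior_assay(decl, n_trials = 60, delays = c(1, 5), streams = s)
  expect_s3_class(res, "behavior_summary")
  expect_true(all(res$summary$p_decline == 1))
  expect_true(all(res$summary$p_take == 0))
  expect_true(all(is.na(res$summary$accuracy_chosen)))
  expect_true(all(res$summary$p_take + res$summary$p_decline == 1))

  s2 <- rng_streams(2)
  oracle <- scripted_agent("perfect_oracle", streams = s2)
  res2 <- run_behavior_assay(oracle, n_trials = 40, delays = c(1, 5),
                             streams = s2)
  expect_true(all(res2$summary$accuracy_forced == 1))
  expect_true(all(res2$summary$accuracy_chosen == 1))
})

test_that("random answerer shows chance-level forced accuracy in the assay", {
  s <- rng_streams(3)
  taker <- scripted_agent("always_take_random", streams = s)
  res <- run_behavior_assay(taker, n_trials = 600, delays = 1, streams = s)
  forced_acc <- with(res$trials[res$trials$protocol == "forced", ],
                     mean(correct))
  se <- sqrt(0.2 * 0.8 / 600)
  expect_lt(abs(forced_acc - 0.2), 3.5 * se)
})

test_that("decline rate by delay: flat curve, CI recovery, input checks", {
  s <- rng_streams(4)
  decl <- scripted_agent("always_decline", streams = s)
  res <- run_behavior_assay(decl, n_trials = 30, delays = c(1, 3, 5),
                            streams = s)
  tbl <- decline_rate_by_delay(res)
  expect_equal(tbl$p_decline, rep(1, 3))
  expect_true(all(tbl$ci_hi == 1))

  one <- run_behavior_assay(decl, n_trials = 10, delays = 1, streams = s)
  expect_error(decline_rate_by_delay(one), ">= 2 delay")
})

test_that("a scripted delay-dependent decline curve is recovered within CI", {
  # agent declining with probability delay/(delay + 10), known ground truth
  make_pdecl_agent <- function(streams) {
    a <- new.env(parent = emptyenv())
    a$streams <- streams
    a$last_delay_steps <- 0L
    class(a) <- c("pdecl_agent", "agent")
    a
  }
  registerS3method("agent_reset", "pdecl_agent",
                   function(agent) { agent$last_delay_steps <- 0L; invisible(agent) },
                   envir = asNamespace("metamem"))
  registerS3method("agent_observe", "pdecl_agent",
                   function(agent, input, reps) {
                     if (round(input[6]) == 1) {  # choice phase
                       d <- agent$last_delay_steps / 3
                       p <- d / (d + 10)
                       u <- with_stream(agent$streams, "task", runif(1))
                       return(c(if (u < p) 1 else -1, -1))
                     }
                     if (all(round(input[1:5]) == 0)) {
                       agent$last_delay_steps <- agent$last_delay_steps + reps
                     }
                     c(-1, -1)
                   },
                   envir = asNamespace("metamem"))
  s <- rng_streams(5)
  ag <- make_pdecl_agent(s)
  res <- run_behavior_assay(ag, n_trials = 400, delays = c(2, 10, 30),
                            streams = s)
  tbl <- decline_rate_by_delay(res, conf = 0.99)
  truth <- c(2, 10, 30) / (c(2, 10, 30) + 10)
  expect_true(all(tbl$ci_lo <= truth & truth <= tbl$ci_hi))
  # and the decline rate increases with delay
  expect_true(all(diff(tbl$p_decline) > 0))
})

test_that("trace recording is complete and does not disturb outcomes", {
  g <- make_toy_genome("zero")
  # zero genome, noise off: all outputs stay 0 at every step
  tr <- record_trace(g, task_config(), seed = 11, noise = FALSE,
                     fixed_delay = 2, force_skip_choice = TRUE)
  expect_s3_class(tr, "trace_record")
  outs <- vapply(tr$steps, function(s) max(abs(s$outputs[8:23])), numeric(1))
  expect_true(all(outs == 0))
  # forced trial, no answer: 3 study + 3*2 delay + 5*3 test presentations
  expect_length(tr$steps, 3 + 6 + 15)

  # offered trial with the zero agent: choice block adds 4 steps
  tr2 <- record_trace(g, cfg_force_choice(), seed = 11, noise = FALSE,
                      fixed_delay = 2)
  expect_length(tr2$steps, 3 + 6 + 4 + 15)
  expect_equal(unique(vapply(tr2$steps, `[[`, "", "phase")),
               c("study", "delay", "choice", "test"))

  # same seeds, tracing on vs off: identical outcome
  g3 <- make_toy_genome("full_random", seed = 6)
  s1 <- rng_streams(21)
  plain <- run_trial(network_agent(g3, streams = s1), task_config(), s1)
  s2 <- rng_streams(21)
  traced <- record_trace(g3, task_config(), streams = s2)
  expect_identical(traced$outcome$reward, plain$reward)
  expect_identical(traced$outcome$target, plain$target)
  expect_identical(traced$outcome$declined, plain$declined)

  # weights frozen while no modulation (zero genome trace)
  wmax <- vapply(tr$steps, function(s) max(abs(s$weights)), numeric(1))
  expect_true(all(wmax == 0))

  # tidy export
  df <- as.data.frame(tr2)
  expect_true(all(c("step", "phase", "unit", "quantity", "value") %in% names(df)))
  expect_true(all(abs(df$value[df$quantity == "weight"]) <= 10))
})
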