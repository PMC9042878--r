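test_that("phenotype build maps, masks and caches index sets", {
  # single expressed connection
  g <- make_toy_genome("zero")
  g$weights[1, 1] <- 1.0
  st <- build_phenotype(g, init_outputs = "zero")
  expect_equal(st$weights[1, 1], 10.0)
  expect_equal(sum(st$weights != 0), 1)

  # a deactivated neuron contributes nothing to any drive
  set.seed(4)
  g2 <- random_genome(active_prob = 1)
  g3 <- g2
  g3$neuron_active[5] <- FALSE
  st2 <- build_phenotype(g2, init_outputs = "zero")
  st3 <- build_phenotype(g3, init_outputs = "zero")
  expect_true(all(st3$weights[, 5] == 0))
  expect_true(all(st3$weights[7 + 5, ] == 0))

  # masking is equivalent to removing the neuron from every sum
  st2$weights[, 5] <- 0
  st2$weights[7 + 5, ] <- 0
  inp <- encode_inputs("study", "00100")
  a2 <- quiet_step(st2, inp)
  a3 <- quiet_step(st3, inp)
  expect_equal(a3$outputs[-(7 + 5)], a2$outputs[-(7 + 5)], tolerance = 1e-12)
})

test_that("synchronous step follows the tanh dynamics", {
  st <- build_phenotype(make_toy_genome("zero"), init_outputs = "zero")
  st <- quiet_step(st, rep(0, 7))
  expect_true(all(st$outputs == 0))

  # one strong connection from a saturated input
  g <- make_toy_genome("zero")
  g$weights[1, 1] <- 1.0   # phenotype 10
  st <- build_phenotype(g, init_outputs = "zero")
  st <- quiet_step(st, c(1, 0, 0, 0, 0, 0, 0))  # inputs appear this step
  st <- quiet_step(st, c(1, 0, 0, 0, 0, 0, 0))  # neuron sees them next step
  expect_equal(st$outputs[8], tanh(10), tolerance = 1e-12)

  # input units emit raw values (no squashing)
  expect_equal(st$outputs[1], 1)
})

test_that("modulatory input drives m, not a", {
  # neuron 3 (modulatory) -> neuron 4 (standard) is neuron 4's only input
  g <- make_toy_genome("zero")
  g$neuron_active[3:4] <- TRUE
  g$neuron_type[3] <- "modulatory"
  g$weights[7, 3] <- 1.0        # bias drives the modulatory neuron
  g$weights[7 + 3, 4] <- 1.0    # modulatory -> standard
  st <- build_phenotype(g, init_outputs = "zero")
  for (i in 1:4) st <- quiet_step(st, c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(st$outputs[7 + 4], 0)          # no standard drive
  expect_equal(st$activation_sums[4], 0)
  expect_gt(abs(st$modulation_sums[4]), 1)    # but strong modulation
})

test_that("converting a presynaptic neuron between types moves its drive exactly", {
  set.seed(11)
  for (rep in 1:5) {
    g <- random_genome(active_prob = 1)
    g$neuron_type[4] <- "standard"
    gm <- g
    gm$neuron_type[4] <- "modulatory"
    st <- build_phenotype(g, init_outputs = "zero")
    stm <- build_phenotype(gm, init_outputs = "zero")
    o0 <- runif(23, -1, 1)
    st$outputs <- o0
    stm$outputs <- o0
    st <- step_network(st, rep(0, 7), noise = FALSE, plastic = FALSE)
    stm <- step_network(stm, rep(0, 7), noise = FALSE, plastic = FALSE)
    expect_equal(st$activation_sums + st$modulation_sums,
                 stm$activation_sums + stm$modulation_sums, tolerance = 1e-9)
  }
})

test_that("weight updates clip to [-10, 10] and zero deltas are inert", {
  g <- make_toy_genome("zero")
  st <- build_phenotype(g, init_outputs = "zero")
  st$weights[1, 1] <- 9.5
  d <- matrix(0, 23, 16)
  d[1, 1] <- 2.0
  st2 <- apply_weight_updates(st, d)
  expect_equal(st2$weights[1, 1], 10.0)
  st3 <- apply_weight_updates(st2, matrix(0, 23, 16))
  expect_identical(st3$weights, st2$weights)
})

test_that("weights never leave [-10, 10] under stress (extreme eta)", {
  set.seed(21)
  for (rep in 1:5) {
    g <- random_genome(active_prob = 1)
    g$rule <- plasticity_rule(eta = sample(c(-100, 100), 1), A = 1, B = 1,
                              C = -1, D = 1)
    ag <- network_agent(g, streams = rng_streams(rep), noise = TRUE)
    agent_reset(ag)
    for (b in 1:40) {
      agent_observe(ag, runif(7, -1, 1), 3)
      expect_lte(max(abs(ag$state$weights)), 10)
    }
  }
})

test_that("clamping modulatory outputs to zero freezes all weights", {
  set.seed(31)
  g <- random_genome(active_prob = 1)
  g$rule <- plasticity_rule(eta = 10, A = 1, B = 0.5, C = 0.5, D = 0.5)
  st <- build_phenotype(g, init_outputs = "zero")
  inp <- encode_inputs("study", "00001")
  for (i in 1:5) st <- quiet_step(st, inp)   # let plasticity act first
  mod_rows <- st$mod_rows
  for (i in 1:10) {
    st$outputs[mod_rows] <- 0
    w_before <- st$weights
    st <- quiet_step(st, inp)
    expect_identical(st$weights, w_before)
  }
})

test_that("identical genome and seed give bitwise-identical trajectories", {
  g <- make_toy_genome("full_random", seed = 9)
  run <- function() {
    s <- rng_streams(123)
    ag <- network_agent(g, streams = s, noise = TRUE)
    out <- replicate(3, {
      tr <- run_trial(ag, task_config(), s)
      c(tr$reward, tr$delay_steps)
    })
    list(out = out, w = ag$state$weights)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$out, r2$out)
  expect_identical(r1$w, r2$w)
})

test_that("compiled kernel matches the reference R engine step for step", {
  for (seed in 1:4) {
    g <- make_toy_genome("full_random", seed = seed)
    a_cpp <- network_agent(g, streams = rng_streams(seed + 100), engine = "cpp")
    a_r <- network_agent(g, streams = rng_streams(seed + 100), engine = "R")
    agent_reset(a_cpp)
    agent_reset(a_r)
    for (b in 1:6) {
      inp <- encode_inputs("test", sample(rownames(dmts_patterns()), 1))
      o1 <- agent_observe(a_cpp, inp, 3)
      o2 <- agent_observe(a_r, inp, 3)
      expect_equal(o1, o2, tolerance = 1e-12)
    }
    expect_equal(a_cpp$state$weights, a_r$state$weights, tolerance = 1e-12)
    expect_equal(a_cpp$state$outputs, a_r$state$outputs, tolerance = 1e-12)
  }
})
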