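test_that("segment selection picks the best of each circular segment", {
  sel <- segment_select(c(5, 1, 2, 3, 4), segment_size = 5, offset = 0)
  expect_equal(sel$parents, 1L)

  sel <- segment_select(rep(0, 10), segment_size = 5, offset = 2)
  expect_equal(sel$segments[[1]], c(3L, 4L, 5L, 6L, 7L))
  expect_equal(sel$segments[[2]], c(8L, 9L, 10L, 1L, 2L))

  # ties broken by lowest array index within the segment ordering
  sel <- segment_select(rep(1, 5), segment_size = 5, offset = 0)
  expect_equal(sel$parents, 1L)

  expect_error(segment_select(rep(0, 7), 5), "divisible")
})

test_that("selected parents are at least as fit as the population mean", {
  set.seed(9)
  for (rep in 1:10) {
    f <- runif(50, 0, 300)
    sel <- segment_select(f, 5, offset = sample(0:4, 1))
    expect_gte(mean(f[sel$parents]), mean(f))
  }
})

test_that("submatrix crossover swaps the top-left block", {
  set.seed(2)
  a <- random_genome()
  b <- random_genome()

  child <- crossover(a, b, r = 23, cc = 16, take_b = rep(FALSE, 5))
  expect_equal(child$weights, b$weights)
  expect_equal(child$rule$eta, a$rule$eta)

  child <- crossover(a, b, r = 1, cc = 1, take_b = rep(TRUE, 5))
  expect_equal(child$weights[1, 1], b$weights[1, 1])
  expect_equal(child$weights[-1, ], a$weights[-1, ])
  expect_equal(child$weights[1, -1], a$weights[1, -1])
  expect_equal(child$rule$D, b$rule$D)

  # types and activity come from the first parent
  expect_identical(child$neuron_type, a$neuron_type)
  expect_identical(child$neuron_active, a$neuron_active)
})

test_that("parameter mutation respects probability and genotype clipping", {
  set.seed(3)
  g <- random_genome()
  cfg0 <- ga_config(p_param_mutation = 0)
  expect_equal(mutate(g, cfg0)$weights, g$weights)
  expect_equal(mutate(g, cfg0)$rule$eta, g$rule$eta)

  # empirical per-gene rate ~ 0.1
  cfg <- ga_config()
  hits <- 0L
  n_genes <- 0L
  for (i in 1:300) {
    m <- mutate(g, cfg)
    hits <- hits + sum(m$weights != g$weights)
    n_genes <- n_genes + length(g$weights)
  }
  rate <- hits / n_genes
  se <- sqrt(0.1 * 0.9 / n_genes)
  expect_lt(abs(rate - 0.1), 4 * se)

  # boundary clip
  gb <- g
  gb$weights[] <- 99.9
  cfg1 <- ga_config(p_param_mutation = 1, sigma_weight_mut = 5)
  for (i in 1:5) {
    m <- mutate(gb, cfg1)
    expect_true(all(m$weights <= 100 & m$weights >= -100))
    expect_true(all(abs(c(m$rule$A, m$rule$B, m$rule$C, m$rule$D)) <= 1))
    expect_lte(abs(m$rule$eta), 100)
  }
})

test_that("structural operators respect the neuron cap and output protection", {
  set.seed(4)
  g16 <- full_genome()
  cfg_ins <- ga_config(p_insert = 1, p_delete = 0, p_duplicate = 0)
  for (i in 1:5) {
    m <- structural_mutation(g16, cfg_ins)
    expect_equal(sum(m$neuron_active), 16)   # insertion at cap is a no-op
    expect_identical(m$weights, g16$weights)
  }

  cfg_del <- ga_config(p_insert = 0, p_delete = 1, p_duplicate = 0)
  m <- structural_mutation(g16, cfg_del)
  expect_equal(which(m$neuron_active), c(1L, 2L))  # outputs survive
  expect_true(all(m$weights[, 3:16] == 0))
  expect_true(all(m$weights[7 + (3:16), ] == 0))

  set.seed(5)
  g <- make_toy_genome("zero")
  g$weights[1:23, 3] <- 0.7
  g$neuron_active[3] <- TRUE
  g$neuron_type[3] <- "modulatory"
  cfg_dup <- ga_config(p_insert = 0, p_delete = 0, p_duplicate = 1)
  m <- structural_mutation(g, cfg_dup)
  expect_equal(sum(m$neuron_active), sum(g$neuron_active) + 3)  # 1,2,3 duplicated
  new_mod <- setdiff(which(m$neuron_active & m$neuron_type == "modulatory"), 3)
  expect_length(new_mod, 1)                    # the copy keeps its type
  expect_equal(m$weights[1, new_mod], 0.7)     # incoming weights copied
})

test_that("structural operator rates are honoured and closure holds", {
  set.seed(6)
  g <- random_genome(active_prob = 0.3)
  cfg <- ga_config()
  ins <- 0L
  n <- 2000L
  for (i in seq_len(n)) {
    m <- structural_mutation(g, cfg)
    if (!is.na(attr(m, "ops")$inserted)) ins <- ins + 1L
    validate_genome(m)
    expect_lte(sum(m$neuron_active), 16)
  }
  se <- sqrt(0.04 * 0.96 / n)
  expect_lt(abs(ins / n - 0.04), 4 * se)
})

test_that("fitness schedule: guided generations and unsolvable accounting", {
  cfg <- ga_config(tasks_per_eval = 60L, unsolvable_per_eval = 10L,
                   guided_generations = 3L)
  tcfg <- task_config()
  s <- rng_streams(10)
  silent <- scripted_agent("constant_output", value = 0)

  guided <- evaluate_fitness(silent, cfg, tcfg, generation = 1, streams = s,
                             fixed_delay = 1, return_details = TRUE)
  expect_equal(sum(guided$trials$unsolvable), 0)
  expect_false(any(guided$trials$choice_offered))

  post <- evaluate_fitness(silent, cfg, tcfg, generation = 4, streams = s,
                           fixed_delay = 1, return_details = TRUE)
  expect_equal(sum(post$trials$unsolvable), 10)
  expect_true(any(post$trials$choice_offered))
  expect_equal(guided$fitness, 0)
})

test_that("zero genome earns zero fitness", {
  s <- rng_streams(2)
  f <- evaluate_fitness(make_toy_genome("zero"),
                        ga_config(tasks_per_eval = 30L, unsolvable_per_eval = 5L),
                        task_config(), streams = s, fixed_delay = 1)
  expect_equal(f, 0)
})

test_that("evolution is reproducible and preserves population size", {
  cfg <- ga_config(pop_size = 10L, generations = 2L, tasks_per_eval = 5L,
                   unsolvable_per_eval = 1L, guided_generations = 0L)
  r1 <- evolve(cfg, task_config(), seed = 42, fixed_delay = 1, noise = FALSE)
  r2 <- evolve(cfg, task_config(), seed = 42, fixed_delay = 1, noise = FALSE)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_genome$weights, r2$best_genome$weights)
  expect_length(r1$population, 10)
  for (g in r1$population) validate_genome(g)
})

test_that("evolve writes run artifacts", {
  out <- tempfile("run")
  cfg <- ga_config(pop_size = 10L, generations = 2L, tasks_per_eval = 5L,
                   unsolvable_per_eval = 0L, guided_generations = 0L)
  evolve(cfg, task_config(), seed = 1, fixed_delay = 1, noise = FALSE,
         out_dir = out)
  expect_true(file.exists(file.path(out, "generations.csv")))
  expect_true(file.exists(file.path(out, "best_genome.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  h <- read.csv(file.path(out, "generations.csv"))
  expect_equal(nrow(h), 2)
  g <- read_genome(file.path(out, "best_genome.json"))
  validate_genome(g)
  unlink(out, recursive = TRUE)
})
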