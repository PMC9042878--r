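#' Genetic-algorithm configuration
#'
#' Defaults are the reference experimental conditions: population 300, 1000 generations,
#' fitness summed over 300 trials of which 50 are unsolvable (after the
#' first 100 guided generations, during which the choice phase is always
#' skipped and no unsolvable trials occur), best-of-5 segmented selection,
#' crossover probability 0.1, per-gene mutation probability 0.1 with
#' Gaussian sd 0.3 (weights, A..D) and 3.0 (eta), and structural
#' insertion/deletion/duplication probabilities 0.04/0.06/0.02 under a
#' 16-neuron cap.
#'
#' @param pop_size population size N (divisible by `segment_size`).
#' @param generations number of generations G.
#' @param tasks_per_eval trials per fitness evaluation T.
#' @param unsolvable_per_eval unsolvable trials per evaluation U.
#' @param segment_size selection segment length.
#' @param p_crossover crossover probability per child.
#' @param p_param_mutation per-gene mutation probability.
#' @param sigma_weight_mut,sigma_eta_mut mutation noise sd.
#' @param p_insert,p_delete,p_duplicate structural operator probabilities.
#' @param guided_generations number of initial generations with the choice
#'   phase force-skipped and no unsolvable trials.
#' @param max_neurons active-neuron cap.
#' @param init_active_prob probability each non-output neuron slot is active
#'   in an initial random genome.
#' @param checkpoint_every write checkpoints every this many generations
#'   (`Inf` = only at the end) when an output directory is given.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 300L, generations = 1000L,
                      tasks_per_eval = 300L, unsolvable_per_eval = 50L,
                      segment_size = 5L, p_crossover = 0.1,
                      p_param_mutation = 0.1, sigma_weight_mut = 0.3,
                      sigma_eta_mut = 3.0, p_insert = 0.04, p_delete = 0.06,
                      p_duplicate = 0.02, guided_generations = 100L,
                      max_neurons = 16L, init_active_prob = 0.25,
                      checkpoint_every = Inf) {
  probs <- c(p_crossover, p_param_mutation, p_insert, p_delete, p_duplicate)
  if (any(probs < 0 | probs > 1)) {
    stop("ga config error: probabilities must be in [0, 1]", call. = FALSE)
  }
  if (pop_size %% segment_size != 0) {
    stop("ga config error: pop_size must be divisible by segment_size", call. = FALSE)
  }
  if (unsolvable_per_eval > tasks_per_eval) {
    stop("ga config error: unsolvable_per_eval must be <= tasks_per_eval", call. = FALSE)
  }
  structure(
    list(pop_size = as.integer(pop_size), generations = as.integer(generations),
         tasks_per_eval = as.integer(tasks_per_eval),
         unsolvable_per_eval = as.integer(unsolvable_per_eval),
         segment_size = as.integer(segment_size), p_crossover = p_crossover,
         p_param_mutation = p_param_mutation,
         sigma_weight_mut = sigma_weight_mut, sigma_eta_mut = sigma_eta_mut,
         p_insert = p_insert, p_delete = p_delete, p_duplicate = p_duplicate,
         guided_generations = as.integer(guided_generations),
         max_neurons = as.integer(max_neurons),
         init_active_prob = init_active_prob,
         checkpoint_every = checkpoint_every),
    class = "ga_config"
  )
}

#' Evaluate fitness over the trial schedule
#'
#' Runs `tasks_per_eval` trials and returns the summed reward. In guided
#' generations (`generation <= guided_generations`) every trial is forced
#' (choice phase skipped) and solvable; afterwards exactly
#' `unsolvable_per_eval` trials, at uniformly random positions in the
#' schedule, are unsolvable and the choice phase occurs with its normal
#' probability.
#'
#' @param agent_or_genome a genome (wrapped in a [network_agent()]) or any
#'   agent object.
#' @param cfg a [ga_config()].
#' @param task_cfg a [task_config()].
#' @param generation 1-based generation index; the default is the first
#'   post-guidance generation.
#' @param streams an [rng_streams()] object.
#' @param fixed_delay optional delay override (simplified task variants).
#' @param noise logical; neural noise for genome-built agents.
#' @param reset_mode phenotype reset convention for genome-built agents.
#' @param return_details if TRUE, also return the per-trial log.
#' @return the fitness (numeric), or when `return_details = TRUE` a list
#'   with `fitness` and `trials` (data.frame).
#' @export
evaluate_fitness <- function(agent_or_genome, cfg = ga_config(),
                             task_cfg = task_config(),
                             generation = cfg$guided_generations + 1L,
                             streams, fixed_delay = NULL, noise = TRUE,
                             reset_mode = "genome_weights",
                             return_details = FALSE) {
  agent <- if (inherits(agent_or_genome, "genome")) {
    network_agent(agent_or_genome, streams = streams, noise = noise,
                  sigma_input = task_cfg$sigma_input,
                  sigma_neuron = task_cfg$sigma_neuron,
                  reset_mode = reset_mode)
  } else {
    agent_or_genome
  }
  guided <- generation <= cfg$guided_generations
  T_ <- cfg$tasks_per_eval
  unsolv <- rep(FALSE, T_)
  if (!guided && cfg$unsolvable_per_eval > 0L) {
    idx <- with_stream(streams, "task",
                       sample.int(T_, cfg$unsolvable_per_eval))
    unsolv[idx] <- TRUE
  }
  total <- 0
  details <- if (return_details) vector("list", T_) else NULL
  for (i in seq_len(T_)) {
    tr <- run_trial(agent, task_cfg, streams, unsolvable = unsolv[i],
                    force_skip_choice = guided, fixed_delay = fixed_delay)
    total <- total + tr$reward
    if (return_details) {
      details[[i]] <- data.frame(
        trial = i, target = tr$target, delay = tr$delay_steps,
        unsolvable = tr$unsolvable, choice_offered = tr$choice_offered,
        declined = tr$declined, correct = tr$correct, reward = tr$reward,
        stringsAsFactors = FALSE
      )
    }
  }
  if (return_details) {
    list(fitness = total, trials = do.call(rbind, details))
  } else {
    total
  }
}

#' Best-of-segment parent selection
#'
#' The population array is partitioned circularly into consecutive segments
#' of `segment_size` starting at a random offset, and the fittest individual
#' of each segment becomes the parent for that segment. Ties are broken by
#' the lowest array index.
#'
#' @param fitness numeric fitness vector (length divisible by
#'   `segment_size`).
#' @param segment_size segment length.
#' @param offset circular offset in `0:(segment_size - 1)`; drawn from the
#'   current RNG when `NULL`.
#' @return list with `parents` (index of the winner per segment) and
#'   `segments` (list of member-index vectors, 1-based).
#' @export
segment_select <- function(fitness, segment_size = 5L, offset = NULL) {
  n <- length(fitness)
  if (n %% segment_size != 0) {
    stop("population size must be divisible by segment_size", call. = FALSE)
  }
  if (is.null(offset)) offset <- sample.int(segment_size, 1L) - 1L
  offset <- as.integer(offset)
  ord <- ((seq_len(n) - 1L + offset) %% n) + 1L
  segs <- split(ord, rep(seq_len(n %/% segment_size), each = segment_size))
  parents <- vapply(segs, function(ix) ix[which.max(fitness[ix])], integer(1))
  list(parents = unname(parents), segments = unname(segs), offset = offset)
}

#' Submatrix crossover
#'
#' The child takes parent A's genome; random integers `r` (rows) and `c`
#' (columns) are drawn uniformly over the weight-matrix dimensions, and the
#' top-left `r x c` block of the weight matrix is replaced by the partner's.
#' Each of the five plasticity-rule parameters is taken from either parent
#' with probability 1/2 (uniform crossover). Neuron types and the activity
#' mask are inherited from parent A. Draws use the current RNG.
#'
#' @param parent_a,partner genomes.
#' @param r,cc block dimensions (rows/columns); drawn uniformly from the
#'   current RNG when `NULL`.
#' @param take_b logical length-5 vector choosing the partner's value for
#'   (eta, A, B, C, D); coin-flipped when `NULL`.
#' @return the child genome.
#' @export
crossover <- function(parent_a, partner, r = NULL, cc = NULL, take_b = NULL) {
  if (is.null(r)) r <- sample.int(MM_N_UNITS, 1L)
  if (is.null(cc)) cc <- sample.int(MM_MAX_NEURONS, 1L)
  w <- parent_a$weights
  w[seq_len(r), seq_len(cc)] <- partner$weights[seq_len(r), seq_len(cc)]
  if (is.null(take_b)) take_b <- stats::runif(5L) < 0.5
  pa <- parent_a$rule
  pb <- partner$rule
  vals <- ifelse(take_b,
                 c(pb$eta, pb$A, pb$B, pb$C, pb$D),
                 c(pa$eta, pa$A, pa$B, pa$C, pa$D))
  new_genome(w, parent_a$neuron_active, parent_a$neuron_type,
             plasticity_rule(vals[1], vals[2], vals[3], vals[4], vals[5]),
             meta = parent_a$meta)
}

#' Gaussian parameter mutation
#'
#' Independently for every genotype weight and for each of A..D, with
#' probability `p_param_mutation` Gaussian noise (sd `sigma_weight_mut`) is
#' added; eta receives noise with sd `sigma_eta_mut` at the same
#' probability. Results are clipped to the genotype ranges (\[-100, 100\]
#' for weights and eta, \[-1, 1\] for A..D). Draws use the current RNG.
#'
#' @param g a genome.
#' @param cfg a [ga_config()].
#' @return the mutated genome.
#' @export
mutate <- function(g, cfg = ga_config()) {
  w <- g$weights
  nw <- length(w)
  hit <- stats::runif(nw) < cfg$p_param_mutation
  if (any(hit)) {
    w[hit] <- w[hit] + stats::rnorm(sum(hit), 0, cfg$sigma_weight_mut)
    w <- pmin(pmax(w, MM_WEIGHT_GENO_RANGE[1]), MM_WEIGHT_GENO_RANGE[2])
  }
  r <- g$rule
  abcd <- c(r$A, r$B, r$C, r$D)
  hitp <- stats::runif(4L) < cfg$p_param_mutation
  if (any(hitp)) {
    abcd[hitp] <- abcd[hitp] + stats::rnorm(sum(hitp), 0, cfg$sigma_weight_mut)
    abcd <- pmin(pmax(abcd, -1), 1)
  }
  eta <- r$eta
  if (stats::runif(1L) < cfg$p_param_mutation) {
    eta <- min(max(eta + stats::rnorm(1L, 0, cfg$sigma_eta_mut), -100), 100)
  }
  new_genome(matrix(w, MM_N_UNITS, MM_MAX_NEURONS), g$neuron_active,
             g$neuron_type,
             plasticity_rule(eta, abcd[1], abcd[2], abcd[3], abcd[4]),
             meta = g$meta)
}

#' Structural mutation: insert, delete, duplicate neurons
#'
#' With probability `p_insert` one new neuron is inserted into a free slot:
#' its genotype row and column are drawn uniformly in \[-1, 1\] and its type
#' is chosen at random. Each active non-output neuron is then deleted with
#' probability `p_delete` (its genotype row and column are zeroed and the
#' slot marked inactive), and each active neuron is duplicated with
#' probability `p_duplicate` (incoming and outgoing genotype weights and the
#' type are copied into a free slot). Insertions and duplications that would
#' exceed the 16-neuron cap are skipped. The designated output neurons are
#' never deleted and never change type. Draws use the current RNG.
#'
#' @param g a genome.
#' @param cfg a [ga_config()].
#' @return the mutated genome, with an `"ops"` attribute logging which
#'   operators fired: a list with `inserted` (slot index or `NA`), `deleted`
#'   (integer vector) and `duplicated` (source-slot vector).
#' @export
structural_mutation <- function(g, cfg = ga_config()) {
  w <- g$weights
  active <- g$neuron_active
  type <- g$neuron_type
  ops <- list(inserted = NA_integer_, deleted = integer(0),
              duplicated = integer(0))

  free_slot <- function() {
    free <- which(!active)
    if (length(free) == 0L) return(NA_integer_)
    free[sample.int(length(free), 1L)]
  }

  # insertion
  if (stats::runif(1L) < cfg$p_insert && sum(active) < cfg$max_neurons) {
    k <- free_slot()
    if (!is.na(k)) {
      w[, k] <- stats::runif(MM_N_UNITS, -1, 1)
      w[MM_N_INPUTS + k, ] <- stats::runif(MM_MAX_NEURONS, -1, 1)
      type[k] <- sample(c("standard", "modulatory"), 1L)
      active[k] <- TRUE
      ops$inserted <- k
    }
  }

  # deletion (output neurons protected)
  candidates <- setdiff(which(active), MM_OUTPUT_NEURONS)
  if (length(candidates)) {
    del <- candidates[stats::runif(length(candidates)) < cfg$p_delete]
    for (k in del) {
      w[, k] <- 0
      w[MM_N_INPUTS + k, ] <- 0
      active[k] <- FALSE
    }
    ops$deleted <- del
  }

  # duplication
  dup_src <- which(active)
  if (length(dup_src)) {
    dup <- dup_src[stats::runif(length(dup_src)) < cfg$p_duplicate]
    for (k in dup) {
      if (sum(active) >= cfg$max_neurons) break
      s <- free_slot()
      if (is.na(s)) break
      # column copy first, then row copy: the new neuron's self-connection
      # ends up equal to the original's self-connection
      w[, s] <- w[, k]
      w[MM_N_INPUTS + s, ] <- w[MM_N_INPUTS + k, ]
      type[s] <- type[k]
      active[s] <- TRUE
      ops$duplicated <- c(ops$duplicated, k)
    }
  }

  out <- new_genome(w, active, type, g$rule, meta = g$meta)
  attr(out, "ops") <- ops
  out
}

#' Run the genetic algorithm
#'
#' Per generation: every individual's fitness is evaluated on its own fresh
#' task schedule; the population is partitioned into segments of
#' `segment_size` at a random circular offset and the best of each segment
#' becomes a parent; each parent emits `segment_size` children (crossover
#' with probability `p_crossover`, with a partner drawn uniformly from the
#' whole population, otherwise a copy), every child is mutated and
#' structurally mutated, and the children replace the population.
#'
#' @param cfg a [ga_config()].
#' @param task_cfg a [task_config()].
#' @param seed master seed (all randomness derives from it; runs are
#'   bitwise reproducible).
#' @param fixed_delay optional delay override (simplified task variants).
#' @param noise logical; neural noise during evaluation.
#' @param reset_mode phenotype reset convention.
#' @param out_dir optional directory for run artifacts (`generations.csv`,
#'   `best_genome.json`, `manifest.json`).
#' @param verbose print per-generation progress.
#' @return list of class `evolve_result`: `history` (data.frame gen/best/
#'   mean/sd), `population` (final children), `best_genome` and
#'   `best_fitness` (best evaluated individual across all generations, with
#'   its generation in the genome's `meta`), and the configurations.
#' @export
evolve <- function(cfg = ga_config(), task_cfg = task_config(), seed = 1L,
                   fixed_delay = NULL, noise = TRUE,
                   reset_mode = "genome_weights", out_dir = NULL,
                   verbose = FALSE) {
  streams <- rng_streams(seed)
  pop <- with_stream(streams, "ga", replicate(
    cfg$pop_size,
    random_genome(active_prob = cfg$init_active_prob, meta = list(seed = seed)),
    simplify = FALSE
  ))

  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric(), sd = numeric())
  best_fit <- -Inf
  best_genome <- NULL

  for (gen in seq_len(cfg$generations)) {
    fitness <- vapply(pop, function(g) {
      evaluate_fitness(g, cfg, task_cfg, generation = gen, streams = streams,
                       fixed_delay = fixed_delay, noise = noise,
                       reset_mode = reset_mode)
    }, numeric(1))

    gb <- max(fitness)
    if (gb > best_fit) {
      best_fit <- gb
      best_genome <- pop[[which.max(fitness)]]
      best_genome$meta$generation <- gen
      best_genome$meta$fitness <- gb
    }
    history <- rbind(history, data.frame(
      generation = gen, best = gb, mean = mean(fitness), sd = stats::sd(fitness)
    ))
    if (verbose) {
      message(sprintf("gen %d: best %.1f mean %.1f", gen, gb, mean(fitness)))
    }

    pop <- with_stream(streams, "ga", {
      sel <- segment_select(fitness, cfg$segment_size)
      children <- vector("list", cfg$pop_size)
      pos <- 1L
      for (s in seq_along(sel$parents)) {
        parent <- pop[[sel$parents[s]]]
        for (j in seq_len(cfg$segment_size)) {
          child <- if (stats::runif(1L) < cfg$p_crossover) {
            crossover(parent, pop[[sample.int(cfg$pop_size, 1L)]])
          } else {
            parent
          }
          child <- mutate(child, cfg)
          child <- structural_mutation(child, cfg)
          children[[pos]] <- child
          pos <- pos + 1L
        }
      }
      children
    })

    if (!is.null(out_dir) && (gen %% cfg$checkpoint_every == 0 ||
                              gen == cfg$generations)) {
      .write_run_artifacts(out_dir, history, best_genome, cfg, task_cfg, seed)
    }
  }

  res <- list(history = history, population = pop, best_genome = best_genome,
              best_fitness = best_fit, ga_config = cfg, task_config = task_cfg,
              seed = seed)
  class(res) <- "evolve_result"
  if (!is.null(out_dir)) {
    .write_run_artifacts(out_dir, history, best_genome, cfg, task_cfg, seed)
  }
  res
}

.write_run_artifacts <- function(out_dir, history, best_genome, cfg,
                                 task_cfg, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(history, file.path(out_dir, "generations.csv"),
                   row.names = FALSE)
  if (!is.null(best_genome)) {
    write_genome(best_genome, file.path(out_dir, "best_genome.json"))
  }
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("metamem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ga_config = unclass(cfg),
    task_config = unclass(task_cfg),
    files = c("generations.csv", "best_genome.json", "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.evolve_result <- function(x, ...) {
  h <- x$history
  cat("<evolve_result> ", nrow(h), " generations, pop ", x$ga_config$pop_size,
      "\n  best fitness ", signif(x$best_fitness, 5), " (gen ",
      x$best_genome$meta$generation, ")\n", sep = "")
  invisible(x)
}
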