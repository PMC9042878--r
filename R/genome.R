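# Fixed architecture: 7 input units (5 pattern bits, choice-phase signal,
# bias) feeding a pool of at most 16 evolvable neurons. Neurons 1 and 2 are
# the designated outputs (decline/take and test answer) and are always active
# standard neurons. The genome weight matrix has one row per presynaptic unit
# (7 inputs, then the 16 neuron slots) and one column per postsynaptic neuron
# slot; connections into input units do not exist.

MM_N_INPUTS <- 7L
MM_MAX_NEURONS <- 16L
MM_N_UNITS <- MM_N_INPUTS + MM_MAX_NEURONS
MM_OUTPUT_NEURONS <- c(1L, 2L)
MM_WEIGHT_GENO_RANGE <- c(-100, 100)
MM_WEIGHT_PHENO_RANGE <- c(-10, 10)

#' Construct an agent genome
#'
#' The genotype of an agent: a fixed-shape matrix of real-valued connection
#' weights, an activity mask and a type flag per neuron slot, and the five
#' plasticity-rule parameters. Inactive slots keep their rows/columns in the
#' matrix (they are simply masked when the phenotype is built), which makes
#' crossover between parents with different topologies well defined.
#'
#' @param weights numeric 23 x 16 matrix (rows: 7 inputs then 16 neuron
#'   slots, presynaptic; columns: 16 neuron slots, postsynaptic), entries in
#'   \[-100, 100\].
#' @param neuron_active logical vector of length 16.
#' @param neuron_type character vector of length 16, `"standard"` or
#'   `"modulatory"`.
#' @param rule genotype [plasticity_rule()].
#' @param meta optional list of provenance fields (seed, generation, ...).
#' @return object of class `genome`.
#' @export
new_genome <- function(weights = matrix(0, MM_N_UNITS, MM_MAX_NEURONS),
                       neuron_active = c(TRUE, TRUE, rep(FALSE, MM_MAX_NEURONS - 2L)),
                       neuron_type = rep("standard", MM_MAX_NEURONS),
                       rule = plasticity_rule(),
                       meta = list()) {
  g <- structure(
    list(weights = weights, neuron_active = neuron_active,
         neuron_type = neuron_type, rule = rule, meta = meta),
    class = "genome"
  )
  validate_genome(g)
  g
}

#' Validate genome invariants
#'
#' Checks matrix shape, genotype ranges, the 16-neuron cap, and that the two
#' designated output neurons are active standard neurons.
#'
#' @param g a [new_genome()] object.
#' @return `g`, invisibly; signals an error on violation.
#' @export
validate_genome <- function(g) {
  if (!inherits(g, "genome")) stop("invalid genome: not a genome object", call. = FALSE)
  w <- g$weights
  if (!is.matrix(w) || !identical(dim(w), c(MM_N_UNITS, MM_MAX_NEURONS))) {
    stop("invalid genome: weight matrix must be 23 x 16", call. = FALSE)
  }
  if (any(!is.finite(w))) stop("invalid genome: non-finite weight", call. = FALSE)
  if (any(w < MM_WEIGHT_GENO_RANGE[1] - 1e-12) || any(w > MM_WEIGHT_GENO_RANGE[2] + 1e-12)) {
    stop("invalid genome: genotype weight outside [-100, 100]", call. = FALSE)
  }
  if (!is.logical(g$neuron_active) || length(g$neuron_active) != MM_MAX_NEURONS ||
      any(is.na(g$neuron_active))) {
    stop("invalid genome: neuron_active must be logical, length 16", call. = FALSE)
  }
  if (length(g$neuron_type) != MM_MAX_NEURONS ||
      !all(g$neuron_type %in% c("standard", "modulatory"))) {
    stop("invalid genome: neuron_type must be 'standard' or 'modulatory'", call. = FALSE)
  }
  if (sum(g$neuron_active) > MM_MAX_NEURONS) {
    stop("invalid genome: more than 16 active neurons", call. = FALSE)
  }
  if (!all(g$neuron_active[MM_OUTPUT_NEURONS])) {
    stop("invalid genome: output neurons must be active", call. = FALSE)
  }
  if (!all(g$neuron_type[MM_OUTPUT_NEURONS] == "standard")) {
    stop("invalid genome: output neurons must be standard", call. = FALSE)
  }
  r <- g$rule
  if (!inherits(r, "plasticity_rule")) stop("invalid genome: missing plasticity rule", call. = FALSE)
  if (abs(r$eta) > 100 + 1e-12) stop("invalid genome: eta outside [-100, 100]", call. = FALSE)
  for (p in c("A", "B", "C", "D")) {
    if (abs(r[[p]]) > 1 + 1e-12) {
      stop(sprintf("invalid genome: %s outside [-1, 1]", p), call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  act <- which(x$neuron_active)
  cat("<genome> ", length(act), " active neurons (",
      sum(x$neuron_type[act] == "modulatory"), " modulatory); eta = ",
      signif(x$rule$eta, 4), "\n", sep = "")
  invisible(x)
}

#' Draw a random genome
#'
#' Initial genomes for evolution (drawn from the *current* RNG state; wrap in
#' [with_stream()] to use a named stream). Genotype weights are uniform in
#' \[-1, 1\] — the same convention the structural insertion operator uses —
#' so that after the cubic mapping roughly half of all connections start
#' silent. The two output neurons are always active; each remaining slot is
#' active with probability `active_prob` with a uniformly random type. Rule
#' parameters are uniform over their genotype ranges.
#'
#' @param active_prob probability that each non-output neuron slot starts
#'   active (default 0.25).
#' @param meta optional provenance list.
#' @return a [new_genome()] object.
#' @export
random_genome <- function(active_prob = 0.25, meta = list()) {
  w <- matrix(stats::runif(MM_N_UNITS * MM_MAX_NEURONS, -1, 1),
              MM_N_UNITS, MM_MAX_NEURONS)
  active <- c(TRUE, TRUE, stats::runif(MM_MAX_NEURONS - 2L) < active_prob)
  type <- c("standard", "standard",
            sample(c("standard", "modulatory"), MM_MAX_NEURONS - 2L, replace = TRUE))
  rule <- plasticity_rule(
    eta = stats::runif(1, -100, 100),
    A = stats::runif(1, -1, 1), B = stats::runif(1, -1, 1),
    C = stats::runif(1, -1, 1), D = stats::runif(1, -1, 1)
  )
  new_genome(w, active, type, rule, meta)
}

#' Deterministic toy genomes for testing and demonstration
#'
#' * `"zero"` — all weights zero, only the two output neurons active; the
#'   phenotype is completely silent.
#' * `"minimal_modulated"` — a minimal gated circuit: an input drives a relay
#'   standard neuron which feeds output neuron 1, and a bias-driven
#'   modulatory neuron projects onto neuron 1, so neuron 1's incoming
#'   weights are plastic exactly when the modulatory neuron is active.
#' * `"full_random"` — [random_genome()] under the given seed
#'   (reproducible).
#'
#' @param name fixture name.
#' @param seed seed for `"full_random"`.
#' @return a [new_genome()] object.
#' @export
make_toy_genome <- function(name = c("zero", "minimal_modulated", "full_random"),
                            seed = 1L) {
  name <- match.arg(name)
  if (name == "zero") {
    return(new_genome(meta = list(fixture = "zero")))
  }
  if (name == "minimal_modulated") {
    w <- matrix(0, MM_N_UNITS, MM_MAX_NEURONS)
    # input 1 -> relay neuron 4 (phenotype weight 10)
    w[1L, 4L] <- 1
    # relay neuron 4 -> output neuron 1 (phenotype weight 10 * 0.125 = 1.25)
    w[MM_N_INPUTS + 4L, 1L] <- 0.5
    # bias input (unit 7) -> modulatory neuron 3
    w[MM_N_INPUTS, 3L] <- 1
    # modulatory neuron 3 -> output neuron 1 (the gate)
    w[MM_N_INPUTS + 3L, 1L] <- 1
    active <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, MM_MAX_NEURONS - 4L))
    type <- rep("standard", MM_MAX_NEURONS)
    type[3L] <- "modulatory"
    return(new_genome(w, active, type,
                      plasticity_rule(eta = 1, A = 1),
                      meta = list(fixture = "minimal_modulated")))
  }
  prev <- .save_rng_state()
  on.exit(.restore_rng_state(prev), add = TRUE)
  set.seed(as.integer(seed))
  g <- random_genome(meta = list(fixture = "full_random", seed = as.integer(seed)))
  g
}

#' Write a genome to a JSON file
#'
#' The on-disk format has keys `weights` (row-major matrix), `neuron_active`,
#' `neuron_type`, `eta`, `A`, `B`, `C`, `D` and `meta`. Numbers are written at
#' full precision so that save/load round-trips are lossless.
#'
#' @param g a [new_genome()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  validate_genome(g)
  obj <- list(
    weights = g$weights,
    neuron_active = g$neuron_active,
    neuron_type = g$neuron_type,
    eta = g$rule$eta, A = g$rule$A, B = g$rule$B, C = g$rule$C, D = g$rule$D,
    meta = g$meta
  )
  # digits = I(17): enough significant digits to reproduce any double exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a genome from a JSON file
#'
#' @param path file written by [write_genome()].
#' @return a [new_genome()] object.
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(as.numeric(obj$weights), nrow = MM_N_UNITS, ncol = MM_MAX_NEURONS,
              byrow = FALSE)
  # jsonlite reads the nested array back as a matrix already; guard both forms
  if (is.matrix(obj$weights)) w <- obj$weights
  new_genome(
    weights = w,
    neuron_active = as.logical(obj$neuron_active),
    neuron_type = as.character(obj$neuron_type),
    rule = plasticity_rule(eta = obj$eta, A = obj$A, B = obj$B,
                           C = obj$C, D = obj$D),
    meta = if (is.null(obj$meta)) list() else as.list(obj$meta)
  )
}
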