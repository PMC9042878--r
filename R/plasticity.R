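#' Genotype-to-phenotype mapping for connection weights
#'
#' Genotype weights live in \[-100, 100\]; the expressed (phenotype) weight is
#' `10 * w^3` with a dead zone — whenever `|w^3| < 0.1` the connection is
#' silenced (weight 0). The cube keeps small genotype values near zero so that
#' mutation can tune weights finely around the origin, while the dead zone
#' lets evolution prune connections outright. Mapped values are clipped to the
#' network's absolute weight range \[-10, 10\].
#'
#' @param w_geno numeric vector of genotype weights.
#' @return phenotype weights, same shape as `w_geno`.
#' @examples
#' genotype_to_phenotype_weight(c(1, 0.4, -0.6, 2))
#' @export
genotype_to_phenotype_weight <- function(w_geno) {
  if (!is.numeric(w_geno) || any(!is.finite(w_geno))) {
    stop("invalid genome: non-finite genotype weight", call. = FALSE)
  }
  cube <- w_geno^3
  out <- 10 * cube
  out[abs(cube) < 0.1] <- 0
  pmin(pmax(out, -10), 10)
}

#' Genotype-to-phenotype mapping for plasticity-rule coefficients
#'
#' The rule coefficients A, B, C, D are cubed with the same `|p^3| < 0.1` dead
#' zone as the weights but without the factor of 10: phenotype coefficients
#' stay in \[-1, 1\]. The learning rate eta is *not* mapped; its genotype value
#' is used directly.
#'
#' @param p_geno numeric vector of genotype coefficients in \[-1, 1\].
#' @return phenotype coefficients.
#' @export
genotype_to_phenotype_param <- function(p_geno) {
  if (!is.numeric(p_geno) || any(!is.finite(p_geno))) {
    stop("invalid genome: non-finite rule parameter", call. = FALSE)
  }
  cube <- p_geno^3
  cube[abs(cube) < 0.1] <- 0
  cube
}

#' Plasticity rule parameters
#'
#' Bundles the learning rate `eta` and the four extended-Hebbian coefficients.
#' The same container is used for genotype values (ranges: eta in
#' \[-100, 100\], A..D in \[-1, 1\]) and for phenotype values obtained through
#' [genotype_to_phenotype_param()].
#'
#' @param eta learning-rate scalar.
#' @param A,B,C,D rule coefficients (correlation, presynaptic, postsynaptic
#'   and constant terms respectively).
#' @return object of class `plasticity_rule`.
#' @export
plasticity_rule <- function(eta = 0, A = 0, B = 0, C = 0, D = 0) {
  vals <- c(eta = eta, A = A, B = B, C = C, D = D)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("invalid genome: non-finite plasticity-rule parameter", call. = FALSE)
  }
  structure(list(eta = eta, A = A, B = B, C = C, D = D),
            class = "plasticity_rule")
}

#' Map a genotype plasticity rule to its phenotype
#'
#' @param rule a genotype [plasticity_rule()].
#' @return a phenotype `plasticity_rule` (A..D cubed with dead zone, eta
#'   unchanged).
#' @export
phenotype_rule <- function(rule) {
  plasticity_rule(
    eta = rule$eta,
    A = genotype_to_phenotype_param(rule$A),
    B = genotype_to_phenotype_param(rule$B),
    C = genotype_to_phenotype_param(rule$C),
    D = genotype_to_phenotype_param(rule$D)
  )
}

#' Extended Hebbian weight change
#'
#' The neuromodulated update for a connection from presynaptic unit `j` to
#' postsynaptic neuron `i`:
#' \deqn{\Delta w_{ji} = \tanh(m_i)\,\eta\,(A o_j o_i + B o_j + C o_i + D)}
#' where `m_i` is the summed modulatory drive onto neuron `i`. With no
#' modulatory input (`m_i = 0`) the change is exactly zero: plasticity is
#' gated by the modulatory neurons.
#'
#' Arguments are recycled, so vectors of presynaptic/postsynaptic outputs can
#' be evaluated in one call.
#'
#' @param o_j presynaptic output(s).
#' @param o_i postsynaptic output(s).
#' @param m_i modulatory sum(s) at the postsynaptic neuron.
#' @param rule a phenotype [plasticity_rule()].
#' @return the weight change(s), unclipped.
#' @export
compute_hebbian_delta <- function(o_j, o_i, m_i, rule) {
  tanh(m_i) * rule$eta * (rule$A * o_j * o_i + rule$B * o_j + rule$C * o_i + rule$D)
}
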