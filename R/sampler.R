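# Gibbs MCMC driver: per-block sampling with derived RNG streams, plus the
# elementary sampling operations exposed for testing and reuse.

# Per-block seed derived from the master seed; depends only on the block
# index, so sequential and parallel execution produce identical chains.
.block_seed <- function(seed, block) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(block)) %% 2147483647)
}

#' Sample peptide error indicators
#'
#' In PEP mode each peptide is sampled, independently and anew at each
#' iteration, as mistakenly detected (1) or correctly detected (0) from a
#' Bernoulli with its posterior error probability.
#'
#' @param pep numeric vector of posterior error probabilities.
#' @return integer 0/1 vector.
#' @export
sample_epsilon <- function(pep) {
  as.integer(runif(length(pep)) < pep)
}

#' Allocation probabilities for one peptide
#'
#' The abundance of a peptide compatible with the isoform set `psi` is
#' spread with probabilities proportional to pi_p / M_p on `psi` and zero
#' elsewhere; dividing by the peptide multiplicity M_p normalizes for the
#' number of peptides feeding each isoform. If every pi_p on `psi` is
#' numerically zero the allocation falls back to uniform over `psi`.
#'
#' @param pi relative-abundance vector over all P isoforms.
#' @param m integer vector of peptide multiplicities M_p (all >= 1).
#' @param psi integer indices of the isoforms compatible with the peptide.
#' @return length-P probability vector, zero outside `psi`, summing to 1.
#' @export
allocation_probs <- function(pi, m, psi) {
  stopifnot(length(pi) == length(m), length(psi) >= 1L, all(m >= 1))
  w <- pi[psi] / m[psi]
  s <- sum(w)
  if (s <= 0) w <- rep(1 / length(psi), length(psi)) else w <- w / s
  out <- numeric(length(pi))
  out[psi] <- w
  out
}

#' Allocate one peptide's abundance across its compatible isoforms
#'
#' Draws Multinomial(Y * (1 - epsilon), probs); a peptide sampled as
#' mistakenly detected (epsilon = 1), or with zero abundance, contributes a
#' zero vector without drawing.
#'
#' @param y non-negative integer abundance Y.
#' @param epsilon 0/1 error indicator.
#' @param probs allocation probabilities from [allocation_probs()].
#' @return integer vector of the same length as `probs` summing to
#'   `y * (1 - epsilon)`.
#' @export
allocate_peptide <- function(y, epsilon, probs) {
  stopifnot(y >= 0, epsilon %in% c(0L, 1L))
  if (epsilon == 1L || y == 0L) return(integer(length(probs)))
  as.integer(rmultinom(1L, y, probs)[, 1L])
}

#' Draw pi from its conjugate Dirichlet conditional
#'
#' Given latent abundances X and hyper-parameters delta, pi is Dirichlet
#' (x_1 + delta_1, ..., x_P + delta_P), drawn via normalized gammas.
#'
#' @param x non-negative integer vector of latent abundances.
#' @param delta positive Dirichlet hyper-parameters.
#' @return probability vector of length P.
#' @export
sample_pi <- function(x, delta) {
  stopifnot(length(x) == length(delta))
  if (any(x + delta <= 0)) stop("internal error: non-positive Dirichlet shape")
  g <- stats::rgamma(length(x), shape = x + delta, rate = 1)
  if (sum(g) <= 0) return(rep(1 / length(g), length(g)))
  g / sum(g)
}

#' Run the Gibbs sampler
#'
#' Iterates, per block of isoforms sharing no peptides: (PEP mode only)
#' sample the per-peptide error indicators; allocate each retained peptide's
#' abundance across its compatible isoforms (multinomial with weights
#' pi_p / M_p); draw pi from the conjugate Dirichlet conditional. In FDR mode
#' the error indicators are fixed at 0. Blocks are sampled on independent RNG
#' streams derived from the master seed, so results are identical for any
#' thread count; the global pi chain is recovered by normalizing the
#' concatenated per-block gamma draws per iteration (the gamma representation
#' of the Dirichlet), which reproduces the single-block sampler exactly.
#'
#' @param map a `peptide_protein_map` from [apply_trivial_filter()].
#' @param prior a `protiso_prior` from [build_prior()]; `delta` must be
#'   ordered like `map$proteins`.
#' @param config a [run_config()].
#' @return object of class `posterior_draws`: list with `pi_chain` and
#'   `x_chain` (post-burn-in draws x P matrices, columns ordered and named
#'   like `map$proteins$protein_id`), `kept_abundance` (per-iteration total
#'   retained abundance) and `meta`.
#' @export
run_mcmc <- function(map, prior, config) {
  stopifnot(inherits(map, "peptide_protein_map"),
            inherits(prior, "protiso_prior"),
            inherits(config, "protiso_config"))
  P <- nrow(map$proteins)
  if (length(prior$delta) != P)
    .validation_error("prior length does not match the number of analyzed isoforms")
  keep <- config$iterations - config$burn_in
  pep_mode <- config$mode == "pep"

  run_block <- function(b) {
    idx <- map$blocks[[b]]
    rows <- which(map$peptide_block == b)
    local_of <- integer(P)
    local_of[idx] <- seq_along(idx)
    psi_local <- lapply(map$incidence[rows], function(v) local_of[v] - 1L)
    set.seed(.block_seed(config$seed, b))
    .gibbs_block(y = map$peptides$abundance[rows],
                 pep = map$peptides$pep[rows],
                 psi = psi_local,
                 m = map$proteins$m_detected[idx],
                 delta = prior$delta[idx],
                 iterations = config$iterations,
                 burn_in = config$burn_in,
                 pep_mode = pep_mode)
  }

  nb <- length(map$blocks)
  res <- if (config$threads > 1L) {
    parallel::mclapply(seq_len(nb), run_block,
                       mc.cores = config$threads, mc.set.seed = FALSE)
  } else {
    lapply(seq_len(nb), run_block)
  }

  x_chain <- matrix(0L, keep, P)
  g_chain <- matrix(0, keep, P)
  kept <- integer(keep)
  for (b in seq_len(nb)) {
    idx <- map$blocks[[b]]
    x_chain[, idx] <- res[[b]]$x
    g_chain[, idx] <- res[[b]]$gamma
    kept <- kept + res[[b]]$kept
  }
  pi_chain <- g_chain / rowSums(g_chain)
  colnames(x_chain) <- colnames(pi_chain) <- map$proteins$protein_id

  structure(list(pi_chain = pi_chain,
                 x_chain = x_chain,
                 kept_abundance = kept,
                 meta = list(seed = config$seed, mode = config$mode,
                             iterations = config$iterations,
                             burn_in = config$burn_in,
                             n_blocks = nb)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d isoforms (%s mode, %d blocks)\n",
              nrow(x$pi_chain), ncol(x$pi_chain), x$meta$mode, x$meta$n_blocks))
  invisible(x)
}
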