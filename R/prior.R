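# Dirichlet prior construction: flat, or informed by transcript abundances.

#' Transcript relative abundances for the analyzed isoforms
#'
#' Restricts a transcript-abundance table to the analyzed isoforms (ids
#' missing from the table contribute 0), normalizes to relative abundances,
#' adds a small constant `epsilon` to every entry to avoid zeros, and
#' renormalizes so the vector sums to 1.
#'
#' @param mrna data.frame from [read_mrna_table()].
#' @param analyzed_ids ordered character vector of analyzed protein ids
#'   (typically `map$proteins$protein_id`).
#' @param epsilon positive zero-avoidance constant (default 1e-5).
#' @return numeric vector, same order as `analyzed_ids`, summing to 1.
#' @export
mrna_relative_abundance <- function(mrna, analyzed_ids, epsilon = 1e-5) {
  if (!length(analyzed_ids)) .validation_error("'analyzed_ids' is empty")
  if (!is.numeric(epsilon) || epsilon <= 0)
    .validation_error("'epsilon' must be positive")
  ab <- mrna$abundance[match(analyzed_ids, mrna$isoform_id)]
  ab[is.na(ab)] <- 0
  if (any(ab < 0)) .validation_error("negative transcript abundance")
  tot <- sum(ab)
  pi_t <- if (tot > 0) ab / tot else rep(0, length(ab))
  out <- (pi_t + epsilon) / sum(pi_t + epsilon)
  out
}

#' Build the Dirichlet prior over isoform relative abundances
#'
#' Without transcript data the prior is weakly informative: delta_p = 1 for
#' every isoform. With transcript data the hyper-parameters are proportional
#' to the renormalized transcript relative abundances and scaled so the total
#' prior mass is `c` times the total observed peptide abundance:
#' delta_p = pi_tilde_p * c * sum(X). With the default c = 0.1 the proteomics
#' data has ten times more weight than the transcript prior in the posterior.
#'
#' @param n_proteins number of analyzed isoforms P.
#' @param pi_T_tilde renormalized transcript relative abundances from
#'   [mrna_relative_abundance()], or `NULL` for a flat prior.
#' @param total_abundance total observed (post-filter) peptide abundance;
#'   required when `pi_T_tilde` is supplied.
#' @param c prior-strength constant (default 0.1).
#' @return list of class `protiso_prior` with `delta` (positive vector of
#'   length P) and `pi_T` (the transcript relative abundances, or `NULL`).
#' @export
build_prior <- function(n_proteins, pi_T_tilde = NULL, total_abundance = NULL,
                        c = 0.1) {
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L)
    .validation_error("'n_proteins' must be a positive integer")
  if (is.null(pi_T_tilde)) {
    delta <- rep(1, n_proteins)
    pi_T <- NULL
  } else {
    if (!is.numeric(c) || length(c) != 1L || c <= 0)
      .validation_error("prior-strength constant 'c' must be positive")
    if (length(pi_T_tilde) != n_proteins)
      .validation_error("'pi_T_tilde' length does not match 'n_proteins'")
    if (abs(sum(pi_T_tilde) - 1) > 1e-6)
      .validation_error("'pi_T_tilde' must sum to 1")
    if (is.null(total_abundance) || is.na(total_abundance) || total_abundance <= 0)
      .validation_error("informative prior requires a positive 'total_abundance'")
    delta <- pi_T_tilde * c * total_abundance
    pi_T <- pi_T_tilde
  }
  structure(list(delta = delta, pi_T = pi_T), class = "protiso_prior")
}
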