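# Synthetic-data generator: ground-truth isoform abundances, a peptide-protein
# compatibility structure with controllable sharing, equal-probability
# multinomial allocation of true protein abundance to peptides, synthetic
# PEP/FDR scores (with optional decoys), and a transcript table with a target
# log10 correlation to the protein truth.

#' Generate a synthetic isoform/peptide structure with ground truth
#'
#' Draws ground-truth isoform abundances (log-normal, a configurable fraction
#' absent, i.e. abundance 0), groups isoforms into genes, and assigns each
#' isoform a set of peptides of which a configurable fraction is shared with
#' a second isoform — preferentially from the same gene, mirroring the
#' situation in real searches where most shared peptides stay within a gene.
#' Every isoform owns at least one peptide.
#'
#' Defaults emulate the sharing structure reported for deep multi-protease
#' searches: about 47% of PSM mass on shared peptides, with an 85/15
#' within/between-gene split.
#'
#' @param P number of isoforms (>= 2).
#' @param absent_frac fraction of isoforms with true abundance 0.
#' @param meanlog,sdlog log-normal parameters of the present isoforms'
#'   true abundance (rounded to integers, floored at 1).
#' @param gene_size_probs sampling weights for gene sizes 1, 2, 3, ...
#' @param peptides_per_protein_lambda each isoform owns `1 + Poisson(lambda)`
#'   peptides.
#' @param shared_frac target fraction of abundance mass landing on shared
#'   peptides. Internally, each owned peptide is marked shared with
#'   probability `q = shared_frac / (2 - shared_frac)`: with `q k` of a
#'   protein's own `k` peptides shared and about `q k` shared peptides
#'   received from partners, the expected shared share of its uniformly
#'   allocated mass is `2q / (1 + q)`, which this inversion sets to
#'   `shared_frac`.
#' @param within_gene_share probability that a shared peptide's partner comes
#'   from the same gene (when the gene has another isoform).
#' @return list with `structure` (data.frame `peptide_id`, list column
#'   `protein_ids`), `gene_map`, and `truth` (list: `protein_id`,
#'   `true_abundance`, `present`, `pi_true`, `params`).
#' @export
generate_structure <- function(P,
                               absent_frac = 0.25,
                               meanlog = 1.5, sdlog = 1,
                               gene_size_probs = c(0.4, 0.3, 0.2, 0.1),
                               peptides_per_protein_lambda = 2,
                               shared_frac = 0.47,
                               within_gene_share = 0.85) {
  P <- as.integer(P)
  if (is.na(P) || P < 2L) .validation_error("'P' must be >= 2")
  if (shared_frac < 0 || shared_frac > 1)
    .validation_error("'shared_frac' must be in [0, 1]")
  if (shared_frac >= 1 && length(gene_size_probs) == 1L &&
      within_gene_share >= 1)
    .validation_error("all peptides shared within genes is infeasible with single-isoform genes")

  sizes <- integer(0)
  while (sum(sizes) < P)
    sizes <- c(sizes, sample.int(length(gene_size_probs), 1L,
                                 prob = gene_size_probs))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - P)
  sizes <- sizes[sizes > 0L]
  gene_of <- rep(seq_along(sizes), sizes)
  protein_id <- sprintf("P%05d", seq_len(P))
  gene_id <- sprintf("G%05d", gene_of)

  present <- runif(P) >= absent_frac
  true_abundance <- ifelse(present,
                           pmax(1, .round_half_away(rlnorm(P, meanlog, sdlog))),
                           0)
  true_abundance <- as.integer(true_abundance)

  k <- rpois(P, peptides_per_protein_lambda) + 1L
  owner <- rep(seq_len(P), k)
  n_pep <- length(owner)
  gene_members <- split(seq_len(P), gene_of)
  q_mark <- shared_frac / (2 - shared_frac)
  psi <- vector("list", n_pep)
  for (i in seq_len(n_pep)) {
    p <- owner[i]
    if (runif(1) < q_mark) {
      mates <- gene_members[[gene_of[p]]]
      mates <- mates[mates != p]
      partner <- if (length(mates) && runif(1) < within_gene_share) {
        mates[sample.int(length(mates), 1L)]
      } else {
        others <- seq_len(P)[-p]
        others[sample.int(length(others), 1L)]
      }
      psi[[i]] <- protein_id[c(p, partner)]
    } else {
      psi[[i]] <- protein_id[p]
    }
  }
  structure_df <- data.frame(peptide_id = sprintf("pep%06d", seq_len(n_pep)),
                             stringsAsFactors = FALSE)
  structure_df$protein_ids <- psi

  list(structure = structure_df,
       gene_map = data.frame(isoform_id = protein_id, gene_id = gene_id,
                             stringsAsFactors = FALSE),
       truth = list(protein_id = protein_id,
                    true_abundance = true_abundance,
                    present = true_abundance > 0L,
                    pi_true = true_abundance / sum(true_abundance),
                    params = list(P = P, absent_frac = absent_frac,
                                  meanlog = meanlog, sdlog = sdlog,
                                  shared_frac = shared_frac,
                                  within_gene_share = within_gene_share)))
}

#' Allocate ground-truth protein abundance to peptides
#'
#' Each isoform's true abundance is split across all its compatible peptides
#' by a multinomial with equal probability per peptide; a peptide's abundance
#' is the sum of the contributions of every isoform it is compatible with, so
#' total peptide abundance conserves total true protein abundance exactly.
#'
#' @param truth,structure from [generate_structure()].
#' @param drop_zero if `TRUE` (default) peptides with final abundance 0 are
#'   treated as undetected and removed.
#' @return peptide data.frame (`fdr`/`pep` initialized to 0; see
#'   [assign_error_scores()]).
#' @export
allocate_truth_to_peptides <- function(truth, structure, drop_zero = TRUE) {
  ids <- truth$protein_id
  idx_of <- stats::setNames(seq_along(ids), ids)
  pep_idx <- rep(seq_len(nrow(structure)), lengths(structure$protein_ids))
  prot_idx <- idx_of[unlist(structure$protein_ids, use.names = FALSE)]
  compat <- split(pep_idx, factor(prot_idx, levels = seq_along(ids)))
  y <- integer(nrow(structure))
  for (p in seq_along(ids)) {
    n_p <- truth$true_abundance[p]
    if (n_p == 0L) next
    idx <- compat[[p]]
    if (length(idx) == 0L)
      stop("present isoform without compatible peptides")
    if (length(idx) == 1L) {
      y[idx] <- y[idx] + n_p
    } else {
      alloc <- rmultinom(1L, n_p, rep(1 / length(idx), length(idx)))[, 1L]
      y[idx] <- y[idx] + alloc
    }
  }
  out <- data.frame(peptide_id = structure$peptide_id,
                    abundance = as.integer(y),
                    fdr = 0, pep = 0,
                    stringsAsFactors = FALSE)
  out$protein_ids <- structure$protein_ids
  out$zero_abundance <- out$abundance == 0L
  out$is_decoy <- FALSE
  if (drop_zero) {
    out <- out[out$abundance > 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Convert posterior error probabilities to q-values
#'
#' The q-value (reported as `fdr`) of a peptide is the running mean of the
#' PEPs in PEP-ascending order: the expected fraction of errors among all
#' peptides at least as confident.
#'
#' @param pep numeric vector of posterior error probabilities.
#' @return numeric vector of q-values, same order as the input.
#' @export
pep_to_fdr <- function(pep) {
  ord <- order(pep)
  fdr <- numeric(length(pep))
  fdr[ord] <- cumsum(pep[ord]) / seq_along(pep)
  fdr
}

#' Assign synthetic PEP and FDR scores, optionally injecting decoys
#'
#' True-positive peptides receive posterior error probabilities from a Beta
#' concentrated near 0; optionally, spurious "decoy" peptides with PEP near 1
#' and random compatibility lists are appended. The FDR (q-value) of each
#' peptide is the running mean of the PEPs in PEP-ascending order, the
#' standard q-value-from-PEP construction. This scoring layer goes beyond
#' what a search engine would report and exists so the error-aware mode can
#' be exercised without one.
#'
#' @param peptides peptide data.frame from [allocate_truth_to_peptides()].
#' @param protein_pool character vector of protein ids decoys may map to.
#' @param decoy_frac decoys appended as a fraction of the true peptide count.
#' @param tp_pep_shape,decoy_pep_shape Beta shape pairs for true-positive and
#'   decoy PEPs (defaults: mean 0.01 and 0.95).
#' @return peptide data.frame with `pep`, `fdr` and `is_decoy` filled.
#' @export
assign_error_scores <- function(peptides, protein_pool = NULL,
                                decoy_frac = 0,
                                tp_pep_shape = c(1, 99),
                                decoy_pep_shape = c(40, 2)) {
  n <- nrow(peptides)
  peptides$pep <- rbeta(n, tp_pep_shape[1L], tp_pep_shape[2L])
  n_decoy <- round(decoy_frac * n)
  if (n_decoy > 0) {
    if (is.null(protein_pool))
      protein_pool <- unique(unlist(peptides$protein_ids, use.names = FALSE))
    dec <- data.frame(peptide_id = sprintf("decoy%05d", seq_len(n_decoy)),
                      abundance = rpois(n_decoy, 2) + 1L,
                      fdr = 0,
                      pep = rbeta(n_decoy, decoy_pep_shape[1L], decoy_pep_shape[2L]),
                      stringsAsFactors = FALSE)
    dec$protein_ids <- lapply(seq_len(n_decoy), function(i) {
      protein_pool[sample.int(length(protein_pool), sample(1:2, 1L))]
    })
    dec$zero_abundance <- FALSE
    dec$is_decoy <- TRUE
    peptides <- rbind(peptides, dec[, names(peptides)])
  }
  peptides$fdr <- pep_to_fdr(peptides$pep)
  rownames(peptides) <- NULL
  peptides
}

#' Generate a transcript table correlated with the protein ground truth
#'
#' Transcript log10 abundances are the protein-truth log10 abundances shrunk
#' towards their mean by the target correlation plus matched Gaussian noise,
#' so the realized Pearson correlation of log10(truth + 1) with
#' log10(transcript + 1) approaches `target_log_corr` for large P.
#'
#' @param truth from [generate_structure()].
#' @param target_log_corr target log10 Pearson correlation in (-1, 1);
#'   default 0.65, a typical mRNA-protein agreement in deep datasets.
#' @return data.frame (`isoform_id`, `abundance`).
#' @export
generate_correlated_mrna <- function(truth, target_log_corr = 0.65) {
  if (target_log_corr <= -1 || target_log_corr >= 1)
    .validation_error("'target_log_corr' must be in (-1, 1)")
  t_log <- log10(truth$true_abundance + 1)
  s <- sd(t_log)
  rho <- target_log_corr
  m_log <- mean(t_log) + rho * (t_log - mean(t_log)) +
    sqrt(1 - rho^2) * s * rnorm(length(t_log))
  data.frame(isoform_id = truth$protein_id,
             abundance = pmax(10^m_log - 1, 0),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_structure()],
#' [allocate_truth_to_peptides()], [assign_error_scores()] and (optionally)
#' [generate_correlated_mrna()] under one seed.
#'
#' @param P number of isoforms.
#' @param seed RNG seed.
#' @param mrna generate a correlated transcript table?
#' @param mrna_target_corr target log10 correlation of the transcript table.
#' @param decoy_frac decoy fraction for [assign_error_scores()].
#' @param drop_zero drop undetected (zero-abundance) peptides?
#' @param ... further arguments to [generate_structure()].
#' @return list with `peptides`, `mrna` (or `NULL`), `gene_map`, `truth`.
#' @export
simulate_dataset <- function(P = 1000, seed = 1, mrna = TRUE,
                             mrna_target_corr = 0.65, decoy_frac = 0,
                             drop_zero = TRUE, ...) {
  set.seed(seed)
  gs <- generate_structure(P, ...)
  peptides <- allocate_truth_to_peptides(gs$truth, gs$structure,
                                         drop_zero = drop_zero)
  peptides <- assign_error_scores(peptides,
                                  protein_pool = gs$truth$protein_id,
                                  decoy_frac = decoy_frac)
  mrna_tab <- if (mrna) generate_correlated_mrna(gs$truth, mrna_target_corr)
              else NULL
  list(peptides = peptides, mrna = mrna_tab, gene_map = gs$gene_map,
       truth = gs$truth)
}

#' Score inferred results against a simulation ground truth
#'
#' Computes, over the analyzed isoforms: the AUC of the presence probability
#' against true presence/absence; the Pearson correlation of
#' log10(estimated + 1) versus log10(true + 1) abundances; the credible
#' interval coverage (fraction of isoforms, and of truly present isoforms,
#' whose true abundance lies inside the interval); and the mean estimated
#' abundance separately for truly present and absent isoforms.
#'
#' @param isoform_results isoform data.frame from [summarize_posterior()].
#' @param truth ground truth from [generate_structure()] /
#'   [simulate_dataset()].
#' @return one-row data.frame of metrics.
#' @export
evaluate_results <- function(isoform_results, truth) {
  idx <- match(isoform_results$protein_id, truth$protein_id)
  if (anyNA(idx))
    .validation_error("results contain isoforms absent from the truth")
  present <- truth$present[idx]
  true_ab <- truth$true_abundance[idx]
  est <- isoform_results$abundance_mean

  auc <- NA_real_
  if (length(unique(present)) < 2L) {
    warning("AUC undefined: all analyzed isoforms are in one presence class")
  } else {
    roc <- pROC::roc(response = present, predictor = isoform_results$prob_present,
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  covered <- true_ab >= isoform_results$abundance_lo &
             true_ab <= isoform_results$abundance_hi
  log_est <- log10(est + 1)
  log_true <- log10(true_ab + 1)
  log10_corr <- if (sd(log_est) == 0 || sd(log_true) == 0) NA_real_
                else cor(log_est, log_true)
  data.frame(auc = auc,
             log10_corr = log10_corr,
             ci_coverage = mean(covered),
             ci_coverage_present = mean(covered[present]),
             mean_abundance_present = mean(est[present]),
             mean_abundance_absent = if (any(!present)) mean(est[!present]) else NA_real_,
             n_isoforms = length(est))
}
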