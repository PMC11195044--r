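# Posterior summaries: presence probabilities, HPD intervals, gene-level
# aggregation and protein-vs-transcript comparison.

#' Posterior probability of presence
#'
#' Fraction of post-burn-in draws in which an isoform's latent abundance is
#' strictly positive.
#'
#' @param x_column integer vector, one isoform's abundance chain.
#' @return probability in \[0, 1\].
#' @export
prob_present <- function(x_column) {
  if (!length(x_column)) stop("empty chain")
  mean(x_column > 0)
}

#' Highest-posterior-density interval
#'
#' Shortest contiguous interval among windows of `ceiling(level * n)`
#' consecutive sorted draws; ties are broken by the smallest lower bound.
#'
#' @param samples numeric vector of posterior draws.
#' @param level credible level in (0, 1).
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)")
  if (level * n < 1) stop("too few samples for the requested level")
  m <- ceiling(level * n)
  s <- sort(samples)
  if (m >= n) return(c(s[1L], s[n]))
  lo_idx <- seq_len(n - m + 1L)
  widths <- s[lo_idx + m - 1L] - s[lo_idx]
  i <- which.min(widths)  # first minimum: smallest lo on ties
  c(s[i], s[i + m - 1L])
}

#' Protein-vs-transcript comparison
#'
#' For each isoform, the log2 fold change between protein and transcript
#' relative abundances, stabilized by a small constant kappa added to both,
#' and the posterior probability that the protein relative abundance exceeds
#' the transcript one (fraction of draws with pi_p > pi_T_p, strict).
#'
#' @param pi_chain draws x P matrix of relative-abundance draws.
#' @param pi_T transcript relative abundances, length P.
#' @param kappa positive stabilizing constant (default 1.5e-6).
#' @return data.frame with `log2_fc` and `prob_pi_gt_piT`.
#' @export
transcript_comparison <- function(pi_chain, pi_T, kappa = 1.5e-6) {
  if (!is.numeric(kappa) || kappa <= 0)
    .validation_error("'kappa' must be positive")
  if (length(pi_T) != ncol(pi_chain))
    .validation_error("'pi_T' length does not match the chain")
  pi_mean <- colMeans(pi_chain)
  log2_fc <- log2((pi_mean + kappa) / (pi_T + kappa))
  prob <- colMeans(sweep(pi_chain, 2L, pi_T, `>`))
  data.frame(log2_fc = log2_fc, prob_pi_gt_piT = prob)
}

#' Summarize posterior draws into isoform- and gene-level results
#'
#' Per isoform: posterior presence probability, posterior means of the
#' overall abundance X_p and relative abundance pi_p, with HPD credible
#' intervals. Per gene: the member isoforms' abundances are summed within
#' each iteration and the gene chain is summarized the same way, so gene
#' intervals reflect the within-gene posterior correlation. When the prior
#' carries transcript relative abundances, the protein-vs-transcript log2
#' fold change and exceedance probability are appended.
#'
#' @param draws a `posterior_draws` object from [run_mcmc()].
#' @param map the `peptide_protein_map` the draws were generated from.
#' @param prior the `protiso_prior` used (its `pi_T`, if any, feeds the
#'   transcript comparison).
#' @param gene_map optional data.frame (`isoform_id`, `gene_id`); isoforms
#'   missing from it are assigned their own id as gene id, with a warning.
#' @param config the [run_config()] used (CI level, kappa).
#' @return list with data.frames `isoform` and `gene`.
#' @export
summarize_posterior <- function(draws, map, prior, gene_map = NULL,
                                config = run_config()) {
  stopifnot(inherits(draws, "posterior_draws"))
  ids <- map$proteins$protein_id
  P <- length(ids)
  level <- config$ci_level

  gene_id <- ids
  if (!is.null(gene_map)) {
    hit <- match(ids, gene_map$isoform_id)
    if (anyNA(hit))
      warning(sprintf("%d isoform(s) missing from the gene map; using their own id",
                      sum(is.na(hit))))
    gene_id <- ifelse(is.na(hit), ids, gene_map$gene_id[hit])
  }

  x_ci <- apply(draws$x_chain, 2L, hpd_interval, level = level)
  pi_ci <- apply(draws$pi_chain, 2L, hpd_interval, level = level)
  iso <- data.frame(protein_id = ids,
                    gene_id = gene_id,
                    prob_present = apply(draws$x_chain, 2L, prob_present),
                    abundance_mean = colMeans(draws$x_chain),
                    abundance_lo = x_ci[1L, ],
                    abundance_hi = x_ci[2L, ],
                    pi_mean = colMeans(draws$pi_chain),
                    pi_lo = pi_ci[1L, ],
                    pi_hi = pi_ci[2L, ],
                    stringsAsFactors = FALSE)
  if (!is.null(prior$pi_T)) {
    tc <- transcript_comparison(draws$pi_chain, prior$pi_T, config$kappa_fc)
    iso$pi_T <- prior$pi_T
    iso$log2_fc <- tc$log2_fc
    iso$prob_pi_gt_piT <- tc$prob_pi_gt_piT
  } else {
    iso$pi_T <- NA_real_
    iso$log2_fc <- NA_real_
    iso$prob_pi_gt_piT <- NA_real_
  }
  rownames(iso) <- NULL

  # per-iteration within-gene sums
  genes <- sort(unique(gene_id))
  gmat <- t(rowsum(t(draws$x_chain), group = gene_id, reorder = TRUE))
  g_ci <- apply(gmat, 2L, hpd_interval, level = level)
  gene <- data.frame(gene_id = colnames(gmat),
                     abundance_mean = colMeans(gmat),
                     abundance_lo = g_ci[1L, ],
                     abundance_hi = g_ci[2L, ],
                     stringsAsFactors = FALSE)
  rownames(gene) <- NULL

  list(isoform = iso, gene = gene)
}

# fixed column order for the result TSVs
.isoform_cols <- c("protein_id", "gene_id", "prob_present", "abundance_mean",
                   "abundance_lo", "abundance_hi", "pi_mean", "pi_lo", "pi_hi",
                   "pi_T", "log2_fc", "prob_pi_gt_piT")
.gene_cols <- c("gene_id", "abundance_mean", "abundance_lo", "abundance_hi")

#' Write isoform- and gene-level result tables
#'
#' Writes `isoform_results.tsv` and `gene_results.tsv` with a fixed column
#' order; transcript-comparison columns are emitted as empty strings when no
#' mRNA data was used.
#'
#' @param results list from [summarize_posterior()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iso_path <- file.path(out_dir, "isoform_results.tsv")
  gene_path <- file.path(out_dir, "gene_results.tsv")
  write.table(results$isoform[, .isoform_cols], iso_path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(results$gene[, .gene_cols], gene_path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(c(isoform = iso_path, gene = gene_path))
}
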