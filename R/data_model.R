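# Readers, validation, mode-specific filtering and the peptide-protein map.
#
# A peptide table is represented as a data.frame with columns
#   peptide_id   character
#   abundance    integer (PSM count, or intensity rounded to integer)
#   fdr          numeric in [0, 1]
#   pep          numeric in [0, 1]
#   protein_ids  list column of character vectors (compatible isoforms)
#   zero_abundance logical flag (abundance 0 after rounding; still "detected")

.schema_error <- function(msg) {
  stop(structure(class = c("protiso_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.validation_error <- function(msg) {
  stop(structure(class = c("protiso_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.empty_error <- function(msg) {
  stop(structure(class = c("protiso_empty_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# deterministic half-away-from-zero rounding (round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Run configuration
#'
#' Collect and validate the tunable parameters of an inference run.
#'
#' @param mode `"fdr"` (filter peptides at `fdr_threshold`, error indicators
#'   fixed at 0) or `"pep"` (keep peptides up to a weak FDR filter at
#'   `pep_mode_max_fdr` and sample per-peptide error indicators from their
#'   posterior error probabilities each iteration).
#' @param fdr_threshold FDR cutoff used in FDR mode; peptides with
#'   `fdr <= fdr_threshold` are kept. Default 0.01.
#' @param pep_mode_max_fdr weak FDR cutoff used in PEP mode. Default 0.1:
#'   peptides above it carry error probabilities near 1 and are too unreliable
#'   to analyze.
#' @param iterations total MCMC iterations (default 2000).
#' @param burn_in iterations discarded before recording draws (default 1000).
#' @param prior_strength_c scale of the transcript-informed Dirichlet prior:
#'   the prior carries `prior_strength_c` units of pseudo-abundance per unit
#'   of observed abundance (default 0.1, i.e. the proteomics data weighs ten
#'   times more than the transcript prior).
#' @param epsilon_mrna small constant added to transcript relative abundances
#'   to avoid zeros (default 1e-5).
#' @param kappa_fc stabilizing constant added to relative abundances in the
#'   protein-vs-transcript log2 fold change (default 1.5e-6).
#' @param ci_level credible level of the highest-posterior-density intervals
#'   (default 0.95).
#' @param seed integer master seed; per-block RNG streams are derived from it.
#' @param threads number of parallel workers for block-level parallelism
#'   (default 1; results are identical for any thread count).
#' @return a validated list of class `protiso_config`.
#' @export
run_config <- function(mode = c("fdr", "pep"),
                       fdr_threshold = 0.01,
                       pep_mode_max_fdr = 0.1,
                       iterations = 2000L,
                       burn_in = 1000L,
                       prior_strength_c = 0.1,
                       epsilon_mrna = 1e-5,
                       kappa_fc = 1.5e-6,
                       ci_level = 0.95,
                       seed = 1L,
                       threads = 1L) {
  mode <- match.arg(mode)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (is.na(iterations) || iterations < 1L)
    .validation_error("'iterations' must be a positive integer")
  if (is.na(burn_in) || burn_in < 1L)
    .validation_error("'burn_in' must be a positive integer")
  if (burn_in >= iterations)
    .validation_error(sprintf("'burn_in' (%d) must be smaller than 'iterations' (%d)",
                              burn_in, iterations))
  for (nm in c("fdr_threshold", "pep_mode_max_fdr", "ci_level")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      .validation_error(sprintf("'%s' must be a probability in (0, 1]", nm))
  }
  if (ci_level >= 1) .validation_error("'ci_level' must be in (0, 1)")
  if (!is.numeric(prior_strength_c) || prior_strength_c <= 0)
    .validation_error("'prior_strength_c' must be positive")
  if (!is.numeric(epsilon_mrna) || epsilon_mrna <= 0)
    .validation_error("'epsilon_mrna' must be positive")
  if (!is.numeric(kappa_fc) || kappa_fc <= 0)
    .validation_error("'kappa_fc' must be positive")
  threads <- as.integer(threads)
  if (is.na(threads) || threads < 1L)
    .validation_error("'threads' must be a positive integer")
  structure(list(mode = mode,
                 fdr_threshold = fdr_threshold,
                 pep_mode_max_fdr = pep_mode_max_fdr,
                 iterations = iterations,
                 burn_in = burn_in,
                 prior_strength_c = prior_strength_c,
                 epsilon_mrna = epsilon_mrna,
                 kappa_fc = kappa_fc,
                 ci_level = ci_level,
                 seed = as.integer(seed),
                 threads = threads),
            class = "protiso_config")
}

.validate_peptides <- function(pt) {
  bad <- which(is.na(pt$abundance) | pt$abundance < 0)
  if (length(bad))
    .validation_error(sprintf("negative or missing abundance at row %d", bad[1L]))
  for (col in c("fdr", "pep")) {
    bad <- which(is.na(pt[[col]]) | pt[[col]] < 0 | pt[[col]] > 1)
    if (length(bad))
      .validation_error(sprintf("'%s' outside [0, 1] at row %d", col, bad[1L]))
  }
  nprot <- vapply(pt$protein_ids, length, 1L)
  if (any(nprot == 0L))
    .validation_error(sprintf("empty protein id list at row %d", which(nprot == 0L)[1L]))
  dup <- vapply(pt$protein_ids, anyDuplicated, 0L) > 0L
  if (any(dup))
    .validation_error(sprintf("duplicate protein ids at row %d", which(dup)[1L]))
  invisible(pt)
}

#' Read a peptide-level table
#'
#' Reads the tab-separated peptide table produced by upstream search-engine
#' post-processing: one row per detected peptide with its abundance, FDR
#' (q-value), posterior error probability and the delimiter-separated list of
#' compatible protein isoform identifiers.
#'
#' Intensity abundances are continuous and are rounded half-away-from-zero to
#' the nearest integer; PSM counts must already be integral. Rows whose
#' abundance rounds to 0 are retained (they are detected peptides and count
#' towards peptide multiplicity) but flagged in the `zero_abundance` column.
#'
#' @param path path to a TSV with columns `peptide_id`, `abundance`, `fdr`,
#'   `pep`, `protein_ids`.
#' @param abundance_kind `"psm"` for spectral counts, `"intensity"` for
#'   continuous intensities (rounded to integers).
#' @param id_delim delimiter between protein ids inside `protein_ids`
#'   (default `";"`).
#' @return a validated peptide data.frame (see package overview).
#' @export
read_peptide_table <- function(path, abundance_kind = c("psm", "intensity"),
                               id_delim = ";") {
  abundance_kind <- match.arg(abundance_kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("peptide_id", "abundance", "fdr", "pep", "protein_ids")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    .schema_error(sprintf("peptide table is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  ab <- as.numeric(dt$abundance)
  if (anyNA(ab))
    .validation_error(sprintf("non-numeric abundance at row %d", which(is.na(ab))[1L]))
  if (any(ab < 0))
    .validation_error(sprintf("negative abundance at row %d", which(ab < 0)[1L]))
  if (abundance_kind == "intensity") {
    ab <- .round_half_away(ab)
  } else if (any(ab != floor(ab))) {
    .validation_error(sprintf("non-integer PSM count at row %d",
                              which(ab != floor(ab))[1L]))
  }
  pt <- data.frame(peptide_id = as.character(dt$peptide_id),
                   abundance = as.integer(ab),
                   fdr = as.numeric(dt$fdr),
                   pep = as.numeric(dt$pep),
                   stringsAsFactors = FALSE)
  pt$protein_ids <- strsplit(as.character(dt$protein_ids), id_delim, fixed = TRUE)
  pt$zero_abundance <- pt$abundance == 0L
  .validate_peptides(pt)
  pt
}

#' Read a transcript-abundance table
#'
#' @param path TSV with columns `isoform_id`, `abundance` (e.g. TPM).
#' @return data.frame with unique ids and non-negative abundances.
#' @export
read_mrna_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(c("isoform_id", "abundance"), names(dt))
  if (length(missing))
    .schema_error(sprintf("mRNA table is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  if (anyDuplicated(dt$isoform_id))
    .validation_error("duplicate isoform ids in mRNA table")
  if (any(is.na(dt$abundance) | dt$abundance < 0))
    .validation_error("mRNA abundances must be non-negative")
  data.frame(isoform_id = as.character(dt$isoform_id),
             abundance = as.numeric(dt$abundance),
             stringsAsFactors = FALSE)
}

#' Read an isoform-to-gene map
#'
#' @param path TSV with columns `isoform_id`, `gene_id`.
#' @return data.frame mapping isoform ids to gene ids.
#' @export
read_gene_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(c("isoform_id", "gene_id"), names(dt))
  if (length(missing))
    .schema_error(sprintf("gene map is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  data.frame(isoform_id = as.character(dt$isoform_id),
             gene_id = as.character(dt$gene_id),
             stringsAsFactors = FALSE)
}

#' Mode-specific peptide filtering
#'
#' In FDR mode, keep peptides with `fdr <= fdr_threshold` (the conventional
#' 0.01 cut; the boundary is inclusive so q = 0.01 rows pass a 0.01 cut). In
#' PEP mode, a deliberately weak filter `fdr <= pep_mode_max_fdr` (default
#' 0.1) removes only peptides whose error probabilities are close to 1; the
#' retained peptides keep their PEP for per-iteration error sampling.
#'
#' @param peptides peptide data.frame (see [read_peptide_table()]).
#' @param config a [run_config()].
#' @return the filtered peptide data.frame.
#' @export
filter_for_mode <- function(peptides, config) {
  thr <- if (config$mode == "fdr") config$fdr_threshold else config$pep_mode_max_fdr
  keep <- peptides$fdr <= thr
  if (!any(keep))
    .empty_error(sprintf(
      "no peptides pass the %s-mode filter (fdr <= %g); nothing to analyze",
      config$mode, thr))
  out <- peptides[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the peptide-protein compatibility map
#'
#' Applies the trivial filter: only isoforms associated with at least one
#' detected peptide can be identified, so the analyzed protein set is the
#' union of all compatibility lists. For each analyzed isoform, the peptide
#' multiplicity M_p (number of detected unique + shared peptides compatible
#' with it) is recorded; M_p >= 1 by construction. Isoforms are partitioned
#' into blocks — connected components of the bipartite peptide-protein graph —
#' which share no peptides and can be sampled independently.
#'
#' @param peptides peptide data.frame, already mode-filtered
#'   (see [filter_for_mode()]).
#' @param search_db_proteins optional character vector of all protein ids in
#'   the search database. Peptides referencing an id absent from it are an
#'   upstream inconsistency and raise an error; `NULL` skips the check.
#' @return an object of class `peptide_protein_map`: list with `peptides`,
#'   `proteins` (data.frame `protein_id`, `m_detected`), `incidence` (per
#'   peptide, integer indices into `proteins`), `blocks` (list of protein
#'   index vectors) and `peptide_block`.
#' @export
apply_trivial_filter <- function(peptides, search_db_proteins = NULL) {
  if (NROW(peptides) == 0L)
    .empty_error("no detected peptides")
  .validate_peptides(peptides)
  all_ids <- unlist(peptides$protein_ids, use.names = FALSE)
  if (!is.null(search_db_proteins)) {
    unknown <- setdiff(all_ids, search_db_proteins)
    if (length(unknown))
      .validation_error(sprintf(
        "peptides reference protein id(s) absent from the search database: %s",
        paste(head(unknown, 5L), collapse = ", ")))
  }
  protein_id <- sort(unique(all_ids))
  idx_of <- stats::setNames(seq_along(protein_id), protein_id)
  incidence <- lapply(peptides$protein_ids, function(ids) unname(idx_of[ids]))
  m_detected <- tabulate(unlist(incidence, use.names = FALSE),
                         nbins = length(protein_id))
  stopifnot(all(m_detected >= 1L))

  # connected components of the bipartite graph, taken on its protein
  # projection: chain the proteins of each multi-protein peptide
  edges <- do.call(rbind, lapply(incidence, function(v) {
    if (length(v) < 2L) NULL else cbind(v[-length(v)], v[-1L])
  }))
  g <- igraph::make_empty_graph(n = length(protein_id), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  blocks <- unname(split(seq_along(protein_id), comp))
  peptide_block <- vapply(incidence, function(v) comp[v[1L]], 0)

  structure(list(peptides = peptides,
                 proteins = data.frame(protein_id = protein_id,
                                       m_detected = as.integer(m_detected),
                                       stringsAsFactors = FALSE),
                 incidence = incidence,
                 blocks = blocks,
                 peptide_block = as.integer(peptide_block)),
            class = "peptide_protein_map")
}

#' @export
print.peptide_protein_map <- function(x, ...) {
  cat(sprintf("peptide_protein_map: %d peptides, %d isoforms, %d blocks\n",
              NROW(x$peptides), nrow(x$proteins), length(x$blocks)))
  invisible(x)
}
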