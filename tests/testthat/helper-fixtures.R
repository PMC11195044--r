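# Fixture builders shared across the test files. All fixtures are generated
# in code; TSVs are written to tempfiles.

make_peptides <- function(peptide_id, abundance, psi, fdr = 0, pep = 0) {
  n <- length(peptide_id)
  df <- data.frame(peptide_id = peptide_id,
                   abundance = as.integer(abundance),
                   fdr = rep_len(fdr, n),
                   pep = rep_len(pep, n),
                   stringsAsFactors = FALSE)
  df$protein_ids <- psi
  df$zero_abundance <- df$abundance == 0L
  df
}

write_peptide_fixture <- function(peptides, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(peptide_id = peptides$peptide_id,
                    abundance = peptides$abundance,
                    fdr = peptides$fdr,
                    pep = peptides$pep,
                    protein_ids = vapply(peptides$protein_ids, paste, "",
                                         collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Monte-Carlo standard error of a chain mean via non-overlapping batch means
batch_se <- function(x, n_batches = 50) {
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(n_batches)
}

quick_config <- function(...) {
  run_config(iterations = 400L, burn_in = 200L, ...)
}
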