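# Shared fixture builders. Everything is generated in code; no data files.

CONDS <- c("CDKN1A.DMSO", "CDKN1A.etoposide",
           "BBC3.DMSO", "BBC3.etoposide",
           "TP53.DMSO", "TP53.etoposide")

# random lognormal screen matrix
random_screen <- function(n = 20, seed = 1, role = "library", cv = 0.2) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  vals <- matrix(rlnorm(n * 6, 0, sdlog), n, 6, dimnames = list(NULL, CONDS))
  screen_matrix(vals, genes = sprintf("G%03d", seq_len(n)), role = role)
}

# z-score table with prescribed z values (for classification-rule tests)
ztable_from_z <- function(z, genes, role = "library") {
  z <- as.matrix(z)
  colnames(z) <- CONDS
  structure(
    list(genes = genes, role = rep_len(role, length(genes)), z = z,
         mu = setNames(rep(0, 6), CONDS), theta = setNames(rep(1, 6), CONDS),
         n_used = setNames(rep(length(genes), 6), CONDS),
         include_controls = FALSE),
    class = "zscore_table"
  )
}

# screen matrix where selected genes carry fixed fold-changes, no noise
planted_screen <- function(n, planted = list(), baseline = 1) {
  vals <- matrix(baseline, n, 6, dimnames = list(NULL, CONDS))
  genes <- sprintf("G%03d", seq_len(n))
  for (p in planted) {
    vals[p$gene, p$cols] <- baseline * 2^p$log2fc
  }
  screen_matrix(vals, genes = genes)
}
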