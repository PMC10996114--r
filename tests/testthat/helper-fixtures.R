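# Shared in-code fixtures for the test suite.

# A tiny deterministic meth_matrix built directly from count matrices.
make_meth_matrix <- function(sites, meth, total, populations) {
  accs <- colnames(meth)
  m <- list(sites = sites, meth = meth, total = total, level = meth / total,
            accessions = accs, populations = populations[accs], min_reads = 0)
  class(m) <- "meth_matrix"
  m
}

# Small simulated panel reused by several test files (cheap: ~1 s).
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_panel(sim_config(
        n_chroms = 1, chrom_length = 6e5, n_per_pop = 8,
        n_sites_per_context = 2500, n_planted_dmrs = 8, n_snps = 3000,
        n_sweeps = 2, sweep_width = 40000, n_meqtl_dmrs = 1,
        n_coupled_genes = 4, seed = 42))
    cache
  }
})

# Write records to a temporary cytosine report file.
write_report_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# Brute-force per-site pi: fraction of differing pairs among n alleles.
brute_pi <- function(j, n) {
  alleles <- c(rep(1, j), rep(0, n - j))
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]]) * 1  # fraction differing
}
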