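null_cfg <- function(seed = 1) sim_config(
  n_chroms = 1, chrom_length = 4e5, n_per_pop = 6, n_sites_per_context = 1200,
  n_planted_dmrs = 4, stage_shift = 0, dmr_effect = 0, meqtl_effect = 0,
  n_snps = 1500, n_sweeps = 0, n_meqtl_dmrs = 1, n_coupled_genes = 0,
  expr_coupling_rho = 0, seed = seed)

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(n_per_pop = 3))
  expect_error(sim_config(dmr_n_sites = 7))
  expect_error(sim_config(dmr_effect = 1.2))
  expect_error(sim_config(sweep_diversity_reduction = 0))
  expect_error(sim_config(n_coupled_genes = 50, n_planted_dmrs = 10))
  # planted regions must fit on the genome
  expect_error(simulate_panel(sim_config(n_chroms = 1, chrom_length = 5e4,
                                         n_planted_dmrs = 30)),
               "disjointly")
})

test_that("the same seed reproduces the panel byte-for-byte", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 3e5, n_per_pop = 4,
                    n_sites_per_context = 600, n_planted_dmrs = 4,
                    n_snps = 600, n_sweeps = 1, sweep_width = 30000,
                    n_meqtl_dmrs = 1, n_coupled_genes = 2, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$meth_rep, p2$meth_rep)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_dataset(p1, d1)
  m2 <- write_dataset(p2, d2)
  expect_identical(m1$md5, m2$md5)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the null configuration shows no stage differences", {
  p <- simulate_panel(null_cfg())
  m <- panel_meth_matrix(p)
  s <- population_level_summary(m)
  cg <- s$population_means[s$population_means$context == "CG", ]
  expect_lt(diff(range(cg$level)), 0.01)
  d <- suppressWarnings(call_dmrs(m, "wild", "landrace", "CG"))
  expect_lte(nrow(d), 1)   # at most an occasional false segment
})

test_that("planted effect size is realized within sampling error", {
  # Monte-Carlo oracle: the mean level difference inside planted regions
  # across seeds should match the nominal effect
  deltas <- c()
  for (seed in 1:10) {
    cfg <- sim_config(n_chroms = 1, chrom_length = 1e6, n_per_pop = 12,
                      n_sites_per_context = 600, n_planted_dmrs = 20,
                      dmr_effect = 0.4, mean_coverage = 20, n_snps = 500,
                      n_sweeps = 0, n_meqtl_dmrs = 0, n_coupled_genes = 0,
                      seed = seed)
    p <- simulate_panel(cfg)
    m <- panel_meth_matrix(p)
    td <- p$truth$dmr_regions
    td <- td[td$context == "CG", ]
    for (i in seq_len(nrow(td))) {
      lv <- region_methylation_level(m, td$chrom[i], td$start[i], td$end[i],
                                     "CG")
      pops <- m$populations
      anc <- if (td$stage_pair[i] == "domestication") "wild" else "landrace"
      der <- if (td$stage_pair[i] == "domestication") "landrace" else
        "improved"
      deltas <- c(deltas, abs(mean(lv[names(pops)[pops == der]], na.rm = TRUE) -
                                mean(lv[names(pops)[pops == anc]],
                                     na.rm = TRUE)))
    }
  }
  expect_lt(abs(mean(deltas) - 0.4), 0.05)
})

test_that("zero-FST genotypes give near-zero Weir-Cockerham theta", {
  p <- simulate_panel(sim_config(n_chroms = 1, chrom_length = 1e6,
                                 n_per_pop = 10, n_sites_per_context = 100,
                                 n_planted_dmrs = 4, fst_target = 0,
                                 n_snps = 6000, n_sweeps = 0,
                                 n_meqtl_dmrs = 0, n_coupled_genes = 0,
                                 seed = 5))
  pops <- p$populations
  dw <- p$genotypes$dosage[, names(pops)[pops == "wild"]]
  dl <- p$genotypes$dosage[, names(pops)[pops == "landrace"]]
  comp <- methylpop:::fst_components(dw, dl)
  theta <- sum(comp[, "a"], na.rm = TRUE) / sum(comp, na.rm = TRUE)
  expect_lt(abs(theta), 0.01)
})

test_that("genome-wide methylation increases strictly along stages", {
  p <- small_panel()
  m <- panel_meth_matrix(p)
  s <- population_level_summary(m)
  pm <- s$population_means
  for (ctx in c("CG", "CHG")) {
    lv <- pm$level[pm$context == ctx][match(c("wild", "landrace", "improved"),
                                            pm$population[pm$context == ctx])]
    expect_true(all(diff(lv) > 0))
  }
})

test_that("truth regions lie on the genome and ids resolve", {
  p <- small_panel()
  cl <- p$annotation$chrom_lengths
  td <- p$truth$dmr_regions
  expect_true(all(td$start >= 0 & td$end <= cl[td$chrom]))
  sw <- p$truth$sweep_regions
  expect_true(all(sw$start >= 0 & sw$end <= cl[sw$chrom]))
  expect_true(all(p$truth$meqtl_pairs$dmr_id %in% td$dmr_id))
  expect_true(all(p$truth$meqtl_pairs$snp_id %in% p$genotypes$snps$snp_id))
  expect_true(all(p$truth$coupled_genes$gene_id %in%
                    p$annotation$genes$gene_id))
})

test_that("written datasets round-trip through the package readers", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 3e5, n_per_pop = 4,
                    n_sites_per_context = 500, n_planted_dmrs = 4,
                    n_snps = 500, n_sweeps = 1, sweep_width = 30000,
                    n_meqtl_dmrs = 1, n_coupled_genes = 2, seed = 17)
  p <- simulate_panel(cfg)
  out <- tempfile()
  manifest <- write_dataset(p, out)
  expect_true(all(file.exists(file.path(out, manifest$file))))

  # methylomes: pooled counts equal the in-memory panel
  ds <- read_dataset_methylomes(out)
  acc <- p$accessions[1]
  rec <- ds$accession_records[[acc]]
  key_panel <- paste(p$sites$chrom, p$sites$pos, p$sites$context)
  key_file <- paste(rec$chrom, rec$pos, rec$context)
  idx <- match(key_panel, key_file)
  expect_false(anyNA(idx))
  expect_equal(rec$n_meth[idx], unname(p$meth[, acc]))
  expect_equal(rec$n_total[idx], unname(p$total[, acc]))

  # VCF: dosages and 1-based positions round-trip through vcfR
  g <- read_vcf_genotypes(file.path(out, "genotypes.vcf"),
                          maf_min = 0, max_missing = 1)
  idx2 <- match(p$genotypes$snps$snp_id, g$snps$snp_id)
  expect_false(anyNA(idx2))
  expect_equal(g$snps$pos[idx2], p$genotypes$snps$pos)
  expect_equal(unname(g$dosage[idx2, p$accessions]),
               unname(p$genotypes$dosage))

  # expression round-trips
  ex <- as.data.frame(data.table::fread(file.path(out, "expression.tsv")))
  rownames(ex) <- ex$gene_id
  expect_equal(as.matrix(ex[rownames(p$expression), p$accessions]),
               p$expression, tolerance = 1e-6, ignore_attr = TRUE)

  # empty panel refuses to write
  p0 <- p; p0$accessions <- character(); p0$sample_sheet <- p$sample_sheet[0, ]
  expect_error(write_dataset(p0, tempfile()), "empty panel")
  unlink(out, recursive = TRUE)
})

test_that("VCF writer emits 1-based positions", {
  p <- small_panel()
  out <- tempfile()
  write_dataset(p, out)
  lines <- readLines(file.path(out, "genotypes.vcf"))
  body <- lines[!startsWith(lines, "#")]
  first <- strsplit(body[1], "\t")[[1]]
  snp1 <- p$genotypes$snps[1, ]
  expect_equal(as.integer(first[2]), snp1$pos)   # POS column is 1-based
  expect_equal(first[1], snp1$chrom)
  unlink(out, recursive = TRUE)
})
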