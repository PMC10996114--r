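test_that("cytosine report parsing follows the 7-column dialect", {
  f <- write_report_file(c("chr1\t100\t+\t3\t7\tCG\tCGA",
                           "chr1\t205\t-\t0\t0\tCHH\tCAT"))
  r <- read_cytosine_report(f)
  expect_equal(r$chrom, c("chr1", "chr1"))
  expect_equal(r$pos, c(100L, 205L))
  expect_equal(r$n_meth, c(3L, 0L))
  expect_equal(r$n_total, c(10L, 0L))   # 0/0 site kept at parse stage
  expect_equal(r$context, c("CG", "CHH"))

  # order preserved over many lines
  n <- 1000
  lines <- sprintf("chr2\t%d\t+\t1\t1\tCG\tCGT", sample(seq_len(50000), n))
  f2 <- write_report_file(lines)
  r2 <- read_cytosine_report(f2)
  expect_equal(nrow(r2), n)
  expect_equal(r2$pos, as.integer(sub(".*\t(\\d+)\t\\+.*", "\\1", lines)))

  # malformed line reported with its number
  f3 <- write_report_file(c("chr1\t10\t+\t1\t1\tCG\tCGA",
                            "chr1\t20\t+\t1\t1\tBAD\tCGA"))
  expect_error(read_cytosine_report(f3), "line 2")

  # empty file -> empty frame
  f4 <- write_report_file(character())
  expect_equal(nrow(read_cytosine_report(f4)), 0L)
})

test_that("replicate pooling sums counts over the union of sites", {
  rec <- function(pos, m, t) data.frame(chrom = "chr1", pos = pos,
                                        strand = "+", context = "CG",
                                        n_meth = m, n_total = t)
  sheet <- data.frame(replicate = c("r1", "r2"), accession = c("A", "A"))
  pooled <- pool_replicates(list(r1 = rec(100, 3, 10), r2 = rec(100, 2, 10)),
                            sheet)
  expect_equal(pooled$A$n_meth, 5)
  expect_equal(pooled$A$n_total, 20)

  # site present in one replicate only
  pooled2 <- pool_replicates(list(r1 = rec(c(100, 200), c(3, 1), c(10, 4)),
                                  r2 = rec(100, 2, 10)), sheet)
  expect_equal(pooled2$A$n_total[pooled2$A$pos == 200], 4)

  # single replicate is the identity
  pooled3 <- pool_replicates(list(r1 = rec(100, 3, 10)),
                             data.frame(replicate = "r1", accession = "A"))
  expect_equal(pooled3$A$n_meth, 3)

  # a replicate mapped to two accessions is rejected
  expect_error(pool_replicates(list(r1 = rec(100, 3, 10)),
                               data.frame(replicate = c("r1", "r1"),
                                          accession = c("A", "B"))),
               "two accessions")
})

test_that("coverage filter is strict and idempotent", {
  r <- data.frame(n_total = c(0, 3, 4, 10))
  kept <- filter_coverage(r, min_reads = 3)
  expect_equal(kept$n_total, c(4, 10))     # n_total = 3 removed, 4 kept
  expect_equal(filter_coverage(kept, 3), kept)
  expect_equal(nrow(filter_coverage(data.frame(n_total = 0), 0)), 0L)
})

test_that("matrix assembly applies the per-population presence rule", {
  rec <- function(pos, m, t) data.frame(chrom = "chr1", pos = pos,
                                        strand = "+", context = "CG",
                                        n_meth = m, n_total = t)
  pops <- c(W1 = "wild", W2 = "wild", L1 = "landrace", L2 = "landrace")
  # site 100 in everyone (5/10); site 200 missing in half of wild
  recs <- list(W1 = rec(c(100, 200), 5, 10), W2 = rec(100, 5, 10),
               L1 = rec(c(100, 200), 5, 10), L2 = rec(c(100, 200), 5, 10))
  m <- build_methylation_matrix(recs, pops, min_fraction_present = 0.7)
  expect_equal(m$sites$pos, 100L)
  expect_equal(unname(m$level[1, ]), rep(0.5, 4))
  # with threshold 0.5, one accession per population suffices
  m2 <- build_methylation_matrix(recs, pops, min_fraction_present = 0.5)
  expect_setequal(m2$sites$pos, c(100L, 200L))
  # no retained cell has support at or below min_reads
  expect_true(all(m2$total > 3, na.rm = TRUE))
})

test_that("region level is the pooled-count ratio, not a mean of ratios", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = "+",
                      context = "CG")
  meth <- matrix(c(1, 9), 2, 1, dimnames = list(NULL, "A"))
  total <- matrix(c(4, 16), 2, 1, dimnames = list(NULL, "A"))
  m <- make_meth_matrix(sites, meth, total, c(A = "wild"))
  lv <- region_methylation_level(m, "chr1", 0, 100, "CG")
  expect_equal(unname(lv["A"]), 0.5)       # 10/20, not mean(0.25, 0.5625)
  expect_false(isTRUE(all.equal(unname(lv["A"]), mean(c(1 / 4, 9 / 16)))))

  # one site 0/8 -> exactly 0; empty region -> NA flagged
  m0 <- make_meth_matrix(sites[1, ], matrix(0, 1, 1, dimnames = list(NULL, "A")),
                         matrix(8, 1, 1, dimnames = list(NULL, "A")),
                         c(A = "wild"))
  expect_equal(unname(region_methylation_level(m0, "chr1", 0, 100, "CG")["A"]), 0)
  out <- region_methylation_level(m0, "chr1", 500, 600, "CG")
  expect_true(all(is.na(out)))
  expect_true(attr(out, "no_sites"))

  # conservation: whole-chromosome region level equals pooled chromosome level
  p <- small_panel()
  mm <- panel_meth_matrix(p)
  sel <- mm$sites$context == "CG" & mm$sites$chrom == "chr1"
  direct <- colSums(mm$meth[sel, ], na.rm = TRUE) /
    colSums(mm$total[sel, ], na.rm = TRUE)
  via_region <- region_methylation_level(mm, "chr1", 0,
                                         p$config$chrom_length, "CG")
  expect_equal(via_region, direct)
})

test_that("chromosome windows tile correctly", {
  sites <- data.frame(chrom = "chr1", pos = c(1000L, 600000L), strand = "+",
                      context = "CG")
  meth <- matrix(3, 2, 2, dimnames = list(NULL, c("A", "B")))
  total <- matrix(10, 2, 2, dimnames = list(NULL, c("A", "B")))
  m <- make_meth_matrix(sites, meth, total, c(A = "wild", B = "wild"))
  w <- chromosome_window_levels(m, window = 5e5,
                                chrom_lengths = c(chr1 = 1e6))
  expect_equal(nrow(w), 2L)                      # 1 Mb -> 2 windows
  expect_equal(w$level, c(0.3, 0.3))             # constant signal
  # empty window is missing
  w2 <- chromosome_window_levels(m, window = 2.5e5,
                                 chrom_lengths = c(chr1 = 1e6))
  expect_true(is.na(w2$level[2]))
})

test_that("metaprofiles are 80-bin, strand-aware and flip-invariant", {
  # uniform signal: every bin equals the constant level
  set.seed(1)
  pos <- sort(sample.int(20000, 3000))
  sites <- data.frame(chrom = "chr1", pos = pos, strand = "+", context = "CG")
  lev <- matrix(0.4, length(pos), 2, dimnames = list(NULL, c("A", "B")))
  m <- make_meth_matrix(sites, lev * 10, matrix(10, length(pos), 2,
                                                dimnames = list(NULL, c("A", "B"))),
                        c(A = "wild", B = "wild"))
  feats <- data.frame(chrom = "chr1", start = c(5000, 12000),
                      end = c(8000, 15000), strand = c("+", "-"))
  prof <- feature_metaprofile(m, feats, "CG")
  expect_length(prof$bins, 80L)
  expect_equal(unname(prof$bins), rep(0.4, 80), tolerance = 1e-12)

  # hypermethylated gene body: body bins high, flanks low, sharp transition
  body <- pos >= 5000 & pos < 8000
  lev2 <- matrix(ifelse(body, 0.8, 0.2), length(pos), 2,
                 dimnames = list(NULL, c("A", "B")))
  m2 <- make_meth_matrix(sites, lev2 * 10,
                         matrix(10, length(pos), 2,
                                dimnames = list(NULL, c("A", "B"))),
                         c(A = "wild", B = "wild"))
  f1 <- data.frame(chrom = "chr1", start = 5000, end = 8000, strand = "+")
  pr <- feature_metaprofile(m2, f1, "CG")
  expect_true(all(pr$bins[21:60] > 0.75, na.rm = TRUE))
  expect_true(all(pr$bins[c(1:20, 61:80)] < 0.25, na.rm = TRUE))

  # strand-symmetric signal: flipping all strands leaves the profile intact
  pr_minus <- feature_metaprofile(m, transform(feats,
                                               strand = c("-", "+")), "CG")
  expect_equal(pr_minus$bins, prof$bins, tolerance = 1e-12)

  # minus-strand 3' hypermethylation lands in the downstream block
  left_flank <- pos >= 10000 & pos < 12000    # genomic left = 3' of minus gene
  lev3 <- matrix(ifelse(left_flank, 0.9, 0.1), length(pos), 2,
                 dimnames = list(NULL, c("A", "B")))
  m3 <- make_meth_matrix(sites, lev3 * 10,
                         matrix(10, length(pos), 2,
                                dimnames = list(NULL, c("A", "B"))),
                         c(A = "wild", B = "wild"))
  fm <- data.frame(chrom = "chr1", start = 12000, end = 15000, strand = "-")
  prm <- feature_metaprofile(m3, fm, "CG")
  expect_true(mean(prm$bins[61:80], na.rm = TRUE) > 0.8)  # downstream block
  expect_true(mean(prm$bins[1:20], na.rm = TRUE) < 0.2)   # 5' flank stays low
})

test_that("population summary pairs by rank and matches the t formula", {
  mk <- function(levels_by_acc, pops) {
    accs <- names(levels_by_acc)
    sites <- data.frame(chrom = "chr1", pos = 100L, strand = "+",
                        context = "CG")
    meth <- matrix(round(unlist(levels_by_acc) * 1000), 1,
                   dimnames = list(NULL, accs))
    total <- matrix(1000, 1, length(accs), dimnames = list(NULL, accs))
    make_meth_matrix(sites, meth, total, pops)
  }
  # identical populations -> t = 0, p = 1
  m_eq <- mk(c(W1 = 0.2, W2 = 0.4, L1 = 0.2, L2 = 0.4),
             c(W1 = "wild", W2 = "wild", L1 = "landrace", L2 = "landrace"))
  s <- population_level_summary(m_eq)
  expect_equal(s$tests$t_paired, 0)
  expect_equal(s$tests$p_paired, 1)

  # frozen hand computation: paired diffs {0.10,0.12,0.08,0.11,0.09}
  w <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  d <- c(0.10, 0.12, 0.08, 0.11, 0.09)
  lv <- c(stats::setNames(w, paste0("W", 1:5)),
          stats::setNames(w + d, paste0("L", 1:5)))
  pops <- c(stats::setNames(rep("wild", 5), paste0("W", 1:5)),
            stats::setNames(rep("landrace", 5), paste0("L", 1:5)))
  s2 <- population_level_summary(mk(lv, pops))
  # t = dbar / (s_d / sqrt(5)) = 0.1 / (0.0158114 / 2.23607) = 14.14214
  expect_equal(s2$tests$t_paired, 14.14214, tolerance = 1e-4)
  expect_lt(s2$tests$p_paired, 0.001)

  # degenerate zero-variance nonzero shift -> p = 0 convention with warning
  lv3 <- c(stats::setNames(w, paste0("W", 1:5)),
           stats::setNames(w + 0.1, paste0("L", 1:5)))
  expect_warning(s3 <- population_level_summary(mk(lv3, pops)),
                 "zero variance")
  expect_equal(s3$tests$p_paired, 0)
})

test_that("site-level spectrum bins close the last bin and sum to one", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(10) * 10L, strand = "+",
                      context = "CG")
  lv <- seq(0.05, 0.95, by = 0.1)
  m <- make_meth_matrix(sites, matrix(lv * 100, 10, 1,
                                      dimnames = list(NULL, "A")),
                        matrix(100, 10, 1, dimnames = list(NULL, "A")),
                        c(A = "wild"))
  sp <- context_site_spectrum(m)
  expect_equal(sp$frequency, rep(0.1, 10))
  expect_equal(sum(sp$frequency), 1)

  m1 <- make_meth_matrix(sites, matrix(100, 10, 1, dimnames = list(NULL, "A")),
                         matrix(100, 10, 1, dimnames = list(NULL, "A")),
                         c(A = "wild"))
  sp1 <- context_site_spectrum(m1)
  expect_equal(sp1$frequency[10], 1)   # levels of exactly 1.0 in the last bin
})
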