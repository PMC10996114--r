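mk_dmrs <- function(id, start, end, context, chrom = "chr1") {
  data.frame(dmr_id = id, chrom = chrom, start = start, end = end,
             context = context, stringsAsFactors = FALSE)
}

test_that("cross-context overlap grouping partitions the DMR set", {
  cg <- mk_dmrs(c("c1", "c2"), c(100, 1000), c(200, 1100), "CG")
  chg <- mk_dmrs(c("h1", "h2"), c(150, 200), c(250, 300), "CHG")
  g <- classify_context_overlap(cg, chg)
  expect_setequal(g$o_cg_chg$dmr_id, c("c1", "h1"))
  # half-open touch at 200 is not an overlap
  expect_setequal(g$u_chg$dmr_id, "h2")
  expect_setequal(g$u_cg$dmr_id, "c2")
  expect_equal(nrow(g$o_cg_chg) + nrow(g$u_cg) + nrow(g$u_chg),
               nrow(cg) + nrow(chg))
  # empty CHG set: everything is unique CG
  g2 <- classify_context_overlap(cg, chg[0, ])
  expect_equal(nrow(g2$o_cg_chg), 0L)
  expect_equal(nrow(g2$u_cg), 2L)
})

test_that("genomic composition respects precedence and conservation", {
  ann <- list(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
                       end = 2000, strand = "+"),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
                       end = 1500),
    tes = data.frame(chrom = "chr1", start = c(1600, 5000),
                     end = c(1900, 5100), class = "LTR"),
    chrom_lengths = c(chr1 = 10000))
  # entirely inside one exon
  comp <- genomic_composition(data.frame(chrom = "chr1", start = 1100,
                                         end = 1200), ann)
  expect_equal(unname(comp["exon"]), 1)
  # half in an exon, half in an intergenic TE
  comp2 <- genomic_composition(data.frame(chrom = "chr1", start = c(1450, 5000),
                                          end = c(1500, 5050)), ann)
  expect_equal(unname(comp2["exon"]), 0.5)
  expect_equal(unname(comp2["TE"]), 0.5)
  expect_equal(sum(comp2), 1)
  # default precedence counts a TE inside an intron as intron
  comp3 <- genomic_composition(data.frame(chrom = "chr1", start = 1600,
                                          end = 1900), ann)
  expect_equal(unname(comp3["intron"]), 1)
  comp3b <- genomic_composition(data.frame(chrom = "chr1", start = 1600,
                                           end = 1900), ann,
                                precedence = c("exon", "TE", "intron",
                                               "flank", "intergenic"))
  expect_equal(unname(comp3b["TE"]), 1)
  # splitting a region in half leaves the fractions unchanged
  whole <- genomic_composition(data.frame(chrom = "chr1", start = 800,
                                          end = 1600), ann)
  halves <- genomic_composition(data.frame(chrom = "chr1",
                                           start = c(800, 1200),
                                           end = c(1200, 1600)), ann)
  expect_equal(whole, halves)
  expect_error(genomic_composition(data.frame(chrom = "chr1", start = 0,
                                              end = 20000), ann), "outside")
})

test_that("gene proximity labels are strand-aware within 2-kb flanks", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(10000, 10000), end = c(13000, 13000),
                      strand = c("+", "-"))
  dmr <- data.frame(dmr_id = "d1", chrom = "chr1", start = 8400, end = 8600)
  near <- genes_near_regions(dmr, genes)
  expect_equal(near$location[near$gene_id == "gp"], "upstream")
  expect_equal(near$location[near$gene_id == "gm"], "downstream")
  # 3 kb away: no pair
  far <- data.frame(dmr_id = "d2", chrom = "chr1", start = 6900, end = 7000)
  expect_equal(nrow(genes_near_regions(far, genes)), 0L)
  # body overlap outranks flank labels
  body <- data.frame(dmr_id = "d3", chrom = "chr1", start = 9900, end = 10100)
  nb <- genes_near_regions(body, genes)
  expect_true(all(nb$location == "body"))
})

test_that("shared-region overlap counts and Jaccard are exact", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  s <- shared_regions(a, b)
  expect_equal(s$jaccard_bp, 1 / 3)
  expect_equal(s$n_a_overlapping, 1L)
  expect_equal(shared_regions(a, a)$jaccard_bp, 1)
  s0 <- shared_regions(a, data.frame(chrom = "chr1", start = 500, end = 600))
  expect_equal(s0$n_a_overlapping, 0L)
  expect_equal(s0$jaccard_bp, 0)
})

test_that("methylation PCA handles duplicates, constants and structure", {
  set.seed(31)
  sites <- data.frame(chrom = "chr1", pos = 1:60 * 100L, strand = "+",
                      context = "CG")
  lev <- matrix(runif(60 * 4, 0.2, 0.8), 60, 4,
                dimnames = list(NULL, c("A", "B", "C", "A2")))
  lev[, "A2"] <- lev[, "A"]
  m <- make_meth_matrix(sites, lev * 20, matrix(20, 60, 4,
                                                dimnames = dimnames(lev)),
                        c(A = "wild", B = "wild", C = "landrace",
                          A2 = "wild"))
  pc <- methylation_pca(m, "CG")
  expect_equal(pc$coordinates["A", ], pc$coordinates["A2", ])
  # constant matrix: zero variance, coordinates all zero
  mc <- make_meth_matrix(sites, matrix(10, 60, 3,
                                       dimnames = list(NULL, c("A", "B", "C"))),
                         matrix(20, 60, 3,
                                dimnames = list(NULL, c("A", "B", "C"))),
                         c(A = "wild", B = "wild", C = "landrace"))
  pcc <- methylation_pca(mc, "CG")
  expect_equal(unname(pcc$coordinates), matrix(0, 3, 2), tolerance = 1e-12)
  expect_error(methylation_pca(make_meth_matrix(
    sites, lev[, 1:2] * 20, matrix(20, 60, 2,
                                   dimnames = list(NULL, c("A", "B"))),
    c(A = "wild", B = "wild")), "CG"), "3 accessions")
})

test_that("stage structure separates populations beyond label permutation", {
  p <- small_panel()
  m <- panel_meth_matrix(p)
  pc <- methylation_pca(m, "CG")
  sep <- function(labels) {
    cent <- apply(pc$coordinates, 2, tapply, labels, mean)
    d <- dist(cent)
    mean(d)
  }
  obs <- sep(unname(m$populations))
  set.seed(32)
  perm <- replicate(99, sep(sample(unname(m$populations))))
  expect_lt((1 + sum(perm >= obs)) / 100, 0.05)
})

test_that("GFF3 and BED annotation round-trip through the writers", {
  p <- small_panel()
  out <- tempfile()
  write_dataset(p, out)
  ann <- read_gff3_annotation(file.path(out, "genes.gff3"))
  expect_equal(ann$genes[, c("gene_id", "chrom", "start", "end", "strand")],
               p$annotation$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand")])
  expect_equal(nrow(ann$exons), nrow(p$annotation$exons))
  te <- read_te_bed(file.path(out, "tes.bed"))
  expect_equal(te[, c("chrom", "start", "end")],
               p$annotation$tes[, c("chrom", "start", "end")])
  unlink(out, recursive = TRUE)
})
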