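#' Configuration for the synthetic panel generator
#'
#' Defaults emulate a three-stage (wild -> landrace -> improved)
#' domestication panel: small globally increasing methylation across
#' stages, planted DMRs with known effect and direction, Balding-Nichols
#' differentiated SNPs, planted sweeps with reduced derived-population
#' diversity, planted meQTLs, and promoter-methylation-coupled genes.
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 2e6).
#' @param n_per_pop Accessions per population (default 12; >= 4).
#' @param replicates_per_accession Biological replicates pooled per
#'   accession (default 2).
#' @param n_sites_per_context Background cytosine sites per context per
#'   chromosome (default 8000).
#' @param mean_coverage Poisson mean read coverage per site (default 20).
#' @param baseline_level Named context -> baseline methylation level
#'   (default CG 0.5, CHG 0.35, CHH 0.1).
#' @param stage_shift Global level increment per domestication stage
#'   (default 0.02).
#' @param n_planted_dmrs Number of planted CG DMRs (default 30).
#' @param dmr_effect Planted level difference (default 0.4).
#' @param dmr_n_sites Sites per planted DMR (default 12; >= 8).
#' @param hyper_fraction Fraction of planted DMRs that are
#'   hypermethylated in the derived stage (default 2/3, reflecting the
#'   global methylation gain during domestication).
#' @param coupling_fraction Fraction of planted CG DMRs with a co-located
#'   CHG DMR of the same effect (default 0.5).
#' @param n_snps Background SNPs genome-wide (default 20000).
#' @param fst_target Wright's F_ST for Balding-Nichols population
#'   frequencies (default 0.1).
#' @param n_sweeps Planted sweep regions (default 6).
#' @param sweep_width Sweep region width in bp (default 60000).
#' @param sweep_diversity_reduction Multiplier (0,1) applied to derived
#'   heterozygosity in sweeps (default 0.1).
#' @param n_meqtl_dmrs Planted DMRs also driven by a nearby SNP
#'   (default 1; <= n_planted_dmrs).
#' @param meqtl_effect Level shift per alt allele (default 0.15).
#' @param n_coupled_genes Genes whose expression tracks their promoter
#'   DMR (default 10; <= n_planted_dmrs).
#' @param expr_coupling_rho Target Pearson correlation on the log2 scale
#'   (default -0.7; negative = promoter repression).
#' @param beta_concentration Beta concentration of the between-accession
#'   level jitter (default 50).
#' @param seed RNG seed (default 1).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 2e6, n_per_pop = 12,
                       replicates_per_accession = 2,
                       n_sites_per_context = 8000, mean_coverage = 20,
                       baseline_level = c(CG = 0.5, CHG = 0.35, CHH = 0.1),
                       stage_shift = 0.02, n_planted_dmrs = 30,
                       dmr_effect = 0.4, dmr_n_sites = 12,
                       hyper_fraction = 2 / 3, coupling_fraction = 0.5,
                       n_snps = 20000, fst_target = 0.1, n_sweeps = 6,
                       sweep_width = 60000,
                       sweep_diversity_reduction = 0.1, n_meqtl_dmrs = 1,
                       meqtl_effect = 0.15, n_coupled_genes = 10,
                       expr_coupling_rho = -0.7, beta_concentration = 50,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_per_pop >= 4, cfg$dmr_n_sites >= 8,
            cfg$replicates_per_accession >= 1,
            all(cfg$baseline_level >= 0 & cfg$baseline_level <= 1),
            cfg$dmr_effect >= 0, cfg$dmr_effect <= 1,
            cfg$hyper_fraction >= 0, cfg$hyper_fraction <= 1,
            cfg$coupling_fraction >= 0, cfg$coupling_fraction <= 1,
            cfg$sweep_diversity_reduction > 0,
            cfg$sweep_diversity_reduction < 1,
            cfg$fst_target >= 0, cfg$fst_target < 1,
            cfg$n_meqtl_dmrs <= cfg$n_planted_dmrs,
            cfg$n_coupled_genes <= cfg$n_planted_dmrs,
            abs(cfg$expr_coupling_rho) <= 1)
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$baseline_level)))
    stop("baseline_level must name CG, CHG and CHH")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic gene/TE tiling of one chromosome: one gene every 10 kb
# (3 kb long, 3 exons), one TE in each intergenic gap.
tile_annotation <- function(chroms, chrom_length) {
  genes <- list(); exons <- list(); tes <- list()
  te_classes <- c("LTR/Gypsy", "LTR/Copia", "DNA/MULE", "LINE/L1")
  gid <- 0L
  for (ch in chroms) {
    n_genes <- max(0L, (chrom_length - 6000) %/% 10000)
    for (k in seq_len(n_genes)) {
      gid <- gid + 1L
      gs <- 3000 + (k - 1) * 10000
      strand <- if (k %% 2 == 1) "+" else "-"
      id <- sprintf("gene%05d", gid)
      genes[[gid]] <- data.frame(gene_id = id, chrom = ch, start = gs,
                                 end = gs + 3000, strand = strand,
                                 stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(gene_id = id, chrom = ch,
                                 start = gs + c(0, 1100, 2400),
                                 end = gs + c(600, 1900, 3000),
                                 stringsAsFactors = FALSE)
      tes[[gid]] <- data.frame(chrom = ch, start = gs + 4500,
                               end = gs + 6000,
                               class = te_classes[(k - 1) %% 4 + 1],
                               stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons),
       tes = do.call(rbind, tes),
       chrom_lengths = stats::setNames(rep(chrom_length, length(chroms)),
                                       chroms))
}

#' Simulate a multi-population WGBS + SNP + expression panel
#'
#' Generates genotypes (Balding-Nichols), replicate-level methylomes
#' (beta-jittered latent levels, Poisson coverage, binomial counts),
#' gene/TE annotation, an expression matrix, and a machine-readable
#' truth table of everything planted. Fixing the seed fixes all outputs.
#'
#' @param config A \code{sim_config}.
#' @return Object of class \code{methylpop_panel}; see fields
#'   \code{sample_sheet}, \code{sites}, \code{meth}/\code{total} (pooled
#'   per accession), \code{meth_rep}/\code{total_rep} (per replicate),
#'   \code{genotypes}, \code{expression}, \code{annotation},
#'   \code{truth}, \code{latent}.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  ann <- tile_annotation(chroms, config$chrom_length)
  stages <- c(wild = 0L, landrace = 1L, improved = 2L)
  pops <- rep(names(stages), each = config$n_per_pop)
  accs <- paste0(c(wild = "W", landrace = "L", improved = "I")[pops],
                 sprintf("%02d", sequence(rep(config$n_per_pop, 3))))
  stage <- stages[pops]
  n_acc <- length(accs)
  R <- config$replicates_per_accession
  sample_sheet <- data.frame(
    accession = rep(accs, each = R), population = rep(pops, each = R),
    replicate = paste0(rep(accs, each = R), ".rep",
                       sequence(rep(R, n_acc))),
    stringsAsFactors = FALSE)

  ## ---- planted DMR layout: promoters of evenly spaced genes ----
  n_genes <- nrow(ann$genes)
  if (config$n_planted_dmrs > n_genes)
    stop("cannot fit ", config$n_planted_dmrs,
         " planted DMRs disjointly: only ", n_genes, " gene promoters")
  site_spacing <- 60
  span <- (config$dmr_n_sites - 1) * site_spacing + 1
  if (span > 1800)
    stop("planted DMR span (", span, " bp) exceeds the promoter flank")
  host_idx <- round(seq(1, n_genes, length.out = config$n_planted_dmrs))
  if (anyDuplicated(host_idx)) stop("planted DMRs cannot be placed disjointly")
  truth_dmrs <- list(); planted_sites <- list()
  n_coupled <- round(config$coupling_fraction * config$n_planted_dmrs)
  for (i in seq_len(config$n_planted_dmrs)) {
    g <- ann$genes[host_idx[i], ]
    flank_start <- if (g$strand == "+") g$start - 2000 else g$end
    s0 <- flank_start + 200
    pos0 <- s0 + (seq_len(config$dmr_n_sites) - 1) * site_spacing
    stage_pair <- if (i %% 2 == 1) "domestication" else "improvement"
    direction <- if ((i - 1) %% 3 < round(3 * config$hyper_fraction))
      "hyper" else "hypo"
    ctxs <- if (i <= n_coupled) c("CG", "CHG") else "CG"
    for (ctx in ctxs) {
      off <- if (ctx == "CG") 0L else 17L  # interleave CHG partner sites
      truth_dmrs[[length(truth_dmrs) + 1L]] <- data.frame(
        dmr_id = sprintf("planted_%03d_%s", i, ctx),
        chrom = g$chrom, start = min(pos0), end = max(pos0) + off + 1,
        context = ctx, stage_pair = stage_pair, direction = direction,
        effect = config$dmr_effect, host_gene = g$gene_id,
        stringsAsFactors = FALSE)
      planted_sites[[length(planted_sites) + 1L]] <- data.frame(
        chrom = g$chrom, pos0 = pos0 + off, context = ctx,
        stringsAsFactors = FALSE)
    }
  }
  truth_dmrs <- do.call(rbind, truth_dmrs)

  ## ---- cytosine sites ----
  site_list <- list()
  for (ch in chroms) {
    for (ctx in c("CG", "CHG", "CHH")) {
      pos0 <- sort(sample.int(config$chrom_length, config$n_sites_per_context))
      site_list[[paste(ch, ctx)]] <- data.frame(chrom = ch, pos0 = pos0,
                                                context = ctx,
                                                stringsAsFactors = FALSE)
    }
  }
  ps <- do.call(rbind, planted_sites)
  sites <- rbind(do.call(rbind, site_list), ps)
  sites <- sites[!duplicated(sites[, c("chrom", "pos0", "context")]), ]
  sites <- sites[order(sites$chrom, sites$pos0, sites$context), ]
  rownames(sites) <- NULL
  n_sites <- nrow(sites)
  sites$strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  sites$trinucleotide <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")[sites$context]

  ## ---- genotypes (Balding-Nichols) ----
  snp_pos <- lapply(chroms, function(ch)
    sort(sample.int(config$chrom_length, round(config$n_snps / length(chroms)))))
  snps <- data.frame(chrom = rep(chroms, lengths(snp_pos)),
                     pos = unlist(snp_pos), stringsAsFactors = FALSE)
  # dedicated meQTL SNPs next to the first n_meqtl_dmrs planted CG DMRs
  meqtl_truth <- NULL
  if (config$n_meqtl_dmrs > 0) {
    cg_truth <- truth_dmrs[truth_dmrs$context == "CG", ]
    tgt <- cg_truth[seq_len(config$n_meqtl_dmrs), ]
    mq <- data.frame(chrom = tgt$chrom, pos = tgt$start - 500 + 1,
                     stringsAsFactors = FALSE)
    snps <- rbind(snps, mq)
    meqtl_truth <- data.frame(snp_id = paste0(mq$chrom, "_", mq$pos),
                              dmr_id = tgt$dmr_id,
                              effect = config$meqtl_effect,
                              stringsAsFactors = FALSE)
  }
  snps <- snps[!duplicated(snps[, c("chrom", "pos")]), ]
  snps <- snps[order(snps$chrom, snps$pos), ]
  rownames(snps) <- NULL
  n_snps <- nrow(snps)
  snps$snp_id <- paste0(snps$chrom, "_", snps$pos)
  snps$ref <- "A"; snps$alt <- "G"
  p_anc <- stats::runif(n_snps, 0.05, 0.95)
  is_meqtl_snp <- snps$snp_id %in% meqtl_truth$snp_id
  Fst <- config$fst_target
  pop_freq <- sapply(names(stages), function(p) {
    if (Fst == 0) p_anc
    else stats::rbeta(n_snps, p_anc * (1 - Fst) / Fst,
                      (1 - p_anc) * (1 - Fst) / Fst)
  })
  # meQTL SNPs stay undifferentiated at 0.5 so the dosage gradient spans
  # all populations
  pop_freq[is_meqtl_snp, ] <- 0.5

  ## ---- planted sweeps ----
  truth_sweeps <- NULL
  if (config$n_sweeps > 0) {
    sw <- list()
    for (s in seq_len(config$n_sweeps)) {
      ch <- chroms[(s - 1) %% length(chroms) + 1]
      start <- round(config$chrom_length * 0.25) +
        ((s - 1) %/% length(chroms)) * (2 * config$sweep_width)
      if (start + config$sweep_width > config$chrom_length)
        stop("planted sweeps do not fit on the genome")
      sw[[s]] <- data.frame(chrom = ch, start = start,
                            end = start + config$sweep_width,
                            stage_pair = if (s %% 2 == 1) "domestication"
                            else "improvement", stringsAsFactors = FALSE)
    }
    truth_sweeps <- do.call(rbind, sw)
    m <- config$sweep_diversity_reduction
    for (s in seq_len(nrow(truth_sweeps))) {
      inw <- snps$chrom == truth_sweeps$chrom[s] &
        (snps$pos - 1) >= truth_sweeps$start[s] &
        (snps$pos - 1) < truth_sweeps$end[s] & !is_meqtl_snp
      derived <- if (truth_sweeps$stage_pair[s] == "domestication")
        c("landrace", "improved") else "improved"
      # one sweep event: every derived population is dragged toward the
      # boundary nearest the ancestral frequency, so they fix the same
      # allele; heterozygosity drops to m x its previous value
      to_hi <- p_anc[inw] >= 0.5
      for (dp in derived) {
        p <- pop_freq[inw, dp]
        disc <- pmax(1 - 4 * m * p * (1 - p), 0)
        hi <- (1 + sqrt(disc)) / 2
        lo <- (1 - sqrt(disc)) / 2
        pop_freq[inw, dp] <- ifelse(to_hi, hi, lo)
      }
    }
  }
  dosage <- matrix(NA_integer_, n_snps, n_acc,
                   dimnames = list(snps$snp_id, accs))
  for (a in seq_len(n_acc))
    dosage[, a] <- stats::rbinom(n_snps, 2, pop_freq[, pops[a]])

  ## ---- latent methylation levels ----
  base <- config$baseline_level[sites$context]
  P <- outer(base, rep(1, n_acc)) +
    outer(rep(1, n_sites), config$stage_shift * stage)
  site_key <- paste(sites$chrom, sites$pos0, sites$context)
  for (i in seq_len(nrow(truth_dmrs))) {
    td <- truth_dmrs[i, ]
    rows <- which(sites$chrom == td$chrom & sites$context == td$context &
                    sites$pos0 >= td$start & sites$pos0 < td$end)
    lev_anc <- if (td$direction == "hyper") 0.3 else 0.3 + td$effect
    lev_der <- if (td$direction == "hyper") 0.3 + td$effect else 0.3
    affected <- if (td$stage_pair == "domestication") stage >= 1 else
      stage >= 2
    P[rows, ] <- rep(ifelse(affected, lev_der, lev_anc),
                     each = length(rows))
  }
  if (!is.null(meqtl_truth)) {
    for (i in seq_len(nrow(meqtl_truth))) {
      td <- truth_dmrs[truth_dmrs$dmr_id == meqtl_truth$dmr_id[i], ]
      rows <- which(sites$chrom == td$chrom & sites$context == td$context &
                      sites$pos0 >= td$start & sites$pos0 < td$end)
      dos <- dosage[meqtl_truth$snp_id[i], ]
      P[rows, ] <- P[rows, ] +
        rep(config$meqtl_effect * dos, each = length(rows))
    }
  }
  P <- pmin(pmax(P, 0), 1)
  conc <- config$beta_concentration
  inner <- P > 0 & P < 1
  Pj <- P
  Pj[inner] <- stats::rbeta(sum(inner), P[inner] * conc,
                            (1 - P[inner]) * conc)

  ## ---- read counts per replicate ----
  rep_cols <- sample_sheet$replicate
  meth_rep <- matrix(0L, n_sites, length(rep_cols),
                     dimnames = list(NULL, rep_cols))
  total_rep <- matrix(0L, n_sites, length(rep_cols),
                      dimnames = list(NULL, rep_cols))
  for (k in seq_along(rep_cols)) {
    a <- match(sample_sheet$accession[k], accs)
    cov <- stats::rpois(n_sites, config$mean_coverage)
    meth_rep[, k] <- stats::rbinom(n_sites, cov, Pj[, a])
    total_rep[, k] <- cov
  }
  meth <- sapply(accs, function(a)
    rowSums(meth_rep[, sample_sheet$replicate[sample_sheet$accession == a],
                     drop = FALSE]))
  total <- sapply(accs, function(a)
    rowSums(total_rep[, sample_sheet$replicate[sample_sheet$accession == a],
                      drop = FALSE]))

  ## ---- expression ----
  mu_g <- stats::rnorm(n_genes, 3, 1.5)
  expr_log2 <- matrix(stats::rnorm(n_genes * n_acc, rep(mu_g, n_acc), 0.4),
                      n_genes, n_acc,
                      dimnames = list(ann$genes$gene_id, accs))
  coupled_truth <- NULL
  if (config$n_coupled_genes > 0) {
    cg_truth <- truth_dmrs[truth_dmrs$context == "CG", ]
    rows <- seq_len(config$n_coupled_genes)
    rec <- list()
    for (i in rows) {
      td <- cg_truth[i, ]
      srows <- which(sites$chrom == td$chrom & sites$context == "CG" &
                       sites$pos0 >= td$start & sites$pos0 < td$end)
      mlev <- colMeans(Pj[srows, , drop = FALSE])
      rho <- config$expr_coupling_rho
      b <- sign(rho) * 4
      sdm <- stats::sd(mlev)
      if (sdm == 0 || rho == 0) next
      noise_sd <- abs(b) * sdm * sqrt(1 / rho^2 - 1)
      y <- 5 + b * (mlev - mean(mlev)) + stats::rnorm(n_acc, 0, noise_sd)
      expr_log2[td$host_gene, ] <- y
      rec[[length(rec) + 1L]] <- data.frame(gene_id = td$host_gene,
                                            dmr_id = td$dmr_id, rho = rho,
                                            location = "upstream",
                                            stringsAsFactors = FALSE)
    }
    coupled_truth <- if (length(rec)) do.call(rbind, rec) else NULL
  }
  expression <- pmax(2^expr_log2 - 1, 0)

  sites_out <- data.frame(chrom = sites$chrom, pos = sites$pos0 + 1L,
                          strand = sites$strand, context = sites$context,
                          trinucleotide = sites$trinucleotide,
                          stringsAsFactors = FALSE)
  panel <- list(config = config, sample_sheet = sample_sheet,
                accessions = accs,
                populations = stats::setNames(pops, accs),
                sites = sites_out, meth = meth, total = total,
                meth_rep = meth_rep, total_rep = total_rep,
                latent = Pj,
                genotypes = list(snps = snps[, c("snp_id", "chrom", "pos",
                                                 "ref", "alt")],
                                 dosage = dosage),
                expression = expression, annotation = ann,
                truth = list(dmr_regions = truth_dmrs,
                             sweep_regions = truth_sweeps,
                             meqtl_pairs = meqtl_truth,
                             coupled_genes = coupled_truth))
  class(panel) <- "methylpop_panel"
  panel
}

#' @export
print.methylpop_panel <- function(x, ...) {
  cat("methylpop_panel:", length(x$accessions), "accessions x",
      nrow(x$sites), "cytosine sites,",
      nrow(x$genotypes$snps), "SNPs,", nrow(x$expression), "genes\n")
  cat("  planted:", nrow(x$truth$dmr_regions), "DMRs,",
      if (is.null(x$truth$sweep_regions)) 0 else nrow(x$truth$sweep_regions),
      "sweeps,",
      if (is.null(x$truth$meqtl_pairs)) 0 else nrow(x$truth$meqtl_pairs),
      "meQTLs\n")
  invisible(x)
}

#' Build a \code{meth_matrix} from a simulated panel
#'
#' Applies the same coverage (> min_reads pooled reads) and
#' per-population presence rules as [build_methylation_matrix()], working
#' directly from the panel's pooled count matrices.
#'
#' @param panel A \code{methylpop_panel}.
#' @param contexts Contexts kept (default CG, CHG, CHH).
#' @param min_reads Strict pooled coverage threshold (default 3).
#' @param min_fraction_present Presence fraction per population
#'   (default 0.7).
#' @return A \code{meth_matrix}.
#' @export
panel_meth_matrix <- function(panel, contexts = c("CG", "CHG", "CHH"),
                              min_reads = 3, min_fraction_present = 0.7) {
  sel <- panel$sites$context %in% contexts
  meth <- panel$meth[sel, , drop = FALSE] * 1.0
  total <- panel$total[sel, , drop = FALSE] * 1.0
  low <- total <= min_reads
  meth[low] <- NA; total[low] <- NA
  pops <- panel$populations
  keep <- rep(TRUE, nrow(total))
  for (p in unique(pops)) {
    cols <- which(pops == p)
    keep <- keep & rowMeans(!is.na(total[, cols, drop = FALSE])) >=
      min_fraction_present
  }
  sites <- panel$sites[sel, c("chrom", "pos", "strand", "context")]
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  m <- list(sites = sites, meth = meth[keep, , drop = FALSE],
            total = total[keep, , drop = FALSE],
            level = meth[keep, , drop = FALSE] / total[keep, , drop = FALSE],
            accessions = panel$accessions, populations = pops,
            min_reads = min_reads)
  class(m) <- "meth_matrix"
  m
}
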