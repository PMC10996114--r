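#' Parameters for the end-to-end pipeline
#'
#' All thresholds default to the analysis' canonical values: coverage
#' > 3 reads, DMR rules (gap < 300 bp, >= 8 sites, |delta| > 0.25,
#' q < 0.01), 10 kb / 1 kb sweep windows with top-10% joint thresholds,
#' MAF >= 0.05 and missing <= 0.7, Bonferroni alpha 0.01, r^2 < 0.25
#' clumping, 1 Mb locality, 2 kb flanks, 20/40/20 metaprofile bins.
#'
#' @param min_reads,min_fraction_present Methylome filters.
#' @param max_gap,min_sites,min_delta,q_cut DMR caller rules.
#' @param window,step,top_fraction Sweep scan geometry and tail.
#' @param maf_min,max_missing SNP filters.
#' @param alpha,r2_max,local_dist,n_pcs meQTL scan settings.
#' @param flank Gene flank width (bp).
#' @param bins Metaprofile bin layout (upstream, body, downstream).
#' @return list of class \code{pipeline_params}.
#' @export
pipeline_params <- function(min_reads = 3, min_fraction_present = 0.7,
                            max_gap = 300, min_sites = 8, min_delta = 0.25,
                            q_cut = 0.01, window = 10000, step = 1000,
                            top_fraction = 0.10, maf_min = 0.05,
                            max_missing = 0.7, alpha = 0.01, r2_max = 0.25,
                            local_dist = 1e6, n_pcs = 2, flank = 2000,
                            bins = c(20L, 40L, 20L)) {
  p <- as.list(environment())
  class(p) <- "pipeline_params"
  p
}

#' Run the full population-methylome analysis
#'
#' Orchestrates, in dependency order: panel simulation (or a supplied
#' panel), methylome matrix assembly, population methylation summaries
#' and PCA, DMR calling for the domestication (wild vs landrace) and
#' improvement (landrace vs improved) comparisons in CG and CHG,
#' diversity/F_ST window scans and sweep detection, per-region diversity
#' for DMRs/DSRs/NSRs, cross-context overlap groups and co-evolution
#' correlation, genomic composition, meQTL mapping with locality and
#' pure-DMR accounting, and methylation-expression correlation. The
#' returned report validates its internal consistency.
#'
#' @param config A \code{sim_config} (used when \code{panel} is NULL).
#' @param panel Optionally a pre-built \code{methylpop_panel}.
#' @param params A \code{pipeline_params}.
#' @return Object of class \code{methylpop_report}.
#' @export
run_pipeline <- function(config = sim_config(), panel = NULL,
                         params = pipeline_params()) {
  t0 <- Sys.time()
  if (is.null(panel)) panel <- simulate_panel(config)
  stage_of <- c(wild = 0, landrace = 1, improved = 2)
  comparisons <- list(
    domestication = c(a = "wild", b = "landrace"),
    improvement = c(a = "landrace", b = "improved"))

  ## methylome stage
  m <- panel_meth_matrix(panel, min_reads = params$min_reads,
                         min_fraction_present = params$min_fraction_present)
  pop_summary <- population_level_summary(m)
  spectrum <- context_site_spectrum(m)
  pca <- list(CG = methylation_pca(m, "CG"),
              CHG = methylation_pca(m, "CHG"))

  ## DMR stage
  dmrs <- list(); dmr_summary <- list()
  for (cmp in names(comparisons)) {
    for (ctx in c("CG", "CHG")) {
      d <- suppressWarnings(call_dmrs(
        m, comparisons[[cmp]]["a"], comparisons[[cmp]]["b"], ctx,
        max_gap = params$max_gap, min_sites = params$min_sites,
        min_delta = params$min_delta, q_cut = params$q_cut))
      if (nrow(d)) d$comparison <- cmp
      dmrs[[paste(cmp, ctx, sep = "_")]] <- d
      dmr_summary[[paste(cmp, ctx, sep = "_")]] <- summarize_dmrs(d)
    }
  }
  all_dmrs <- do.call(rbind, unname(lapply(dmrs, function(d)
    if (nrow(d)) d else NULL)))
  if (is.null(all_dmrs)) all_dmrs <- empty_dmr_frame()

  ## popgen stage
  geno <- list(snps = panel$genotypes$snps,
               dosage = panel$genotypes$dosage)
  nc <- rowSums(!is.na(geno$dosage))
  af <- rowSums(geno$dosage, na.rm = TRUE) / (2 * pmax(nc, 1))
  maf <- pmin(af, 1 - af)
  keep <- maf >= params$maf_min & (1 - nc / ncol(geno$dosage)) <= params$max_missing
  geno$snps <- geno$snps[keep, , drop = FALSE]
  geno$snps$maf <- maf[keep]
  geno$dosage <- geno$dosage[keep, , drop = FALSE]
  cl <- panel$annotation$chrom_lengths
  pops <- panel$populations
  acc_of <- function(p) names(pops)[pops == p]
  sweeps <- list(); windows <- list()
  for (cmp in names(comparisons)) {
    anc <- comparisons[[cmp]]["a"]; der <- comparisons[[cmp]]["b"]
    pa <- window_diversity(geno, acc_of(anc), cl, params$window, params$step)
    pd <- window_diversity(geno, acc_of(der), cl, params$window, params$step)
    fst <- window_fst(geno, acc_of(anc), acc_of(der), cl, params$window,
                      params$step)
    sw <- sweep_scan(pa, pd, fst, comparison = cmp,
                     top_fraction = params$top_fraction)
    sweeps[[cmp]] <- sw
    windows[[cmp]] <- sw$windows
  }
  dsrs <- do.call(rbind, unname(lapply(sweeps, function(s)
    if (nrow(s$regions)) s$regions else NULL)))
  if (is.null(dsrs)) dsrs <- data.frame(chrom = character(),
                                        start = integer(), end = integer(),
                                        n_windows = integer(),
                                        comparison = character())
  nsrs <- complement_regions(list(all_dmrs, dsrs), cl)
  all_acc <- panel$accessions
  # bp-weighted pooled diversity per region class (sum pi / sum bp)
  pooled_pi <- function(r) {
    if (!nrow(r)) return(NA_real_)
    stats::weighted.mean(region_diversity(geno, r, all_acc), r$end - r$start)
  }
  region_pi <- list(dmr = pooled_pi(all_dmrs), dsr = pooled_pi(dsrs),
                    nsr = pooled_pi(nsrs))

  ## annotation stage
  groups <- list(); coevolution <- NULL; composition <- list()
  for (cmp in names(comparisons)) {
    grp <- classify_context_overlap(dmrs[[paste0(cmp, "_CG")]],
                                    dmrs[[paste0(cmp, "_CHG")]])
    groups[[cmp]] <- grp
    co <- coevolution_correlation(grp, m)
    co$comparison <- cmp
    coevolution <- rbind(coevolution, co)
  }
  if (nrow(all_dmrs))
    composition$dmr <- genomic_composition(all_dmrs, panel$annotation,
                                           flank = params$flank)
  if (nrow(dsrs))
    composition$dsr <- genomic_composition(dsrs, panel$annotation,
                                           flank = params$flank)
  shared_dmrs <- shared_regions(
    do.call(rbind, lapply(dmrs[c("domestication_CG", "domestication_CHG")],
                          function(d) d[, c("chrom", "start", "end")])),
    do.call(rbind, lapply(dmrs[c("improvement_CG", "improvement_CHG")],
                          function(d) d[, c("chrom", "start", "end")])))
  near_genes <- genes_near_regions(all_dmrs, panel$annotation$genes,
                                   flank = params$flank)

  ## meQTL stage
  meqtl <- list(n_snps = nrow(geno$snps), threshold = NA_real_,
                associations = NULL, significant = NULL,
                n_local = 0L, n_distal = 0L, pure = NULL)
  if (nrow(all_dmrs) && nrow(geno$snps) > 0) {
    traits_raw <- dmr_level_matrix(m, all_dmrs)
    traits <- t(apply(traits_raw, 1, function(x)
      tryCatch(suppressWarnings(inverse_normal_transform(x)),
               error = function(e) rep(NA_real_, length(x)))))
    dimnames(traits) <- dimnames(traits_raw)
    K <- ibs_kinship(geno$dosage)
    assoc <- lmm_scan(t(traits), geno, K, n_pcs = params$n_pcs)
    thr <- bonferroni_threshold(params$alpha, nrow(geno$snps))
    sig <- assoc[assoc$p_value < thr, , drop = FALSE]
    sig <- ld_clump(sig, geno, r2_max = params$r2_max)
    sig <- classify_local_distal(sig, all_dmrs, local_dist = params$local_dist)
    meqtl$threshold <- thr
    meqtl$associations <- assoc
    meqtl$significant <- sig
    meqtl$n_local <- sum(sig$locality == "local")
    meqtl$n_distal <- sum(sig$locality == "distal")
    meqtl$pure <- pure_dmr_fraction(all_dmrs, sig)
  }

  ## expression stage
  expr_groups <- expression_quartile_groups(panel$expression)
  expr_profiles <- suppressWarnings(
    groupwise_metaprofile(m, panel$annotation$genes, expr_groups, "CG",
                          flank = params$flank, bins = params$bins))
  expr_corr <- NULL
  if (nrow(all_dmrs) && nrow(near_genes)) {
    traits_raw <- dmr_level_matrix(m, all_dmrs)
    expr_corr <- dmr_expression_correlation(traits_raw, panel$expression,
                                            near_genes)
  }

  report <- list(
    params = params, config = panel$config, seed = panel$config$seed,
    n_accessions = length(panel$accessions),
    n_sites = nrow(m$sites),
    pop_summary = pop_summary, spectrum = spectrum, pca = pca,
    dmrs = dmrs, all_dmrs = all_dmrs, dmr_summary = dmr_summary,
    sweeps = lapply(sweeps, function(s)
      s[c("thresholds", "regions", "n_excluded_zero_pi")]),
    windows = windows, dsrs = dsrs, region_pi = region_pi,
    groups = lapply(groups, function(g) vapply(g, nrow, integer(1))),
    coevolution = coevolution, composition = composition,
    shared_dmrs = shared_dmrs, near_genes = near_genes,
    meqtl = meqtl, expr_groups_n = table(expr_groups),
    expr_profiles = expr_profiles, expr_corr = expr_corr,
    truth = panel$truth,
    wall_clock = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "methylpop_report"
  v <- validate_report(report)
  if (!v$pass)
    stop("pipeline report failed validation: ",
         paste(v$violations, collapse = "; "))
  report
}

#' Validate a pipeline report's internal consistency
#'
#' Checks additive identities (total DMRs = CG + CHG per comparison;
#' local + distal = significant clumped associations; overlap groups
#' partition the DMR sets) and that thresholds are echoed.
#'
#' @param report A \code{methylpop_report}.
#' @return list(pass, violations).
#' @export
validate_report <- function(report) {
  v <- character()
  for (cmp in c("domestication", "improvement")) {
    n_cg <- nrow(report$dmrs[[paste0(cmp, "_CG")]])
    n_chg <- nrow(report$dmrs[[paste0(cmp, "_CHG")]])
    n_cmp <- sum(report$all_dmrs$comparison == cmp)
    if (n_cg + n_chg != n_cmp)
      v <- c(v, sprintf("%s: CG (%d) + CHG (%d) != total (%d)",
                        cmp, n_cg, n_chg, n_cmp))
    grp <- report$groups[[cmp]]
    if (!is.null(grp) && sum(grp) != n_cg + n_chg)
      v <- c(v, sprintf("%s: overlap groups (%d) do not partition DMRs (%d)",
                        cmp, sum(grp), n_cg + n_chg))
    s <- report$dmr_summary[[paste0(cmp, "_CG")]]
    if (!is.null(s) && s$n_hyper + s$n_hypo != n_cg)
      v <- c(v, sprintf("%s CG: hyper + hypo != count", cmp))
  }
  mq <- report$meqtl
  if (!is.null(mq$significant) &&
      mq$n_local + mq$n_distal != nrow(mq$significant))
    v <- c(v, "local + distal != significant clumped associations")
  for (cmp in names(report$sweeps)) {
    if (any(is.na(report$sweeps[[cmp]]$thresholds)))
      v <- c(v, paste0(cmp, ": sweep thresholds not echoed"))
  }
  list(pass = length(v) == 0, violations = v)
}

#' @export
print.methylpop_report <- function(x, ...) {
  cat("methylpop pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(" accessions:", x$n_accessions, " retained sites:", x$n_sites, "\n")
  for (k in names(x$dmrs)) {
    s <- x$dmr_summary[[k]]
    cat(sprintf("  %-22s %4d DMRs (%d hyper / %d hypo; %d / %d bp)\n", k,
                nrow(x$dmrs[[k]]), s$n_hyper, s$n_hypo,
                s$total_len_hyper, s$total_len_hypo))
  }
  for (cmp in names(x$sweeps)) {
    th <- x$sweeps[[cmp]]$thresholds
    cat(sprintf("  %s sweeps: %d regions (pi-ratio > %.3f, FST > %.3f)\n",
                cmp, nrow(x$sweeps[[cmp]]$regions), th["pi_ratio"],
                th["fst"]))
  }
  cat(sprintf("  mean pi: DMR %.3g, DSR %.3g, NSR %.3g\n",
              x$region_pi$dmr, x$region_pi$dsr, x$region_pi$nsr))
  if (!is.null(x$meqtl$significant)) {
    cat(sprintf("  meQTL: %d significant (threshold %.3g): %d local, %d distal; pure-DMR fraction %.3f\n",
                nrow(x$meqtl$significant), x$meqtl$threshold,
                x$meqtl$n_local, x$meqtl$n_distal, x$meqtl$pure$fraction))
  }
  if (!is.null(x$expr_corr))
    cat(sprintf("  DMR-expression pairs: %d (|r| > 0.5: %.3f)\n",
                nrow(x$expr_corr), attr(x$expr_corr, "fraction_strong")))
  cat(sprintf("  wall clock: %.1f s\n", x$wall_clock))
  invisible(x)
}

#' @export
summary.methylpop_report <- function(object, ...) {
  print(object)
  invisible(object)
}
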