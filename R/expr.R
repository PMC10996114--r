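#' Quartile groups of genes by expression
#'
#' Genes are ranked by mean expression across the chosen accessions and
#' split into four groups of near-equal size (low, mid-low, mid-high,
#' high). Ties are broken by stable gene order; genes with zero
#' expression in every accession always go to "low".
#'
#' @param expression Genes x accessions matrix (rownames = gene ids).
#' @param accessions Accessions averaged (default all columns).
#' @return Named character vector gene_id -> group.
#' @export
expression_quartile_groups <- function(expression,
                                       accessions = colnames(expression)) {
  if (nrow(expression) < 4) stop("need at least 4 genes")
  mu <- rowMeans(expression[, accessions, drop = FALSE])
  n <- length(mu)
  r <- rank(mu, ties.method = "first")
  grp <- c("low", "mid-low", "mid-high", "high")[ceiling(4 * r / n)]
  grp[rowSums(expression[, accessions, drop = FALSE] > 0) == 0] <- "low"
  stats::setNames(grp, rownames(expression))
}

#' Metaprofiles per expression group
#'
#' One 80-bin methylation metaprofile (20 upstream / 40 body / 20
#' downstream) per expression quartile group, for one context.
#'
#' @param m A \code{meth_matrix}.
#' @param genes Gene data.frame (gene_id, chrom, start, end, strand).
#' @param groups Named vector gene_id -> group from
#'   [expression_quartile_groups()].
#' @param context Context to profile.
#' @param accessions Accessions averaged into the signal (default all).
#' @param ... Passed to [feature_metaprofile()].
#' @return Named list of \code{metaprofile} objects (low, mid-low,
#'   mid-high, high); empty groups give NULL with a warning.
#' @export
groupwise_metaprofile <- function(m, genes, groups, context,
                                  accessions = m$accessions, ...) {
  out <- list()
  for (g in c("low", "mid-low", "mid-high", "high")) {
    ids <- names(groups)[groups == g]
    feats <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (!nrow(feats)) {
      warning("empty expression group: ", g)
      out[[g]] <- NULL
      next
    }
    out[[g]] <- feature_metaprofile(m, feats, context,
                                    accessions = accessions, ...)
  }
  out
}

#' Pearson correlation between DMR methylation and gene expression
#'
#' For each (DMR, gene, location) pair, correlates the DMR's per-accession
#' methylation level with the gene's expression (log2(FPKM + 1) by
#' default) across accessions. Pairs with fewer than 5 complete
#' accessions, or with a constant vector, get NA.
#'
#' @param dmr_levels DMRs x accessions level matrix (rownames = dmr_id).
#' @param expression Genes x accessions matrix (rownames = gene_id).
#' @param pairs data.frame(region_id or dmr_id, gene_id, location) from
#'   [genes_near_regions()].
#' @param log2_transform Correlate against log2(FPKM + 1) (default TRUE).
#' @return data.frame(dmr_id, gene_id, location, n, pcc, p_value), with
#'   attribute \code{fraction_strong}: share of pairs with |pcc| > 0.5.
#' @export
dmr_expression_correlation <- function(dmr_levels, expression, pairs,
                                       log2_transform = TRUE) {
  id_col <- if ("dmr_id" %in% names(pairs)) "dmr_id" else "region_id"
  accs <- intersect(colnames(dmr_levels), colnames(expression))
  if (length(accs) < 5) stop("fewer than 5 shared accessions")
  ex <- expression[, accs, drop = FALSE]
  if (log2_transform) ex <- log2(ex + 1)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs[[id_col]][i]; g <- pairs$gene_id[i]
    if (!d %in% rownames(dmr_levels) || !g %in% rownames(ex)) return(NULL)
    x <- dmr_levels[d, accs]; y <- ex[g, accs]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 5 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(dmr_id = d, gene_id = g,
                        location = pairs$location[i], n = n,
                        pcc = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(dmr_id = d, gene_id = g, location = pairs$location[i], n = n,
               pcc = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(dmr_id = character(), gene_id = character(),
                      location = character(), n = integer(), pcc = numeric(),
                      p_value = numeric())
  rownames(res) <- NULL
  ok <- !is.na(res$pcc)
  attr(res, "fraction_strong") <-
    if (any(ok)) mean(abs(res$pcc[ok]) > 0.5) else NA_real_
  res
}

#' Per-accession methylation levels of a DMR set
#'
#' Convenience wrapper building the DMRs x accessions trait matrix used
#' by the meQTL scan and the expression correlation: each cell is the
#' pooled-count region level of one DMR in one accession.
#'
#' @param m A \code{meth_matrix}.
#' @param dmrs DMR data.frame.
#' @return Matrix with rownames dmr_id, colnames accessions.
#' @export
dmr_level_matrix <- function(m, dmrs) {
  out <- matrix(NA_real_, nrow(dmrs), length(m$accessions),
                dimnames = list(dmrs$dmr_id, m$accessions))
  for (i in seq_len(nrow(dmrs))) {
    out[i, ] <- region_methylation_level(m, dmrs$chrom[i], dmrs$start[i],
                                         dmrs$end[i], dmrs$context[i])
  }
  out
}
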