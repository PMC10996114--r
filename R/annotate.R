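# Interval helpers: data.frame(chrom, start, end) <-> GRanges (0-based
# half-open externally, 1-based closed inside GRanges).
df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}
gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Group DMRs by cross-context overlap
#'
#' CG and CHG DMRs of one comparison are partitioned into
#' \code{o_cg_chg} (members of either context overlapping, by >= 1 bp, a
#' DMR of the other context), \code{u_cg} (CG-only) and \code{u_chg}
#' (CHG-only). Intervals are half-open, so touching regions do not
#' overlap.
#'
#' @param cg_dmrs,chg_dmrs DMR data.frames from [call_dmrs()].
#' @return list(o_cg_chg, u_cg, u_chg) of DMR data.frames; o_cg_chg also
#'   carries a \code{pairs} attribute (cg_id, chg_id).
#' @export
classify_context_overlap <- function(cg_dmrs, chg_dmrs) {
  if (nrow(cg_dmrs) && nrow(chg_dmrs)) {
    hits <- GenomicRanges::findOverlaps(df_to_gr(cg_dmrs), df_to_gr(chg_dmrs))
    cg_in <- unique(S4Vectors::queryHits(hits))
    chg_in <- unique(S4Vectors::subjectHits(hits))
    pairs <- data.frame(cg_id = cg_dmrs$dmr_id[S4Vectors::queryHits(hits)],
                        chg_id = chg_dmrs$dmr_id[S4Vectors::subjectHits(hits)],
                        stringsAsFactors = FALSE)
  } else {
    cg_in <- integer(); chg_in <- integer()
    pairs <- data.frame(cg_id = character(), chg_id = character())
  }
  o <- rbind(cg_dmrs[cg_in, , drop = FALSE], chg_dmrs[chg_in, , drop = FALSE])
  rownames(o) <- NULL
  attr(o, "pairs") <- pairs
  list(o_cg_chg = o,
       u_cg = cg_dmrs[setdiff(seq_len(nrow(cg_dmrs)), cg_in), , drop = FALSE],
       u_chg = chg_dmrs[setdiff(seq_len(nrow(chg_dmrs)), chg_in), , drop = FALSE])
}

#' CG/CHG co-evolution correlation over DMR groups
#'
#' For each DMR of a group, the CG and CHG methylation levels over the
#' region (population mean of the pooled-count region level) form one
#' point; Pearson correlation is computed across DMRs, per population and
#' pooled over all accessions.
#'
#' @param groups Output of [classify_context_overlap()] (or any named
#'   list of DMR data.frames).
#' @param m A \code{meth_matrix}.
#' @return data.frame(group, population, n, r, p_value); r is NA for
#'   groups with fewer than 3 DMRs.
#' @export
coevolution_correlation <- function(groups, m) {
  pops <- c(list(pooled = m$accessions),
            split(names(m$populations), m$populations))
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (pn in names(pops)) {
      accs <- pops[[pn]]
      if (nrow(d) >= 1) {
        cg <- vapply(seq_len(nrow(d)), function(i)
          mean(region_methylation_level(m, d$chrom[i], d$start[i], d$end[i],
                                        "CG", accs), na.rm = TRUE), numeric(1))
        chg <- vapply(seq_len(nrow(d)), function(i)
          mean(region_methylation_level(m, d$chrom[i], d$start[i], d$end[i],
                                        "CHG", accs), na.rm = TRUE), numeric(1))
        ok <- !is.na(cg) & !is.na(chg)
        n <- sum(ok)
      } else n <- 0
      if (n < 3) {
        out[[length(out) + 1L]] <- data.frame(group = g, population = pn,
                                              n = n, r = NA_real_,
                                              p_value = NA_real_)
        next
      }
      ct <- stats::cor.test(cg[ok], chg[ok])
      out[[length(out) + 1L]] <- data.frame(group = g, population = pn,
                                            n = n, r = unname(ct$estimate),
                                            p_value = ct$p.value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build the labelled annotation interval sets used by
# genomic_composition(), in precedence order.
annotation_label_sets <- function(annotation, flank = 2000,
                                  precedence = c("exon", "intron", "TE",
                                                 "flank", "intergenic")) {
  genes <- df_to_gr(annotation$genes)
  exons <- GenomicRanges::reduce(df_to_gr(annotation$exons))
  introns <- GenomicRanges::setdiff(GenomicRanges::reduce(genes), exons)
  tes <- GenomicRanges::reduce(df_to_gr(annotation$tes))
  fl <- c(GenomicRanges::flank(genes, flank, start = TRUE),
          GenomicRanges::flank(genes, flank, start = FALSE))
  GenomicRanges::start(fl) <- pmax(GenomicRanges::start(fl), 1)
  fl <- GenomicRanges::reduce(fl)
  sets <- list(exon = exons, intron = introns, TE = tes, flank = fl)
  sets[intersect(precedence, names(sets))]
}

#' Genomic composition of a region set
#'
#' Assigns every bp of the regions one label by fixed precedence
#' (default exon > intron > TE > flank > intergenic) and reports bp
#' fractions. "flank" is the 2-kb region on either side of a gene;
#' "intergenic" is everything else.
#'
#' @param regions data.frame(chrom, start, end), 0-based half-open.
#' @param annotation list(genes, exons, tes, chrom_lengths) as produced
#'   by the simulator or the GFF3/BED readers.
#' @param flank Flank width (default 2000).
#' @param precedence Label precedence; "TE" may be placed before
#'   "intron" for a TE-priority view.
#' @return Named numeric vector of fractions over
#'   {exon, intron, TE, flank, intergenic}; sums to 1.
#' @export
genomic_composition <- function(regions, annotation, flank = 2000,
                                precedence = c("exon", "intron", "TE",
                                               "flank", "intergenic")) {
  cl <- annotation$chrom_lengths
  bad <- !(regions$chrom %in% names(cl)) |
    regions$start < 0 | regions$end > cl[regions$chrom]
  if (any(bad)) stop("region(s) outside the annotated chromosomes")
  remaining <- GenomicRanges::reduce(df_to_gr(regions))
  total <- sum(GenomicRanges::width(remaining))
  sets <- annotation_label_sets(annotation, flank, precedence)
  bp <- stats::setNames(numeric(5),
                        c("exon", "intron", "TE", "flank", "intergenic"))
  for (lab in names(sets)) {
    hit <- GenomicRanges::intersect(remaining, sets[[lab]])
    bp[lab] <- sum(GenomicRanges::width(hit))
    remaining <- GenomicRanges::setdiff(remaining, sets[[lab]])
  }
  bp["intergenic"] <- sum(GenomicRanges::width(remaining))
  if (total == 0) return(bp)
  bp / total
}

#' Genes near regions, with strand-aware location labels
#'
#' A gene is near a region when the region overlaps its body or either
#' 2-kb flank. The label is "body" for body overlap, otherwise
#' "upstream" (5' flank) or "downstream" (3' flank), respecting gene
#' strand; body takes precedence when several apply.
#'
#' @param regions data.frame with region_id/dmr_id, chrom, start, end.
#' @param genes data.frame(gene_id, chrom, start, end, strand).
#' @param flank Flank width in bp (default 2000).
#' @return data.frame(region_id, gene_id, location).
#' @export
genes_near_regions <- function(regions, genes, flank = 2000) {
  id_col <- if ("region_id" %in% names(regions)) "region_id" else "dmr_id"
  empty <- data.frame(region_id = character(), gene_id = character(),
                      location = character(), stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(genes)) return(empty)
  rgr <- df_to_gr(regions)
  body <- df_to_gr(genes)
  up <- ifelse(genes$strand == "+", genes$start - flank, genes$end)
  upg <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(pmax(up, 0) + 1, up + flank))
  down <- ifelse(genes$strand == "+", genes$end, genes$start - flank)
  downg <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(pmax(down, 0) + 1,
                                                   down + flank))
  collect <- function(gr, label) {
    h <- GenomicRanges::findOverlaps(rgr, gr)
    data.frame(region_id = regions[[id_col]][S4Vectors::queryHits(h)],
               gene_id = genes$gene_id[S4Vectors::subjectHits(h)],
               location = rep(label, length(h)), stringsAsFactors = FALSE)
  }
  res <- rbind(collect(body, "body"), collect(upg, "upstream"),
               collect(downg, "downstream"))
  if (!nrow(res)) return(empty)
  # body > upstream > downstream when one region hits several parts
  res$rank <- match(res$location, c("body", "upstream", "downstream"))
  res <- res[order(res$region_id, res$gene_id, res$rank), ]
  res <- res[!duplicated(res[, c("region_id", "gene_id")]), ]
  res$rank <- NULL
  rownames(res) <- NULL
  res
}

#' Overlap counts and bp-level Jaccard of two region sets
#'
#' @param set_a,set_b Region data.frames (chrom, start, end).
#' @return list(n_a_overlapping, n_b_overlapping, jaccard_bp).
#' @export
shared_regions <- function(set_a, set_b) {
  if (!nrow(set_a) || !nrow(set_b)) {
    return(list(n_a_overlapping = 0L, n_b_overlapping = 0L,
                jaccard_bp = if (!nrow(set_a) && !nrow(set_b)) NA_real_ else 0))
  }
  ga <- df_to_gr(set_a); gb <- df_to_gr(set_b)
  ha <- GenomicRanges::countOverlaps(ga, gb)
  hb <- GenomicRanges::countOverlaps(gb, ga)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(ga), GenomicRanges::reduce(gb))))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  list(n_a_overlapping = sum(ha > 0), n_b_overlapping = sum(hb > 0),
       jaccard_bp = inter / uni)
}

#' PCA of accessions on methylation levels
#'
#' Centered (unscaled) principal component analysis of accessions over
#' the sites of one context. Missing cells are mean-imputed per site;
#' sites missing in every accession are dropped.
#'
#' @param m A \code{meth_matrix}.
#' @param context Context to use.
#' @param n_components Number of components returned (default 2).
#' @return list(coordinates = accessions x components matrix,
#'   explained_variance = fractions, populations).
#' @export
methylation_pca <- function(m, context, n_components = 2) {
  if (length(m$accessions) < 3) stop("need at least 3 accessions for PCA")
  sel <- m$sites$context == context
  L <- m$level[sel, , drop = FALSE]
  rowm <- rowMeans(L, na.rm = TRUE)
  keep <- !is.na(rowm)
  L <- L[keep, , drop = FALSE]; rowm <- rowm[keep]
  naij <- which(is.na(L), arr.ind = TRUE)
  if (nrow(naij)) L[naij] <- rowm[naij[, 1]]
  X <- t(L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  tv <- sum(pc$sdev^2)
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = if (tv > 0) (pc$sdev^2 / tv)[seq_len(k)]
       else rep(0, k),
       populations = m$populations)
}

#' Read gene/exon annotation from GFF3
#'
#' @param path GFF3 file with \code{gene} and \code{exon} features
#'   (exon Parent = gene ID).
#' @return list(genes, exons) with 0-based half-open coordinates.
#' @export
read_gff3_annotation <- function(path) {
  gff <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                           col.names = c("chrom", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attr"))
  get_attr <- function(a, key) sub(paste0(".*", key, "=([^;]+).*"), "\\1", a)
  g <- gff[gff$type == "gene", ]
  e <- gff[gff$type == "exon", ]
  genes <- data.frame(gene_id = get_attr(g$attr, "ID"), chrom = g$chrom,
                      start = g$start - 1L, end = g$end, strand = g$strand,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = get_attr(e$attr, "Parent"), chrom = e$chrom,
                      start = e$start - 1L, end = e$end,
                      stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Read TE intervals from BED6
#'
#' @param path BED file (0-based half-open, as BED is defined).
#' @return data.frame(chrom, start, end, class).
#' @export
read_te_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             class = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
             stringsAsFactors = FALSE)
}
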