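#' Candidate site blocks by adjacency
#'
#' Splits sorted cytosine positions into maximal runs in which every gap
#' between adjacent sites is strictly less than \code{max_gap}; runs with
#' fewer than \code{min_sites} sites are discarded immediately.
#'
#' @param positions Sorted 1-based site positions on one chromosome, one
#'   context.
#' @param max_gap Strict adjacency bound in bp (default 300).
#' @param min_sites Minimum sites per block (default 8).
#' @return List of integer index vectors into \code{positions}.
#' @export
candidate_blocks <- function(positions, max_gap = 300, min_sites = 8) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (!length(positions)) return(list())
  brk <- which(diff(positions) >= max_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(positions))
  blocks <- Map(seq.int, starts, ends)
  blocks[lengths(blocks) >= min_sites]
}

#' Binary segmentation of a per-site difference signal
#'
#' Recursively splits a candidate block on the per-site mean-level
#' difference d_i = mean_b(i) - mean_a(i), choosing, among breakpoints
#' that leave at least \code{min_sites} sites in each child, the one that
#' maximizes the absolute difference between the two child segments' mean
#' d. A split is accepted while it raises the larger child |mean d| above
#' the parent's |mean d| by more than \code{eps}; segments with no
#' admissible breakpoint (fewer than 2 x min_sites sites) are leaves, so
#' every leaf carries at least \code{min_sites} sites.
#'
#' @param d Per-site difference values (NA sites are skipped with a
#'   warning by the caller).
#' @param min_sites Minimum segment size (default 8).
#' @param eps Minimum improvement in max |segment mean| (default 0.02).
#' @return List of c(start, end) index pairs into \code{d} (inclusive).
#' @export
segment_block <- function(d, min_sites = 8, eps = 0.02) {
  n <- length(d)
  if (n < min_sites) return(list())
  cs <- cumsum(d)
  seg_mean <- function(i, j) (cs[j] - if (i > 1) cs[i - 1] else 0) / (j - i + 1)
  out <- list()
  recurse <- function(i, j) {
    len <- j - i + 1
    parent <- abs(seg_mean(i, j))
    if (len >= 2 * min_sites) {
      ks <- (i + min_sites - 1):(j - min_sites)
      left <- (cs[ks] - if (i > 1) cs[i - 1] else 0) / (ks - i + 1)
      right <- (cs[j] - cs[ks]) / (j - ks)
      k <- ks[which.max(abs(left - right))]
      childmax <- max(abs(seg_mean(i, k)), abs(seg_mean(k + 1, j)))
      if (childmax > parent + eps) {
        recurse(i, k)
        recurse(k + 1, j)
        return(invisible())
      }
    }
    out[[length(out) + 1L]] <<- c(i, j)
    invisible()
  }
  recurse(1L, n)
  out
}

#' Mann-Whitney test of a candidate segment
#'
#' Each accession contributes its mean level over the segment's sites;
#' the two populations' accession means are compared by a two-sided
#' Mann-Whitney U test (exact when the smaller group has at most 8
#' accessions and there are no ties; normal approximation with tie
#' correction otherwise).
#'
#' @param levels_a,levels_b Accession-level segment means for populations
#'   a (ancestral stage) and b (derived stage).
#' @return list(delta, p_value, n_a, n_b), or NULL if either group has
#'   fewer than 3 non-missing accessions.
#' @export
test_segment <- function(levels_a, levels_b) {
  a <- levels_a[!is.na(levels_a)]
  b <- levels_b[!is.na(levels_b)]
  if (length(a) < 3 || length(b) < 3) return(NULL)
  delta <- mean(b) - mean(a)
  if (stats::sd(c(a, b)) == 0)
    return(list(delta = 0, p_value = 1, n_a = length(a), n_b = length(b)))
  exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(b, a, exact = exact,
                                            correct = TRUE))
  list(delta = delta, p_value = wt$p.value, n_a = length(a), n_b = length(b))
}

#' Call differentially methylated regions between two populations
#'
#' Runs the full caller for one context: adjacency blocks
#' ([candidate_blocks()]), mean-difference binary segmentation
#' ([segment_block()]), per-segment Mann-Whitney tests
#' ([test_segment()]), Benjamini-Hochberg correction over all tested
#' segments, and the acceptance filter (at least \code{min_sites} sites,
#' |delta| > \code{min_delta}, q < \code{q_cut}). Direction is "hyper"
#' when the derived-stage population \code{pop_b} is the higher one.
#'
#' @param m A \code{meth_matrix}.
#' @param pop_a,pop_b Population labels: a = ancestral stage, b = derived
#'   stage of the comparison.
#' @param context "CG" or "CHG".
#' @param max_gap Strict adjacency bound (default 300 bp).
#' @param min_sites Minimum sites per DMR (default 8).
#' @param min_delta Minimum absolute mean-level difference (default 0.25).
#' @param q_cut Corrected-p cutoff (default 0.01).
#' @param eps Segmentation improvement threshold (default 0.02).
#' @param adjust Multiple-testing family: "BH" (default) or "bonferroni".
#' @return data.frame of DMRs (0-based half-open coordinates), sorted by
#'   chrom then start, with columns dmr_id, chrom, start, end, context,
#'   n_sites, mean_a, mean_b, delta, p_value, q_value, direction.
#' @export
call_dmrs <- function(m, pop_a, pop_b, context,
                      max_gap = 300, min_sites = 8, min_delta = 0.25,
                      q_cut = 0.01, eps = 0.02, adjust = "BH") {
  cols_a <- names(m$populations)[m$populations == pop_a]
  cols_b <- names(m$populations)[m$populations == pop_b]
  if (!length(cols_a) || !length(cols_b))
    stop("unknown population label(s): ", pop_a, " / ", pop_b)
  sel <- which(m$sites$context == context)
  cand <- list()
  for (ch in unique(m$sites$chrom[sel])) {
    on <- sel[m$sites$chrom[sel] == ch]
    on <- on[order(m$sites$pos[on])]
    pos <- m$sites$pos[on]
    dup <- duplicated(pos)          # collapse +/- records at same position
    if (any(dup)) { on <- on[!dup]; pos <- pos[!dup] }
    la <- m$level[on, cols_a, drop = FALSE]
    lb <- m$level[on, cols_b, drop = FALSE]
    dsite <- rowMeans(lb, na.rm = TRUE) - rowMeans(la, na.rm = TRUE)
    bad <- is.na(dsite)
    if (any(bad)) {
      warning(sum(bad), " all-missing site(s) skipped on ", ch)
      on <- on[!bad]; pos <- pos[!bad]; dsite <- dsite[!bad]
      la <- la[!bad, , drop = FALSE]; lb <- lb[!bad, , drop = FALSE]
    }
    for (blk in candidate_blocks(pos, max_gap, min_sites)) {
      for (sg in segment_block(dsite[blk], min_sites, eps)) {
        rows <- blk[sg[1]:sg[2]]
        tst <- test_segment(colMeans(la[rows, , drop = FALSE], na.rm = TRUE),
                            colMeans(lb[rows, , drop = FALSE], na.rm = TRUE))
        if (is.null(tst)) next
        ma <- colMeans(la[rows, , drop = FALSE], na.rm = TRUE)
        mb <- colMeans(lb[rows, , drop = FALSE], na.rm = TRUE)
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = ch, start = pos[rows[1]] - 1L, end = pos[rows[length(rows)]],
          context = context, n_sites = length(rows),
          mean_a = mean(ma, na.rm = TRUE), mean_b = mean(mb, na.rm = TRUE),
          delta = tst$delta, p_value = tst$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    warning("no testable segments for ", pop_a, " vs ", pop_b, " (", context, ")")
    return(empty_dmr_frame())
  }
  res <- do.call(rbind, cand)
  res$q_value <- stats::p.adjust(res$p_value,
                                 method = if (adjust == "BH") "BH" else "bonferroni")
  res <- res[res$n_sites >= min_sites & abs(res$delta) > min_delta &
               res$q_value < q_cut, , drop = FALSE]
  if (!nrow(res)) return(empty_dmr_frame())
  res$direction <- ifelse(res$delta > 0, "hyper", "hypo")
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$dmr_id <- sprintf("%s_%s_%s_%d", pop_a, pop_b, context,
                        seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("dmr_id", "chrom", "start", "end", "context", "n_sites",
          "mean_a", "mean_b", "delta", "p_value", "q_value", "direction")]
}

empty_dmr_frame <- function() {
  data.frame(dmr_id = character(), chrom = character(), start = integer(),
             end = integer(), context = character(), n_sites = integer(),
             mean_a = numeric(), mean_b = numeric(), delta = numeric(),
             p_value = numeric(), q_value = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}

#' Count and total length of hyper/hypo DMRs
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @return list(n_hyper, n_hypo, total_len_hyper, total_len_hypo).
#' @export
summarize_dmrs <- function(dmrs) {
  hyper <- dmrs[dmrs$direction == "hyper", , drop = FALSE]
  hypo <- dmrs[dmrs$direction == "hypo", , drop = FALSE]
  list(n_hyper = nrow(hyper), n_hypo = nrow(hypo),
       total_len_hyper = sum(hyper$end - hyper$start),
       total_len_hypo = sum(hypo$end - hypo$start))
}

#' Write DMRs as BED6+ text
#'
#' Columns: chrom, start, end, name, score (-log10 q), strand ".", then
#' context, n_sites, mean_a, mean_b, delta, p, q, direction.
#'
#' @param dmrs DMR data.frame.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$dmr_id,
                    round(-log10(pmax(dmrs$q_value, 1e-300)), 3), ".",
                    dmrs$context, dmrs$n_sites, dmrs$mean_a, dmrs$mean_b,
                    dmrs$delta, dmrs$p_value, dmrs$q_value, dmrs$direction)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
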