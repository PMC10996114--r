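#' Read a Bismark-style cytosine report
#'
#' Parses a 7-column tab-separated cytosine report (chromosome, 1-based
#' position, strand, count methylated, count unmethylated, context,
#' trinucleotide) into a per-site data frame. Counts are summed into
#' \code{n_total = n_meth + n_unmeth}; rows are returned in file order.
#'
#' @param path Path to the report file.
#' @return A data.frame with columns \code{chrom}, \code{pos}, \code{strand},
#'   \code{context}, \code{n_meth}, \code{n_total}, \code{trinucleotide}.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer(),
                      trinucleotide = character(),
                      stringsAsFactors = FALSE))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)),
                          fill = TRUE)
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer(),
                      trinucleotide = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(dt) != 7L)
    stop("expected 7 tab-separated columns in ", path, ", found ", ncol(dt))
  names(dt) <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "trinucleotide")
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH") |
                 !dt$strand %in% c("+", "-") |
                 is.na(dt$pos) | dt$pos < 1 |
                 is.na(dt$n_meth) | is.na(dt$n_unmeth) |
                 dt$n_meth < 0 | dt$n_unmeth < 0)
  if (length(bad))
    stop("malformed cytosine report line ", bad[1], " in ", path)
  data.frame(chrom = dt$chrom, pos = as.integer(dt$pos), strand = dt$strand,
             context = dt$context, n_meth = as.integer(dt$n_meth),
             n_total = as.integer(dt$n_meth + dt$n_unmeth),
             trinucleotide = dt$trinucleotide, stringsAsFactors = FALSE)
}

#' Pool replicate cytosine reports into per-accession counts
#'
#' Read counts are summed per site across an accession's biological
#' replicates (the union of the replicates' site universes is taken).
#'
#' @param replicate_records Named list of per-replicate record data frames
#'   (as returned by [read_cytosine_report()]); names are replicate ids.
#' @param sample_sheet Data frame with columns \code{replicate} and
#'   \code{accession} mapping each replicate id to one accession.
#' @return Named list of pooled record data frames, one per accession.
#' @export
pool_replicates <- function(replicate_records, sample_sheet) {
  map <- sample_sheet[, c("replicate", "accession")]
  if (anyDuplicated(map$replicate))
    stop("replicate assigned to two accessions: ",
         paste(unique(map$replicate[duplicated(map$replicate)]), collapse = ", "))
  reps <- names(replicate_records)
  missing <- setdiff(reps, map$replicate)
  if (length(missing))
    stop("replicates absent from sample sheet: ", paste(missing, collapse = ", "))
  acc_of <- stats::setNames(map$accession, map$replicate)
  all <- data.table::rbindlist(lapply(reps, function(r) {
    d <- data.table::as.data.table(replicate_records[[r]])
    d$accession <- acc_of[[r]]
    d
  }))
  pooled <- all[, list(n_meth = sum(n_meth), n_total = sum(n_total)),
                by = c("accession", "chrom", "pos", "strand", "context")]
  data.table::setorderv(pooled, c("accession", "chrom", "pos"))
  out <- split(as.data.frame(pooled[, -1]), pooled$accession)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Coverage-filter cytosine records
#'
#' Keeps sites covered by strictly more than \code{min_reads} mapped reads.
#'
#' @param records Record data frame with an \code{n_total} column.
#' @param min_reads Minimum read support; sites with
#'   \code{n_total > min_reads} are retained (default 3).
#' @export
filter_coverage <- function(records, min_reads = 3) {
  stopifnot(min_reads >= 0)
  records[records$n_total > min_reads, , drop = FALSE]
}

#' Assemble a sites-by-accessions methylation matrix
#'
#' Builds pooled methylated/total count matrices and the derived level
#' matrix (n_meth / n_total). A cell is treated as missing unless its
#' pooled support exceeds \code{min_reads}; a site is retained only if it
#' is non-missing in at least \code{min_fraction_present} of the accessions
#' of every population in \code{populations}.
#'
#' @param accession_records Named list of per-accession record data frames.
#' @param populations Named character vector mapping accession to population.
#' @param contexts Contexts to keep (default CG, CHG, CHH).
#' @param min_reads Strict coverage threshold per cell (default 3).
#' @param min_fraction_present Per-population presence fraction (default 0.7).
#' @return An object of class \code{meth_matrix}: list with \code{sites}
#'   (chrom, pos, strand, context), \code{meth}, \code{total}, \code{level}
#'   matrices, \code{accessions} and \code{populations}.
#' @export
build_methylation_matrix <- function(accession_records, populations,
                                     contexts = c("CG", "CHG", "CHH"),
                                     min_reads = 3,
                                     min_fraction_present = 0.7) {
  accs <- names(accession_records)
  if (length(accs) < 1) stop("need at least one accession")
  if (!all(accs %in% names(populations)))
    stop("populations missing for: ",
         paste(setdiff(accs, names(populations)), collapse = ", "))
  all <- data.table::rbindlist(lapply(accs, function(a) {
    d <- data.table::as.data.table(accession_records[[a]])
    d <- d[d$context %in% contexts & d$n_total > min_reads, ]
    d$accession <- a
    d[, c("accession", "chrom", "pos", "strand", "context",
          "n_meth", "n_total")]
  }))
  if (nrow(all) == 0L) {
    warning("no sites pass the coverage filter; returning empty matrix")
    return(empty_meth_matrix(accs, populations))
  }
  key <- paste(all$chrom, all$pos, all$strand, all$context, sep = "\r")
  ukey <- unique(key)
  si <- match(key, ukey)
  ai <- match(all$accession, accs)
  n_sites <- length(ukey)
  meth <- matrix(NA_real_, n_sites, length(accs), dimnames = list(NULL, accs))
  total <- matrix(NA_real_, n_sites, length(accs), dimnames = list(NULL, accs))
  idx <- cbind(si, ai)
  meth[idx] <- all$n_meth
  total[idx] <- all$n_total
  first <- !duplicated(key)
  sites <- data.frame(chrom = all$chrom[first], pos = all$pos[first],
                      strand = all$strand[first], context = all$context[first],
                      stringsAsFactors = FALSE)
  # presence rule: non-missing in >= min_fraction_present of each population
  pops <- populations[accs]
  keep <- rep(TRUE, n_sites)
  for (p in unique(pops)) {
    cols <- which(pops == p)
    frac <- rowMeans(!is.na(total[, cols, drop = FALSE]))
    keep <- keep & frac >= min_fraction_present
  }
  if (!any(keep)) {
    warning("zero sites retained after the presence filter")
    return(empty_meth_matrix(accs, populations))
  }
  sites <- sites[keep, , drop = FALSE]
  meth <- meth[keep, , drop = FALSE]
  total <- total[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  m <- list(sites = sites, meth = meth[ord, , drop = FALSE],
            total = total[ord, , drop = FALSE],
            level = meth[ord, , drop = FALSE] / total[ord, , drop = FALSE],
            accessions = accs, populations = pops,
            min_reads = min_reads)
  class(m) <- "meth_matrix"
  m
}

empty_meth_matrix <- function(accs, populations) {
  m <- list(sites = data.frame(chrom = character(), pos = integer(),
                               strand = character(), context = character()),
            meth = matrix(numeric(), 0, length(accs),
                          dimnames = list(NULL, accs)),
            total = matrix(numeric(), 0, length(accs),
                           dimnames = list(NULL, accs)),
            level = matrix(numeric(), 0, length(accs),
                           dimnames = list(NULL, accs)),
            accessions = accs, populations = populations[accs],
            min_reads = NA_real_)
  class(m) <- "meth_matrix"
  m
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$sites), "sites x", length(x$accessions),
      "accessions\n")
  if (nrow(x$sites)) {
    tab <- table(x$sites$context)
    cat("  contexts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  populations:", paste(names(table(x$populations)),
                              table(x$populations), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Weighted methylation level of a region
#'
#' Pooled-count level over the sites of one context inside a 0-based
#' half-open interval: sum(n_meth) / sum(n_total) per accession. Returns
#' NA for accessions with no covered site in the region.
#'
#' @param m A \code{meth_matrix}.
#' @param chrom,start,end Region (0-based half-open).
#' @param context Context of the sites to pool.
#' @param accessions Subset of accessions (default all).
#' @return Named numeric vector of levels per accession.
#' @export
region_methylation_level <- function(m, chrom, start, end, context,
                                     accessions = m$accessions) {
  if (end <= start) stop("empty region [", start, ", ", end, ")")
  sel <- m$sites$chrom == chrom & m$sites$context == context &
    (m$sites$pos - 1) >= start & (m$sites$pos - 1) < end
  if (!any(sel)) {
    res <- stats::setNames(rep(NA_real_, length(accessions)), accessions)
    attr(res, "no_sites") <- TRUE
    return(res)
  }
  mm <- m$meth[sel, accessions, drop = FALSE]
  tt <- m$total[sel, accessions, drop = FALSE]
  num <- colSums(mm, na.rm = TRUE)
  den <- colSums(tt, na.rm = TRUE)
  res <- ifelse(den > 0, num / den, NA_real_)
  stats::setNames(res, accessions)
}

#' Per-window mean methylation along chromosomes
#'
#' Tiles each chromosome with non-overlapping windows and reports the mean
#' site-level methylation per window, context and population (site level =
#' mean level across the population's accessions).
#'
#' @param m A \code{meth_matrix}.
#' @param window Window size in bp (default 500 kb).
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default the last covered site defines the extent.
#' @return data.frame(chrom, start, end, context, population, level, n_sites).
#' @export
chromosome_window_levels <- function(m, window = 5e5, chrom_lengths = NULL) {
  stopifnot(window > 0)
  pops <- unique(m$populations)
  out <- list()
  for (ch in unique(m$sites$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(m$sites$pos[m$sites$chrom == ch])
    starts <- seq(0, max(0, len - 1), by = window)
    for (ctx in unique(m$sites$context)) {
      sel <- m$sites$chrom == ch & m$sites$context == ctx
      pos0 <- m$sites$pos[sel] - 1
      win <- findInterval(pos0, starts)
      for (p in pops) {
        cols <- names(m$populations)[m$populations == p]
        slev <- rowMeans(m$level[sel, cols, drop = FALSE], na.rm = TRUE)
        agg_mean <- tapply(slev, win, mean, na.rm = TRUE)
        agg_n <- tapply(slev, win, length)
        lev <- rep(NA_real_, length(starts))
        n <- rep(0L, length(starts))
        iw <- as.integer(names(agg_mean))
        lev[iw] <- agg_mean
        n[iw] <- agg_n
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = starts, end = pmin(starts + window, len),
          context = ctx, population = p, level = lev, n_sites = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Map 0-based site positions onto the 80-bin profile of one feature.
# Bins 1..20 = 5' flank, 21..60 = body, 61..80 = 3' flank.
profile_bin <- function(pos0, start, end, strand, flank, bins) {
  if (strand == "-") pos0 <- start + end - 1 - pos0   # reflect onto + layout
  n_up <- bins[1]; n_body <- bins[2]; n_down <- bins[3]
  len <- end - start
  b <- rep(NA_integer_, length(pos0))
  up <- pos0 >= start - flank & pos0 < start
  b[up] <- pmin(n_up, floor((pos0[up] - (start - flank)) / flank * n_up) + 1L)
  body <- pos0 >= start & pos0 < end
  b[body] <- n_up + pmin(n_body, floor((pos0[body] - start) / len * n_body) + 1L)
  down <- pos0 >= end & pos0 < end + flank
  b[down] <- n_up + n_body +
    pmin(n_down, floor((pos0[down] - end) / flank * n_down) + 1L)
  b
}

#' Methylation metaprofile over a feature set
#'
#' Averages methylation into 20 upstream, 40 body and 20 downstream bins
#' (5' to 3'; minus-strand features are reversed). Flanks are fixed-width;
#' body bins scale with feature length. Bin values are averaged first
#' within a feature, then across features.
#'
#' @param m A \code{meth_matrix}.
#' @param features data.frame(chrom, start, end, strand), 0-based half-open.
#' @param context Context to profile.
#' @param accessions Accessions averaged into the site-level signal.
#' @param flank Flank width in bp (default 2000).
#' @param bins Integer triple: upstream, body, downstream bin counts
#'   (default 20, 40, 20).
#' @return Object of class \code{metaprofile}: list(bins, n_features, context).
#' @export
feature_metaprofile <- function(m, features, context,
                                accessions = m$accessions,
                                flank = 2000, bins = c(20L, 40L, 20L)) {
  stopifnot(flank > 0, length(bins) == 3)
  nb <- sum(bins)
  sel <- m$sites$context == context
  slev <- rowMeans(m$level[sel, accessions, drop = FALSE], na.rm = TRUE)
  spos <- m$sites$pos[sel] - 1L
  schrom <- m$sites$chrom[sel]
  acc <- matrix(0, nrow(features), nb)
  cnt <- matrix(0L, nrow(features), nb)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    on <- which(schrom == f$chrom & spos >= f$start - flank &
                  spos < f$end + flank)
    if (!length(on)) next
    b <- profile_bin(spos[on], f$start, f$end, f$strand, flank, bins)
    ok <- !is.na(b) & !is.na(slev[on])
    if (!any(ok)) next
    sums <- tapply(slev[on][ok], b[ok], sum)
    ns <- tapply(slev[on][ok], b[ok], length)
    ib <- as.integer(names(sums))
    acc[i, ib] <- sums
    cnt[i, ib] <- ns
  }
  per_feature <- acc / ifelse(cnt > 0, cnt, NA)
  prof <- colMeans(per_feature, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  structure(list(bins = prof, n_features = nrow(features), context = context,
                 layout = bins, flank = flank),
            class = "metaprofile")
}

#' Genome-wide population methylation summary and stage comparisons
#'
#' Computes each accession's genome-wide weighted methylation level per
#' context, population means, and for each population pair a paired
#' two-sided t-test (accessions paired by rank of their genome-wide mean
#' within population, truncated to the smaller n) plus an unpaired Welch
#' test.
#'
#' @param m A \code{meth_matrix}.
#' @param stage_order Population labels from ancestral to derived
#'   (default wild, landrace, improved).
#' @return list(accession_means, population_means, tests).
#' @export
population_level_summary <- function(m, stage_order = c("wild", "landrace",
                                                        "improved")) {
  pops <- m$populations
  stages <- intersect(stage_order, unique(pops))
  contexts <- unique(m$sites$context)
  am <- list()
  for (ctx in contexts) {
    sel <- m$sites$context == ctx
    num <- colSums(m$meth[sel, , drop = FALSE], na.rm = TRUE)
    den <- colSums(m$total[sel, , drop = FALSE], na.rm = TRUE)
    am[[ctx]] <- num / den
  }
  accession_means <- do.call(rbind, lapply(contexts, function(ctx)
    data.frame(accession = m$accessions, population = unname(pops),
               context = ctx, level = unname(am[[ctx]]),
               stringsAsFactors = FALSE)))
  population_means <- stats::aggregate(level ~ context + population,
                                       accession_means, mean)
  tests <- list()
  pairs <- if (length(stages) >= 2)
    utils::combn(seq_along(stages), 2, simplify = FALSE) else list()
  for (ctx in contexts) {
    for (pr in pairs) {
      a <- stages[pr[1]]; b <- stages[pr[2]]
      xa <- sort(am[[ctx]][names(pops)[pops == a]])
      xb <- sort(am[[ctx]][names(pops)[pops == b]])
      if (length(xa) < 2 || length(xb) < 2) next
      n <- min(length(xa), length(xb))
      if (length(xa) != length(xb))
        warning("unequal population sizes for ", a, " vs ", b,
                "; pairing truncated to n = ", n)
      d <- xb[seq_len(n)] - xa[seq_len(n)]
      if (stats::sd(d) < 1e-12) {
        if (all(d == 0)) { tstat <- 0; p <- 1 }
        else {
          warning("zero variance of paired differences (", a, " vs ", b,
                  "); reporting p = 0 by convention")
          tstat <- sign(mean(d)) * Inf; p <- 0
        }
      } else {
        tt <- stats::t.test(xb[seq_len(n)], xa[seq_len(n)], paired = TRUE)
        tstat <- unname(tt$statistic); p <- tt$p.value
      }
      wt <- tryCatch(stats::t.test(xb, xa),
                     error = function(e) list(statistic = NA, p.value = NA))
      tests[[length(tests) + 1L]] <- data.frame(
        context = ctx, pop_a = a, pop_b = b, n_pairs = n,
        mean_a = mean(xa), mean_b = mean(xb),
        t_paired = tstat, p_paired = p,
        t_welch = unname(wt$statistic), p_welch = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(accession_means = accession_means,
       population_means = population_means,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Frequency spectrum of per-site methylation levels
#'
#' Bins mean per-site levels into ten equal-width classes
#' [0,0.1), ..., [0.9,1.0] (last bin closed) per context.
#'
#' @param m A \code{meth_matrix}.
#' @param accessions Accessions averaged per site (default all).
#' @return data.frame(context, bin_low, bin_high, frequency); frequencies
#'   sum to 1 within a context.
#' @export
context_site_spectrum <- function(m, accessions = m$accessions) {
  if (nrow(m$sites) == 0) stop("empty methylation matrix")
  out <- list()
  for (ctx in unique(m$sites$context)) {
    sel <- m$sites$context == ctx
    slev <- rowMeans(m$level[sel, accessions, drop = FALSE], na.rm = TRUE)
    slev <- slev[!is.na(slev)]
    b <- pmin(floor(slev * 10) + 1L, 10L)   # closes the last bin at 1.0
    freq <- tabulate(b, 10) / length(b)
    out[[ctx]] <- data.frame(context = ctx, bin_low = seq(0, 0.9, 0.1),
                             bin_high = seq(0.1, 1, 0.1), frequency = freq,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
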