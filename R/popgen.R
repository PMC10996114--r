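#' Read biallelic genotypes from a VCF
#'
#' Loads a multi-sample VCF, keeps biallelic SNPs, converts GT fields to
#' alt-allele dosages (0/1/2, NA when missing) and applies the site
#' filters: minor-allele frequency at least \code{maf_min} and missing
#' rate at most \code{max_missing}.
#'
#' @param path VCF path (plain text or gzipped).
#' @param samples Optional sample subset; an error lists any sample absent
#'   from the VCF.
#' @param maf_min MAF filter (default 0.05).
#' @param max_missing Maximum per-site missing fraction (default 0.7).
#' @return list(snps = data.frame(snp_id, chrom, pos, ref, alt, maf),
#'   dosage = SNPs x samples integer matrix).
#' @export
read_vcf_genotypes <- function(path, samples = NULL, maf_min = 0.05,
                               max_missing = 0.7) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("samples absent from VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt_clean %in% c("0/0")] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% c("1/1")] <- 2L
  fix <- vcfR::getFIX(v)
  snps <- data.frame(snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                     fix[, "ID"]),
                     chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  ncalled <- rowSums(!is.na(dos))
  miss <- 1 - ncalled / ncol(dos)
  af <- rowSums(dos, na.rm = TRUE) / (2 * pmax(ncalled, 1))
  maf <- pmin(af, 1 - af)
  keep <- miss <= max_missing & maf >= maf_min & ncalled > 0
  snps <- snps[keep, , drop = FALSE]
  snps$maf <- maf[keep]
  rownames(snps) <- NULL
  list(snps = snps, dosage = dos[keep, , drop = FALSE])
}

#' Per-site nucleotide diversity
#'
#' pi = 2 j (n - j) / (n (n - 1)) for alt-allele count j among n called
#' alleles: the expected fraction of differing allele pairs.
#'
#' @param j Alt allele count(s).
#' @param n Called allele count(s) (2 x called diploids).
#' @return Numeric; NA where n < 2.
#' @export
site_pi <- function(j, n) {
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

site_pi_from_dosage <- function(dos) {
  called <- rowSums(!is.na(dos))
  j <- rowSums(dos, na.rm = TRUE)
  site_pi(j, 2 * called)
}

# Sliding 0-based half-open windows over one chromosome.
sliding_windows <- function(chrom_len, window, step) {
  starts <- seq(0, max(0, chrom_len - 1), by = step)
  starts <- starts[starts < chrom_len]
  data.frame(start = starts, end = pmin(starts + window, chrom_len))
}

# Sum a per-SNP statistic over sliding windows via cumulative sums.
window_sums <- function(pos0, values, wins) {
  ord <- order(pos0)
  pos0 <- pos0[ord]; values <- values[ord]
  values[is.na(values)] <- 0
  cs <- c(0, cumsum(values))
  lo <- findInterval(wins$start - 0.5, pos0)
  hi <- findInterval(wins$end - 0.5, pos0)
  cs[hi + 1] - cs[lo + 1]
}

#' Sliding-window nucleotide diversity
#'
#' Per-bp pi in sliding windows (default 10 kb with a 1 kb step): the sum
#' of per-site pi over in-window SNPs divided by the window span.
#'
#' @param geno Genotype list from [read_vcf_genotypes()].
#' @param accessions Samples of the population scanned.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window,step Window and step sizes in bp (defaults 10000, 1000).
#' @return data.frame(chrom, start, end, pi, n_snps), 0-based half-open.
#' @export
window_diversity <- function(geno, accessions, chrom_lengths,
                             window = 10000, step = 1000) {
  stopifnot(window >= step)
  dos <- geno$dosage[, accessions, drop = FALSE]
  pi_site <- site_pi_from_dosage(dos)
  out <- list()
  for (ch in names(chrom_lengths)) {
    wins <- sliding_windows(chrom_lengths[[ch]], window, step)
    on <- geno$snps$chrom == ch
    pos0 <- geno$snps$pos[on] - 1
    wins$pi <- window_sums(pos0, pi_site[on], wins) / (wins$end - wins$start)
    wins$n_snps <- as.integer(window_sums(pos0, rep(1, sum(on)), wins))
    wins$chrom <- ch
    out[[ch]] <- wins[, c("chrom", "start", "end", "pi", "n_snps")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Weir & Cockerham (1984) per-site variance components for two
# populations of diploids, from dosage rows. Returns matrix with columns
# a, b, c; rows where either population has < 2 called diploids are NA.
fst_components <- function(dos_a, dos_b) {
  n1 <- rowSums(!is.na(dos_a)); n2 <- rowSums(!is.na(dos_b))
  p1 <- rowSums(dos_a, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- rowSums(dos_b, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- rowMeans(dos_a == 1, na.rm = TRUE)
  h2 <- rowMeans(dos_b == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 < 2 | n2 < 2
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  cbind(a = a, b = b, c = cc)
}

#' Sliding-window Weir-Cockerham F_ST
#'
#' Per-site variance components a, b, c are summed over each window and
#' the window estimate is the ratio of sums, theta = sum(a) / sum(a+b+c)
#' (negative values retained). Windows with a zero denominator are NA.
#'
#' @param geno Genotype list from [read_vcf_genotypes()].
#' @param pop_a_accessions,pop_b_accessions Samples of the two populations.
#' @param chrom_lengths Named chromosome lengths.
#' @param window,step Window and step in bp (defaults 10000, 1000).
#' @return data.frame(chrom, start, end, fst, n_snps).
#' @export
window_fst <- function(geno, pop_a_accessions, pop_b_accessions,
                       chrom_lengths, window = 10000, step = 1000) {
  comp <- fst_components(geno$dosage[, pop_a_accessions, drop = FALSE],
                         geno$dosage[, pop_b_accessions, drop = FALSE])
  out <- list()
  for (ch in names(chrom_lengths)) {
    wins <- sliding_windows(chrom_lengths[[ch]], window, step)
    on <- geno$snps$chrom == ch
    pos0 <- geno$snps$pos[on] - 1
    sa <- window_sums(pos0, comp[on, "a"], wins)
    sabc <- window_sums(pos0, rowSums(comp)[on], wins)
    wins$fst <- ifelse(sabc != 0, sa / sabc, NA_real_)
    wins$n_snps <- as.integer(window_sums(pos0, as.numeric(!is.na(comp[on, "a"])), wins))
    wins$chrom <- ch
    out[[ch]] <- wins[, c("chrom", "start", "end", "fst", "n_snps")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint top-decile selective-sweep scan
#'
#' Ranks windows by the pi ratio pi_ancestral / pi_derived and by F_ST,
#' computes the empirical (1 - top_fraction) quantiles on this dataset,
#' selects windows strictly exceeding BOTH thresholds, and merges
#' overlapping or book-ended selected windows into sweep regions.
#' Windows with zero derived-population pi are excluded from the ratio
#' ranking (their count is reported).
#'
#' @param pi_anc,pi_der Window diversity frames for the ancestral and
#'   derived populations (same window grid).
#' @param fst Window F_ST frame on the same grid.
#' @param comparison Label, e.g. "domestication" or "improvement".
#' @param top_fraction Upper tail fraction (default 0.10).
#' @return list(thresholds = c(pi_ratio, fst), regions = data.frame(chrom,
#'   start, end, n_windows, comparison), windows (annotated grid),
#'   n_excluded_zero_pi).
#' @export
sweep_scan <- function(pi_anc, pi_der, fst, comparison = "domestication",
                       top_fraction = 0.10) {
  stopifnot(nrow(pi_anc) == nrow(pi_der), nrow(pi_anc) == nrow(fst))
  if (nrow(pi_anc) < 10) stop("fewer than 10 windows; quantiles ill-defined")
  w <- pi_anc[, c("chrom", "start", "end")]
  w$pi_ancestral <- pi_anc$pi
  w$pi_derived <- pi_der$pi
  w$fst <- fst$fst
  zero <- w$pi_derived == 0
  w$pi_ratio <- ifelse(zero, NA_real_, w$pi_ancestral / w$pi_derived)
  n_excluded <- sum(zero, na.rm = TRUE)
  thr_ratio <- stats::quantile(w$pi_ratio, 1 - top_fraction, na.rm = TRUE,
                               names = FALSE)
  thr_fst <- stats::quantile(w$fst, 1 - top_fraction, na.rm = TRUE,
                             names = FALSE)
  selected <- !is.na(w$pi_ratio) & !is.na(w$fst) &
    w$pi_ratio > thr_ratio & w$fst > thr_fst
  regions <- merge_intervals(w[selected, c("chrom", "start", "end")])
  if (nrow(regions)) regions$comparison <- comparison
  else regions <- data.frame(chrom = character(), start = integer(),
                             end = integer(), n_windows = integer(),
                             comparison = character())
  list(thresholds = c(pi_ratio = thr_ratio, fst = thr_fst),
       regions = regions, windows = w, n_excluded_zero_pi = n_excluded)
}

# Merge overlapping/book-ended 0-based half-open intervals per chromosome.
merge_intervals <- function(df) {
  if (!nrow(df))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer()))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             n_windows = lengths(red$revmap),
             stringsAsFactors = FALSE)
}

#' Per-region nucleotide diversity
#'
#' Sum of per-site pi over in-region SNPs divided by region length (bp),
#' for one population.
#'
#' @param geno Genotype list from [read_vcf_genotypes()].
#' @param regions data.frame(chrom, start, end), 0-based half-open.
#' @param accessions Samples of the population.
#' @return Numeric vector of per-bp pi, one per region.
#' @export
region_diversity <- function(geno, regions, accessions) {
  if (any(regions$end <= regions$start)) stop("zero-length region")
  dos <- geno$dosage[, accessions, drop = FALSE]
  pi_site <- site_pi_from_dosage(dos)
  pos0 <- geno$snps$pos - 1
  vapply(seq_len(nrow(regions)), function(i) {
    on <- geno$snps$chrom == regions$chrom[i] &
      pos0 >= regions$start[i] & pos0 < regions$end[i]
    sum(pi_site[on], na.rm = TRUE) / (regions$end[i] - regions$start[i])
  }, numeric(1))
}

#' Complement of a region set over the genome
#'
#' Non-selected regions (NSRs): the genome minus the union of the given
#' region sets.
#'
#' @param region_sets List of region data.frames (chrom, start, end).
#' @param chrom_lengths Named chromosome lengths.
#' @return data.frame(chrom, start, end).
#' @export
complement_regions <- function(region_sets, chrom_lengths) {
  all <- do.call(rbind, lapply(region_sets, function(d)
    d[, c("chrom", "start", "end")]))
  genome <- GenomicRanges::GRanges(names(chrom_lengths),
                                   IRanges::IRanges(1, unlist(chrom_lengths)))
  if (!is.null(all) && nrow(all)) {
    occ <- GenomicRanges::GRanges(all$chrom,
                                  IRanges::IRanges(all$start + 1, all$end))
    res <- GenomicRanges::setdiff(genome, occ)
  } else res <- genome
  data.frame(chrom = as.character(GenomicRanges::seqnames(res)),
             start = GenomicRanges::start(res) - 1L,
             end = GenomicRanges::end(res), stringsAsFactors = FALSE)
}
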