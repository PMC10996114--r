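#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles via the Blom offset:
#' x_i -> qnorm((rank_i - 3/8) / (n + 1/4)). Ties receive average ranks;
#' missing values stay missing.
#'
#' @param x Numeric vector (>= 3 non-missing values).
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  out <- rep(NA_real_, length(x))
  if (stats::sd(x[ok]) == 0) {
    warning("all values identical; inverse normal transform returns zeros")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.375) / (n + 0.25))
  out
}

#' Identity-by-state kinship matrix
#'
#' K_ij = mean over SNPs (non-missing in both samples) of
#' 1 - |d_i - d_j| / 2, for dosages d in {0, 1, 2}.
#'
#' @param dosage SNPs x samples dosage matrix.
#' @return Symmetric n x n kinship matrix with unit diagonal.
#' @export
ibs_kinship <- function(dosage) {
  ns <- ncol(dosage)
  if (any(colSums(!is.na(dosage)) == 0))
    stop("accession(s) with all-missing genotypes: ",
         paste(colnames(dosage)[colSums(!is.na(dosage)) == 0], collapse = ", "))
  K <- matrix(1, ns, ns, dimnames = list(colnames(dosage), colnames(dosage)))
  for (i in seq_len(ns - 1)) {
    di <- dosage[, i]
    for (j in (i + 1):ns) {
      s <- 1 - abs(di - dosage[, j]) / 2
      K[i, j] <- K[j, i] <- mean(s, na.rm = TRUE)
    }
  }
  K
}

#' REML fit of the null mixed model
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma_g^2 K), e ~ N(0,
#' sigma_e^2 I) by restricted maximum likelihood: after an
#' eigendecomposition of K the profiled REML criterion is optimized over
#' log delta (delta = sigma_e^2 / sigma_g^2) on [-10, 10] by a grid pass
#' followed by Brent refinement in the bracketing interval. The rotation
#' is returned for reuse across SNPs.
#'
#' @param y Trait vector (typically inverse-normal transformed); missing
#'   entries are dropped together with their rows of K and X.
#' @param K Kinship matrix.
#' @param X Fixed-effect design matrix (default intercept only).
#' @return Object of class \code{lmm_null}: delta, sigma_g2, sigma_e2, h2,
#'   loglik, eigenvalues, rotation U, used sample names.
#' @export
lmm_null_fit <- function(y, K, X = NULL) {
  ok <- !is.na(y)
  y <- y[ok]
  K <- K[ok, ok, drop = FALSE]
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1) else X <- as.matrix(X)[ok, , drop = FALSE]
  q <- ncol(X)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    if (min(ev$values) < -1e-8)
      warning("kinship matrix not PSD; eigenvalues floored at 1e-6")
    ev$values <- pmax(ev$values, 1e-6)
  }
  U <- ev$vectors
  lambda <- ev$values
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  ldet_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus
  reml <- function(logdelta) {
    delta <- exp(logdelta)
    w <- lambda + delta
    XtWX <- crossprod(Xs, Xs / w)
    beta <- solve(XtWX, crossprod(Xs, ys / w))
    r <- ys - Xs %*% beta
    R <- sum(r^2 / w)
    -0.5 * ((n - q) * log(R / (n - q)) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus - ldet_xtx)
  }
  grid <- seq(-10, 10, length.out = 100)
  ll <- vapply(grid, reml, numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE)
  logdelta <- if (opt$objective >= ll[k]) opt$maximum else grid[k]
  delta <- exp(logdelta)
  w <- lambda + delta
  XtWX <- crossprod(Xs, Xs / w)
  beta <- solve(XtWX, crossprod(Xs, ys / w))
  r <- ys - Xs %*% beta
  sigma_g2 <- sum(r^2 / w) / (n - q)
  fit <- list(delta = delta, sigma_g2 = sigma_g2,
              sigma_e2 = delta * sigma_g2,
              h2 = 1 / (1 + delta),
              loglik = max(opt$objective, ll[k]),
              lambda = lambda, U = U, X = X, y = y,
              used = which(ok), beta = drop(beta))
  class(fit) <- "lmm_null"
  fit
}

#' @export
print.lmm_null <- function(x, ...) {
  cat("lmm_null: n =", length(x$y), " delta =", signif(x$delta, 4),
      " sigma_g2 =", signif(x$sigma_g2, 4),
      " h2 =", signif(x$h2, 3), "\n")
  invisible(x)
}

#' Mixed-model association scan (EMMAX approximation)
#'
#' For each trait the variance components are fixed at the null fit; each
#' SNP is then tested by a generalized-least-squares Wald test of beta = 0
#' in the rotated, whitened model, with two-sided p from the t
#' distribution on n - rank(X) - 1 degrees of freedom. Missing dosages
#' are mean-imputed per SNP; SNPs monomorphic in the analyzed samples are
#' skipped.
#'
#' @param traits Samples x traits matrix (columns named by trait id),
#'   already transformed.
#' @param geno Genotype list from [read_vcf_genotypes()] (samples must
#'   cover the trait rows).
#' @param K Kinship matrix over the trait samples.
#' @param X Fixed-effect design (default intercept + \code{n_pcs}
#'   genotype PCs).
#' @param n_pcs Number of genotype principal components added as
#'   covariates when X is NULL (default 2).
#' @return data.frame(snp_id, chrom, pos, dmr_id, beta, se, p_value).
#' @export
lmm_scan <- function(traits, geno, K, X = NULL, n_pcs = 2) {
  traits <- as.matrix(traits)
  samples <- rownames(traits)
  if (is.null(samples)) stop("traits must have sample rownames")
  dos <- geno$dosage[, samples, drop = FALSE]
  if (is.null(X)) {
    X <- matrix(1, length(samples), 1)
    if (n_pcs > 0) {
      G <- t(dos)
      cm <- colMeans(G, na.rm = TRUE)
      G[is.na(G)] <- 0
      G <- sweep(G, 2, cm)
      G[t(is.na(dos))] <- 0
      pcs <- stats::prcomp(G, center = FALSE)$x[, seq_len(min(n_pcs, ncol(G))),
                                                drop = FALSE]
      X <- cbind(X, pcs)
    }
  }
  # mean-impute dosages once
  Gimp <- dos
  rm <- rowMeans(Gimp, na.rm = TRUE)
  naidx <- which(is.na(Gimp), arr.ind = TRUE)
  if (nrow(naidx)) Gimp[naidx] <- rm[naidx[, 1]]
  mono <- apply(Gimp, 1, function(g) stats::var(g) == 0)
  out <- list()
  for (tr in colnames(traits)) {
    y <- traits[, tr]
    ok <- !is.na(y)
    if (sum(ok) < ncol(X) + 3) next
    fit <- lmm_null_fit(y, K, X = X)
    w <- fit$lambda + fit$delta
    A <- 1 / sqrt(w)
    ys <- drop(crossprod(fit$U, fit$y)) * A
    Xs <- crossprod(fit$U, fit$X) * A
    Gs <- (crossprod(fit$U, t(Gimp[, ok, drop = FALSE]))) * A
    qr_x <- qr(Xs)
    ytil <- qr.resid(qr_x, ys)
    Gtil <- qr.resid(qr_x, Gs)
    gg <- colSums(Gtil^2)
    gy <- drop(crossprod(Gtil, ytil))
    usable <- !mono & gg > 1e-12
    n_eff <- sum(ok)
    df <- n_eff - qr_x$rank - 1
    beta <- gy[usable] / gg[usable]
    rss <- sum(ytil^2) - beta * gy[usable]
    sigma2 <- pmax(rss, 0) / df
    se <- sqrt(sigma2 / gg[usable])
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    out[[tr]] <- data.frame(snp_id = geno$snps$snp_id[usable],
                            chrom = geno$snps$chrom[usable],
                            pos = geno$snps$pos[usable],
                            dmr_id = tr, beta = beta, se = se, p_value = p,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), dmr_id = character(), beta = numeric(),
                      se = numeric(), p_value = numeric())
  rownames(res) <- NULL
  res
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate (default 0.01).
#' @param n_tests Number of tests.
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.01, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Greedy LD clumping of associations
#'
#' Within each trait, associations are processed in ascending p order;
#' the best remaining SNP is retained and all SNPs within \code{window}
#' bp on the same chromosome whose genotype correlation r^2 with it is at
#' least \code{r2_max} are discarded.
#'
#' @param associations Association data.frame (snp_id, chrom, pos,
#'   dmr_id, p_value).
#' @param geno Genotype list (for the r^2 computation, pairwise-complete).
#' @param r2_max r^2 cutoff (default 0.25; retained SNPs satisfy
#'   r^2 < r2_max pairwise within the window).
#' @param window Clump window in bp (default 1 Mb).
#' @return The retained association rows; attribute \code{r2_threshold}.
#' @export
ld_clump <- function(associations, geno, r2_max = 0.25, window = 1e6) {
  if (!nrow(associations)) {
    attr(associations, "r2_threshold") <- r2_max
    return(associations)
  }
  dos <- geno$dosage
  rowidx <- match(associations$snp_id, geno$snps$snp_id)
  keep_all <- logical(nrow(associations))
  for (tr in unique(associations$dmr_id)) {
    ii <- which(associations$dmr_id == tr)
    ii <- ii[order(associations$p_value[ii])]
    accepted <- integer()
    for (i in ii) {
      ok <- TRUE
      for (j in accepted) {
        if (associations$chrom[i] == associations$chrom[j] &&
            abs(associations$pos[i] - associations$pos[j]) <= window) {
          r <- suppressWarnings(stats::cor(dos[rowidx[i], ], dos[rowidx[j], ],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 >= r2_max) { ok <- FALSE; break }
        }
      }
      if (ok) accepted <- c(accepted, i)
    }
    keep_all[accepted] <- TRUE
  }
  res <- associations[keep_all, , drop = FALSE]
  res <- res[order(res$dmr_id, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "r2_threshold") <- r2_max
  res
}

#' Classify associations as local or distal
#'
#' Distance is measured from the SNP position to the nearest edge of its
#' associated DMR (0 if inside). Local: same chromosome and distance at
#' most \code{local_dist}; distal otherwise (including different
#' chromosomes, distance Inf).
#'
#' @param associations Association data.frame with dmr_id.
#' @param dmrs DMR data.frame (dmr_id, chrom, start, end; 0-based
#'   half-open).
#' @param local_dist Locality bound in bp (default 1 Mb).
#' @return Associations with added \code{distance} and \code{locality}.
#' @export
classify_local_distal <- function(associations, dmrs, local_dist = 1e6) {
  m <- match(associations$dmr_id, dmrs$dmr_id)
  if (anyNA(m) && nrow(associations))
    stop("associations reference unknown DMR ids: ",
         paste(unique(associations$dmr_id[is.na(m)]), collapse = ", "))
  s0 <- associations$pos - 1  # SNP to 0-based
  dstart <- dmrs$start[m]; dend <- dmrs$end[m]
  same <- associations$chrom == dmrs$chrom[m]
  dist <- ifelse(!same, Inf,
                 ifelse(s0 >= dstart & s0 < dend, 0,
                        ifelse(s0 < dstart, dstart - s0, s0 - (dend - 1))))
  associations$distance <- dist
  associations$locality <- ifelse(same & dist <= local_dist, "local", "distal")
  associations
}

#' Pure-DMR accounting
#'
#' DMRs with no significant (thresholded, clumped) association are "pure"
#' - methylation variation not tagged by any SNP.
#'
#' @param dmrs DMR data.frame.
#' @param significant_associations Thresholded + clumped associations.
#' @return list(fraction, n_pure, n_total, pure_ids).
#' @export
pure_dmr_fraction <- function(dmrs, significant_associations) {
  tagged <- unique(significant_associations$dmr_id)
  pure <- setdiff(dmrs$dmr_id, tagged)
  list(fraction = if (nrow(dmrs)) length(pure) / nrow(dmrs) else NA_real_,
       n_pure = length(pure), n_total = nrow(dmrs), pure_ids = pure)
}
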