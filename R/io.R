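#' Write a simulated panel to disk
#'
#' Emits one Bismark-dialect cytosine report per replicate, a VCF 4.2
#' with GT fields, GFF3 gene annotation, BED6 TE annotation, the
#' expression TSV, the sample sheet, the planted-truth JSON, and a
#' manifest with MD5 checksums. All coordinates in files are 1-based
#' (reports, VCF, GFF3) except BED (0-based half-open, as BED defines).
#'
#' @param panel A \code{methylpop_panel}.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the manifest data.frame(file, md5).
#' @export
write_dataset <- function(panel, outdir) {
  stopifnot(inherits(panel, "methylpop_panel"))
  if (length(panel$accessions) == 0)
    stop("empty panel: no accessions to write")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  ## cytosine reports, one per replicate
  for (k in seq_len(nrow(panel$sample_sheet))) {
    rep_id <- panel$sample_sheet$replicate[k]
    f <- file.path(outdir, paste0(rep_id, ".CX_report.txt"))
    n_meth <- panel$meth_rep[, rep_id]
    rpt <- data.frame(panel$sites$chrom, panel$sites$pos,
                      panel$sites$strand, n_meth,
                      panel$total_rep[, rep_id] - n_meth,
                      panel$sites$context, panel$sites$trinucleotide)
    data.table::fwrite(rpt, f, sep = "\t", col.names = FALSE)
    files <- c(files, f)
  }

  ## sample sheet
  sheet <- panel$sample_sheet
  sheet$file <- paste0(sheet$replicate, ".CX_report.txt")
  f <- file.path(outdir, "sample_sheet.tsv")
  data.table::fwrite(sheet, f, sep = "\t")
  files <- c(files, f)

  ## VCF 4.2
  f <- file.path(outdir, "genotypes.vcf")
  snps <- panel$genotypes$snps
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- matrix("./.", nrow(snps), length(panel$accessions))
  ok <- !is.na(panel$genotypes$dosage)
  gt[ok] <- gt_code[as.character(panel$genotypes$dosage[ok])]
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(panel$annotation$chrom_lengths),
                   panel$annotation$chrom_lengths),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$accessions), collapse = "\t"))
  body <- do.call(paste, c(list(snps$chrom, snps$pos, snps$snp_id, snps$ref,
                                snps$alt, ".", "PASS", ".", "GT"),
                           lapply(seq_len(ncol(gt)), function(j) gt[, j]),
                           sep = "\t"))
  writeLines(c(hdr, body), f)
  files <- c(files, f)

  ## GFF3 (genes + exons) and BED6 (TEs)
  f <- file.path(outdir, "genes.gff3")
  g <- panel$annotation$genes
  e <- panel$annotation$exons
  gff <- c("##gff-version 3",
           sprintf("%s\tmethylpop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
           sprintf("%s\tmethylpop\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                   e$chrom, e$start + 1L, e$end,
                   g$strand[match(e$gene_id, g$gene_id)],
                   paste0(e$gene_id, ".e", stats::ave(seq_len(nrow(e)),
                                                      e$gene_id,
                                                      FUN = seq_along)),
                   e$gene_id))
  writeLines(gff, f)
  files <- c(files, f)

  f <- file.path(outdir, "tes.bed")
  te <- panel$annotation$tes
  data.table::fwrite(data.frame(te$chrom, te$start, te$end, te$class, 0L, "+"),
                     f, sep = "\t", col.names = FALSE)
  files <- c(files, f)

  ## expression matrix
  f <- file.path(outdir, "expression.tsv")
  ex <- data.frame(gene_id = rownames(panel$expression),
                   panel$expression, check.names = FALSE)
  data.table::fwrite(ex, f, sep = "\t")
  files <- c(files, f)

  ## planted truth
  f <- file.path(outdir, "truth.json")
  jsonlite::write_json(panel$truth, f, dataframe = "rows", digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

#' Read a written dataset back into per-accession records
#'
#' Convenience loader pairing [read_cytosine_report()] and
#' [pool_replicates()] using the written sample sheet.
#'
#' @param dir Dataset directory produced by [write_dataset()].
#' @return list(accession_records, populations, sample_sheet).
#' @export
read_dataset_methylomes <- function(dir) {
  sheet <- as.data.frame(data.table::fread(file.path(dir, "sample_sheet.tsv")))
  recs <- lapply(sheet$file, function(f)
    read_cytosine_report(file.path(dir, f)))
  names(recs) <- sheet$replicate
  pooled <- pool_replicates(recs, sheet)
  pops <- stats::setNames(sheet$population[!duplicated(sheet$accession)],
                          sheet$accession[!duplicated(sheet$accession)])
  list(accession_records = pooled, populations = pops, sample_sheet = sheet)
}
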