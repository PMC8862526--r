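#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records (single-base REF and ALT) are retained;
#' multiallelic and INDEL records are dropped with a message. Phasing is
#' ignored; `./.` (or `.`) genotypes become code -1.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   samples; unknown names are an error.
#' @return a [geno_matrix()] with chromosome lengths taken from `##contig`
#'   headers when present.
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no variant records in ", path)
  if (ncol(vcf@gt) < 2 || !all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("VCF has no GT field")
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0) message(n_drop, " non-biallelic-SNP record(s) dropped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  avail <- colnames(gt)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, avail)
    if (length(missing_s)) stop("unknown sample name(s): ",
                                paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  gt <- gt[snp, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- matrix(-1L, nrow = nrow(gt), ncol = ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  code[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  # contig lengths from the header, if declared
  meta <- vcf@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  cl <- NULL
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    has_len <- grepl("length=", contig)
    if (any(has_len)) {
      lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", contig)))
      cl <- stats::setNames(lens[has_len], ids[has_len])
    }
  }
  geno_matrix(t(code), chrom = fix[snp, "CHROM"],
              pos = as.integer(fix[snp, "POS"]),
              ref = ref[snp], alt = alt[snp],
              sample_ids = colnames(gt), chrom_lengths = cl)
}

#' Write a genotype matrix as VCF 4.2 (GT only)
#'
#' @param gm a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  cl <- chrom_lengths(gm)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  gt_str <- c("./.", "0/0", "0/1", "1/1")[gm$geno + 2L]
  dim(gt_str) <- dim(gm$geno)
  body <- paste(gm$variants$chrom, gm$variants$pos, ".", gm$variants$ref,
                gm$variants$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write small headered TSV tables
#'
#' Convenience wrappers used for the metadata interchange formats
#' (sibling-pair tables, population assignments, ancestral-allele tables,
#' phenotype tables).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
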