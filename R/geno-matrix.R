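#' Construct a genotype matrix
#'
#' The common currency of the pipeline: biallelic SNP genotypes for a set of
#' lines, coded 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate) and -1 (missing). Variants are kept sorted by chromosome and
#' position.
#'
#' @param geno integer matrix, samples in rows, variants in columns, codes in
#'   \{-1, 0, 1, 2\}.
#' @param chrom,pos,ref,alt per-variant chromosome, 1-based position (as in
#'   VCF), reference and alternate allele (single bases).
#' @param sample_ids character vector of line identifiers; defaults to the row
#'   names of `geno`.
#' @param chrom_lengths optional named vector of chromosome lengths in bp.
#'   When absent, lengths are derived on demand from the maximum variant
#'   position.
#' @return An object of class `geno_matrix`: a list with elements
#'   `sample_ids`, `variants` (data.frame with chrom, pos, ref, alt) and
#'   `geno`, plus a `chrom_lengths` attribute.
#' @export
geno_matrix <- function(geno, chrom, pos, ref, alt, sample_ids = rownames(geno),
                        chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(geno)))
  stopifnot(length(sample_ids) == nrow(geno),
            length(chrom) == ncol(geno), length(pos) == ncol(geno))
  bad <- !(geno %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) stop("genotype codes must be in {-1, 0, 1, 2}")
  chrom <- as.character(chrom)
  ord <- order(match(chrom, unique(chrom)), pos)
  variants <- data.frame(chrom = chrom[ord], pos = as.integer(pos[ord]),
                         ref = as.character(ref)[ord], alt = as.character(alt)[ord],
                         stringsAsFactors = FALSE)
  dup <- duplicated(variants[c("chrom", "pos")])
  if (any(dup)) {
    variants <- variants[!dup, , drop = FALSE]
    ord <- ord[!dup]
    warning(sum(dup), " duplicated positions dropped")
  }
  rownames(geno) <- sample_ids
  obj <- list(sample_ids = as.character(sample_ids), variants = variants,
              geno = geno[, ord, drop = FALSE])
  attr(obj, "chrom_lengths") <- chrom_lengths
  class(obj) <- "geno_matrix"
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "biallelic SNPs on",
      length(unique(x$variants$chrom)), "chromosomes\n")
  miss <- mean(x$geno == -1L)
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param x a [geno_matrix()].
#' @param samples character vector of sample ids (or integer indices).
#' @param variants integer or logical index over variant columns.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  si <- seq_along(x$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$sample_ids) else samples
    if (anyNA(si)) stop("unknown sample(s): ",
                        paste(samples[is.na(si)], collapse = ", "))
  }
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  geno_matrix(x$geno[si, vi, drop = FALSE],
              x$variants$chrom[vi], x$variants$pos[vi],
              x$variants$ref[vi], x$variants$alt[vi],
              sample_ids = x$sample_ids[si],
              chrom_lengths = attr(x, "chrom_lengths"))
}

#' Chromosome lengths of a genotype matrix
#'
#' Uses VCF contig headers when they were present; otherwise the maximum
#' variant position rounded up to a whole window, so that a deterministic
#' window grid exists without an external genome index.
#'
#' @param gm a [geno_matrix()].
#' @param window_size bp used for the rounding fallback.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(gm, window_size = 1e4) {
  cl <- attr(gm, "chrom_lengths")
  chroms <- unique(gm$variants$chrom)
  if (!is.null(cl) && all(chroms %in% names(cl))) return(cl[chroms])
  mx <- tapply(gm$variants$pos, factor(gm$variants$chrom, levels = chroms), max)
  out <- ceiling(as.numeric(mx) / window_size) * window_size
  names(out) <- chroms
  out
}

#' Filter variants on missingness and minor allele frequency
#'
#' Minor allele frequency is computed from allele dosage over non-missing
#' genotypes; variants exactly at the threshold are retained (`>=`).
#'
#' @param gm a [geno_matrix()].
#' @param max_missing_frac maximum tolerated fraction of missing genotypes.
#' @param min_maf minimum minor-allele frequency.
#' @return filtered `geno_matrix` (possibly with zero variants, with a
#'   warning).
#' @export
filter_variants <- function(gm, max_missing_frac = 1, min_maf = 0) {
  stopifnot(inherits(gm, "geno_matrix"),
            max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 1)
  g <- gm$geno
  nonmiss <- colSums(g != -1L)
  missfrac <- 1 - nonmiss / nrow(g)
  dos <- g
  dos[dos == -1L] <- 0L
  p <- ifelse(nonmiss > 0, colSums(dos) / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- missfrac <= max_missing_frac & !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("no variants pass the filters; returning empty matrix")
  subset_geno(gm, variants = which(keep))
}

#' Genotype-level heterozygosity rate per line
#'
#' Heterozygous calls over non-missing calls, optionally excluding
#' chromosomes (e.g. the sex chromosome of heterogametic individuals).
#'
#' @param gm a [geno_matrix()].
#' @param exclude_chroms chromosomes left out of the tally.
#' @return named numeric vector, one rate per line.
#' @export
het_rate <- function(gm, exclude_chroms = NULL) {
  keep <- !(gm$variants$chrom %in% exclude_chroms)
  g <- gm$geno[, keep, drop = FALSE]
  rowSums(g == 1L) / pmax(rowSums(g != -1L), 1L)
}
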