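#' Build a non-overlapping window grid over chromosomes
#'
#' Windows are 0-based half-open tiles (`[start, end)`, BED convention): a
#' variant at VCF position `p` belongs to window `floor((p - 1)/window_size)`.
#' The terminal window of a chromosome may be shorter.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @return object of class `window_grid`: data.frame with chrom, start, end
#'   plus `window_size` and `chrom_lengths` attributes.
#' @export
window_grid <- function(chrom_lengths, window_size) {
  stopifnot(window_size > 0, all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    start <- seq(0, L - 1, by = window_size)
    data.frame(chrom = ch, start = start, end = pmin(start + window_size, L),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  attr(g, "window_size") <- window_size
  attr(g, "chrom_lengths") <- chrom_lengths
  class(g) <- c("window_grid", "data.frame")
  g
}

# window index (1-based, into the rows of `grid`) for variant coordinates
window_index <- function(grid, chrom, pos) {
  ws <- attr(grid, "window_size")
  cl <- attr(grid, "chrom_lengths")
  if (!all(unique(chrom) %in% names(cl)))
    stop("grid does not cover chromosome(s): ",
         paste(setdiff(unique(chrom), names(cl)), collapse = ", "))
  if (any(pos > cl[chrom] | pos < 1))
    stop("variant position beyond declared chromosome length")
  nwin <- ceiling(cl / ws)
  offset <- stats::setNames(cumsum(c(0, nwin[-length(nwin)])), names(nwin))
  as.integer(offset[chrom] + (pos - 1) %/% ws + 1)
}

#' Count heterozygous SNPs per line in genomic windows
#'
#' The input for the homozygosity HMM: for every line, the number of
#' heterozygous genotypes in each window of `grid`, together with the number
#' of genotyped (non-missing) SNPs.
#'
#' @param gm a [geno_matrix()].
#' @param grid a [window_grid()] covering every chromosome present in `gm`.
#' @return object of class `window_counts`: list with `grid`, `counts`
#'   (lines x windows), `n_sites` and `sample_ids`.
#' @export
window_het_counts <- function(gm, grid) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(grid, "window_grid"))
  w <- window_index(grid, gm$variants$chrom, gm$variants$pos)
  nw <- nrow(grid)
  nl <- length(gm$sample_ids)
  counts <- matrix(0L, nl, nw, dimnames = list(gm$sample_ids, NULL))
  n_sites <- counts
  for (l in seq_len(nl)) {
    g <- gm$geno[l, ]
    counts[l, ] <- tabulate(w[g == 1L], nbins = nw)
    n_sites[l, ] <- tabulate(w[g != -1L], nbins = nw)
  }
  structure(list(grid = grid, counts = counts, n_sites = n_sites,
                 sample_ids = gm$sample_ids),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", nrow(x$counts), "lines x", ncol(x$counts),
      "windows of", attr(x$grid, "window_size"), "bp\n")
  invisible(x)
}

#' Export window counts as TSV (line, chrom, start, end, n_het, n_sites)
#'
#' @param wc a [window_het_counts()] result.
#' @param path output file.
#' @export
write_window_counts <- function(wc, path) {
  long <- data.frame(line = rep(wc$sample_ids, each = nrow(wc$grid)),
                     chrom = rep(wc$grid$chrom, length(wc$sample_ids)),
                     start = rep(wc$grid$start, length(wc$sample_ids)),
                     end = rep(wc$grid$end, length(wc$sample_ids)),
                     n_het = as.vector(t(wc$counts)),
                     n_sites = as.vector(t(wc$n_sites)))
  write_tsv_table(long, path)
}
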