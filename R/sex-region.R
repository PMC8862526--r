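# Refinement of obligate-heterozygous regions (e.g. the sex-determining
# segment kept heterozygous in heterogametic males) from per-window
# heterozygosity tracks.

#' Proportion of lines with more than `threshold` het SNPs per window
#'
#' The count-based heterozygosity track: for each window, the fraction of
#' lines whose heterozygous-SNP count strictly exceeds the threshold.
#'
#' @param wc a [window_het_counts()] result.
#' @param threshold integer; strict inequality (`count > threshold`).
#' @return numeric vector, one fraction per window of the grid.
#' @export
het_proportion_by_count <- function(wc, threshold = 5L) {
  stopifnot(inherits(wc, "window_counts"), threshold >= 0)
  colMeans(wc$counts > threshold)
}

#' HMM-weighted per-window heterozygosity estimate
#'
#' Each line contributes the min-max normalised emission rate of its decoded
#' state: state 0 has weight 0, the most heterozygous state weight 1, so
#' states with higher heterozygosity levels contribute more.
#'
#' @param paths a `state_paths` object (typically from a 4-state fit).
#' @param object the `poisson_hmm` the paths were decoded with.
#' @return numeric vector, one weighted fraction per window.
#' @export
het_proportion_weighted <- function(paths, object) {
  stopifnot(inherits(paths, "state_paths"), inherits(object, "poisson_hmm"),
            paths$K == object$K)
  lam <- object$lambda
  if (lam[object$K] <= lam[1] + 1e-12)
    stop("degenerate model: emission rates are not separated")
  w <- (lam - lam[1]) / (lam[object$K] - lam[1])
  colMeans(matrix(w[paths$states + 1L], nrow(paths$states)))
}

#' Build a per-chromosome heterozygosity-proportion track
#'
#' Combines the count-based and HMM-weighted estimates for one chromosome.
#'
#' @param wc a [window_het_counts()] result.
#' @param paths decoded `state_paths` on the same grid.
#' @param object the fitted `poisson_hmm`.
#' @param chrom target chromosome.
#' @param threshold het-SNP count threshold for the count-based track.
#' @return object of class `het_track`: list with `chrom`, `windows`
#'   (data.frame chrom/start/end), `count_based`, `weighted`.
#' @export
het_proportion_track <- function(wc, paths, object, chrom, threshold = 5L) {
  sel <- wc$grid$chrom == chrom
  if (!any(sel)) stop("chromosome ", chrom, " not in grid")
  structure(list(chrom = chrom,
                 windows = as.data.frame(wc$grid)[sel, c("chrom", "start", "end")],
                 count_based = het_proportion_by_count(wc, threshold)[sel],
                 weighted = het_proportion_weighted(paths, object)[sel]),
            class = "het_track")
}

#' @export
print.het_track <- function(x, ...) {
  cat("het_track on", x$chrom, ":", nrow(x$windows), "windows; weighted range",
      sprintf("[%.3f, %.3f]\n", min(x$weighted), max(x$weighted)))
  invisible(x)
}

#' Write a heterozygosity track as TSV
#'
#' @param track a [het_proportion_track()] result.
#' @param path output file.
#' @export
write_het_track <- function(track, path) {
  write_tsv_table(cbind(track$windows, count_based = track$count_based,
                        weighted = track$weighted), path)
}

#' Locate the obligate-heterozygous region on a track
#'
#' Returns the longest contiguous run of windows whose weighted
#' heterozygosity estimate is at least `min_level`, provided its span
#' reaches `min_span`. Coordinates are reported 1-based inclusive.
#'
#' @param track a `het_track`.
#' @param min_level minimum weighted het proportion defining the region.
#' @param min_span minimum region span in bp.
#' @return data.frame with columns chrom, start, end, n_windows, mean_level;
#'   zero rows when no run qualifies.
#' @export
refine_obligate_het_region <- function(track, min_level = 0.8, min_span = 3e5) {
  stopifnot(inherits(track, "het_track"))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), mean_level = numeric())
  above <- track$weighted >= min_level
  if (!any(above)) return(empty)
  r <- rle(above)
  last <- cumsum(r$lengths)
  first <- c(1L, utils::head(last, -1) + 1L)
  runs <- data.frame(first = first[r$values], last = last[r$values])
  runs$start <- track$windows$start[runs$first]
  runs$end <- track$windows$end[runs$last]
  runs$span <- runs$end - runs$start
  best <- runs[which.max(runs$span), ]
  if (best$span < min_span) return(empty)
  data.frame(chrom = track$chrom, start = best$start + 1L, end = best$end,
             n_windows = best$last - best$first + 1L,
             mean_level = mean(track$weighted[best$first:best$last]))
}
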