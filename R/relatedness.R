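# Identity-by-state relatedness: pairwise IBS similarity, average-linkage
# clustering with deterministic leaf order, sibling-pair adjacency in the
# dendrogram, and windowed haplotype-sharing fractions between line pairs.

#' Pairwise identity-by-state matrix
#'
#' Mean per-site IBS similarity `(2 - |dosage_a - dosage_b|)/2` over sites
#' non-missing in both samples; `1 - IBS` is the clustering distance.
#'
#' @param gm a [geno_matrix()] with at least two samples.
#' @return symmetric numeric matrix in [0, 1] with unit diagonal; NA for
#'   pairs with no shared genotyped site.
#' @export
ibs_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"), length(gm$sample_ids) >= 2)
  D <- gm$geno
  storage.mode(D) <- "double"
  M <- (D != -1) * 1
  D0 <- D * M            # dosages, zeroed where missing (missing code is -1)
  G1 <- (D >= 1) * 1
  G2 <- (D == 2) * 1
  N <- M %*% t(M)
  # sum over shared sites of |da - db| = da + db - 2 * min(da, db),
  # with min(da, db) = [da>=1][db>=1] + [da==2][db==2]
  S1 <- D0 %*% t(M)
  Sabs <- S1 + t(S1) - 2 * (G1 %*% t(G1) + G2 %*% t(G2))
  ibs <- 1 - Sabs / (2 * N)
  ibs[N == 0] <- NA_real_
  diag(ibs) <- 1
  dimnames(ibs) <- list(gm$sample_ids, gm$sample_ids)
  ibs
}

#' Cluster lines on 1 - IBS with deterministic leaf order
#'
#' Average-linkage hierarchical clustering of the IBS distance; samples are
#' sorted lexicographically before clustering so that ties resolve
#' identically across runs.
#'
#' @param ibs an [ibs_matrix()] result (complete; missing entries are an
#'   error instructing imputation).
#' @return object of class `ibs_clustering`: list with `order` (leaf labels
#'   left to right), `hclust` and `linkage`.
#' @export
cluster_and_order <- function(ibs) {
  if (anyNA(ibs[upper.tri(ibs)]))
    stop("IBS matrix has missing entries; impute them first, e.g. with the ",
         "matrix mean of the defined off-diagonal entries")
  ord0 <- order(rownames(ibs))
  ibs <- ibs[ord0, ord0]
  hc <- stats::hclust(stats::as.dist(1 - ibs), method = "average")
  structure(list(order = rownames(ibs)[hc$order], hclust = hc,
                 linkage = "average"),
            class = "ibs_clustering")
}

#' @export
print.ibs_clustering <- function(x, ...) {
  cat("ibs_clustering (", x$linkage, " linkage): ",
      length(x$order), " leaves\n", sep = "")
  invisible(x)
}

#' Export an IBS clustering as Newick
#'
#' @param clustering an [cluster_and_order()] result.
#' @param path output file.
#' @export
write_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Fraction of sibling pairs adjacent in the leaf order
#'
#' @param order character vector of leaf labels (from [cluster_and_order()]).
#' @param pairs data.frame with columns `line_a`, `line_b` (each line in at
#'   most one pair); all paired lines must appear in `order`.
#' @return fraction of pairs occupying adjacent leaf positions.
#' @export
sibling_adjacency_fraction <- function(order, pairs) {
  pa <- match(pairs$line_a, order)
  pb <- match(pairs$line_b, order)
  if (anyNA(pa) || anyNA(pb)) stop("paired line absent from leaf order")
  mean(abs(pa - pb) == 1)
}

#' Windowed haplotype-sharing fraction between two lines
#'
#' A window is "shared" when the mean per-site IBS between the two lines
#' reaches `identity_floor` — for near-isogenic lines, windows where both
#' fixed the same founder haplotype. Two denominators are available:
#' `"co_fixed"` (default) restricts to windows where each line is itself
#' fixed (its within-line heterozygous-site fraction is at most
#' `1 - identity_floor`), measuring the probability that the two lines fixed
#' the same haplotype; `"all"` divides by every co-genotyped window, which
#' additionally discounts genome not yet fixed in either line.
#'
#' @param gm a [geno_matrix()].
#' @param line_a,line_b sample ids.
#' @param grid a [window_grid()] (10-kb in the reference analysis).
#' @param identity_floor per-window mean-IBS threshold declaring identity;
#'   the default 0.99 tolerates residual heterozygosity and genotype error.
#' @param denominator see Details.
#' @return fraction in [0, 1]; NA when no window qualifies.
#' @export
pairwise_sharing_fraction <- function(gm, line_a, line_b, grid,
                                      identity_floor = 0.99,
                                      denominator = c("co_fixed", "all")) {
  denominator <- match.arg(denominator)
  ia <- match(line_a, gm$sample_ids)
  ib <- match(line_b, gm$sample_ids)
  if (is.na(ia) || is.na(ib)) stop("unknown line id")
  da <- gm$geno[ia, ]
  db <- gm$geno[ib, ]
  ok <- da != -1L & db != -1L
  w <- window_index(grid, gm$variants$chrom, gm$variants$pos)
  nw <- nrow(grid)
  n_ok <- tabulate(w[ok], nbins = nw)
  ibs_sum <- rep(0, nw)
  s <- rowsum((2 - abs(da[ok] - db[ok])) / 2, w[ok])
  ibs_sum[as.integer(rownames(s))] <- s
  mean_ibs <- ifelse(n_ok > 0, ibs_sum / n_ok, NA_real_)
  if (denominator == "co_fixed") {
    het_tol <- 1 - identity_floor
    fixed_frac <- function(d) {
      nm <- tabulate(w[d != -1L], nbins = nw)
      het <- tabulate(w[d == 1L], nbins = nw)
      ifelse(nm > 0, het / nm, NA_real_)
    }
    in_denom <- n_ok > 0 & fixed_frac(da) <= het_tol & fixed_frac(db) <= het_tol
  } else {
    in_denom <- n_ok > 0
  }
  in_denom[is.na(in_denom)] <- FALSE
  if (!any(in_denom)) return(NA_real_)
  mean(mean_ibs[in_denom] >= identity_floor)
}

#' Write an IBS matrix as TSV
#'
#' @param ibs an [ibs_matrix()] result.
#' @param path output file.
#' @export
write_ibs_matrix <- function(ibs, path) {
  df <- data.frame(sample = rownames(ibs), ibs, check.names = FALSE)
  write_tsv_table(df, path)
}
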